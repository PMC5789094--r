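# On-disk formats: localization CSV with a mandatory metadata header,
# YAML configuration, 16-bit grayscale TIFF images, reference-pitch CSV,
# and text exports of budgets, candidates, fits and transforms.

#' Write a localization table to CSV
#'
#' The dialect is a plain CSV with header
#' `frame,x_nm,y_nm,photons,sigma_nm,source`, preceded by `#`-prefixed
#' metadata lines (`pixel_size_nm`, `frame_time_s`, optionally `seed`).
#' Coordinates and precisions are written at 3 decimals (0.001 nm).
#'
#' @param table a [localization_table()]; its metadata attributes are
#'   mandatory.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_localizations <- function(table, path) {
  px <- attr(table, "pixel_size")
  ft <- attr(table, "frame_time")
  if (is.null(px) || is.null(ft))
    stop("localization table lacks pixel_size/frame_time metadata",
         call. = FALSE)
  seed <- attr(table, "seed")
  hdr <- c(sprintf("# pixel_size_nm: %.10g", px),
           sprintf("# frame_time_s: %.10g", ft))
  if (!is.null(seed) && !is.na(seed))
    hdr <- c(hdr, sprintf("# seed: %d", as.integer(seed)))
  fld <- attr(table, "field")
  if (!is.null(fld))
    hdr <- c(hdr, sprintf("# field_nm: %.10g %.10g", fld[1], fld[2]))
  body <- sprintf("%d,%.3f,%.3f,%.10g,%.3f,%s",
                  table$frame, table$x_nm, table$y_nm,
                  table$photons, table$sigma_nm, table$source)
  writeLines(c(hdr, "frame,x_nm,y_nm,photons,sigma_nm,source", body), path)
  invisible(path)
}

#' Read a localization table from CSV
#'
#' @param path file written by [write_localizations()] (or any CSV in the
#'   same dialect). Missing `pixel_size_nm` / `frame_time_s` metadata is a
#'   schema error.
#' @return a [localization_table()].
#' @export
read_localizations <- function(path) {
  head_lines <- readLines(path, n = 50L)
  meta_lines <- grep("^#", head_lines, value = TRUE)
  get_meta <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), meta_lines, value = TRUE)
    if (!length(ln)) return(NULL)
    as.numeric(strsplit(sub(paste0("^#\\s*", key, ":\\s*"), "", ln[1]),
                        "\\s+")[[1]])
  }
  px <- get_meta("pixel_size_nm")
  ft <- get_meta("frame_time_s")
  if (is.null(px) || is.null(ft))
    stop("schema error: metadata pixel_size_nm and frame_time_s are mandatory",
         call. = FALSE)
  seed <- get_meta("seed")
  fld <- get_meta("field_nm")
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c(frame = "integer", x_nm = "numeric",
                                       y_nm = "numeric", photons = "numeric",
                                       sigma_nm = "numeric",
                                       source = "character"))
  localization_table(df, px, ft,
                     seed = if (is.null(seed)) NA_integer_ else
                       as.integer(seed),
                     field = fld)
}

#' Write / read a simulation configuration as YAML
#'
#' The flat key-value text mirrors the [sim_config()] fields; the site
#' layout is stored as paired `x`/`y` lists. Unknown keys in a file are
#' rejected.
#'
#' @param config a [sim_config()].
#' @param path file path.
#' @return `write_sim_config`: `path` invisibly; `read_sim_config`: a
#'   validated [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  lst <- unclass(config)
  lst$site_layout <- list(x = unname(lst$site_layout[, 1]),
                          y = unname(lst$site_layout[, 2]))
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(lst$site_layout))
    lst$site_layout <- cbind(x = unlist(lst$site_layout$x),
                             y = unlist(lst$site_layout$y))
  if (!is.null(lst$drift_velocity))
    lst$drift_velocity <- unlist(lst$drift_velocity)
  do.call(sim_config, lst)
}

#' Write / read a 16-bit grayscale TIFF image
#'
#' @param image integer/numeric matrix with counts in 0..65535.
#' @param path file path.
#' @return `write_image_tiff`: `path` invisibly; `read_image_tiff`: an
#'   integer matrix.
#' @export
write_image_tiff <- function(image, path) {
  tiff::writeTIFF(pmin(pmax(image, 0), 65535) / 65535, path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  out <- round(img * 65535)
  storage.mode(out) <- "integer"
  out
}

#' Read a reference-pitch file
#'
#' CSV with columns `interval_id`, `length_nm`, `U_k2_nm` (expanded
#' uncertainty, k = 2) describing the calibrated stage-micrometre intervals.
#'
#' @param path file path.
#' @return data.frame in [calibrate_pixel_size()]'s expected form.
#' @export
read_reference_pitches <- function(path) {
  df <- utils::read.csv(path)
  need <- c("length_nm", "U_k2_nm")
  if (!all(need %in% names(df)))
    stop("reference pitch file needs columns length_nm and U_k2_nm",
         call. = FALSE)
  df
}

#' Export an uncertainty budget as CSV
#'
#' Columns mirror the budget table (input quantity, standard uncertainty,
#' unit, kind, contribution in nm) with the expanded-uncertainty footer as a
#' final comment line.
#'
#' @param budget an [build_budget()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_budget_csv <- function(budget, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.csv(budget$table, con, row.names = FALSE)
  writeLines(sprintf("# expanded uncertainty (k = %g): U = %.1f nm",
                     budget$k, budget$U_nm), con)
  invisible(path)
}

#' Export candidates and per-structure fits as CSV
#'
#' @param cands a [cluster_localizations()] result.
#' @param fits a [fit_candidates()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_candidates_csv <- function(cands, path) {
  utils::write.csv(cands$candidates, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_candidates_csv
#' @export
write_fits_csv <- function(fits, path) {
  df <- do.call(rbind, lapply(fits, function(f) {
    data.frame(id = attr(f, "id"), d_nm = f$d_nm, u_fit_nm = f$u_fit_nm,
               angle = f$angle, n_mark1 = f$counts[1], n_mark2 = f$counts[2],
               n_outliers = f$n_outliers, failed = f$failed,
               reason = f$reason)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Store / load a channel transform as a six-value text record
#'
#' @param transform a [channel_transform()].
#' @param path file path.
#' @return `write_transform`: `path` invisibly; `read_transform`: a
#'   [channel_transform()].
#' @export
write_transform <- function(transform, path) {
  co <- transform$coef
  writeLines(sprintf("%s %.12g", names(co), co), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  ln <- strsplit(readLines(path), "\\s+")
  vals <- stats::setNames(vapply(ln, function(x) as.numeric(x[2]),
                                 numeric(1)),
                          vapply(ln, `[[`, character(1), 1))
  do.call(channel_transform, as.list(vals[c("a", "b", "c", "d", "e", "f")]))
}
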