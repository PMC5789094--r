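#' Construct a localization table
#'
#' The common currency of the pipeline: one row per single-molecule
#' localization with frame index (1-based), position (nm), detected photons,
#' the per-localization precision `sigma_nm`, and a provenance label
#' (`source`: a site id, `"merged"` for fused simultaneous emitters, or
#' `"fp"` for a false positive). Camera metadata travel as attributes.
#'
#' @param df data.frame with columns `frame`, `x_nm`, `y_nm`, `photons`,
#'   `sigma_nm`, `source`.
#' @param pixel_size object-space pixel size (nm/pixel).
#' @param frame_time camera integration time (s).
#' @param seed optional seed used to generate the data.
#' @param field optional c(width, height) of the field of view in nm.
#' @return object of class `localization_table` (a data.frame).
#' @export
localization_table <- function(df, pixel_size, frame_time, seed = NA_integer_,
                               field = NULL) {
  need <- c("frame", "x_nm", "y_nm", "photons", "sigma_nm", "source")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("localization table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(pixel_size), pixel_size > 0,
            is.numeric(frame_time), frame_time > 0)
  df <- df[, need, drop = FALSE]
  attr(df, "pixel_size") <- pixel_size
  attr(df, "frame_time") <- frame_time
  attr(df, "seed") <- seed
  if (!is.null(field)) attr(df, "field") <- field
  class(df) <- c("localization_table", "data.frame")
  df
}

empty_localization_table <- function(pixel_size, frame_time, seed = NA_integer_,
                                     field = NULL) {
  localization_table(
    data.frame(frame = integer(), x_nm = numeric(), y_nm = numeric(),
               photons = numeric(), sigma_nm = numeric(),
               source = character(), stringsAsFactors = FALSE),
    pixel_size, frame_time, seed, field)
}

#' @export
print.localization_table <- function(x, ...) {
  cat(sprintf("Localization table: %d localizations, pixel %g nm, frame %g s\n",
              nrow(x), attr(x, "pixel_size"), attr(x, "frame_time")))
  fld <- attr(x, "field")
  if (!is.null(fld))
    cat(sprintf("  field of view: %.1f x %.1f um\n",
                fld[1] / 1000, fld[2] / 1000))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ...\n")
  invisible(x)
}
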