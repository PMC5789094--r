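# Two-state (dark <-> bright) renewal process per binding site, plus the
# camera discretization that turns bright intervals into localizations.

# Bright intervals of one site over [0, T]; starts dark. Exponential dwell
# times with means t_off (dark) and t_on (bright).
.site_events <- function(T_total, t_on, t_off) {
  n_guess <- max(16L, ceiling(T_total / (t_on + t_off) * 1.5) + 10L)
  off <- stats::rexp(n_guess, rate = 1 / t_off)
  on <- stats::rexp(n_guess, rate = 1 / t_on)
  # extend until the cycle chain covers T_total
  while (sum(off) + sum(on) < T_total) {
    off <- c(off, stats::rexp(n_guess, rate = 1 / t_off))
    on <- c(on, stats::rexp(n_guess, rate = 1 / t_on))
  }
  t_start <- cumsum(off) + c(0, cumsum(on))[seq_along(off)]
  keep <- t_start < T_total
  t_start <- t_start[keep]
  t_end <- pmin(t_start + on[keep], T_total)
  cbind(t_start = t_start, t_end = t_end)
}

#' Simulate binding (blinking) events for a set of docking sites
#'
#' Each site independently alternates between a dark and a bright state with
#' exponentially distributed dwell times (means `t_off` and `t_on`); the
#' transient binding of imager strands in DNA-PAINT follows exactly this
#' two-state kinetics. Events are truncated to the acquisition window
#' `[0, n_frames * frame_time]`.
#'
#' Randomness is drawn from the current RNG state; the field-level generators
#' seed it from `config$seed` (see [generate_nanoruler_field()]).
#'
#' @param config a [sim_config()].
#' @param sites matrix of site positions (nm); only the number of rows is
#'   used here, positions matter downstream.
#' @return data.frame with columns `site`, `t_start`, `t_end` (s), one row
#'   per bright interval.
#' @export
simulate_binding_events <- function(config, sites) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  if (is.null(sites) || nrow(sites) == 0L)
    return(data.frame(site = integer(), t_start = numeric(),
                      t_end = numeric()))
  T_total <- config$n_frames * config$frame_time
  evs <- lapply(seq_len(nrow(sites)), function(i) {
    e <- .site_events(T_total, config$t_on, config$t_off)
    if (nrow(e) == 0L) return(NULL)
    data.frame(site = i, t_start = e[, 1], t_end = e[, 2])
  })
  evs <- evs[!vapply(evs, is.null, logical(1))]
  if (!length(evs))
    return(data.frame(site = integer(), t_start = numeric(),
                      t_end = numeric()))
  do.call(rbind, evs)
}

# union-find grouping of emitters closer than `radius` (single linkage)
.merge_groups <- function(xx, yy, radius) {
  k <- length(xx)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  r2 <- radius^2
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      if ((xx[i] - xx[j])^2 + (yy[i] - yy[j])^2 < r2) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(k), find, integer(1))
}

#' Convert binding events into a localization table
#'
#' Discretizes bright intervals onto camera frames. A site that is ON for a
#' fraction `f` of a frame collects `Poisson(photons_per_frame * f)` photons;
#' frames below the `min_photons` detection threshold yield no localization.
#' Sites that are simultaneously ON in the same frame and closer than
#' `merge_radius` are detected as a single event at their photon-weighted
#' centroid (label `"merged"`) — the mechanism behind the systematic distance
#' shortening at high `t_on/t_off`. Localization noise is isotropic Gaussian
#' with `sigma = sigma_psf / sqrt(photons)`; linear drift and uniform false
#' positives are added per frame.
#'
#' @param events data.frame from [simulate_binding_events()].
#' @param config a [sim_config()].
#' @param sites matrix of absolute site positions (nm), rows matching the
#'   `site` indices in `events`; optional `rownames` become source labels.
#' @param field optional c(width, height) nm, required for false positives.
#' @return a [localization_table()].
#' @export
events_to_localizations <- function(events, config, sites, field = NULL) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  ft <- config$frame_time
  nfr <- config$n_frames
  noiseless <- is.infinite(config$photons_per_frame)

  out <- NULL
  if (!is.null(events) && nrow(events)) {
    f0 <- pmax(0, floor(events$t_start / ft))
    f1 <- pmin(nfr - 1, floor((events$t_end - 1e-12) / ft))
    ok <- f1 >= f0
    events <- events[ok, , drop = FALSE]
    f0 <- f0[ok]; f1 <- f1[ok]
    if (nrow(events)) {
      nf <- as.integer(f1 - f0 + 1)
      ev <- rep.int(seq_len(nrow(events)), nf)
      frame <- rep.int(f0, nf) + sequence(nf) - 1
      fs <- frame * ft
      ovl <- (pmin(events$t_end[ev], fs + ft) -
                pmax(events$t_start[ev], fs)) / ft
      if (noiseless) {
        photons <- rep(Inf, length(ev))
      } else {
        photons <- stats::rpois(length(ev), config$photons_per_frame * ovl)
      }
      keep <- photons >= config$min_photons
      ev <- ev[keep]; frame <- frame[keep]; photons <- photons[keep]
      if (length(ev)) {
        site_id <- events$site[ev]
        labs <- rownames(sites)
        if (is.null(labs)) labs <- paste0("site", seq_len(nrow(sites)))
        x <- sites[site_id, 1]
        y <- sites[site_id, 2]
        src <- labs[site_id]
        # fuse simultaneous emitters within merge_radius, frame by frame
        o <- order(frame)
        frame <- frame[o]; x <- x[o]; y <- y[o]
        photons <- photons[o]; src <- src[o]
        dupf <- unique(frame[duplicated(frame)])
        if (length(dupf)) {
          multi <- frame %in% dupf
          idx_multi <- split(which(multi), frame[multi])
          drop_rows <- integer(0)
          for (ii in idx_multi) {
            grp <- .merge_groups(x[ii], y[ii], config$merge_radius)
            for (g in unique(grp)) {
              m <- ii[grp == g]
              if (length(m) > 1L) {
                w <- photons[m]
                if (any(!is.finite(w))) w <- rep(1, length(m))
                tot <- if (noiseless) Inf else sum(photons[m])
                x[m[1]] <- sum(w * x[m]) / sum(w)
                y[m[1]] <- sum(w * y[m]) / sum(w)
                photons[m[1]] <- tot
                src[m[1]] <- "merged"
                drop_rows <- c(drop_rows, m[-1])
              }
            }
          }
          if (length(drop_rows)) {
            keep2 <- setdiff(seq_along(frame), drop_rows)
            frame <- frame[keep2]; x <- x[keep2]; y <- y[keep2]
            photons <- photons[keep2]; src <- src[keep2]
          }
        }
        sigma <- ifelse(is.finite(photons),
                        config$sigma_psf / sqrt(photons), 0)
        n <- length(frame)
        x <- x + stats::rnorm(n) * sigma
        y <- y + stats::rnorm(n) * sigma
        t_mid <- (frame + 0.5) * ft
        x <- x + config$drift_velocity[1] * t_mid / 3600
        y <- y + config$drift_velocity[2] * t_mid / 3600
        out <- data.frame(frame = as.integer(frame + 1), x_nm = x, y_nm = y,
                          photons = photons, sigma_nm = sigma, source = src,
                          stringsAsFactors = FALSE)
      }
    }
  }

  if (config$fp_density > 0 && !is.null(field)) {
    area_um2 <- prod(field) / 1e6
    n_fp <- stats::rpois(1, config$fp_density * area_um2 * nfr)
    if (n_fp > 0) {
      ppf <- if (noiseless) 1000 else config$photons_per_frame
      phot <- pmax(config$min_photons, stats::rpois(n_fp, ppf))
      fp <- data.frame(frame = sample.int(nfr, n_fp, replace = TRUE),
                       x_nm = stats::runif(n_fp, 0, field[1]),
                       y_nm = stats::runif(n_fp, 0, field[2]),
                       photons = phot,
                       sigma_nm = config$sigma_psf / sqrt(phot),
                       source = "fp", stringsAsFactors = FALSE)
      out <- if (is.null(out)) fp else rbind(out, fp)
    }
  }

  if (is.null(out))
    return(empty_localization_table(config$pixel_size, ft, config$seed, field))
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  localization_table(out, config$pixel_size, ft, config$seed, field)
}
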