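# Drift and resolution benchmarking: per-structure localization transients,
# windowed-centroid drift estimation/correction, and cross-section Gaussian
# spot-width (FWHM) analysis of rendered images.

#' Localization transient of one structure
#'
#' Time series of a candidate structure's localizations over the
#' acquisition: when it was localized and where.
#'
#' @param candidate logical/integer index of the structure's rows in
#'   `table`, or a [cluster_localizations()] result together with `id`.
#' @param table a [localization_table()].
#' @param id candidate id when `candidate` is a `nanoruler_candidates`
#'   object.
#' @return data.frame `frame`, `t_s`, `x_nm`, `y_nm` with attributes
#'   `rate_nm_per_h` and `rate_se_nm_per_h` (least-squares centroid drift
#'   rate in x/y) when at least 3 localizations are present.
#' @export
localization_transient <- function(candidate, table, id = NULL) {
  idx <- if (inherits(candidate, "nanoruler_candidates")) {
    if (is.null(id)) stop("give the candidate id", call. = FALSE)
    which(candidate$assignment == id)
  } else if (is.logical(candidate)) which(candidate) else as.integer(candidate)
  ft <- attr(table, "frame_time")
  if (is.null(ft)) ft <- 1
  out <- data.frame(frame = table$frame[idx],
                    t_s = (table$frame[idx] - 0.5) * ft,
                    x_nm = table$x_nm[idx], y_nm = table$y_nm[idx])
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) >= 3) {
    th <- out$t_s / 3600
    fx <- stats::lm.fit(cbind(1, th), out$x_nm)
    fy <- stats::lm.fit(cbind(1, th), out$y_nm)
    se <- function(f) {
      s2 <- sum(f$residuals^2) / (length(f$residuals) - 2)
      sqrt(s2 / sum((th - mean(th))^2))
    }
    attr(out, "rate_nm_per_h") <- c(x = unname(fx$coefficients[2]),
                                    y = unname(fy$coefficients[2]))
    attr(out, "rate_se_nm_per_h") <- c(x = se(fx), y = se(fy))
  }
  out
}

#' Estimate and correct lateral sample drift
#'
#' Windowed structure-residual method: every clustered structure's
#' localizations are referenced to their mark centres (a deterministic 1D
#' two-means split along the structure's principal axis, so both marks of a
#' ruler act as rigid anchors), the acquisition is cut into windows of
#' `window_frames`, and the mean residual per window — pooled over all
#' structures — gives the drift at the window midpoint. Tracking residuals
#' to the mark centres instead of raw structure centroids removes the
#' mark-geometry noise of sparse blinking bursts. The trace is anchored at
#' (0, 0) in the first window, linearly interpolated per frame, and
#' subtracted.
#'
#' @param table a [localization_table()].
#' @param candidates a [cluster_localizations()] result; its assignment
#'   defines the structures used as drift tracers.
#' Because the mark anchors are computed from drift-smeared coordinates, a
#' single pass slightly underestimates the drift; the estimate-correct cycle
#' is therefore iterated (`n_iter` times or until the update falls below
#' 0.05 nm), which makes the correction idempotent in practice.
#'
#' @param window_frames window length in frames.
#' @param n_iter maximum estimate-correct iterations.
#' @return list with `table` (drift-corrected), `trace` (class
#'   `drift_trace`: accumulated `t_s`, `dx_nm`, `dy_nm`, starting at 0),
#'   `rate_nm_per_h` and `rate_se_nm_per_h` (linear fit to the trace).
#' @export
estimate_and_correct_drift <- function(table, candidates,
                                       window_frames = 500, n_iter = 3) {
  asn <- candidates$assignment
  use <- asn > 0
  if (!any(use)) stop("no clustered structures to track", call. = FALSE)
  ft <- attr(table, "frame_time")
  if (is.null(ft)) ft <- 1
  w <- (table$frame - 1L) %/% window_frames + 1L
  idx_use <- which(use)
  by_struct <- split(seq_along(idx_use), asn[idx_use])
  wid <- w[idx_use]
  t_frame <- (table$frame - 0.5) * ft

  # one pass: mark-residual window means on the current coordinates
  drift_pass <- function(x_all, y_all) {
    res_x <- numeric(length(idx_use))
    res_y <- numeric(length(idx_use))
    for (rows in by_struct) {
      ii <- idx_use[rows]
      xy <- cbind(x_all[ii], y_all[ii])
      ctr <- colMeans(xy)
      # deterministic 1D two-means along the principal axis -> mark anchors
      grp <- rep(1L, nrow(xy))
      if (nrow(xy) >= 6) {
        ax <- eigen(stats::cov(xy), symmetric = TRUE)$vectors[, 1]
        s1 <- as.vector(sweep(xy, 2, ctr) %*% ax)
        c12 <- stats::quantile(s1, c(0.25, 0.75), names = FALSE)
        if (diff(c12) > 1e-6) {
          for (it in 1:25) {
            a <- abs(s1 - c12[1]) <= abs(s1 - c12[2])
            if (!any(a) || all(a)) break
            new12 <- c(mean(s1[a]), mean(s1[!a]))
            conv <- max(abs(new12 - c12)) < 1e-9
            c12 <- new12
            if (conv) break
          }
          a <- abs(s1 - c12[1]) <= abs(s1 - c12[2])
          if (any(a) && !all(a)) grp <- ifelse(a, 1L, 2L)
        }
      }
      for (g in unique(grp)) {
        m <- grp == g
        res_x[rows[m]] <- xy[m, 1] - mean(xy[m, 1])
        res_y[rows[m]] <- xy[m, 2] - mean(xy[m, 2])
      }
    }
    nw <- max(wid)
    dx <- rep(NA_real_, nw)
    dy <- rep(NA_real_, nw)
    for (wi in unique(wid)) {
      m <- wid == wi
      dx[wi] <- mean(res_x[m])
      dy[wi] <- mean(res_y[m])
    }
    seen <- which(!is.na(dx))
    list(t_mid = ((seen - 0.5) * window_frames) * ft,
         dx = dx[seen] - dx[seen[1]], dy = dy[seen] - dy[seen[1]])
  }

  # linear interpolation between window midpoints, linear extrapolation
  # from the end segments beyond them
  interp_extrap <- function(tm, v) {
    if (length(tm) == 1L) return(rep(v, length(t_frame)))
    out <- stats::approx(tm, v, xout = t_frame, rule = 2)$y
    k <- length(tm)
    lo <- t_frame < tm[1]
    hi <- t_frame > tm[k]
    sl1 <- (v[2] - v[1]) / (tm[2] - tm[1])
    slk <- (v[k] - v[k - 1]) / (tm[k] - tm[k - 1])
    out[lo] <- v[1] + sl1 * (t_frame[lo] - tm[1])
    out[hi] <- v[k] + slk * (t_frame[hi] - tm[k])
    out
  }

  # iterate: drift-smeared mark anchors shrink a single-pass estimate, so
  # re-estimate on the corrected coordinates until the update is negligible
  x_cur <- table$x_nm
  y_cur <- table$y_nm
  acc_x <- NULL
  acc_y <- NULL
  t_mid <- NULL
  for (it in seq_len(max(1L, n_iter))) {
    est <- drift_pass(x_cur, y_cur)
    t_mid <- est$t_mid
    if (is.null(acc_x)) {
      acc_x <- est$dx
      acc_y <- est$dy
    } else {
      acc_x <- acc_x + est$dx
      acc_y <- acc_y + est$dy
    }
    x_cur <- table$x_nm - interp_extrap(t_mid, acc_x)
    y_cur <- table$y_nm - interp_extrap(t_mid, acc_y)
    if (max(abs(c(est$dx, est$dy))) < 0.05) break
  }
  table$x_nm <- x_cur
  table$y_nm <- y_cur
  dx0 <- acc_x
  dy0 <- acc_y
  trace <- data.frame(t_s = t_mid, dx_nm = dx0, dy_nm = dy0)
  class(trace) <- c("drift_trace", "data.frame")
  th <- t_mid / 3600
  rate <- c(x = NA_real_, y = NA_real_)
  rate_se <- c(x = NA_real_, y = NA_real_)
  if (length(t_mid) >= 3) {
    fx <- stats::lm.fit(cbind(1, th), dx0)
    fy <- stats::lm.fit(cbind(1, th), dy0)
    sxx <- sum((th - mean(th))^2)
    rate <- c(x = unname(fx$coefficients[2]), y = unname(fy$coefficients[2]))
    rate_se <- c(x = sqrt(sum(fx$residuals^2) / (length(th) - 2) / sxx),
                 y = sqrt(sum(fy$residuals^2) / (length(th) - 2) / sxx))
  }
  list(table = table, trace = trace,
       rate_nm_per_h = rate, rate_se_nm_per_h = rate_se)
}

#' @export
print.drift_trace <- function(x, ...) {
  cat(sprintf("Drift trace: %d windows over %.1f min, extent (%.2f, %.2f) nm\n",
              nrow(x), max(x$t_s) / 60,
              max(x$dx_nm) - min(x$dx_nm), max(x$dy_nm) - min(x$dy_nm)))
  invisible(x)
}

#' @export
plot.drift_trace <- function(x, ...) {
  graphics::plot(x$t_s / 60, x$dx_nm, type = "l", col = "steelblue",
                 xlab = "time (min)", ylab = "drift (nm)",
                 ylim = range(c(x$dx_nm, x$dy_nm)), ...)
  graphics::lines(x$t_s / 60, x$dy_nm, col = "indianred")
  graphics::legend("topleft", c("x", "y"), lty = 1,
                   col = c("steelblue", "indianred"), bty = "n")
  invisible(x)
}

# bilinear sampling of an image at continuous nm coordinates
.sample_image <- function(img, xs, ys, bin_nm) {
  px <- xs / bin_nm + 0.5
  py <- ys / bin_nm + 0.5
  j0 <- floor(px); i0 <- floor(py)
  fx <- px - j0; fy <- py - i0
  val <- function(i, j) {
    ok <- i >= 1 & i <= nrow(img) & j >= 1 & j <= ncol(img)
    v <- numeric(length(i))
    v[ok] <- img[cbind(i[ok], j[ok])]
    v
  }
  val(i0, j0) * (1 - fx) * (1 - fy) + val(i0, j0 + 1L) * fx * (1 - fy) +
    val(i0 + 1L, j0) * (1 - fx) * fy + val(i0 + 1L, j0 + 1L) * fx * fy
}

#' Cross-section spot-width analysis of a rendered image
#'
#' Extracts the intensity profile along a line segment (averaging
#' perpendicular to it over `width_nm`), detects the peaks above background,
#' and fits one Gaussian (amplitude, centre, sigma, offset) per peak by
#' least squares. The FWHM is reported from the fitted sigma as
#' `2 * sqrt(2 * ln 2) * sigma = 2.3548 * sigma`.
#'
#' @param image rendered image from [render_sr_image()] (needs `bin_nm`).
#' @param p0,p1 segment end points, c(x, y) in nm.
#' @param width_nm perpendicular averaging width.
#' @param min_prominence peak threshold as a fraction of (max - background)
#'   above background.
#' @param min_separation_nm minimum peak separation; closer maxima are
#'   treated as one peak.
#' @return data.frame `center_nm` (position along the segment), `sigma_nm`,
#'   `fwhm_nm`, `amplitude`, with the sampled profile as attribute
#'   `profile` (`s_nm`, `intensity`).
#' @export
cross_section_fwhm <- function(image, p0, p1, width_nm = 40,
                               min_prominence = 0.3,
                               min_separation_nm = 10) {
  bin_nm <- attr(image, "bin_nm")
  if (is.null(bin_nm)) stop("image lacks a bin_nm attribute", call. = FALSE)
  v <- c(p1[1] - p0[1], p1[2] - p0[2])
  L <- sqrt(sum(v^2))
  if (L <= 0) stop("degenerate segment", call. = FALSE)
  u <- v / L
  nperp <- c(-u[2], u[1])
  step <- bin_nm / 2
  s <- seq(0, L, by = step)
  offs <- seq(-width_nm / 2, width_nm / 2, by = step)
  prof <- vapply(s, function(si) {
    cx <- p0[1] + si * u[1] + offs * nperp[1]
    cy <- p0[2] + si * u[2] + offs * nperp[2]
    mean(.sample_image(image, cx, cy, bin_nm))
  }, numeric(1))
  bg <- stats::quantile(prof, 0.2, names = FALSE)
  amp <- max(prof) - bg
  if (amp <= 0 || max(prof) <= 0)
    stop("no peak above background in cross-section", call. = FALSE)
  thr <- bg + min_prominence * amp
  np <- length(prof)
  is_max <- prof > thr &
    prof >= c(-Inf, prof[-np]) & prof >= c(prof[-1], -Inf)
  peaks <- which(is_max)
  if (!length(peaks))
    stop("no peak above background in cross-section", call. = FALSE)
  # merge maxima closer than min_separation_nm (keep the higher one)
  keep <- integer(0)
  for (p in peaks[order(prof[peaks], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(s[keep] - s[p]) >= min_separation_nm))
      keep <- c(keep, p)
  }
  peaks <- sort(keep)
  fits <- lapply(peaks, function(p) {
    # local window: half-way to the neighbouring peaks (or profile ends)
    lo <- max(1, floor(mean(c(p, max(c(1, peaks[peaks < p]))))))
    hi <- min(np, ceiling(mean(c(p, min(c(np, peaks[peaks > p]))))))
    win <- lo:hi
    obj <- function(par) {
      mu <- par[1]; sg <- exp(par[2]); a <- exp(par[3]); b <- par[4]
      sum((prof[win] - (b + a * exp(-(s[win] - mu)^2 / (2 * sg^2))))^2)
    }
    sg0 <- max(bin_nm, sum(prof[win] > bg + 0.5 * (prof[p] - bg)) * step / 2.3548)
    op <- stats::optim(c(s[p], log(sg0), log(max(prof[p] - bg, 1e-6)), bg),
                       obj, method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
    c(center_nm = op$par[1], sigma_nm = exp(op$par[2]),
      amplitude = exp(op$par[3]))
  })
  out <- as.data.frame(do.call(rbind, fits))
  out$fwhm_nm <- 2 * sqrt(2 * log(2)) * out$sigma_nm
  out <- out[, c("center_nm", "sigma_nm", "fwhm_nm", "amplitude")]
  attr(out, "profile") <- data.frame(s_nm = s, intensity = prof)
  out
}
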