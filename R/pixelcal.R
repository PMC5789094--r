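# Object-space pixel-size calibration against a calibrated stage micrometre.
# Field distortion is *not* corrected; the scatter of per-interval pixel
# sizes enters the budget as an uncertainty contribution instead.

#' Locate grating lines with sub-pixel precision
#'
#' Averages the image columns over a row band into a 1D profile and detects
#' the dark-line valleys as runs below the half-depth threshold. Each line
#' centre is the midpoint of the two half-depth edge crossings, found by
#' linear interpolation on the flanks — robust for the wide, weakly defined
#' lines of a stage micrometre, whose flat valley bottom carries no centre
#' information. Centers are returned in continuous pixel coordinates where
#' column j spans `[j-1, j)`, i.e. `center_px = center_nm / pixel_size` for
#' a perfect image.
#'
#' @param image numeric/integer matrix (rows y, columns x).
#' @param band integer rows to average over; default the middle half.
#' @param min_contrast minimum (max - min) / max profile contrast below
#'   which the image is considered flat.
#' @return increasing numeric vector of line centers (pixels) with attribute
#'   `u_px`, a per-center standard uncertainty propagated from the profile
#'   noise through the edge slopes.
#' @export
locate_lines <- function(image, band = NULL, min_contrast = 0.05) {
  nr <- nrow(image)
  if (is.null(band)) band <- seq.int(max(1L, nr %/% 4), max(1L, nr - nr %/% 4))
  profile <- colMeans(image[band, , drop = FALSE])
  rng <- max(profile) - min(profile)
  if (rng <= min_contrast * max(max(profile), 1))
    stop("no grating lines found: image profile is flat", call. = FALSE)
  thr <- min(profile) + 0.5 * rng
  below <- profile < thr
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  centers <- numeric(0)
  u_c <- numeric(0)
  # profile noise estimate from first differences of the flat background
  bgd <- diff(profile[!below])
  noise <- if (length(bgd) > 4) stats::mad(bgd) / sqrt(2) else 0
  for (ri in runs) {
    i0 <- starts[ri]; i1 <- ends[ri]
    if (i0 <= 1L || i1 >= length(profile)) next  # clipped at border
    # half-depth crossings by linear interpolation; pixel j centre = j - 0.5
    xl <- (i0 - 1L - 0.5) +
      (profile[i0 - 1L] - thr) / (profile[i0 - 1L] - profile[i0])
    xr <- (i1 - 0.5) +
      (profile[i1] - thr) / (profile[i1] - profile[i1 + 1L])
    centers <- c(centers, (xl + xr) / 2)
    if (noise > 0) {
      sl <- abs(profile[i0] - profile[i0 - 1L])
      sr <- abs(profile[i1 + 1L] - profile[i1])
      u_c <- c(u_c, sqrt((noise / max(sl, 1e-9))^2 +
                           (noise / max(sr, 1e-9))^2) / 2)
    } else u_c <- c(u_c, 0)
  }
  if (length(centers) < 2L)
    stop("fewer than 2 grating lines detected", call. = FALSE)
  o <- order(centers)
  structure(centers[o], u_px = u_c[o])
}

#' Calibrate the object-space pixel size from located grating lines
#'
#' Each calibrated interval i gives `P_i = L_ref,i / (c_{i+1} - c_i)`
#' nm/pixel; the calibration result is the mean of the `P_i`. Its standard
#' uncertainty combines, in quadrature,
#' * the reference-pitch uncertainty (expanded `U(k=2)` values halved to
#'   standard, scaled per interval, averaged as independent contributions),
#' * the scatter of the `P_i` as the field-variation / distortion term
#'   (taken at full value, not divided by the interval count: distortion
#'   does not average out), and
#' * the line-localization uncertainty propagated from [locate_lines()].
#'
#' @param centers line centers in pixels (from [locate_lines()]), with
#'   optional attribute `u_px`.
#' @param reference data.frame with columns `length_nm` and `U_k2_nm`
#'   (expanded, k = 2), one row per interval between consecutive centers.
#' @return object of class `pixel_calibration`: `P` (nm/px), `u_P`, `U_P`
#'   (k = 2), component uncertainties `u_ref`, `u_dist`, `u_line`, the
#'   per-interval `P_i`, and `k = 2`.
#' @export
calibrate_pixel_size <- function(centers, reference) {
  m <- length(centers) - 1L
  if (!is.data.frame(reference) || !all(c("length_nm", "U_k2_nm") %in%
                                        names(reference)))
    stop("reference must be a data.frame with length_nm and U_k2_nm",
         call. = FALSE)
  if (nrow(reference) != m)
    stop(sprintf("%d intervals between centers but %d reference pitches",
                 m, nrow(reference)), call. = FALSE)
  dpx <- diff(centers)
  if (any(dpx <= 0)) stop("line centers must be strictly increasing",
                          call. = FALSE)
  P_i <- reference$length_nm / dpx
  P <- mean(P_i)
  # (a) reference: standard uncertainties (U/2)/dpx, independent, mean of m
  u_ref_i <- (reference$U_k2_nm / 2) / dpx
  u_ref <- sqrt(sum(u_ref_i^2)) / m
  # (b) field variation / distortion: scatter of the per-interval pixel sizes
  u_dist <- if (m >= 2) stats::sd(P_i) else 0
  # (c) line-fit: centre uncertainties through P_i = L/dpx
  u_px <- attr(centers, "u_px")
  if (is.null(u_px)) u_px <- rep(0, m + 1L)
  u_line_i <- (P_i / dpx) * sqrt(u_px[-length(u_px)]^2 + u_px[-1L]^2)
  u_line <- sqrt(sum(u_line_i^2)) / m
  u_P <- sqrt(u_ref^2 + u_dist^2 + u_line^2)
  structure(list(P = P, u_P = u_P, U_P = 2 * u_P, k = 2,
                 u_ref = u_ref, u_dist = u_dist, u_line = u_line,
                 P_i = P_i, intervals_px = dpx,
                 reference = reference),
            class = "pixel_calibration")
}

#' @export
print.pixel_calibration <- function(x, ...) {
  cat(sprintf("Pixel-size calibration: P = %.3f +/- %.3f nm/pixel (U, k = 2)\n",
              x$P, x$U_P))
  cat(sprintf("  relative expanded uncertainty: %.2f %%\n", 100 * x$U_P / x$P))
  cat(sprintf("  components (standard, nm/px): reference %.4f | field variation %.4f | line fit %.4f\n",
              x$u_ref, x$u_dist, x$u_line))
  cat(sprintf("  %d intervals, per-interval P in [%.3f, %.3f] nm/px\n",
              length(x$P_i), min(x$P_i), max(x$P_i)))
  invisible(x)
}

#' @export
coef.pixel_calibration <- function(object, ...) {
  c(P = object$P, u_P = object$u_P)
}
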