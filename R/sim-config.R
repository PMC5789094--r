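#' Default binding-site layout of one fluorescent mark
#'
#' A mark on the rectangular origami carries a small grid of single-stranded
#' docking sites. The default is a 3 x 3 arrangement with 3 nm pitch (the
#' centre-to-centre distance of adjacent helices), giving a compact mark
#' footprint of about 6 x 6 nm.
#'
#' @param n_side sites per grid side.
#' @param pitch_nm centre-to-centre site spacing in nm.
#' @return numeric matrix with columns `x`, `y` (nm, mark-local frame,
#'   centred on the mark).
#' @export
#' @examples
#' site_layout_grid()        # 9 sites, 6 nm footprint
#' site_layout_grid(2, 2)    # compact mark for short rulers
site_layout_grid <- function(n_side = 3L, pitch_nm = 3) {
  stopifnot(n_side >= 1, pitch_nm >= 0)
  g <- (seq_len(n_side) - (n_side + 1) / 2) * pitch_nm
  as.matrix(expand.grid(x = g, y = g))
}

#' Simulation configuration for a DNA-PAINT nanoruler experiment
#'
#' Bundles every ground-truth parameter of the Monte-Carlo simulator:
#' two-state binding kinetics, camera discretization, photon statistics,
#' mark geometry, labeling efficiency, false positives and drift. The same
#' configuration plus the same seed reproduces a simulation bit-identically.
#'
#' The defaults describe a typical DNA-PAINT acquisition: mean bright time
#' 0.5 s, mean dark time 500 s (duty cycle about 1e-3, the regime in which
#' simultaneous-emitter merging is rare), 12000 frames of 100 ms, around
#' 5000 detected photons per bright frame and a PSF standard deviation of
#' 130 nm, so single localizations are precise to roughly
#' `sigma_psf / sqrt(N)` = 1.8 nm. Under these conditions the fitted
#' ensemble of identical rulers scatters by about 1 nm.
#'
#' @param t_on mean bright-state dwell time (s).
#' @param t_off mean dark-state dwell time (s).
#' @param frame_time camera integration time per frame (s).
#' @param n_frames number of acquired frames.
#' @param photons_per_frame mean detected photons for a site that is ON for a
#'   whole frame. `Inf` disables photon (localization) noise, a convenience
#'   limit for exactness tests.
#' @param sigma_psf standard deviation of the point-spread function (nm).
#' @param pixel_size object-space pixel size (nm/pixel).
#' @param merge_radius distance (nm) below which simultaneously emitting
#'   sites are detected as one localization (default 2.5 * sigma_psf,
#'   a diffraction-limited detection footprint).
#' @param site_layout matrix of per-mark binding-site coordinates
#'   (nm, mark-local frame); default [site_layout_grid()].
#' @param true_distance_mean designed intermark distance (nm).
#' @param true_distance_sd Gaussian ruler-to-ruler spread of the true
#'   distance (nm); 0 means every ruler has the identical distance.
#' @param site_activity_prob probability that a docking site is present and
#'   active (labeling efficiency).
#' @param fp_density false-positive localizations per square micrometre per
#'   frame.
#' @param drift_velocity length-2 numeric, linear drift (nm/h) in x and y.
#' @param min_photons detection threshold: frames in which a site collects
#'   fewer photons are not localized.
#' @param seed master random seed; per-ruler substreams are derived from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(true_distance_mean = 60)
#' cfg
sim_config <- function(t_on = 0.5, t_off = 500, frame_time = 0.1,
                       n_frames = 12000L, photons_per_frame = 5000,
                       sigma_psf = 130, pixel_size = 100,
                       merge_radius = 2.5 * sigma_psf,
                       site_layout = site_layout_grid(),
                       true_distance_mean = 60, true_distance_sd = 0,
                       site_activity_prob = 0.8, fp_density = 0,
                       drift_velocity = c(0, 0), min_photons = 50,
                       seed = 1L) {
  cfg <- list(t_on = t_on, t_off = t_off, frame_time = frame_time,
              n_frames = as.integer(n_frames),
              photons_per_frame = photons_per_frame,
              sigma_psf = sigma_psf, pixel_size = pixel_size,
              merge_radius = merge_radius, site_layout = site_layout,
              true_distance_mean = true_distance_mean,
              true_distance_sd = true_distance_sd,
              site_activity_prob = site_activity_prob,
              fp_density = fp_density, drift_velocity = drift_velocity,
              min_photons = min_photons, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  pos <- c("t_on", "t_off", "frame_time", "n_frames", "photons_per_frame",
           "sigma_psf", "pixel_size", "merge_radius", "true_distance_mean")
  for (f in pos) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !(v > 0))
      stop("invalid sim_config: '", f, "' must be a single positive number",
           call. = FALSE)
  }
  nneg <- c("true_distance_sd", "fp_density", "min_photons")
  for (f in nneg) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || v < 0)
      stop("invalid sim_config: '", f, "' must be >= 0", call. = FALSE)
  }
  p <- cfg$site_activity_prob
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("invalid sim_config: 'site_activity_prob' must lie in [0, 1]",
         call. = FALSE)
  if (!is.numeric(cfg$drift_velocity) || length(cfg$drift_velocity) != 2L)
    stop("invalid sim_config: 'drift_velocity' must be length-2 numeric",
         call. = FALSE)
  sl <- cfg$site_layout
  if (!is.matrix(sl) || ncol(sl) != 2L || nrow(sl) < 1L)
    stop("invalid sim_config: 'site_layout' must be an n x 2 matrix",
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("invalid sim_config: 'seed' must be a single integer", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("DNA-PAINT simulation configuration\n")
  cat(sprintf("  kinetics: t_on = %g s, t_off = %g s (duty cycle %.2g)\n",
              x$t_on, x$t_off, x$t_on / (x$t_on + x$t_off)))
  cat(sprintf("  camera:   %d frames x %g s, pixel %g nm\n",
              x$n_frames, x$frame_time, x$pixel_size))
  cat(sprintf("  optics:   sigma_psf = %g nm, %g photons/frame, merge < %g nm\n",
              x$sigma_psf, x$photons_per_frame, x$merge_radius))
  cat(sprintf("  ruler:    d = %g nm (sd %g nm), %d sites/mark, activity %.2f\n",
              x$true_distance_mean, x$true_distance_sd,
              nrow(x$site_layout), x$site_activity_prob))
  cat(sprintf("  noise:    fp_density = %g /um^2/frame, drift (%g, %g) nm/h\n",
              x$fp_density, x$drift_velocity[1], x$drift_velocity[2]))
  cat(sprintf("  seed:     %d\n", x$seed))
  invisible(x)
}

#' Designed intermark distance of a rectangular origami
#'
#' Converts a design offset given in integer numbers of helices (across the
#' helix bundle) and nucleotides (along the helical axis) into nanometres,
#' using 0.34 nm per nucleotide along the double helix and 3 nm between the
#' centres of adjacent helices, combined as a Euclidean distance.
#'
#' @param helix_separation integer number of helices between mark centres.
#' @param base_separation integer number of nucleotides between mark centres.
#' @return designed centre-to-centre distance in nm.
#' @export
#' @examples
#' design_distance(0, 100)  # 34 nm along one helix
#' design_distance(10, 0)   # 30 nm across the bundle
design_distance <- function(helix_separation, base_separation) {
  stopifnot(is.numeric(helix_separation), is.numeric(base_separation),
            helix_separation >= 0, base_separation >= 0,
            helix_separation == round(helix_separation),
            base_separation == round(base_separation))
  sqrt((3 * helix_separation)^2 + (0.34 * base_separation)^2)
}
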