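# Field-level generators: nanoruler fields, stage-micrometre gratings,
# matched bead pairs, and super-resolution rendering.

.substream_seed <- function(master, k, stride = 1009L) {
  as.integer((as.double(master) + stride * as.double(k)) %% 2147483647)
}

#' Simulate a field of DNA origami nanorulers
#'
#' Places `n_rulers` rectangular-origami nanorulers in the field of view with
#' uniform random orientations. Each ruler's true intermark distance is drawn
#' from `Normal(true_distance_mean, true_distance_sd)` (truncated at zero),
#' its two marks carry the configured site layout thinned by the labeling
#' efficiency, and its blinking, photon and localization noise are simulated
#' with [simulate_binding_events()] / [events_to_localizations()].
#'
#' Positions are drawn on a shuffled jittered grid (cell size
#' `2 * min_spacing`, jitter up to `min_spacing / 2`), which guarantees the
#' pairwise minimum spacing; each ruler uses its own seed substream derived
#' from `config$seed`, so enlarging `n_rulers` leaves existing rulers
#' unchanged.
#'
#' @param config a [sim_config()].
#' @param n_rulers number of rulers (>= 1).
#' @param field c(width, height) of the field of view in nm; defaults to the
#'   smallest square grid that can host `n_rulers`.
#' @param min_spacing minimum centre-to-centre ruler spacing (nm).
#' @return list with elements `table` (a [localization_table()]; `source`
#'   labels carry the ruler id) and `truth` (data.frame `ruler`, `x_nm`,
#'   `y_nm`, `theta`, `distance_nm`).
#' @export
generate_nanoruler_field <- function(config, n_rulers, field = NULL,
                                     min_spacing = 1000) {
  if (!inherits(config, "sim_config")) validate_sim_config(config)
  stopifnot(n_rulers >= 1)
  cell <- 2 * min_spacing
  if (is.null(field)) {
    ncell <- ceiling(sqrt(n_rulers))
    field <- c(ncell * cell, ncell * cell)
  }
  nx <- floor(field[1] / cell)
  ny <- floor(field[2] / cell)
  if (nx * ny < n_rulers)
    stop(sprintf(paste0("field %.0f x %.0f nm too small for %d rulers at ",
                        "minimum spacing %.0f nm"),
                 field[1], field[2], n_rulers, min_spacing), call. = FALSE)

  set.seed(config$seed)
  cells <- sample.int(nx * ny)[seq_len(n_rulers)]
  cx <- ((cells - 1) %% nx) * cell + cell / 2
  cy <- ((cells - 1) %/% nx) * cell + cell / 2

  layout <- config$site_layout
  tabs <- vector("list", n_rulers)
  truth <- data.frame(ruler = seq_len(n_rulers), x_nm = NA_real_,
                      y_nm = NA_real_, theta = NA_real_,
                      distance_nm = NA_real_)
  for (k in seq_len(n_rulers)) {
    set.seed(.substream_seed(config$seed, k))
    x0 <- cx[k] + stats::runif(1, -min_spacing / 2, min_spacing / 2)
    y0 <- cy[k] + stats::runif(1, -min_spacing / 2, min_spacing / 2)
    theta <- stats::runif(1, 0, pi)
    d <- if (config$true_distance_sd > 0) {
      max(0, stats::rnorm(1, config$true_distance_mean,
                          config$true_distance_sd))
    } else config$true_distance_mean
    truth$x_nm[k] <- x0; truth$y_nm[k] <- y0
    truth$theta[k] <- theta; truth$distance_nm[k] <- d

    rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    sites_list <- list()
    for (m in 1:2) {
      ctr <- c(x0, y0) + (if (m == 1) -1 else 1) * d / 2 *
        c(cos(theta), sin(theta))
      active <- stats::runif(nrow(layout)) < config$site_activity_prob
      if (!any(active)) next
      s <- layout[active, , drop = FALSE] %*% t(rot)
      s <- sweep(s, 2, ctr, "+")
      rownames(s) <- sprintf("r%d:m%d:s%d", k, m, which(active))
      sites_list[[length(sites_list) + 1]] <- s
    }
    if (!length(sites_list)) next
    sites <- do.call(rbind, sites_list)
    ev <- simulate_binding_events(config, sites)
    tab <- events_to_localizations(ev, config, sites)
    if (nrow(tab)) {
      tab$source[tab$source == "merged"] <- sprintf("r%d:merged", k)
      tabs[[k]] <- as.data.frame(tab)
    }
  }
  tabs <- tabs[!vapply(tabs, is.null, logical(1))]
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    as.data.frame(empty_localization_table(config$pixel_size,
                                           config$frame_time))

  if (config$fp_density > 0) {
    set.seed(.substream_seed(config$seed, 7777777L, stride = 1L))
    fp <- events_to_localizations(NULL, config, NULL, field = field)
    if (nrow(fp)) tab <- rbind(tab, as.data.frame(fp))
  }
  tab <- tab[order(tab$frame), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = localization_table(tab, config$pixel_size, config$frame_time,
                                  config$seed, field),
       truth = truth)
}

#' Synthetic stage-micrometre grating image
#'
#' Renders a 16-bit widefield-style image of a calibrated line grating: dark
#' lines on a bright background, box line profiles convolved with a Gaussian
#' edge blur, optional additive Gaussian noise, and an optional linear field
#' distortion (a position-dependent magnification emulating the optics).
#'
#' @param pitch_nm nominal line pitch (nm); stage micrometres are typically
#'   10 um.
#' @param n_lines number of lines.
#' @param pixel_size object-space pixel size (nm/pixel).
#' @param line_width_nm full width of each dark line (nm).
#' @param edge_blur_nm Gaussian edge blur sigma (nm); 0 gives hard edges.
#' @param noise_sd additive Gaussian noise sigma (counts).
#' @param distortion fractional linear magnification gradient across the
#'   field: the local scale varies from `1 - distortion/2` to
#'   `1 + distortion/2` between the first and last line.
#' @param background,depth bright level and line depth (counts).
#' @param height_px image height in pixels.
#' @param margin_nm margin before the first and after the last line centre.
#' @return list `image` (integer matrix, counts in 0..65535) and `truth`
#'   (data.frame `line`, `center_nm`, `center_px`), where pixel column j
#'   spans `[(j-1) * P, j * P)` nm so `center_px = center_nm / pixel_size`.
#' @export
generate_micrometre_image <- function(pitch_nm = 10000, n_lines = 10,
                                      pixel_size = 100, line_width_nm = 2000,
                                      edge_blur_nm = 300, noise_sd = 0,
                                      distortion = 0, background = 50000,
                                      depth = 40000, height_px = 64,
                                      margin_nm = 5000) {
  stopifnot(n_lines >= 2, pitch_nm > 0, pixel_size > 0)
  centers <- margin_nm + (seq_len(n_lines) - 1) * pitch_nm
  if (distortion != 0) {
    span <- centers[n_lines] - centers[1]
    mid <- (centers[1] + centers[n_lines]) / 2
    centers <- mid + (centers - mid) * (1 + distortion * (centers - mid) / span)
  }
  width_nm <- centers[length(centers)] + margin_nm
  width_px <- ceiling(width_nm / pixel_size)
  xs <- (seq_len(width_px) - 0.5) * pixel_size  # pixel-centre coordinates, nm
  profile <- rep(background, width_px)
  hw <- line_width_nm / 2
  for (c0 in centers) {
    if (edge_blur_nm > 0) {
      dip <- stats::pnorm((xs - (c0 - hw)) / edge_blur_nm) -
        stats::pnorm((xs - (c0 + hw)) / edge_blur_nm)
    } else {
      dip <- as.numeric(xs >= c0 - hw & xs < c0 + hw)
    }
    profile <- profile - depth * dip
  }
  img <- matrix(rep(profile, each = height_px), nrow = height_px)
  if (noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd), nrow = height_px)
  img[] <- pmin(65535, pmax(0, round(img)))
  storage.mode(img) <- "integer"
  list(image = img,
       truth = data.frame(line = seq_len(n_lines), center_nm = centers,
                          center_px = centers / pixel_size))
}

#' Matched two-color bead coordinates
#'
#' Multicolor beads visible in both channels: green coordinates uniform over
#' the field, red coordinates obtained by applying a [channel_transform()]
#' plus isotropic Gaussian noise.
#'
#' @param n number of beads.
#' @param transform a [channel_transform()] mapping green to red.
#' @param noise_nm per-coordinate Gaussian noise sigma (nm).
#' @param field c(width, height) nm.
#' @param seed optional seed (NULL leaves the RNG state alone).
#' @return data.frame `gx`, `gy`, `rx`, `ry` (nm).
#' @export
generate_bead_pairs <- function(n, transform = channel_transform(),
                                noise_nm = 0, field = c(40960, 40960),
                                seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- cbind(stats::runif(n, 0, field[1]), stats::runif(n, 0, field[2]))
  r <- predict(transform, g)
  if (noise_nm > 0) r <- r + matrix(stats::rnorm(2 * n, 0, noise_nm), ncol = 2)
  data.frame(gx = g[, 1], gy = g[, 2], rx = r[, 1], ry = r[, 2])
}

#' Render a super-resolution image from a localization table
#'
#' 2D histogram of localization counts on half-open bins of width `bin_nm`:
#' bin (i, j) covers `[ (i-1)*bin, i*bin )` nm, so a localization sitting
#' exactly on a boundary belongs to the higher bin.
#'
#' @param table a [localization_table()] (or data.frame with `x_nm`, `y_nm`).
#' @param bin_nm bin width in nm.
#' @param field c(width, height) nm; defaults to the table's `field`
#'   attribute, else the data extent rounded up to whole bins.
#' @return integer matrix (rows = y, columns = x) with attribute `bin_nm`;
#'   its sum equals the number of in-field localizations.
#' @export
render_sr_image <- function(table, bin_nm = 10, field = NULL) {
  stopifnot(bin_nm > 0)
  if (is.null(field)) field <- attr(table, "field")
  x <- table$x_nm
  y <- table$y_nm
  if (is.null(field)) {
    field <- c(max(x, bin_nm) , max(y, bin_nm))
    field <- ceiling(field / bin_nm + 1e-9) * bin_nm
  }
  nxb <- max(1L, as.integer(ceiling(field[1] / bin_nm - 1e-9)))
  nyb <- max(1L, as.integer(ceiling(field[2] / bin_nm - 1e-9)))
  inb <- x >= 0 & y >= 0 & x < nxb * bin_nm & y < nyb * bin_nm
  ix <- floor(x[inb] / bin_nm)
  iy <- floor(y[inb] / bin_nm)
  img <- matrix(tabulate(iy * nxb + ix + 1, nbins = nxb * nyb),
                nrow = nyb, ncol = nxb, byrow = TRUE)
  attr(img, "bin_nm") <- bin_nm
  img
}
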