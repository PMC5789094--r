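# Two-color channel registration: a six-coefficient linear (affine) map from
# the green to the red channel, solved from matched bead coordinates, plus
# the correlation-image / correlation-density evaluation of the correction.

#' Affine green-to-red channel transform
#'
#' `x_red = a*x_green + b*y_green + c`, `y_red = d*x_green + e*y_green + f`.
#' `a, b, d, e` are dimensionless, `c, f` are in nm. The identity is
#' `(1, 0, 0, 0, 1, 0)`.
#'
#' @param a,b,c,d,e,f coefficients.
#' @return object of class `channel_transform`.
#' @export
channel_transform <- function(a = 1, b = 0, c = 0, d = 0, e = 1, f = 0) {
  co <- c(a = a, b = b, c = c, d = d, e = e, f = f)
  if (!all(is.finite(co)))
    stop("channel transform coefficients must be finite", call. = FALSE)
  structure(list(coef = co), class = "channel_transform")
}

#' @export
coef.channel_transform <- function(object, ...) object$coef

#' @export
print.channel_transform <- function(x, ...) {
  co <- x$coef
  cat("Channel transform (green -> red):\n")
  cat(sprintf("  x_red = %+.6f * x + %+.6f * y %+.3f nm\n",
              co["a"], co["b"], co["c"]))
  cat(sprintf("  y_red = %+.6f * x + %+.6f * y %+.3f nm\n",
              co["d"], co["e"], co["f"]))
  rs <- attr(x, "rmse_nm")
  if (!is.null(rs)) cat(sprintf("  fit RMSE: %.3f nm (n = %d beads)\n",
                                rs, attr(x, "n_pairs")))
  invisible(x)
}

#' @export
predict.channel_transform <- function(object, newdata, ...) {
  co <- object$coef
  xy <- if (is.data.frame(newdata)) cbind(newdata[[1]], newdata[[2]]) else
    as.matrix(newdata)
  cbind(co["a"] * xy[, 1] + co["b"] * xy[, 2] + co["c"],
        co["d"] * xy[, 1] + co["e"] * xy[, 2] + co["f"])
}

#' Solve the channel transform from matched bead pairs
#'
#' With exactly three non-collinear pairs the 3x3 linear system is solved
#' exactly; with more pairs the coefficients are the least-squares solution.
#'
#' @param pairs data.frame with columns `gx`, `gy`, `rx`, `ry` (nm), e.g.
#'   from [generate_bead_pairs()].
#' @return a [channel_transform()] with attributes `residuals_nm` (n x 2),
#'   `rmse_nm` and `n_pairs`.
#' @export
solve_channel_transform <- function(pairs) {
  n <- nrow(pairs)
  if (n < 3) stop("need at least 3 matched pairs", call. = FALSE)
  A <- cbind(pairs$gx, pairs$gy, 1)
  qa <- qr(A)
  if (qa$rank < 3)
    stop("matched pairs are collinear/degenerate: transform not determined",
         call. = FALSE)
  bx <- qr.coef(qa, pairs$rx)
  by <- qr.coef(qa, pairs$ry)
  tr <- channel_transform(a = bx[1], b = bx[2], c = bx[3],
                          d = by[1], e = by[2], f = by[3])
  res <- cbind(pairs$rx, pairs$ry) - predict(tr, cbind(pairs$gx, pairs$gy))
  attr(tr, "residuals_nm") <- res
  attr(tr, "rmse_nm") <- sqrt(mean(res^2))
  attr(tr, "n_pairs") <- n
  tr
}

#' Invert a channel transform
#'
#' @param transform a [channel_transform()].
#' @return the red-to-green [channel_transform()].
#' @export
invert_transform <- function(transform) {
  co <- transform$coef
  M <- matrix(co[c("a", "d", "b", "e")], 2)
  Mi <- solve(M)
  t0 <- -Mi %*% co[c("c", "f")]
  channel_transform(a = Mi[1, 1], b = Mi[1, 2], c = t0[1],
                    d = Mi[2, 1], e = Mi[2, 2], f = t0[2])
}

#' Apply a channel transform to a localization table
#'
#' Maps `x_nm`, `y_nm`; every other column and all metadata are untouched.
#'
#' @param table a [localization_table()] (or data.frame with `x_nm`,
#'   `y_nm`).
#' @param transform a [channel_transform()].
#' @return the table with transformed coordinates.
#' @export
apply_transform <- function(table, transform) {
  xy <- predict(transform, cbind(table$x_nm, table$y_nm))
  table$x_nm <- xy[, 1]
  table$y_nm <- xy[, 2]
  table
}

#' Correlation image of two rendered channels
#'
#' Element-wise product of the red and green binned images: zero wherever
#' the channels do not overlap, large where registered structures coincide.
#'
#' @param red,green equally sized and equally binned matrices from
#'   [render_sr_image()].
#' @return product matrix, `bin_nm` attribute preserved.
#' @export
correlation_image <- function(red, green) {
  if (!all(dim(red) == dim(green)))
    stop("channel images must have identical dimensions", call. = FALSE)
  br <- attr(red, "bin_nm"); bg <- attr(green, "bin_nm")
  if (!is.null(br) && !is.null(bg) && br != bg)
    stop("channel images must share the same binning", call. = FALSE)
  out <- red * green
  attr(out, "bin_nm") <- if (!is.null(br)) br else bg
  out
}

#' Correlation density over the field of view
#'
#' Sums the correlation image over non-overlapping square tiles (partial
#' edge tiles are dropped; the grid is anchored at the image origin),
#' normalizes the tile map to its maximum, and reports the coefficient of
#' variation of the tile sums as the uniformity statistic: a proper
#' registration gives a constant map within counting noise, a bad one a
#' gradient.
#'
#' @param product correlation image from [correlation_image()] (needs a
#'   `bin_nm` attribute or explicit `bin_nm`).
#' @param tile_um tile side length in micrometres.
#' @param bin_nm bin width override.
#' @return object of class `correlation_map`: `tile_sums`, `normalized`
#'   (max = 1), `cv`, `tile_um`, `bin_nm`.
#' @export
correlation_density <- function(product, tile_um = 1.6, bin_nm = NULL) {
  if (is.null(bin_nm)) bin_nm <- attr(product, "bin_nm")
  if (is.null(bin_nm)) stop("bin_nm unknown: pass it explicitly",
                            call. = FALSE)
  tpx <- as.integer(round(tile_um * 1000 / bin_nm))
  if (tpx < 1) stop("tile smaller than one bin", call. = FALSE)
  nr <- nrow(product) %/% tpx
  nc <- ncol(product) %/% tpx
  if (nr < 1 || nc < 1)
    stop(sprintf("field (%d x %d bins) smaller than one %.1f um tile",
                 nrow(product), ncol(product), tile_um), call. = FALSE)
  sub <- product[seq_len(nr * tpx), seq_len(nc * tpx), drop = FALSE]
  g1 <- rowsum(sub, rep(seq_len(nr), each = tpx))
  sums <- t(rowsum(t(g1), rep(seq_len(nc), each = tpx)))
  mx <- max(sums)
  norm <- if (mx > 0) sums / mx else sums
  mu <- mean(sums)
  cv <- if (mu > 0) stats::sd(sums) / mu else NA_real_
  structure(list(tile_sums = sums, normalized = norm, cv = cv,
                 tile_um = tile_um, bin_nm = bin_nm),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("Correlation density: %d x %d tiles of %.1f um\n",
              nrow(x$tile_sums), ncol(x$tile_sums), x$tile_um))
  cat(sprintf("  tile sums: mean %.1f, CV %.3f\n",
              mean(x$tile_sums), x$cv))
  invisible(x)
}

#' @export
plot.correlation_map <- function(x, ...) {
  graphics::image(t(x$normalized)[, rev(seq_len(nrow(x$normalized))),
                                  drop = FALSE],
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = nrow(x$normalized) / ncol(x$normalized),
                  ...)
  invisible(x)
}
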