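# Measurement model and uncertainty budget for the ensemble-mean projected
# intermark distance, following the GUM: a_proj = P * (d + sum of
# corrections), all corrections with expectation zero but finite standard
# uncertainty; random contributions average as 1/sqrt(n) over the ensemble,
# systematic ones do not; independent inputs combine in quadrature and the
# expanded uncertainty is U = k * u.

#' Define one input quantity of the uncertainty budget
#'
#' @param name quantity name (e.g. `"d_k"`, `"dd_fit"`, `"dd_env"`).
#' @param u standard uncertainty in native units (pixels for distance-like
#'   corrections).
#' @param kind `"random"` (averages as 1/sqrt(n) over the ensemble) or
#'   `"systematic"` (acts identically on every structure).
#' @param unit native unit label.
#' @return object of class `input_quantity`.
#' @export
input_quantity <- function(name, u, kind = c("random", "systematic"),
                           unit = "pixel") {
  kind <- match.arg(kind)
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < 0)
    stop("standard uncertainty of '", name, "' must be a single number >= 0",
         call. = FALSE)
  structure(list(name = name, u = u, kind = kind, unit = unit),
            class = "input_quantity")
}

#' Projected distance measurement model
#'
#' `a_proj = P * (d + sum(corrections))`: the measured 2D-projected distance
#' in nm from the distance in pixels, the pixel size, and additive
#' corrections (pixels) for fit, model, blinking, environment and
#' false-positive effects.
#'
#' @param P pixel size (nm/pixel).
#' @param d measured distance (pixels).
#' @param corrections numeric vector of corrections (pixels).
#' @return projected distance in nm.
#' @export
#' @examples
#' project_distance(100, 0.6)            # 60 nm
#' project_distance(100, 0.6, -0.01)     # 59 nm
project_distance <- function(P, d, corrections = numeric()) {
  P * (d + sum(corrections))
}

#' Combined standard uncertainty of a single projected distance
#'
#' First-order GUM propagation through the measurement model for independent
#' inputs:
#' `u^2 = u_P^2 * (d + sum(dd))^2 + P^2 * (u_d^2 + sum(u_dd^2))`.
#'
#' @param P,u_P pixel size and its standard uncertainty (nm/pixel).
#' @param d,u_d distance (pixels) and its standard uncertainty.
#' @param corrections,u_corrections corrections (pixels) and their standard
#'   uncertainties.
#' @return standard uncertainty of `a_proj` in nm.
#' @export
combine_uncertainty_single <- function(P, u_P, d, u_d = 0,
                                       corrections = numeric(),
                                       u_corrections = numeric()) {
  sqrt(u_P^2 * (d + sum(corrections))^2 +
         P^2 * (u_d^2 + sum(u_corrections^2)))
}

#' Build the uncertainty budget of the ensemble-mean distance
#'
#' Propagates the input standard uncertainties into nm-scale contributions
#' to `u(a_proj_bar)`:
#' * pixel size: `u_P * d_bar` (the correction expectation values are zero,
#'   so the sensitivity of the `P` term is the mean distance itself);
#' * random inputs: `P * u / sqrt(n)`;
#' * systematic inputs: `P * u`.
#' Contributions combine in quadrature (independent inputs) and the expanded
#' uncertainty is `U = k * u`. Contributions are *displayed* at 2 decimals
#' and `U` at 1 decimal, but the combination always uses unrounded values.
#'
#' @param inputs list of [input_quantity()] objects, in budget row order.
#' @param P,u_P pixel size and its standard uncertainty (nm/pixel).
#' @param d_bar ensemble-mean distance (pixels).
#' @param n number of measured structures.
#' @param k coverage factor (default 2, about 95 % coverage).
#' @return object of class `uncertainty_budget`.
#' @export
#' @examples
#' b <- build_budget(
#'   list(input_quantity("d_k", 0.05, "random"),
#'        input_quantity("dd_fit,k", 0.0035, "random"),
#'        input_quantity("dd_env", 0.005, "systematic"),
#'        input_quantity("dd_blink", 0.001, "systematic"),
#'        input_quantity("dd_fp", 0.009, "systematic"),
#'        input_quantity("dd_model", 0.005, "systematic")),
#'   P = 100, u_P = 0.5, d_bar = 0.6, n = 1000)
#' b
build_budget <- function(inputs, P, u_P, d_bar, n, k = 2) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (k <= 0) stop("coverage factor k must be > 0", call. = FALSE)
  if (u_P < 0) stop("u_P must be >= 0", call. = FALSE)
  for (q in inputs)
    if (!inherits(q, "input_quantity"))
      stop("inputs must be a list of input_quantity objects", call. = FALSE)
  contr_P <- u_P * d_bar
  rows <- data.frame(
    quantity = c("P", vapply(inputs, `[[`, character(1), "name")),
    u_input = c(u_P, vapply(inputs, `[[`, numeric(1), "u")),
    unit = c("nm/pixel", vapply(inputs, `[[`, character(1), "unit")),
    kind = c("systematic", vapply(inputs, `[[`, character(1), "kind")),
    stringsAsFactors = FALSE)
  contr <- c(contr_P, vapply(inputs, function(q) {
    if (q$kind == "random") P * q$u / sqrt(n) else P * q$u
  }, numeric(1)))
  rows$contribution_nm <- contr
  u_comb <- sqrt(sum(contr^2))
  structure(list(table = rows, P = P, u_P = u_P, d_bar = d_bar, n = n,
                 k = k, u_combined_nm = u_comb, U_nm = k * u_comb),
            class = "uncertainty_budget")
}

#' @export
print.uncertainty_budget <- function(x, ...) {
  tb <- x$table
  cat(sprintf(
    "Uncertainty budget for the mean intermark distance (n = %d, P = %g nm/pixel, d_bar = %g px)\n\n",
    x$n, x$P, x$d_bar))
  su <- sprintf("%g %s", tb$u_input, tb$unit)
  co <- sprintf("%.2f", tb$contribution_nm)
  w1 <- max(nchar("Input quantity"), nchar(tb$quantity))
  w2 <- max(nchar("Standard uncertainty"), nchar(su))
  fmt <- paste0("  %-", w1, "s  %-", w2, "s  %s\n")
  cat(sprintf(fmt, "Input quantity", "Standard uncertainty",
              "Contribution to u (nm)"))
  for (i in seq_len(nrow(tb)))
    cat(sprintf(fmt, tb$quantity[i], su[i], co[i]))
  cat(sprintf("\n  Combined standard uncertainty: %.2f nm\n",
              x$u_combined_nm))
  cat(sprintf("  Expanded measurement uncertainty (k = %g): U = %.1f nm\n",
              x$k, x$U_nm))
  invisible(x)
}

#' @export
summary.uncertainty_budget <- function(object, ...) print(object, ...)

#' @export
as.data.frame.uncertainty_budget <- function(x, ...) x$table

#' @export
plot.uncertainty_budget <- function(x, ...) {
  tb <- x$table
  graphics::barplot(tb$contribution_nm, names.arg = tb$quantity,
                    las = 2, ylab = "contribution to u (nm)",
                    col = ifelse(tb$kind == "random", "steelblue",
                                 "indianred"), ...)
  invisible(x)
}

#' Assemble the budget from pipeline results
#'
#' Wires the measured ensemble (its SD becomes the per-structure random
#' `u(d_k)`, its mean per-fit uncertainty becomes `u(dd_fit,k)`), the
#' pixel-size calibration, and the supplied systematic correction
#' uncertainties (pixels) into [build_budget()].
#'
#' @param ensemble an [ensemble_stats()] result.
#' @param cal a [calibrate_pixel_size()] result (or list with `P`, `u_P`).
#' @param u_env_px,u_blink_px,u_fp_px,u_model_px systematic standard
#'   uncertainties in pixels.
#' @param k coverage factor.
#' @return an `uncertainty_budget`.
#' @export
budget_from_pipeline <- function(ensemble, cal, u_env_px = 0.005,
                                 u_blink_px = 0.001, u_fp_px = 0.009,
                                 u_model_px = 0.005, k = 2) {
  P <- cal$P
  inputs <- list(
    input_quantity("d_k", ensemble$sd_nm / P, "random"),
    input_quantity("dd_fit,k", ensemble$mean_u_fit_nm / P, "random"),
    input_quantity("dd_env", u_env_px, "systematic"),
    input_quantity("dd_blink", u_blink_px, "systematic"),
    input_quantity("dd_fp", u_fp_px, "systematic"),
    input_quantity("dd_model", u_model_px, "systematic"))
  build_budget(inputs, P = P, u_P = cal$u_P,
               d_bar = ensemble$mean_nm / P, n = ensemble$n, k = k)
}
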