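# Independent oracles and fixture builders used across the test files.
# These deliberately re-derive results by brute force / closed form and do
# not share code with the package internals they check.

# small, fast simulation configuration for tests that only need the shape
quick_config <- function(...) {
  sim_config(n_frames = 4000L, ...)
}

# build a localization table from bare coordinates
make_table <- function(x, y, frame = 1L, photons = 1000, sigma = 2,
                       source = "site", pixel_size = 100, frame_time = 0.1,
                       field = NULL) {
  n <- length(x)
  localization_table(
    data.frame(frame = rep_len(as.integer(frame), n), x_nm = x, y_nm = y,
               photons = rep_len(photons, n), sigma_nm = rep_len(sigma, n),
               source = rep_len(source, n), stringsAsFactors = FALSE),
    pixel_size, frame_time, field = field)
}

# O(n^2) reference DBSCAN (core = >= minPts neighbours incl. self; border
# points join the cluster of their nearest core neighbour)
brute_dbscan <- function(x, y, eps, minPts) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y))) <= eps
  diag(D) <- TRUE
  core <- rowSums(D) >= minPts
  cl <- integer(n)
  cid <- 0L
  for (i in which(core)) {
    if (cl[i]) next
    cid <- cid + 1L
    q <- i
    cl[i] <- cid
    while (length(q)) {
      j <- q[1]
      q <- q[-1]
      nb <- which(D[j, ] & core & cl == 0L)
      cl[nb] <- cid
      q <- c(q, nb)
    }
  }
  for (i in which(!core)) {
    nb <- which(D[i, ] & core)
    if (length(nb)) {
      d2 <- (x[nb] - x[i])^2 + (y[nb] - y[i])^2
      cl[i] <- cl[nb[order(d2, cl[nb])][1]]
    }
  }
  cl
}

# canonical relabeling of a partition so two labelings can be compared
canon_partition <- function(cl) {
  out <- integer(length(cl))
  pos <- cl > 0L
  out[pos] <- match(cl[pos], unique(cl[pos]))
  out
}

# exhaustive-restart EM for a 1D equal-variance two-Gaussian mixture:
# many split-point initialisations, keep the best log-likelihood
oracle_em_1d <- function(s, n_starts = 40) {
  best <- NULL
  n <- length(s)
  qs <- stats::quantile(s, probs = seq(0.05, 0.95, length.out = n_starts),
                        names = FALSE)
  for (q in unique(qs)) {
    lo <- s <= q
    if (!any(lo) || all(lo)) next
    mu <- c(mean(s[lo]), mean(s[!lo]))
    sg <- max(stats::sd(s), 1e-8)
    p <- mean(lo)
    for (it in 1:5000) {
      d1 <- p * stats::dnorm(s, mu[1], sg)
      d2 <- (1 - p) * stats::dnorm(s, mu[2], sg)
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      r <- d1 / tot
      n1 <- sum(r)
      if (n1 < 1e-9 || n - n1 < 1e-9) break
      mu_new <- c(sum(r * s) / n1, sum((1 - r) * s) / (n - n1))
      sg_new <- max(1e-8, sqrt((sum(r * (s - mu_new[1])^2) +
                                  sum((1 - r) * (s - mu_new[2])^2)) / n))
      p_new <- n1 / n
      delta <- max(abs(c(mu_new - mu, sg_new - sg, p_new - p)))
      mu <- mu_new; sg <- sg_new; p <- p_new
      if (delta < 1e-13) break
    }
    ll <- sum(log(p * stats::dnorm(s, mu[1], sg) +
                    (1 - p) * stats::dnorm(s, mu[2], sg)))
    if (is.null(best) || ll > best$ll)
      best <- list(mu = sort(mu), sigma = sg, p = p, ll = ll)
  }
  best
}

# Table-1-style budget used by several tests
reference_budget <- function(n = 1000, k = 2) {
  build_budget(list(
    input_quantity("d_k", 0.05, "random"),
    input_quantity("dd_fit,k", 0.0035, "random"),
    input_quantity("dd_env", 0.005, "systematic"),
    input_quantity("dd_blink", 0.001, "systematic"),
    input_quantity("dd_fp", 0.009, "systematic"),
    input_quantity("dd_model", 0.005, "systematic")),
    P = 100, u_P = 0.5, d_bar = 0.6, n = n, k = k)
}

# two sequential-imaging "color channels" of the same simulated ruler field:
# one long acquisition split in half by frame (independent blinking, shared
# geometry), the classic exchange-imaging situation
two_color_field <- function(n_rulers = 240, seed = 5, min_spacing = 500,
                            n_frames = 24000L) {
  cfg <- sim_config(seed = seed, n_frames = n_frames)
  sim <- generate_nanoruler_field(cfg, n_rulers, min_spacing = min_spacing)
  half <- n_frames %/% 2L
  tab <- sim$table
  green <- tab[tab$frame <= half, , drop = FALSE]
  red <- tab[tab$frame > half, , drop = FALSE]
  for (t2 in list(green, red)) class(t2) <- class(tab)
  attr(green, "field") <- attr(tab, "field")
  attr(red, "field") <- attr(tab, "field")
  list(green = green, red = red, field = attr(tab, "field"),
       truth = sim$truth, table = tab)
}

# predicted tile-sum coefficient of variation for random placement of
# per-structure correlation masses over T tiles (counting-noise oracle)
predicted_cv <- function(masses, n_tiles) {
  sqrt(n_tiles * sum(masses^2)) / sum(masses)
}

# per-ruler correlation mass on a shared 10 nm grid
ruler_corr_masses <- function(green, red, truth, bin_nm = 10) {
  vapply(truth$ruler, function(k) {
    pre <- sprintf("^r%d:", k)
    g <- green[grepl(pre, green$source), , drop = FALSE]
    r <- red[grepl(pre, red$source), , drop = FALSE]
    if (!nrow(g) || !nrow(r)) return(0)
    gk <- paste(floor(g$x_nm / bin_nm), floor(g$y_nm / bin_nm))
    rk <- paste(floor(r$x_nm / bin_nm), floor(r$y_nm / bin_nm))
    gt <- table(gk)
    rt <- table(rk)
    common <- intersect(names(gt), names(rt))
    sum(as.numeric(gt[common]) * as.numeric(rt[common]))
  }, numeric(1))
}
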