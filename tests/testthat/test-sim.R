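# Monte-Carlo simulator: kinetics, camera discretization, field generation,
# rendering, and the origami design-distance rule.

test_that("no sites yield no binding events", {
  cfg <- quick_config()
  ev <- simulate_binding_events(cfg, matrix(numeric(), ncol = 2))
  expect_equal(nrow(ev), 0L)
})

test_that("event count matches the renewal-process expectation", {
  # 1 site over T = 1000 mean cycles: count ~ T/(t_on + t_off) with
  # renewal scatter var ~ n * (var_cycle / mean_cycle^2) = n/2 here
  cfg <- sim_config(t_on = 0.5, t_off = 0.5, frame_time = 1,
                    n_frames = 1000L)
  expected <- 1000
  sd_count <- sqrt(1000 * (0.5^2 + 0.5^2) / 1^2)
  for (s in 1:3) {
    set.seed(s)
    ev <- simulate_binding_events(cfg, matrix(0, 1, 2))
    expect_lt(abs(nrow(ev) - expected), 5 * sd_count)
  }
})

test_that("long-run ON fraction converges to the duty cycle", {
  cfg <- sim_config(t_on = 1, t_off = 4, frame_time = 1, n_frames = 5000L)
  set.seed(42)
  ev <- simulate_binding_events(cfg, matrix(0, 1, 2))
  on_frac <- sum(ev$t_end - ev$t_start) / 5000
  # ~1000 cycles; MC standard error of the ON fraction is ~0.006
  expect_lt(abs(on_frac - 1 / 5), 0.02)
})

test_that("invalid configurations name the offending field", {
  expect_error(sim_config(t_on = -1), "t_on")
  expect_error(sim_config(site_activity_prob = 1.5), "site_activity_prob")
  expect_error(sim_config(fp_density = -0.1), "fp_density")
  expect_error(sim_config(drift_velocity = 1), "drift_velocity")
})

test_that("zero-noise limit puts localizations exactly on the site", {
  cfg <- sim_config(photons_per_frame = Inf, n_frames = 200L,
                    t_on = 5, t_off = 5)
  set.seed(1)
  sites <- matrix(c(123.4, 567.8), 1, 2)
  ev <- simulate_binding_events(cfg, sites)
  tab <- events_to_localizations(ev, cfg, sites)
  expect_gt(nrow(tab), 0)
  expect_equal(tab$x_nm, rep(123.4, nrow(tab)))
  expect_equal(tab$y_nm, rep(567.8, nrow(tab)))
  expect_equal(tab$sigma_nm, rep(0, nrow(tab)))
})

test_that("localization noise follows sigma_psf / sqrt(N)", {
  # permanently ON single site; empirical SD vs closed form across photon
  # levels, tolerance 3 Monte-Carlo standard errors of an SD estimate
  for (N in c(100, 400, 1600)) {
    cfg <- sim_config(photons_per_frame = N, sigma_psf = 100,
                      t_on = 1e9, t_off = 1e-6, n_frames = 4000L,
                      min_photons = 1)
    set.seed(N)
    sites <- matrix(c(5000, 5000), 1, 2)
    tab <- events_to_localizations(simulate_binding_events(cfg, sites),
                                   cfg, sites)
    expected <- 100 / sqrt(N)
    n <- nrow(tab)
    mc_se <- expected / sqrt(2 * n)
    expect_lt(abs(stats::sd(tab$x_nm) - expected), 3 * mc_se + 0.01 * expected)
    expect_lt(abs(stats::sd(tab$y_nm) - expected), 3 * mc_se + 0.01 * expected)
  }
})

test_that("simultaneous emitters within the merge radius fuse at the centroid", {
  cfg <- sim_config(photons_per_frame = Inf, t_on = 1e9, t_off = 1e-6,
                    n_frames = 5L, merge_radius = 100)
  set.seed(3)
  sites <- matrix(c(0, 30, 0, 0), 2, 2)  # 30 nm apart, both always ON
  tab <- events_to_localizations(simulate_binding_events(cfg, sites),
                                 cfg, sites)
  expect_equal(nrow(tab), 5L)            # one localization per frame
  expect_equal(tab$x_nm, rep(15, 5))     # midpoint (equal weights)
  expect_equal(tab$y_nm, rep(0, 5))
  expect_true(all(tab$source == "merged"))
})

test_that("same configuration and seed reproduce the field bit-identically", {
  cfg <- quick_config(seed = 77)
  a <- generate_nanoruler_field(cfg, 12)
  b <- generate_nanoruler_field(cfg, 12)
  expect_identical(a$table, b$table)
  expect_identical(a$truth, b$truth)
  # growing the field keeps existing rulers unchanged
  c <- generate_nanoruler_field(cfg, 15)
  expect_identical(a$truth$distance_nm, c$truth$distance_nm[1:12])
  expect_identical(a$truth$theta, c$truth$theta[1:12])
})

test_that("single ruler with zero spread carries exactly the design distance", {
  cfg <- quick_config(true_distance_mean = 60, true_distance_sd = 0, seed = 2)
  sim <- generate_nanoruler_field(cfg, 1)
  expect_identical(sim$truth$distance_nm, 60)
  expect_error(generate_nanoruler_field(cfg, 100, field = c(3000, 3000)),
               "too small")
})

test_that("every localization carries exactly one source label", {
  cfg <- quick_config(seed = 4, fp_density = 0.00005)
  sim <- generate_nanoruler_field(cfg, 10)
  src <- sim$table$source
  expect_true(all(nchar(src) > 0))
  expect_true(all(grepl("^r[0-9]+:(m[0-9]+:s[0-9]+|merged)$|^fp$", src)))
})

test_that("design distance combines helix and base offsets Euclidean", {
  expect_equal(design_distance(0, 100), 34)
  expect_equal(design_distance(10, 0), 30)
  expect_equal(design_distance(3, 40), sqrt(9^2 + 13.6^2))
  expect_error(design_distance(1.5, 0))
})

test_that("rendered image counts every in-field localization once", {
  tab <- make_table(5, 5, field = c(100, 100))
  img <- render_sr_image(tab, 10)
  expect_equal(sum(img), 1)
  # half-open convention: a localization exactly on a boundary goes to the
  # higher bin
  tab2 <- make_table(20, 0.1, field = c(100, 100))
  img2 <- render_sr_image(tab2, 10)
  expect_equal(which(img2[1, ] == 1), 3L)  # bin [20, 30)
})

test_that("uniform localizations render uniformly (chi-square)", {
  set.seed(11)
  n <- 20000
  tab <- make_table(stats::runif(n, 0, 2000), stats::runif(n, 0, 2000),
                    field = c(2000, 2000))
  img <- render_sr_image(tab, 100)
  p <- stats::chisq.test(as.vector(img))$p.value
  expect_gt(p, 0.01)
})

test_that("micrometre truth hits the configured grid", {
  g <- generate_micrometre_image(pitch_nm = 10000, n_lines = 5,
                                 pixel_size = 100, edge_blur_nm = 0,
                                 noise_sd = 0)
  expect_equal(diff(g$truth$center_nm), rep(10000, 4))
  expect_equal(diff(g$truth$center_px), rep(100, 4))
  expect_true(is.integer(g$image))
  expect_true(all(g$image >= 0 & g$image <= 65535))
})

test_that("bead pairs follow the configured transform", {
  id <- channel_transform()
  p0 <- generate_bead_pairs(10, id, noise_nm = 0, seed = 1)
  expect_equal(p0$rx, p0$gx)
  expect_equal(p0$ry, p0$gy)
  sh <- channel_transform(c = 90, f = -30)
  p1 <- generate_bead_pairs(10, sh, noise_nm = 0, seed = 1)
  expect_equal(p1$rx - p1$gx, rep(90, 10))
  expect_equal(p1$ry - p1$gy, rep(-30, 10))
})
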