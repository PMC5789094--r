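# Channel registration: solving and applying the affine transform, the
# correlation image, and the correlation-density uniformity statistic.

test_that("identical coordinate sets solve to the identity", {
  set.seed(1)
  g <- cbind(stats::runif(10, 0, 5000), stats::runif(10, 0, 5000))
  pairs <- data.frame(gx = g[, 1], gy = g[, 2], rx = g[, 1], ry = g[, 2])
  tr <- solve_channel_transform(pairs)
  expect_equal(unname(coef(tr)), c(1, 0, 0, 0, 1, 0), tolerance = 1e-9)
})

test_that("a pure shift is recovered as a constant vector", {
  pairs <- generate_bead_pairs(15, channel_transform(c = 90, f = -40),
                               noise_nm = 0, seed = 2)
  tr <- solve_channel_transform(pairs)
  co <- coef(tr)
  expect_lt(abs(co["a"] - 1), 1e-9)
  expect_lt(abs(co["e"] - 1), 1e-9)
  expect_lt(abs(co["b"]), 1e-9)
  expect_lt(abs(co["d"]), 1e-9)
  expect_equal(unname(co["c"]), 90, tolerance = 1e-6)
  expect_equal(unname(co["f"]), -40, tolerance = 1e-6)
})

test_that("noiseless affine-generated pairs are recovered to 1e-9", {
  tr0 <- channel_transform(a = 1.0004, b = -3e-4, c = 91.7, d = 2e-4,
                           e = 0.9991, f = -38.2)
  # exactly three non-collinear beads: determined system, exact solve
  g3 <- data.frame(gx = c(0, 4000, 1000), gy = c(0, 500, 3500))
  r3 <- predict(tr0, g3)
  tr_ex <- solve_channel_transform(cbind(g3, rx = r3[, 1], ry = r3[, 2]))
  expect_lt(max(abs(coef(tr_ex) - coef(tr0))), 1e-9)
  # overdetermined: 20 beads
  pairs <- generate_bead_pairs(20, tr0, noise_nm = 0, seed = 3)
  tr <- solve_channel_transform(pairs)
  expect_lt(max(abs(coef(tr) - coef(tr0))), 1e-9)
})

test_that("collinear beads are a rank error", {
  g <- data.frame(gx = c(0, 1000, 2000, 3000), gy = c(0, 100, 200, 300))
  pairs <- cbind(g, rx = g$gx + 90, ry = g$gy - 40)
  expect_error(solve_channel_transform(pairs), "collinear|degenerate")
  expect_error(solve_channel_transform(pairs[1:2, ]), "3")
})

test_that("applying a transform only touches the coordinates", {
  tab <- make_table(c(100, 300), c(200, 400), photons = c(900, 1100))
  tr <- channel_transform(c = 50, f = -20)
  out <- apply_transform(tab, tr)
  expect_equal(out$x_nm, c(150, 350))
  expect_equal(out$y_nm, c(180, 380))
  expect_identical(out$photons, tab$photons)
  expect_identical(out$source, tab$source)
  # identity leaves everything unchanged
  expect_identical(apply_transform(tab, channel_transform()), tab)
})

test_that("apply then apply-inverse restores the coordinates", {
  tr <- channel_transform(a = 1.001, b = 5e-4, c = 90, d = -4e-4,
                          e = 0.999, f = -35)
  tab <- make_table(stats::runif(50, 0, 40000), stats::runif(50, 0, 40000))
  back <- apply_transform(apply_transform(tab, tr), invert_transform(tr))
  expect_lt(max(abs(back$x_nm - tab$x_nm)), 1e-9)
  expect_lt(max(abs(back$y_nm - tab$y_nm)), 1e-9)
})

test_that("the correlation image is the element-wise product", {
  a <- matrix(0, 4, 4); b <- matrix(0, 4, 4)
  a[1:2, 1:2] <- 2
  b[3:4, 3:4] <- 5
  expect_true(all(correlation_image(a, b) == 0))      # disjoint supports
  expect_equal(sum(correlation_image(a, a)), sum(a^2))  # identical images
  # hand-computed checkerboard overlap on a 4 x 4 toy
  ch <- matrix(rep(c(1, 0), 8), 4, 4)
  on <- matrix(1, 4, 4)
  expect_equal(correlation_image(ch, on), ch)
  expect_identical(correlation_image(a, b), correlation_image(b, a))
  expect_error(correlation_image(a, matrix(0, 3, 3)), "dimensions")
})

test_that("correlation density normalizes and flags degenerate fields", {
  img <- matrix(3, 320, 320)
  attr(img, "bin_nm") <- 10
  cm <- correlation_density(img, tile_um = 1.6)
  expect_equal(dim(cm$tile_sums), c(2L, 2L))
  expect_true(all(cm$normalized == 1))
  expect_equal(cm$cv, 0)
  # single hot tile -> indicator map
  img2 <- matrix(0, 320, 320)
  img2[1:160, 1:160] <- 1
  attr(img2, "bin_nm") <- 10
  cm2 <- correlation_density(img2)
  expect_equal(sort(as.vector(cm2$normalized)), c(0, 0, 0, 1))
  # smaller than one tile is an error
  small <- matrix(1, 10, 10)
  attr(small, "bin_nm") <- 10
  expect_error(correlation_density(small), "tile")
})

test_that("the normalized map ignores global intensity scaling", {
  set.seed(6)
  img <- matrix(stats::rpois(320 * 320, 2), 320, 320)
  attr(img, "bin_nm") <- 10
  a <- correlation_density(img)
  img2 <- img * 7
  attr(img2, "bin_nm") <- 10
  b <- correlation_density(img2)
  expect_equal(a$normalized, b$normalized)
  expect_equal(a$cv, b$cv)
})

test_that("registered nanoruler fields correlate homogeneously, shifted ones do not", {
  tc <- two_color_field(n_rulers = 240, seed = 5)
  tr0 <- channel_transform(a = 1.0003, b = 1e-4, c = 88, d = -2e-4,
                           e = 0.9996, f = -35)
  # the raw green channel appears displaced by the inverse mismatch
  green_raw <- apply_transform(tc$green, invert_transform(tr0))
  beads <- generate_bead_pairs(25, tr0, noise_nm = 0, field = tc$field,
                               seed = 31)
  tr_hat <- solve_channel_transform(beads)
  green_cor <- apply_transform(green_raw, tr_hat)
  rimg <- render_sr_image(tc$red, 10, tc$field)
  gimg <- render_sr_image(green_cor, 10, tc$field)
  cm_good <- correlation_density(correlation_image(rimg, gimg))
  masses <- ruler_corr_masses(green_cor, tc$red, tc$truth)
  cv_pred <- predicted_cv(masses[masses > 0], length(cm_good$tile_sums))
  expect_lt(cm_good$cv, 3 * cv_pred)
  # mis-register half of the field: clear gradient, elevated CV
  green_bad <- green_cor
  left <- green_bad$x_nm < tc$field[1] / 2
  green_bad$x_nm[left] <- green_bad$x_nm[left] + 150
  gimg_bad <- render_sr_image(green_bad, 10, tc$field)
  cm_bad <- correlation_density(correlation_image(rimg, gimg_bad))
  expect_gt(cm_bad$cv, cm_good$cv)
  nc <- ncol(cm_bad$tile_sums)
  left_tiles <- cm_bad$tile_sums[, seq_len(nc %/% 2)]
  right_tiles <- cm_bad$tile_sums[, seq.int(nc %/% 2 + 1, nc)]
  expect_lt(mean(left_tiles), 0.2 * mean(right_tiles))
})
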