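# Structure picking: density-based clustering against a brute-force oracle,
# the filter cascade, and the picking-bias (false positive) estimate.

test_that("well-separated rulers produce one candidate each", {
  set.seed(21)
  mk <- function(cx, cy) {
    x <- c(stats::rnorm(40, cx - 30, 3), stats::rnorm(40, cx + 30, 3))
    y <- stats::rnorm(80, cy, 3)
    cbind(x, y)
  }
  a <- mk(2000, 2000)
  b <- mk(7000, 7000)
  tab <- make_table(c(a[, 1], b[, 1]), c(a[, 2], b[, 2]),
                    field = c(10000, 10000))
  cands <- cluster_localizations(tab, picking_config())
  expect_equal(nrow(cands$candidates), 2L)
  expect_equal(sort(cands$candidates$n_locs), c(80L, 80L))
})

test_that("clustering matches a brute-force DBSCAN on small instances", {
  for (s in 1:4) {
    set.seed(s)
    n <- 50
    x <- stats::runif(n, 0, 1500)
    y <- stats::runif(n, 0, 1500)
    # add one dense clump so both outcomes occur
    if (s %% 2 == 0) {
      x <- c(x, stats::rnorm(15, 700, 10))
      y <- c(y, stats::rnorm(15, 700, 10))
    }
    cfg <- picking_config(radius_nm = 100, min_neighbors = 5)
    tab <- make_table(x, y, field = c(1500, 1500))
    got <- cluster_localizations(tab, cfg)$assignment
    ref <- brute_dbscan(x, y, 100, 5)
    expect_identical(canon_partition(got), canon_partition(ref))
  }
})

test_that("sparse uniform noise yields no candidates", {
  set.seed(9)
  tab <- make_table(stats::runif(50, 0, 20000), stats::runif(50, 0, 20000),
                    field = c(20000, 20000))
  cands <- cluster_localizations(tab, picking_config())
  expect_equal(nrow(cands$candidates), 0L)
  # empty table is not an error
  e <- cluster_localizations(make_table(numeric(), numeric()),
                             picking_config())
  expect_equal(nrow(e$candidates), 0L)
})

test_that("a simulated ruler is recovered nearly completely", {
  cfg <- quick_config(seed = 31)
  sim <- generate_nanoruler_field(cfg, 1)
  cands <- cluster_localizations(sim$table, default_picking(60))
  expect_equal(nrow(cands$candidates), 1L)
  ruler_rows <- grepl("^r1:", sim$table$source)
  caught <- cands$assignment[ruler_rows] == cands$candidates$id[1]
  expect_gte(mean(caught), 0.95)
})

test_that("filters fire in fixed order and record the first failure", {
  cfg <- picking_config(min_locs = 20, min_rgyr_nm = 8, max_rgyr_nm = 80,
                        bimodality_min = 3, edge_margin_nm = 100)
  # tiny candidate -> too_few_locs
  tab <- make_table(stats::rnorm(3, 500, 30), stats::rnorm(3, 500, 30),
                    field = c(5000, 5000))
  cands <- list(candidates = data.frame(id = 1L, x_nm = 500, y_nm = 500,
                                        rgyr_nm = 30, n_locs = 3L,
                                        accepted = NA, reason = ""),
                assignment = rep(1L, 3), config = cfg,
                field = c(5000, 5000))
  class(cands) <- "nanoruler_candidates"
  out <- filter_candidates(cands, tab, cfg)
  expect_false(out$candidates$accepted)
  expect_equal(out$candidates$reason, "too_few_locs")

  # unimodal isotropic blob -> not_bimodal
  set.seed(5)
  x <- stats::rnorm(100, 1000, 15)
  y <- stats::rnorm(100, 1000, 15)
  tab2 <- make_table(x, y, field = c(5000, 5000))
  c2 <- filter_candidates(cluster_localizations(tab2, cfg), tab2, cfg)
  expect_equal(c2$candidates$reason, "not_bimodal")

  # simulated true ruler with defaults -> accepted
  sim <- generate_nanoruler_field(quick_config(seed = 8), 1)
  c3 <- filter_candidates(cluster_localizations(sim$table,
                                                default_picking(60)),
                          sim$table, default_picking(60))
  expect_true(all(c3$candidates$accepted))
})

test_that("row order does not change the accepted structures", {
  cfg <- quick_config(seed = 13)
  sim <- generate_nanoruler_field(cfg, 8)
  pk <- default_picking(60)
  base <- filter_candidates(cluster_localizations(sim$table, pk),
                            sim$table, pk)
  set.seed(99)
  perm <- sample.int(nrow(sim$table))
  tab2 <- sim$table[perm, , drop = FALSE]
  attr(tab2, "pixel_size") <- attr(sim$table, "pixel_size")
  attr(tab2, "frame_time") <- attr(sim$table, "frame_time")
  attr(tab2, "field") <- attr(sim$table, "field")
  class(tab2) <- class(sim$table)
  shuf <- filter_candidates(cluster_localizations(tab2, pk), tab2, pk)
  # same accepted clusters as sets of original row indices
  sets_of <- function(cands, row_map) {
    acc <- cands$candidates$id[cands$candidates$accepted]
    sets <- lapply(acc, function(id) sort(row_map[cands$assignment == id]))
    sets[order(vapply(sets, min, numeric(1)))]
  }
  expect_identical(sets_of(base, seq_len(nrow(sim$table))),
                   sets_of(shuf, perm))
})

test_that("loosening one bound never shrinks the accepted set", {
  cfg <- quick_config(seed = 17)
  sim <- generate_nanoruler_field(cfg, 20)
  strict <- picking_config(radius_nm = 90, min_locs = 60, min_rgyr_nm = 12,
                           max_rgyr_nm = 40, bimodality_min = 6)
  cands <- cluster_localizations(sim$table, strict)
  acc_ids <- function(cfg) {
    f <- filter_candidates(cands, sim$table, cfg)
    f$candidates$id[f$candidates$accepted]
  }
  base_ids <- acc_ids(strict)
  for (loose in list(picking_config(radius_nm = 90, min_locs = 20,
                                    min_rgyr_nm = 12, max_rgyr_nm = 40,
                                    bimodality_min = 6),
                     picking_config(radius_nm = 90, min_locs = 60,
                                    min_rgyr_nm = 5, max_rgyr_nm = 40,
                                    bimodality_min = 6),
                     picking_config(radius_nm = 90, min_locs = 60,
                                    min_rgyr_nm = 12, max_rgyr_nm = 70,
                                    bimodality_min = 6),
                     picking_config(radius_nm = 90, min_locs = 60,
                                    min_rgyr_nm = 12, max_rgyr_nm = 40,
                                    bimodality_min = 2))) {
    expect_true(all(base_ids %in% acc_ids(loose)))
  }
})

test_that("picking-bias estimate behaves directionally", {
  pkA <- default_picking(60)
  pkB <- picking_config(radius_nm = 90, min_neighbors = 12, min_locs = 40,
                        max_locs = 5000, min_rgyr_nm = 12, max_rgyr_nm = 50,
                        bimodality_min = 5, edge_margin_nm = 300)
  # identical configurations give exactly zero
  sim <- generate_nanoruler_field(sim_config(seed = 23), 60)
  same <- estimate_fp_uncertainty(sim$table, pkA, pkA)
  expect_identical(same$u_fp_nm, 0)
  # clean data: small picking bias
  clean <- estimate_fp_uncertainty(sim$table, pkA, pkB)
  expect_lt(clean$u_fp_nm, 0.5)
  # heavy false-positive contamination makes the two arms disagree
  simfp <- generate_nanoruler_field(
    sim_config(seed = 23, fp_density = 3e-3), 60)
  dirty <- estimate_fp_uncertainty(simfp$table, pkA, pkB)
  expect_gt(dirty$u_fp_nm, 0)
  # too few structures is an error naming the counts
  few <- generate_nanoruler_field(quick_config(seed = 29), 5)
  expect_error(estimate_fp_uncertainty(few$table, pkA, pkB), "[0-9]+")
})
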