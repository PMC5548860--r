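# Brute-force one-sided binomial tail: P(X >= k), X ~ Binomial(n, p).
tail_sum <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) stats::dbinom(j, n, p), numeric(1)))
}

test_that("detection test equals the exact binomial tail", {
  # zero alternate reads: never detected, vaf 0
  d <- detect_variant(make_column("A", A = 5000), "C", error_rate = 1e-4)
  expect_false(d$detected)
  expect_equal(d$observed_vaf, 0)
  expect_equal(d$p_value, 1)

  # 30 alt reads at 30000x against error 1e-4: overwhelming
  d <- detect_variant(make_column("A", A = 29970, C = 30), "C",
                      error_rate = 1e-4)
  expect_true(d$detected)
  expect_equal(d$p_value, tail_sum(30, 30000, 1e-4 / 3), tolerance = 1e-10)

  # two alt reads: blocked by the min-count floor regardless of p
  d <- detect_variant(make_column("A", A = 29998, C = 2), "C",
                      error_rate = 1e-6)
  expect_false(d$detected)
  expect_lt(d$p_value, 0.05)

  expect_error(detect_variant(make_column("A", A = 10), "A", 1e-4),
               "equals the reference")
})

test_that("p-values match brute-force tail sums on small depths", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(10:1000, 1)
    k <- sample(0:min(n, 20), 1)
    e <- runif(1, 1e-5, 0.02)
    col <- make_column("A", A = n - k, G = k)
    d <- detect_variant(col, "G", error_rate = e)
    expect_equal(d$p_value, tail_sum(k, n, e / 3), tolerance = 1e-10)
  }
})

test_that("series summary computes means, SEs and detection rates", {
  des <- dilution_design(
    data.frame(contig = "chrT", position = 1L, ref = "A", alt = "C",
               name = "v1"),
    levels = c(0.001, 0.002), replicates = 3)
  obs <- data.frame(
    variant = "v1",
    level = c(0.001, 0.001, 0.001, 0.002, 0.002),
    replicate = c(1, 2, 3, 1, 2),
    observed_vaf = c(0.001, 0.001, 0.001, 0.001, 0.003),
    detected = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  rep <- summarize_series(obs, des)
  c1 <- rep$cells[rep$cells$level == 0.001, ]
  expect_equal(c1$mean_vaf, 0.001)
  expect_equal(c1$se_vaf, 0)
  expect_equal(c1$detection_rate, 2 / 3)
  c2 <- rep$cells[rep$cells$level == 0.002, ]
  expect_equal(c2$mean_vaf, 0.002)
  expect_equal(c2$se_vaf, 0.001)  # sd(c(0.001, 0.003))/sqrt(2)

  # missing cells are reported absent, not imputed
  des2 <- dilution_design(des$variants, levels = c(0.001, 0.002, 0.005),
                          replicates = 3)
  rep2 <- summarize_series(obs, des2)
  expect_true(is.na(rep2$cells$mean_vaf[rep2$cells$level == 0.005]))
})

test_that("limit of detection matches a brute-force CDF scan", {
  # no-error regime: LOD is the smallest f with P(X >= 3) >= 0.95
  lod <- limit_of_detection(depth = 10000, error_rate = 0, power = 0.95,
                            min_alt = 3)
  grid <- seq(1e-5, 0.05, by = 1e-5)
  oracle <- grid[which(vapply(grid, function(f)
    1 - pbinom(2, 10000, f) >= 0.95, logical(1)))[1]]
  expect_equal(lod$lod, oracle)
  expect_equal(lod$critical_count, 3L)

  # doubling depth never raises the LOD
  lod2 <- limit_of_detection(depth = 20000, error_rate = 0)
  expect_lte(lod2$lod, lod$lod)

  # unreachable power errors out
  expect_error(limit_of_detection(depth = 10, error_rate = 0,
                                  grid_max = 0.01), "unreachable")
})

test_that("LOD is monotone over a depth x error lattice", {
  depths <- c(10000, 30000, 100000)
  errors <- c(0, 1e-4, 1e-3)
  lod <- outer(depths, errors, Vectorize(function(d, e)
    limit_of_detection(d, e)$lod))
  # non-increasing in depth (rows), non-decreasing in error rate (cols)
  for (j in seq_along(errors)) expect_true(all(diff(lod[, j]) <= 0))
  for (i in seq_along(depths)) expect_true(all(diff(lod[i, ]) >= 0))
})

test_that("type-I detections at error-only sites stay near alpha", {
  # 1000 error-only columns at 30000x, error 1e-4: the fraction detected
  # must not exceed alpha + 0.02
  set.seed(63)
  depth <- 30000L
  k <- rbinom(1000, depth, 1e-4 / 3)
  det <- vapply(k, function(ki) {
    detect_variant(make_column("A", A = depth - ki, C = ki), "C",
                   error_rate = 1e-4)$detected
  }, logical(1))
  expect_lte(mean(det), 0.05 + 0.02)
})

test_that("simulated dilution series recovers nominal levels", {
  w <- tiny_world()
  cfg <- tiny_config(seed = 19)
  des <- dilution_design(w$panel$hotspots[1:2, c("contig", "position",
                                                 "ref", "alt")],
                         levels = c(0.001, 0.01), replicates = 5,
                         depth = 30000)
  ser <- simulate_spikein_series(des, cfg)
  rep <- summarize_series(ser$observations, des)
  ok <- !is.na(rep$cells$se_vaf) & rep$cells$se_vaf > 0
  expect_true(all(abs(rep$cells$mean_vaf[ok] - rep$cells$level[ok]) <=
                    3 * rep$cells$se_vaf[ok] + cfg$base_error_rate / 3))
  # same seed gives an identical series
  ser2 <- simulate_spikein_series(des, cfg)
  expect_identical(ser2$observations, ser$observations)
})
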