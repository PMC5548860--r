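test_that("position VAF is total non-reference frequency", {
  # the canonical worked example: ref A with 9990/3/5/2 -> 1/1000
  v <- position_vaf(make_column("A", A = 9990, C = 3, G = 5, T = 2))
  expect_equal(v$maf, 0.001)
  expect_equal(unname(v$per_allele[c("C", "G", "T")]),
               c(3, 5, 2) / 10000)

  expect_equal(position_vaf(make_column("A", A = 100))$maf, 0)

  v <- position_vaf(make_column("C", C = 50, T = 50))
  expect_equal(v$maf, 0.5)
  expect_equal(unname(v$per_allele[["T"]]), 0.5)

  expect_error(position_vaf(make_column("A")), "zero depth")
  expect_error(position_vaf(make_column("N", A = 10)), "A/C/G/T")
})

test_that("maf plus reference fraction is one on random columns", {
  set.seed(21)
  for (i in 1:50) {
    cnt <- as.integer(rmultinom(1, 1000, c(0.9, 0.05, 0.03, 0.02)))
    ref <- sample(c("A", "C", "G", "T"), 1)
    col <- make_column(ref, A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4])
    v <- position_vaf(col)
    expect_equal(v$maf + col[[ref]] / col$depth, 1)
    expect_equal(sum(v$per_allele), v$maf)
  }
})

test_that("locus filters apply strict depth and MAF boundaries", {
  prof <- make_profile(pos = 1:4,
                       maf = c(0.001, 0.001, 0.5, 0.1),
                       depth = c(9999, 10000, 20000, 10000))
  out <- quiet(filter_positions(prof))
  # depth 9999 removed; depth 10000 kept; maf 0.5 removed; maf 0.1 kept
  expect_equal(out$positions$pos, c(2L, 4L))
  expect_equal(attr(out, "log")$removed_low_depth, 1L)
  expect_equal(attr(out, "log")$removed_high_maf, 1L)

  # idempotent
  again <- quiet(filter_positions(out))
  expect_identical(again$positions, out$positions)
})

test_that("gene frequency averages per-position MAFs over amplicon length", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcontig\tstart\tend", "G1\tchrT\t0\t2"), tmp)
  panel <- quiet(load_panel(tmp))

  prof <- make_profile(pos = 0:1, maf = c(0.001, 0.003), depth = 20000)
  expect_equal(gene_frequency(prof, panel, "G1")$f_gene, 0.002)

  prof0 <- make_profile(pos = 0:1, maf = c(0, 0), depth = 20000)
  expect_equal(gene_frequency(prof0, panel, "G1")$f_gene, 0)

  # uncovered positions count as zero against the designed length...
  prof1 <- make_profile(pos = 0L, maf = 0.004, depth = 20000)
  expect_equal(gene_frequency(prof1, panel, "G1")$f_gene, 0.002)
  # ...unless covered-only mode is requested
  expect_equal(gene_frequency(prof1, panel, "G1", covered_only = TRUE)$f_gene,
               0.004)

  expect_error(gene_frequency(prof, panel, "NOPE"), "not in panel")
})

test_that("gene frequency is permutation-invariant and linear in maf", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcontig\tstart\tend", "G1\tchrT\t0\t10"), tmp)
  panel <- quiet(load_panel(tmp))
  set.seed(31)
  maf <- sample.int(1000, 10) / 20000  # exact multiples of 1/depth
  f1 <- gene_frequency(make_profile(0:9, maf, 20000), panel, "G1")$f_gene
  perm <- sample.int(10)
  f2 <- gene_frequency(make_profile((0:9)[perm], maf[perm], 20000),
                       panel, "G1")$f_gene
  expect_equal(f2, f1)
  # linearity: doubling every maf doubles F (profile rounding kept exact
  # by using depth divisible by the doubled counts)
  f3 <- gene_frequency(make_profile(0:9, 2 * maf, 20000), panel, "G1")$f_gene
  expect_equal(f3, 2 * f1)
})

test_that("estimated gene frequency matches simulated truth at 40000x", {
  # a 1000-position gene with known truth frequencies; binomial counts
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcontig\tstart\tend", "G1\tchrT\t0\t1000"), tmp)
  panel <- quiet(load_panel(tmp))
  set.seed(32)
  truth <- rexp(1000, rate = 1 / 2e-4)
  depth <- 40000L
  obs <- rbinom(1000, depth, truth) / depth
  prof <- make_profile(0:999, obs, depth)
  f <- gene_frequency(prof, panel, "G1")$f_gene
  se <- sqrt(sum(truth * (1 - truth) / depth)) / 1000
  expect_lt(abs(f - mean(truth)), 3 * se + 1 / (2 * depth))
})

test_that("gene ranking is descending with lexicographic ties", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcontig\tstart\tend",
               "B\tchrT\t0\t2", "A\tchrT\t2\t4", "C\tchrT\t4\t6"), tmp)
  panel <- quiet(load_panel(tmp))
  prof <- make_profile(pos = 0:5,
                       maf = c(0.002, 0.002, 0.001, 0.001, 0, 0),
                       depth = 20000)
  rk <- rank_genes(list(prof), panel)
  expect_equal(rk$gene, c("B", "A", "C"))
  expect_equal(rk$rank, 1:3)

  # equal frequencies -> lexicographic, stable across repeated calls
  prof_tie <- make_profile(pos = 0:5, maf = rep(0.001, 6), depth = 20000)
  rk1 <- rank_genes(list(prof_tie), panel)
  rk2 <- rank_genes(list(prof_tie), panel)
  expect_equal(rk1$gene, c("A", "B", "C"))
  expect_identical(rk1, rk2)

  expect_error(rank_genes(list(), panel), "at least one")
})

test_that("per-position maf is an unbiased estimator under binomial sampling", {
  # error-free binomial sampling at 40000x over >= 1000 positions:
  # observed maf within 3 binomial SE of truth for >= 99% of positions
  w <- tiny_world()
  cfg <- sim_config(w$panel, w$reference, seed = 17, mean_depth = 40000,
                    base_error_rate = 0, germline_het_density = 0,
                    gene_elevation = stats::setNames(numeric(0), character(0)))
  hits <- 0L; total <- 0L
  for (i in 1:3) {  # 3 x 400 bp panel = 1200 positions
    pr <- simulate_pair(cfg, i)
    j <- merge(pr$truth, pr$wbc$positions, by = c("contig", "pos"))
    se <- sqrt(j$wbc_f * (1 - j$wbc_f) / j$depth)
    hits <- hits + sum(abs(j$maf - j$wbc_f) <= 3 * se + 1e-12)
    total <- total + nrow(j)
  }
  expect_gte(total, 1000L)
  expect_gte(hits / total, 0.99)
})
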