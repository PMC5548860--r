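test_that("replica panel generator honors requested cardinalities", {
  w <- simulate_reference_and_panel(seed = 2, n_genes = 2, n_amplicons = 2,
                                    total_bp = 200, n_hotspots = 5)
  lens <- w$panel$amplicons$end - w$panel$amplicons$start
  expect_equal(sort(lens), c(100L, 100L))
  expect_equal(panel_total_bp(w$panel), 200L)
  expect_equal(nrow(w$panel$hotspots), 5L)
  # every hotspot lies inside an amplicon with a matching reference base
  for (i in seq_len(nrow(w$panel$hotspots))) {
    h <- w$panel$hotspots[i, ]
    expect_equal(substring(w$reference[[h$contig]], h$position + 1L,
                           h$position + 1L), h$ref)
    expect_true(h$alt != h$ref)
  }
  expect_error(simulate_reference_and_panel(seed = 2, n_genes = 3,
                                            n_amplicons = 2),
               "at least one amplicon")
  expect_error(simulate_reference_and_panel(seed = 2, n_genes = 2,
                                            n_amplicons = 4, total_bp = 100),
               "infeasible")
})

test_that("generators are byte-identical under a repeated seed", {
  w1 <- simulate_reference_and_panel(seed = 77)
  w2 <- simulate_reference_and_panel(seed = 77)
  expect_identical(w1, w2)
  f1 <- tempfile(); f2 <- tempfile()
  write_reference(w1$reference, f1)
  write_reference(w2$reference, f2)
  expect_identical(readLines(f1), readLines(f2))

  cfg <- tiny_config(seed = 15)
  p1 <- simulate_pair(cfg, 1)
  p2 <- simulate_pair(cfg, 1)
  expect_identical(p1, p2)
  r1 <- simulate_replicates(cfg)
  r2 <- simulate_replicates(cfg)
  expect_identical(r1$rep1$positions, r2$rep1$positions)
})

test_that("full sharing makes true cfDNA and WBC frequencies identical", {
  cfg <- tiny_config(seed = 15, shared_weight = 1, germline_het_density = 0)
  pr <- simulate_pair(cfg, 1)
  expect_equal(pr$truth$cf_f, pr$truth$wbc_f)
  r <- paired_correlation(pr$truth$wbc_f, pr$truth$cf_f)
  expect_equal(r$r_squared, 1)
})

test_that("zero sharing decorrelates the true frequencies", {
  # |r| < 0.1 on ~20000 truth positions, fixed seed
  rp <- replica_panel()
  ref <- replica_reference()
  cfg <- sim_config(rp, ref, seed = 15, shared_weight = 0,
                    germline_het_density = 0)
  pr <- simulate_pair(cfg, 1)
  expect_gte(nrow(pr$truth), 20000L)
  expect_lt(abs(cor(pr$truth$wbc_f, pr$truth$cf_f)), 0.1)
})

test_that("replicates share one truth and converge to it at high depth", {
  cfg <- tiny_config(seed = 16, mean_depth = 1e6, base_error_rate = 0,
                     germline_het_density = 0)
  r <- simulate_replicates(cfg)
  j1 <- merge(r$truth, r$rep1$positions, by = c("contig", "pos"))
  j2 <- merge(r$truth, r$rep2$positions, by = c("contig", "pos"))
  expect_lt(max(abs(j1$maf - j1$f)), 1e-3)
  expect_lt(max(abs(j2$maf - j2$f)), 1e-3)
})

test_that("germline heterozygous sites sit near 0.5 in both members", {
  cfg <- tiny_config(seed = 18, germline_het_density = 0.05)
  pr <- simulate_pair(cfg, 1)
  g <- pr$truth$germline
  expect_gt(sum(g), 0)
  expect_true(all(pr$truth$wbc_f[g] == 0.5 & pr$truth$cf_f[g] == 0.5))
  j <- merge(pr$truth[g, ], pr$wbc$positions, by = c("contig", "pos"))
  expect_true(all(abs(j$maf - 0.5) < 0.05))
})

test_that("gene elevation propagates into simulated backgrounds", {
  rp <- replica_panel()
  ref <- replica_reference()
  cfg <- sim_config(rp, ref, seed = 25, gene_elevation = c(NPM1 = 10),
                    germline_het_density = 0, clonal_fraction = 0)
  pr <- simulate_pair(cfg, 1)
  t_npm1 <- pr$truth$wbc_f[pr$truth$gene == "NPM1"]
  t_rest <- pr$truth$wbc_f[pr$truth$gene != "NPM1"]
  expect_gt(mean(t_npm1), 4 * mean(t_rest))
})

test_that("trio construction places variants per the truth table", {
  cfg <- tiny_config(seed = 27, mean_depth = 100000, base_error_rate = 0)
  trio <- simulate_trio(cfg, n_truncal = 2, n_private_per_section = 1,
                        n_cf_detectable = 1)
  expect_equal(sum(trio$truth$group == "truncal"), 2L)
  expect_equal(sum(trio$truth$cf_detectable), 1L)

  # truncal variants visible in both sections; private only in one
  for (i in seq_len(nrow(trio$truth))) {
    tr <- trio$truth[i, ]
    vaf_in <- function(prof) {
      p <- prof$positions[prof$positions$pos == tr$pos, ]
      p[[tr$alt]] / p$depth
    }
    if (tr$group == "truncal") {
      expect_gt(vaf_in(trio$tumor1), 0.05)
      expect_gt(vaf_in(trio$tumor2), 0.05)
    } else if (tr$group == "private1") {
      expect_gt(vaf_in(trio$tumor1), 0.05)
      expect_lt(vaf_in(trio$tumor2), 0.01)
    }
    if (tr$cf_detectable) expect_gt(vaf_in(trio$cfdna), 0.01)
  }

  # zero truncal variants -> zero shared calls
  trio0 <- simulate_trio(cfg, n_truncal = 0, n_private_per_section = 2,
                         n_cf_detectable = 0)
  c1 <- quiet(call_hotspots(trio0$tumor1, cfg$panel$hotspots))
  c2 <- quiet(call_hotspots(trio0$tumor2, cfg$panel$hotspots))
  k1 <- quiet(subtract_wbc_background(c1, trio0$wbc))
  k2 <- quiet(subtract_wbc_background(c2, trio0$wbc))
  expect_equal(unname(shared_mutations(k1, k2)$counts["shared"]), 0L)

  expect_error(simulate_trio(cfg, n_truncal = 100,
                             n_private_per_section = 100),
               "exceed")
})

test_that("generated SAM and pileup files parse cleanly through panel io", {
  w <- tiny_world()
  cfg <- tiny_config(seed = 33)
  reads <- simulate_reads(cfg, n_reads = 100, read_length = 50)
  sam <- tempfile(fileext = ".sam")
  write_sam(reads, w$reference, sam)
  expect_no_warning(back <- read_alignments(sam, w$panel, w$reference))
  expect_equal(length(back), length(reads))

  pu <- build_pileup(quiet(filter_reads(reads)), w$panel, w$reference)
  tmp <- tempfile()
  expect_no_warning(write_pileup(pu, tmp))
  expect_no_warning(read_pileup(tmp))
})
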