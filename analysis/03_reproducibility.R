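#!/usr/bin/env Rscript
# Technical-replicate reproducibility: one sample split in half and
# sequenced twice (same truth, independent counts). Concordance of
# per-position MAFs above the 0.3% inclusion threshold separates
# biological background from PCR/sequencing noise.
suppressMessages(library(cfbackground))
dir.create("results", showWarnings = FALSE)
seed <- 20170808

panel <- suppressMessages(load_panel(
  system.file("extdata", "replica_panel.tsv", package = "cfbackground"),
  system.file("extdata", "replica_hotspots.tsv", package = "cfbackground")))
reference <- load_reference(
  system.file("extdata", "replica_reference.fa", package = "cfbackground"))
cfg <- sim_config(panel, reference, seed = seed)

rows <- list()
for (material in c("WBC", "cfDNA")) {
  reps <- simulate_replicates(cfg, material = material)
  rc <- replicate_concordance(
    suppressMessages(filter_positions(reps$rep1)),
    suppressMessages(filter_positions(reps$rep2)))
  cat(sprintf("%s replicates: ", material)); print(rc)
  rows[[material]] <- data.frame(material = material, n = rc$n,
                                 pearson_r = rc$pearson_r,
                                 adjusted_r_squared = rc$adjusted_r_squared)
}

# control: two samples from independent truths should not be concordant
r1 <- simulate_replicates(cfg, replicate_seed = 11)
r2 <- simulate_replicates(cfg, replicate_seed = 12)
rc0 <- replicate_concordance(
  suppressMessages(filter_positions(r1$rep1)),
  suppressMessages(filter_positions(r2$rep1)))
cat("Independent-truth control: "); print(rc0)
rows$control <- data.frame(material = "independent_control", n = rc0$n,
                           pearson_r = rc0$pearson_r,
                           adjusted_r_squared = rc0$adjusted_r_squared)

cat("\nReplicates from one truth are near-perfectly concordant at 40000x;",
    "\nunrelated samples show no concordance, so the statistic tracks",
    "biology,\nnot depth.\n")
write.table(do.call(rbind, rows), "results/reproducibility.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
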