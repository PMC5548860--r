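#!/usr/bin/env Rscript
# Cohort-level and within-individual correlation of cfDNA vs WBC mutant
# allele frequencies on the default synthetic cohort (20 pairs, 40000x,
# shared_weight 0.9), plus the shared_weight = 0 control. Writes
# results/cohort_correlation.tsv and the scatter data.
suppressMessages(library(cfbackground))
dir.create("results", showWarnings = FALSE)
seed <- 20170808

panel <- suppressMessages(load_panel(
  system.file("extdata", "replica_panel.tsv", package = "cfbackground"),
  system.file("extdata", "replica_hotspots.tsv", package = "cfbackground")))
reference <- load_reference(
  system.file("extdata", "replica_reference.fa", package = "cfbackground"))

run_cohort <- function(shared_weight) {
  cfg <- sim_config(panel, reference, seed = seed, n_pairs = 20,
                    shared_weight = shared_weight)
  lapply(simulate_cohort(cfg), function(p)
    list(wbc = suppressMessages(filter_positions(p$wbc)),
         cfdna = suppressMessages(filter_positions(p$cfdna))))
}

cohort <- run_cohort(0.9)
cc <- cohort_correlation(cohort)
cat("Cohort of 20 pairs, cfDNA 90% blood-derived:\n  ")
print(cc)

ind <- individual_correlation(cohort[[1]]$wbc, cohort[[1]]$cfdna)
cat("Single individual (pair 1):\n  ")
print(ind)

cohort0 <- run_cohort(0)
cc0 <- cohort_correlation(cohort0)
cat("Control, cfDNA independent of WBC:\n  ")
print(cc0)

cat("\nThe blood-derived fraction drives the correlation: with 90% sharing",
    "\nthe position-level means are almost collinear; with 0% they are",
    "uncorrelated.\n")

summary <- data.frame(
  analysis = c("cohort_w0.9", "individual_w0.9", "cohort_w0"),
  n = c(cc$n, ind$n, cc0$n),
  pearson_r = c(cc$pearson_r, ind$pearson_r, cc0$pearson_r),
  adjusted_r_squared = c(cc$adjusted_r_squared, ind$adjusted_r_squared,
                         cc0$adjusted_r_squared),
  slope = c(cc$slope, ind$slope, cc0$slope))
write.table(summary, "results/cohort_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

scatter <- cohort_mean_profile(cohort)
write.table(scatter, "results/cohort_scatter.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
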