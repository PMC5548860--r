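#!/usr/bin/env Rscript
# End-to-end manifest-driven run: simulate three pairs over a 5-amplicon
# subpanel, write their pileups to disk, run the full pipeline (read ->
# filter -> VAF -> gene ranking -> paired correlation -> hotspot calls)
# and save report.json. A subpanel at 12000x keeps the mpileup text files
# desk-sized (the format stores one character per read per position).
suppressMessages(library(cfbackground))
dir.create("results/pipeline", recursive = TRUE, showWarnings = FALSE)
seed <- 20170808

full <- suppressMessages(load_panel(
  system.file("extdata", "replica_panel.tsv", package = "cfbackground"),
  system.file("extdata", "replica_hotspots.tsv", package = "cfbackground")))
reference <- load_reference(
  system.file("extdata", "replica_reference.fa", package = "cfbackground"))

amp <- full$amplicons[1:5, ]
panel_tsv <- "results/pipeline/subpanel.tsv"
hs_tsv <- "results/pipeline/subpanel_hotspots.tsv"
write.table(amp, panel_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
keep_hs <- vapply(seq_len(nrow(full$hotspots)), function(i)
  any(full$hotspots$position[i] >= amp$start &
        full$hotspots$position[i] < amp$end), logical(1))
write.table(full$hotspots[keep_hs, ], hs_tsv, sep = "\t", quote = FALSE,
            row.names = FALSE)
panel <- suppressMessages(load_panel(panel_tsv, hs_tsv))

elev <- if ("NPM1" %in% panel$genes) c(NPM1 = 10) else
  stats::setNames(numeric(0), character(0))
cfg <- sim_config(panel, reference, seed = seed, n_pairs = 3,
                  mean_depth = 12000, gene_elevation = elev)

rows <- list()
for (i in 1:3) {
  pr <- simulate_pair(cfg, i)
  for (m in c("wbc", "cfdna")) {
    prof <- pr[[m]]
    path <- sprintf("results/pipeline/%s.pileup", prof$sample_id)
    write_pileup(prof$positions[, c("contig", "pos", "ref", "A", "C", "G",
                                    "T", "depth")], path)
    rows[[prof$sample_id]] <- data.frame(
      sample_id = prof$sample_id, material = prof$material, path = path,
      pair_id = sprintf("pair%03d", i))
  }
}
manifest <- do.call(rbind, rows)
write.table(manifest, "results/pipeline/manifest.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

stopifnot(length(validate_manifest(manifest)) == 0)
report <- suppressMessages(run_pipeline(manifest, panel))
print(report)
for (p in names(report$correlations)) {
  cat(p, ": ")
  cr <- report$correlations[[p]]
  if (inherits(cr, "correlation_result")) print(cr) else cat(cr, "\n")
}
write_report(report, "results/pipeline/report.json")
cat("wrote results/pipeline/report.json\n")
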