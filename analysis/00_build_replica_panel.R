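#!/usr/bin/env Rscript
# Regenerates the packaged replica panel fixtures (inst/extdata): a synthetic
# single-contig reference plus a 50-gene / 207-amplicon / 22027-bp panel with
# 2800 hotspot sites. Deterministic: seed 20170808. Run from the repo root.
library(cfbackground)

rp <- simulate_reference_and_panel(seed = 20170808)
dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)
write_panel(rp$panel, "inst/extdata/replica_panel.tsv")
write_hotspots(rp$panel, "inst/extdata/replica_hotspots.tsv")
write_reference(rp$reference, "inst/extdata/replica_reference.fa")
cat(sprintf("replica panel: %d genes, %d amplicons, %d bp, %d hotspots\n",
            length(rp$panel$genes), nrow(rp$panel$amplicons),
            panel_total_bp(rp$panel), nrow(rp$panel$hotspots)))
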