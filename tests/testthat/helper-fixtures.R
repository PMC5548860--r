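# Shared fixtures: everything is generated in code, no stored test data.

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# A tiny two-gene panel on a short synthetic reference.
tiny_world <- function(seed = 5L) {
  simulate_reference_and_panel(seed = seed, n_genes = 2L, n_amplicons = 3L,
                               total_bp = 400L, n_hotspots = 10L)
}

tiny_config <- function(seed = 3L, ...) {
  w <- tiny_world()
  sim_config(w$panel, w$reference, seed = seed,
             gene_elevation = stats::setNames(numeric(0), character(0)), ...)
}

# The packaged replica panel (full study cardinalities).
replica_panel <- function() {
  load_panel(
    system.file("extdata", "replica_panel.tsv", package = "cfbackground"),
    system.file("extdata", "replica_hotspots.tsv", package = "cfbackground"))
}

replica_reference <- function() {
  load_reference(
    system.file("extdata", "replica_reference.fa", package = "cfbackground"))
}

# Construct an aligned_read from parallel vectors.
make_read <- function(qbase, rbase, qual = 35L, rpos = NULL,
                      name = "r1", contig = "chrT", duplicate = FALSE) {
  n <- length(qbase)
  if (length(qual) == 1) qual <- rep(qual, n)
  if (is.null(rpos)) rpos <- seq_len(n) - 1L
  aligned_read(name, contig,
               data.frame(qbase = qbase, qual = as.integer(qual),
                          rpos = as.integer(rpos), rbase = rbase,
                          stringsAsFactors = FALSE),
               duplicate = duplicate)
}

# One pileup row as a data.frame.
make_column <- function(ref, A = 0, C = 0, G = 0, T = 0,
                        contig = "chrT", pos = 0L) {
  data.frame(contig = contig, pos = pos, ref = ref, A = A, C = C, G = G,
             T = T, depth = A + C + G + T, stringsAsFactors = FALSE)
}

# A profile built directly from per-position (maf, depth) specs; signal on
# a fixed alternate allele.
make_profile <- function(pos, maf, depth, ref = "A", alt = "C",
                         sample_id = "s1", material = "WBC",
                         contig = "chrT") {
  n <- length(pos)
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  depth <- rep_len(depth, n)
  altc <- round(maf * depth)
  counts <- matrix(0L, n, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  counts[cbind(seq_len(n), match(ref, colnames(counts)))] <- depth - altc
  counts[cbind(seq_len(n), match(alt, colnames(counts)))] <- altc
  cols <- data.frame(contig = contig, pos = as.integer(pos), ref = ref,
                     A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                     T = counts[, "T"], depth = depth,
                     stringsAsFactors = FALSE)
  profile_from_pileup(cols, sample_id, material)
}

# Independent naive implementation of the read filter + pileup tally:
# explicit loops, no shared code with the package internals.
naive_filter_pileup <- function(reads, panel, reference,
                                max_frac = 0.05, min_q = 30L) {
  counts <- list()
  pp <- panel_positions(panel)
  panel_key <- paste(pp$contig, pp$pos)
  for (r in reads) {
    if (isTRUE(r$duplicate)) next
    mism <- 0L; tot <- 0L
    for (i in seq_len(nrow(r$pairs))) {
      if (!r$pairs$rbase[i] %in% c("A", "C", "G", "T")) next
      tot <- tot + 1L
      if (r$pairs$qbase[i] != r$pairs$rbase[i]) mism <- mism + 1L
    }
    if (tot == 0L || mism / tot > max_frac) next
    for (i in seq_len(nrow(r$pairs))) {
      if (r$pairs$qual[i] < min_q) next
      b <- r$pairs$qbase[i]
      if (!b %in% c("A", "C", "G", "T")) next
      if (!r$pairs$rbase[i] %in% c("A", "C", "G", "T")) next
      key <- paste(r$contig, r$pairs$rpos[i])
      if (!key %in% panel_key) next
      if (is.null(counts[[key]])) {
        counts[[key]] <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      }
      counts[[key]][b] <- counts[[key]][b] + 1L
    }
  }
  counts
}

# Compare a pileup data.frame against naive counts exactly.
expect_pileup_equals_naive <- function(pileup, naive) {
  keys <- paste(pileup$contig, pileup$pos)
  expect_setequal(keys, names(naive))
  for (i in seq_len(nrow(pileup))) {
    expect_identical(
      c(A = pileup$A[i], C = pileup$C[i], G = pileup$G[i], T = pileup$T[i]),
      naive[[keys[i]]],
      label = paste("counts at", keys[i]))
  }
}
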