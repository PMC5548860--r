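test_that("panel loading merges overlaps and computes covered length", {
  tmp <- tempfile(fileext = ".tsv")

  writeLines(c("gene\tcontig\tstart\tend",
               "G1\tchr1\t0\t100",
               "G1\tchr1\t200\t300"), tmp)
  p <- quiet(load_panel(tmp))
  expect_equal(panel_total_bp(p), 200L)
  expect_equal(nrow(p$amplicons), 2L)

  # overlapping amplicons merge; covered length equals the brute-force
  # union of position sets
  writeLines(c("gene\tcontig\tstart\tend",
               "G1\tchr1\t0\t100",
               "G1\tchr1\t50\t150"), tmp)
  p <- quiet(load_panel(tmp))
  oracle <- length(union(0:99, 50:149))
  expect_equal(panel_total_bp(p), oracle)
  expect_equal(nrow(p$amplicons), 1L)
})

test_that("panel totals are invariant under row shuffling", {
  w <- tiny_world()
  amp <- w$panel$amplicons
  tmp <- tempfile(fileext = ".tsv")
  for (seed in 1:3) {
    set.seed(seed)
    shuffled <- amp[sample.int(nrow(amp)), ]
    utils::write.table(shuffled, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    p <- quiet(load_panel(tmp))
    expect_equal(length(p$genes), length(w$panel$genes))
    expect_equal(nrow(p$amplicons), nrow(w$panel$amplicons))
    expect_equal(panel_total_bp(p), panel_total_bp(w$panel))
  }
})

test_that("malformed panel rows fail with the offending line number", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("gene\tcontig\tstart\tend",
               "G1\tchr1\t0\t100",
               "G2\tchr1\tnotanumber\t300"), tmp)
  expect_error(load_panel(tmp), "line 3")

  writeLines(c("gene\tcontig\tstart\tend",
               "G1\tchr1\t100\t100"), tmp)
  expect_error(load_panel(tmp), "start < end")
})

test_that("hotspots must be valid substitutions inside amplicons", {
  w <- tiny_world()
  tmp_p <- tempfile(fileext = ".tsv"); tmp_h <- tempfile(fileext = ".tsv")
  write_panel(w$panel, tmp_p)
  hs <- w$panel$hotspots
  utils::write.table(hs, tmp_h, sep = "\t", quote = FALSE, row.names = FALSE)
  p <- quiet(load_panel(tmp_p, tmp_h))
  expect_equal(nrow(p$hotspots), nrow(hs))

  hs_bad <- hs; hs_bad$position[1] <- 1L  # before the first amplicon
  utils::write.table(hs_bad, tmp_h, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(quiet(load_panel(tmp_p, tmp_h)), "outside")

  hs_bad <- hs; hs_bad$alt[1] <- hs_bad$ref[1]
  utils::write.table(hs_bad, tmp_h, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(quiet(load_panel(tmp_p, tmp_h)), "ref == alt")
})

test_that("reference FASTA loads uppercase, rejects duplicates and empties", {
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">c1", paste(rep("acgt", 250), collapse = "")), tmp)
  ref <- load_reference(tmp)
  expect_equal(nchar(ref[["c1"]]), 1000L)
  expect_false(grepl("[acgt]", ref[["c1"]]))

  writeLines(character(0), tmp)
  expect_error(load_reference(tmp), "empty")

  writeLines(c(">c1", "ACGT", ">c1", "GGCC"), tmp)
  expect_error(load_reference(tmp), "duplicate")

  # synthetic reference round-trips write -> read byte-identically
  w <- tiny_world()
  write_reference(w$reference, tmp)
  expect_identical(load_reference(tmp), w$reference)
})

test_that("read_alignments keeps exactly the panel-overlapping mapped reads", {
  w <- tiny_world()
  amp <- w$panel$amplicons
  ref_len <- nchar(w$reference[["chrP"]])
  sam <- tempfile(fileext = ".sam")
  seg <- function(start, len) substring(w$reference[["chrP"]],
                                        start + 1L, start + len)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:chrP\tLN:%d", ref_len),
    sprintf("in1\t0\tchrP\t%d\t60\t20M\t*\t0\t0\t%s\t%s",
            amp$start[1] + 1L, seg(amp$start[1], 20), strrep("I", 20)),
    sprintf("in2\t0\tchrP\t%d\t60\t20M\t*\t0\t0\t%s\t%s",
            amp$start[2] + 5L, seg(amp$start[2] + 4L, 20), strrep("I", 20)),
    # placed in the 20 bp gap before the first amplicon
    sprintf("out1\t0\tchrP\t%d\t60\t10M\t*\t0\t0\t%s\t%s",
            amp$start[1] - 15L, seg(amp$start[1] - 16L, 10), strrep("I", 10)),
    "unmapped\t4\t*\t0\t0\t*\t*\t0\t0\tACGT\tIIII"), sam)
  reads <- read_alignments(sam, w$panel, w$reference)
  expect_equal(sort(vapply(reads, `[[`, character(1), "query_name")),
               c("in1", "in2"))

  # brute-force interval check agrees
  keep <- vapply(reads, function(r) {
    any(r$pairs$rpos[1] < amp$end &
          (r$pairs$rpos[nrow(r$pairs)] + 1L) > amp$start)
  }, logical(1))
  expect_true(all(keep))
})

test_that("CIGAR walk matches a manual walk on clips and indels", {
  w <- tiny_world()
  refseq <- w$reference[["chrP"]]
  start0 <- w$panel$amplicons$start[1]
  sam <- tempfile(fileext = ".sam")
  # 3S 5M 2I 4M 3D 6M 2S: query length 3+5+2+4+6+2 = 22
  qseq <- paste0("TTT",
                 substring(refseq, start0 + 1, start0 + 5),
                 "GG",
                 substring(refseq, start0 + 6, start0 + 9),
                 substring(refseq, start0 + 13, start0 + 18),
                 "TT")
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:chrP\tLN:%d", nchar(refseq)),
    sprintf("r1\t0\tchrP\t%d\t60\t3S5M2I4M3D6M2S\t*\t0\t0\t%s\t%s",
            start0 + 1L, qseq, strrep("I", nchar(qseq)))), sam)
  reads <- read_alignments(sam, w$panel, w$reference)
  expect_length(reads, 1L)
  p <- reads[[1]]$pairs
  # manual walk: M blocks at ref offsets 0-4, 5-8, 12-17
  expect_equal(p$rpos, start0 + c(0:4, 5:8, 12:17))
  expect_equal(nrow(p), 15L)
  expect_true(all(p$qbase == p$rbase))  # constructed as reference-matching
  expect_true(all(diff(p$rpos) > 0))
})

test_that("pileup text I/O is a faithful 1-based mpileup dialect", {
  col0 <- make_column("A", A = 3, C = 1, pos = 0L)
  tmp <- tempfile()
  write_pileup(col0, tmp)
  line <- readLines(tmp)
  expect_equal(strsplit(line, "\t")[[1]][2], "1")  # 0-based -> 1-based

  # round trip preserves all counts
  w <- tiny_world()
  cfg <- tiny_config()
  reads <- simulate_reads(cfg, n_reads = 80, read_length = 50)
  pu <- build_pileup(quiet(filter_reads(reads)), w$panel, w$reference)
  write_pileup(pu, tmp)
  back <- read_pileup(tmp)
  rownames(pu) <- NULL
  expect_identical(back, pu)

  # empty column list -> empty file
  write_pileup(pu[0, ], tmp)
  expect_length(readLines(tmp), 0L)

  # unsorted input refused
  expect_error(write_pileup(pu[rev(seq_len(nrow(pu))), ], tmp), "sorted")
})

test_that("0-based/1-based coordinate conversion is a bijection", {
  pos <- sort(sample.int(10000L, 200L)) - 1L
  cols <- make_column("A", A = 1, pos = 0L)[rep(1, length(pos)), ]
  cols$pos <- pos
  tmp <- tempfile()
  write_pileup(cols, tmp)
  back <- read_pileup(tmp)
  expect_identical(back$pos, pos)
})
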