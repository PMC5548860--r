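#' Aligned reads
#'
#' An `aligned_read` holds one read's per-base alignment to the reference:
#' for every match/mismatch alignment column, the query base, its Phred
#' quality, the 0-based reference position, and the reference base.
#' Insertions, deletions, and clipped bases carry no aligned pair and are
#' therefore invisible to all downstream mutant-fraction and VAF
#' computations (SNV-only analysis).
#'
#' @param query_name Read name.
#' @param contig Reference contig name.
#' @param pairs data.frame with columns `qbase`, `qual` (integer Phred),
#'   `rpos` (0-based reference position, strictly increasing), `rbase`.
#' @param duplicate Logical, PCR/optical duplicate flag.
#' @return An object of class `aligned_read`.
#' @export
aligned_read <- function(query_name, contig, pairs, duplicate = FALSE) {
  stopifnot(all(c("qbase", "qual", "rpos", "rbase") %in% names(pairs)))
  if (nrow(pairs) > 1 && any(diff(pairs$rpos) <= 0)) {
    stop("aligned pair reference positions must be strictly increasing")
  }
  structure(list(query_name = query_name, contig = contig,
                 ref_start = if (nrow(pairs)) pairs$rpos[1] else NA_integer_,
                 pairs = pairs, duplicate = duplicate),
            class = "aligned_read")
}

#' @export
print.aligned_read <- function(x, ...) {
  cat(sprintf("<aligned_read> %s %s:%d, %d aligned bases\n",
              x$query_name, x$contig, x$ref_start, nrow(x$pairs)))
  invisible(x)
}

# Walk a CIGAR string, pairing query bases/qualities with reference
# positions. Only M/=/X columns produce pairs; I and S consume query only,
# D and N consume reference only, H and P consume nothing.
cigar_pairs <- function(cigar, seq, qual, pos0, refseq) {
  ops_len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1]]
  if (length(ops) != length(ops_len)) stop("malformed CIGAR: ", cigar)
  qbases <- strsplit(seq, "")[[1]]
  quals <- utf8ToInt(qual) - 33L
  qi <- 1L
  ri <- pos0  # 0-based
  out <- vector("list", length(ops))
  for (k in seq_along(ops)) {
    n <- ops_len[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      idx <- qi:(qi + n - 1L)
      rpos <- ri + seq_len(n) - 1L
      out[[k]] <- data.frame(
        qbase = qbases[idx], qual = quals[idx], rpos = rpos,
        rbase = substring(refseq, rpos + 1L, rpos + 1L),
        stringsAsFactors = FALSE)
      qi <- qi + n
      ri <- ri + n
    } else if (op %in% c("I", "S")) {
      qi <- qi + n
    } else if (op %in% c("D", "N")) {
      ri <- ri + n
    } # H, P: nothing
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

#' Read alignments overlapping a panel
#'
#' Streams reads from a SAM or BAM file, keeping only mapped,
#' non-duplicate reads whose alignment overlaps a panel amplicon, and
#' converts each to an [aligned_read()] with per-base aligned pairs.
#' A plain-text SAM input is converted/sorted/indexed on the fly via
#' Rsamtools.
#'
#' @param path SAM or BAM file.
#' @param panel A `panel_def`.
#' @param reference Named character vector from [load_reference()]; must
#'   cover every contig the panel uses.
#' @param keep_duplicates Keep duplicate-flagged reads (default FALSE).
#' @return List of `aligned_read` objects.
#' @export
read_alignments <- function(path, panel, reference, keep_duplicates = FALSE) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  missing_contig <- setdiff(panel$amplicons$contig, names(reference))
  if (length(missing_contig) > 0) {
    stop("panel contig absent from reference: ", missing_contig[1])
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = TRUE)
  } else if (!file.exists(paste0(bam, ".bai"))) {
    Rsamtools::indexBam(bam)
  }
  amp <- panel$amplicons
  which <- GenomicRanges::reduce(GenomicRanges::GRanges(
    amp$contig, IRanges::IRanges(amp$start + 1L, amp$end)))
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (keep_duplicates) NA else FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, which = which,
    what = c("qname", "rname", "pos", "cigar", "seq", "qual", "flag"))
  chunks <- Rsamtools::scanBam(bam, param = param)

  seen <- character(0)
  reads <- list()
  for (ch in chunks) {
    n <- length(ch$qname)
    if (n == 0) next
    for (i in seq_len(n)) {
      key <- paste(ch$qname[i], ch$pos[i], ch$cigar[i])
      if (key %in% seen) next  # read may span two query windows
      seen <- c(seen, key)
      contig <- as.character(ch$rname[i])
      refseq <- reference[[contig]]
      if (is.null(refseq)) stop("contig absent from reference: ", contig)
      pairs <- cigar_pairs(ch$cigar[i], as.character(ch$seq[i]),
                           as.character(ch$qual[i]), ch$pos[i] - 1L, refseq)
      if (is.null(pairs) || nrow(pairs) == 0) next
      reads[[length(reads) + 1L]] <- aligned_read(
        ch$qname[i], contig, pairs,
        duplicate = bitwAnd(ch$flag[i], 1024L) > 0L)
    }
  }
  reads
}

#' Write aligned reads as a SAM text file
#'
#' Emits a minimal, valid SAM (used mainly by the synthetic-data generator
#' so generated reads can round-trip through [read_alignments()]).
#'
#' @param reads List of `aligned_read` objects with contiguous aligned
#'   pairs (no indels), or raw read tuples from [simulate_reads()].
#' @param reference Named character vector of contig sequences (for the
#'   `@SQ` header lines).
#' @param path Output path, should end in `.sam`.
#' @export
write_sam <- function(reads, reference, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (nm in names(reference)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", nm, nchar(reference[[nm]])), con)
  }
  for (r in reads) {
    flag <- if (isTRUE(r$duplicate)) 1024L else 0L
    seq <- paste(r$pairs$qbase, collapse = "")
    qual <- intToUtf8(pmin(r$pairs$qual, 93L) + 33L)
    cigar <- paste0(nrow(r$pairs), "M")
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                       r$query_name, flag, r$contig, r$pairs$rpos[1] + 1L,
                       cigar, seq, qual), con)
  }
  invisible(path)
}
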