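#' Filtering configuration
#'
#' Thresholds for the three bespoke filters applied before any VAF is
#' computed, with the conventions:
#' reads whose per-read mutant fraction is *strictly greater* than
#' `max_read_mutant_fraction` are discarded whole; bases with Phred quality
#' *strictly lower* than `min_base_quality` are masked; loci with retained
#' depth *strictly lower* than `min_locus_depth` are removed at the profile
#' stage. Boundary cases (fraction exactly 0.05, Q30, 10000x) are kept.
#'
#' @param max_read_mutant_fraction Per-read mismatch fraction above which
#'   the whole read is dropped. Default 0.05.
#' @param min_base_quality Minimum Phred base quality. Default 30.
#' @param min_locus_depth Minimum retained depth per locus. Default 10000.
#' @return A `filter_config` list.
#' @export
filter_config <- function(max_read_mutant_fraction = 0.05,
                          min_base_quality = 30L,
                          min_locus_depth = 10000L) {
  stopifnot(max_read_mutant_fraction >= 0, max_read_mutant_fraction <= 1,
            min_base_quality >= 0, min_locus_depth >= 0)
  structure(list(max_read_mutant_fraction = max_read_mutant_fraction,
                 min_base_quality = as.integer(min_base_quality),
                 min_locus_depth = as.integer(min_locus_depth)),
            class = "filter_config")
}

#' Per-read mutant fraction
#'
#' Fraction of a read's aligned (match/mismatch) bases that differ from the
#' reference. Computed on *all* aligned pairs, before any quality masking;
#' pairs whose reference base is ambiguous (N) are excluded from both
#' numerator and denominator.
#'
#' @param read An `aligned_read`.
#' @return Fraction in \[0, 1\].
#' @export
read_mutant_fraction <- function(read) {
  p <- read$pairs
  keep <- p$rbase %in% BASES
  n <- sum(keep)
  if (n == 0) stop("read has no aligned pairs with unambiguous reference")
  sum(p$qbase[keep] != p$rbase[keep]) / n
}

#' Apply read-level and base-level filters
#'
#' Drops reads whose mutant fraction exceeds the threshold (computed before
#' quality masking), then masks remaining bases below the quality cutoff so
#' they contribute nothing downstream. Duplicate-flagged reads are dropped
#' unless configured otherwise.
#'
#' @param reads List of `aligned_read` objects.
#' @param config A [filter_config()].
#' @param keep_duplicates Keep duplicate-flagged reads.
#' @return Filtered list of reads; each surviving read's `pairs` retain only
#'   unmasked bases (possibly zero rows). Filter tallies are attached as
#'   attribute `log` and reported via `message()`.
#' @export
filter_reads <- function(reads, config = filter_config(),
                         keep_duplicates = FALSE) {
  n_in <- length(reads)
  if (!keep_duplicates) {
    reads <- Filter(function(r) !isTRUE(r$duplicate), reads)
  }
  n_dup <- n_in - length(reads)
  fractions <- vapply(reads, read_mutant_fraction, numeric(1))
  keep <- fractions <= config$max_read_mutant_fraction
  n_maf <- sum(!keep)
  reads <- reads[keep]
  masked_bases <- 0L
  reads <- lapply(reads, function(r) {
    ok <- r$pairs$qual >= config$min_base_quality & r$pairs$rbase %in% BASES
    masked_bases <<- masked_bases + sum(!ok)
    r$pairs <- r$pairs[ok, , drop = FALSE]
    r
  })
  log <- list(reads_in = n_in, duplicates_removed = n_dup,
              mutant_fraction_removed = n_maf, reads_kept = length(reads),
              bases_masked = masked_bases)
  message(sprintf(
    "filter_reads: %d in, %d duplicate, %d over mutant-fraction, %d kept; %d bases masked",
    n_in, n_dup, n_maf, length(reads), masked_bases))
  structure(reads, log = log)
}

#' Build per-position allele counts from filtered reads
#'
#' Tallies retained, unmasked aligned bases into pileup columns over the
#' panel's covered positions. Positions with no retained base produce no
#' column.
#'
#' @param reads Filtered list of `aligned_read` objects.
#' @param panel A `panel_def`.
#' @param reference Named character vector from [load_reference()].
#' @return Pileup data.frame (see [pileup]).
#' @export
build_pileup <- function(reads, panel, reference) {
  pp <- panel_positions(panel)
  panel_key <- paste(pp$contig, pp$pos)
  pairs <- lapply(reads, function(r) {
    if (nrow(r$pairs) == 0) return(NULL)
    data.frame(contig = r$contig, pos = r$pairs$rpos,
               qbase = r$pairs$qbase, stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, pairs[!vapply(pairs, is.null, logical(1))])
  if (is.null(pairs) || nrow(pairs) == 0) return(pileup_frame())
  pairs <- pairs[paste(pairs$contig, pairs$pos) %in% panel_key &
                   pairs$qbase %in% BASES, , drop = FALSE]
  if (nrow(pairs) == 0) return(pileup_frame())
  key <- paste(pairs$contig, pairs$pos)
  tab <- table(key, factor(pairs$qbase, levels = BASES))
  ukey <- rownames(tab)
  sp <- strsplit(ukey, " ", fixed = TRUE)
  contig <- vapply(sp, `[[`, character(1), 1)
  pos <- as.integer(vapply(sp, `[[`, character(1), 2))
  ref <- vapply(seq_along(pos), function(i) {
    seq <- reference[[contig[i]]]
    if (is.null(seq) || pos[i] + 1L > nchar(seq)) {
      stop("reference base missing for ", contig[i], ":", pos[i])
    }
    substring(seq, pos[i] + 1L, pos[i] + 1L)
  }, character(1))
  out <- pileup_frame(contig, pos, ref,
                      as.integer(tab[, "A"]), as.integer(tab[, "C"]),
                      as.integer(tab[, "G"]), as.integer(tab[, "T"]))
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
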