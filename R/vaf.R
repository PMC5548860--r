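#' Sample profiles of per-position mutant allele frequencies
#'
#' A `sample_profile` carries one sample's per-position VAFs: a positions
#' data.frame with `contig pos ref depth A C G T maf`, where `maf` is the
#' *total* non-reference frequency at the position (all three alternate
#' bases summed), plus sample metadata. Positions are sorted and unique per
#' (contig, pos).
#'
#' @param sample_id Sample identifier.
#' @param material One of `"cfDNA"`, `"WBC"`, `"tumor"`.
#' @param positions Positions data.frame, typically from
#'   [profile_from_pileup()].
#' @return A `sample_profile` object.
#' @export
sample_profile <- function(sample_id, material, positions) {
  material <- match.arg(material, c("cfDNA", "WBC", "tumor"))
  stopifnot(all(c("contig", "pos", "ref", "depth", BASES, "maf")
                %in% names(positions)))
  o <- order(positions$contig, positions$pos)
  positions <- positions[o, , drop = FALSE]
  if (anyDuplicated(paste(positions$contig, positions$pos))) {
    stop("duplicate (contig, pos) in profile positions")
  }
  rownames(positions) <- NULL
  structure(list(sample_id = sample_id, material = material,
                 positions = positions,
                 mean_depth = if (nrow(positions)) mean(positions$depth)
                              else NA_real_),
            class = "sample_profile")
}

#' @export
print.sample_profile <- function(x, ...) {
  cat(sprintf("<sample_profile> %s (%s): %d positions, mean depth %.0f\n",
              x$sample_id, x$material, nrow(x$positions), x$mean_depth))
  invisible(x)
}

#' Per-position mutant allele frequency
#'
#' The total non-reference frequency at a position: the sum of all
#' alternate-base counts divided by the retained depth. For a reference-A
#' position with counts A:9990, C:3, G:5, T:2 the MAF is
#' (3 + 5 + 2) / 10000 = 0.001.
#'
#' @param column One pileup row (data.frame with `ref`, `A`, `C`, `G`, `T`,
#'   `depth`), or a pileup data.frame of one row.
#' @return List with `maf` (total non-reference fraction) and `per_allele`
#'   (named fractions for each alternate base).
#' @export
position_vaf <- function(column) {
  if (nrow(column) != 1) stop("position_vaf expects a single pileup row")
  if (column$depth <= 0) stop("cannot compute VAF at zero depth")
  ref <- column$ref
  if (!ref %in% BASES) stop("reference base must be A/C/G/T, got ", ref)
  counts <- vapply(BASES, function(b) as.numeric(column[[b]]), numeric(1))
  alt <- setdiff(BASES, ref)
  per_allele <- counts[alt] / column$depth
  list(maf = sum(per_allele), per_allele = per_allele)
}

#' Build a sample profile from pileup columns
#'
#' Vectorized [position_vaf()] over a whole pileup: positions with
#' ambiguous reference or zero depth are dropped (they admit no VAF).
#'
#' @param columns Pileup data.frame.
#' @param sample_id,material Profile metadata.
#' @return A [sample_profile()].
#' @export
profile_from_pileup <- function(columns, sample_id, material) {
  check_pileup(columns)
  keep <- columns$ref %in% BASES & columns$depth > 0
  columns <- columns[keep, , drop = FALSE]
  refcount <- numeric(nrow(columns))
  for (b in BASES) {
    sel <- columns$ref == b
    refcount[sel] <- columns[[b]][sel]
  }
  columns$maf <- (columns$depth - refcount) / columns$depth
  sample_profile(sample_id, material, columns)
}

#' Locus-level filters on a profile
#'
#' Keeps positions with retained depth at least `min_depth` and total MAF
#' at most `max_maf`. The depth rule removes poorly covered loci; the MAF
#' cap removes germline heterozygous sites (near 0.5) and other
#' constitutional variation from the somatic background analysis. Both
#' thresholds are strict as worded: depth 10000 and MAF exactly 0.1 are
#' retained. Idempotent.
#'
#' @param profile A `sample_profile`.
#' @param min_depth Minimum retained depth (default 10000).
#' @param max_maf Maximum total MAF (default 0.1).
#' @return Filtered `sample_profile` with removal tallies in attribute
#'   `log`.
#' @export
filter_positions <- function(profile, min_depth = 10000, max_maf = 0.1) {
  pos <- profile$positions
  low_depth <- pos$depth < min_depth
  high_maf <- !low_depth & pos$maf > max_maf
  keep <- !low_depth & !high_maf
  out <- sample_profile(profile$sample_id, profile$material,
                        pos[keep, , drop = FALSE])
  log <- list(positions_in = nrow(pos),
              removed_low_depth = sum(low_depth),
              removed_high_maf = sum(high_maf),
              positions_kept = sum(keep))
  message(sprintf(
    "filter_positions [%s]: %d in, %d below %gx, %d above maf %g, %d kept",
    profile$sample_id, nrow(pos), sum(low_depth), min_depth,
    sum(high_maf), max_maf, sum(keep)))
  attr(out, "log") <- log
  out
}

#' Per-gene mutant allele frequency
#'
#' The gene-level statistic is the arithmetic mean of per-position total
#' MAFs over the gene's amplicon positions:
#' F_gene = (F_1 + ... + F_n) / n with n the gene's total amplicon length.
#' Positions with no surviving pileup column contribute 0 to the numerator
#' while n stays the full amplicon length (default); `covered_only = TRUE`
#' divides by the number of covered positions instead.
#'
#' @param profile A `sample_profile` (typically after [filter_positions()]).
#' @param panel A `panel_def`.
#' @param gene Gene symbol.
#' @param covered_only Divide by covered rather than designed length.
#' @return List with `gene`, `n_positions`, `f_gene`.
#' @export
gene_frequency <- function(profile, panel, gene, covered_only = FALSE) {
  if (!gene %in% panel$genes) stop("gene not in panel: ", gene)
  amp <- panel$amplicons[panel$amplicons$gene == gene, , drop = FALSE]
  n_designed <- sum(amp$end - amp$start)
  pos <- profile$positions
  in_gene <- rep(FALSE, nrow(pos))
  for (i in seq_len(nrow(amp))) {
    in_gene <- in_gene | (pos$contig == amp$contig[i] &
                            pos$pos >= amp$start[i] & pos$pos < amp$end[i])
  }
  n_cov <- sum(in_gene)
  denom <- if (covered_only) n_cov else n_designed
  f <- if (denom == 0) NA_real_ else sum(pos$maf[in_gene]) / denom
  list(gene = gene, n_positions = denom, f_gene = f)
}

#' Gene frequencies for every panel gene
#'
#' @inheritParams gene_frequency
#' @return data.frame `gene n_positions f_gene`.
#' @export
gene_frequencies <- function(profile, panel, covered_only = FALSE) {
  rows <- lapply(panel$genes, function(g)
    gene_frequency(profile, panel, g, covered_only))
  data.frame(gene = vapply(rows, `[[`, character(1), "gene"),
             n_positions = vapply(rows, `[[`, numeric(1), "n_positions"),
             f_gene = vapply(rows, `[[`, numeric(1), "f_gene"),
             stringsAsFactors = FALSE)
}

#' Rank genes by mean frequency across samples
#'
#' Averages each gene's F statistic across the supplied profiles and ranks
#' in descending order; ties break lexicographically by gene symbol, so the
#' ordering is deterministic.
#'
#' @param profiles List of `sample_profile` objects.
#' @param panel A `panel_def`.
#' @param covered_only Passed to [gene_frequency()].
#' @return data.frame `gene n_positions f_gene rank`, ranked descending.
#' @export
rank_genes <- function(profiles, panel, covered_only = FALSE) {
  if (length(profiles) == 0) stop("rank_genes needs at least one profile")
  per_sample <- lapply(profiles, gene_frequencies, panel = panel,
                       covered_only = covered_only)
  f <- rowMeans(do.call(cbind, lapply(per_sample, `[[`, "f_gene")),
                na.rm = TRUE)
  out <- per_sample[[1]]
  out$f_gene <- f
  out <- out[order(-out$f_gene, out$gene), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
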