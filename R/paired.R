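#' Paired correlation of mutant allele frequencies
#'
#' Least-squares simple regression of `y` on `x` with Pearson correlation,
#' R-squared, and adjusted R-squared (one predictor):
#' adj R^2 = 1 - (1 - R^2) (n - 1) / (n - 2).
#' Slope and intercept are direction-dependent (y on x); r is symmetric.
#'
#' @param x,y Numeric vectors of equal length (n >= 3); e.g. WBC MAFs as
#'   `x` and the paired cfDNA MAFs as `y`.
#' @param labels Optional per-point labels (e.g. "contig:pos").
#' @return A `correlation_result`: list with `pearson_r`, `r_squared`,
#'   `adjusted_r_squared`, `slope`, `intercept`, `n`.
#' @export
paired_correlation <- function(x, y, labels = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired points, got ", n)
  if (stats::sd(x) == 0) stop("x is constant; correlation undefined")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  r2 <- r^2
  structure(list(pearson_r = r, r_squared = r2,
                 adjusted_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = n, labels = labels),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> n = %d, r = %.4f, R2 = %.4f, adj R2 = %.4f, y = %.4f x + %.2g\n",
    x$n, x$pearson_r, x$r_squared, x$adjusted_r_squared, x$slope,
    x$intercept))
  invisible(x)
}

# Inner join of two profiles' positions on (contig, pos).
join_positions <- function(p1, p2, suffixes = c("_1", "_2")) {
  merge(p1$positions, p2$positions, by = c("contig", "pos", "ref"),
        suffixes = suffixes)
}

#' Cohort-averaged paired profile
#'
#' For each panel position, averages the WBC and cfDNA MAFs over the pairs
#' in which the position passes the inclusion thresholds (retained depth
#' strictly above `min_depth` and MAF strictly above `min_maf` in *both*
#' members of the pair). Positions passing in zero pairs are omitted.
#'
#' @param pairs List of pairs; each element a list with `wbc` and `cfdna`
#'   `sample_profile`s (as produced by [simulate_pair()]).
#' @param min_depth Inclusion depth threshold, applied as `depth > min_depth`.
#' @param min_maf Inclusion MAF threshold, applied as `maf > min_maf`
#'   (0.003 equals the 0.3% display convention).
#' @return data.frame `contig pos n_pairs wbc_mean cfdna_mean`.
#' @export
cohort_mean_profile <- function(pairs, min_depth = 10000, min_maf = 0.003) {
  if (length(pairs) == 0) stop("cohort_mean_profile needs at least one pair")
  acc <- NULL
  for (p in pairs) {
    j <- join_positions(p$wbc, p$cfdna, c("_wbc", "_cf"))
    pass <- j$depth_wbc > min_depth & j$maf_wbc > min_maf &
      j$depth_cf > min_depth & j$maf_cf > min_maf
    j <- j[pass, c("contig", "pos", "maf_wbc", "maf_cf"), drop = FALSE]
    if (nrow(j) == 0) next
    j$n <- 1L
    acc <- if (is.null(acc)) j else rbind(acc, j)
  }
  if (is.null(acc)) {
    return(data.frame(contig = character(), pos = integer(),
                      n_pairs = integer(), wbc_mean = numeric(),
                      cfdna_mean = numeric()))
  }
  agg <- stats::aggregate(cbind(maf_wbc, maf_cf, n) ~ contig + pos,
                          data = acc, FUN = sum)
  out <- data.frame(contig = agg$contig, pos = agg$pos,
                    n_pairs = as.integer(agg$n),
                    wbc_mean = agg$maf_wbc / agg$n,
                    cfdna_mean = agg$maf_cf / agg$n,
                    stringsAsFactors = FALSE)
  out[order(out$contig, out$pos), , drop = FALSE]
}

#' Cohort-level cfDNA vs WBC correlation
#'
#' Correlates the position-wise cohort means from [cohort_mean_profile()]
#' (WBC mean as x, cfDNA mean as y).
#'
#' @inheritParams cohort_mean_profile
#' @return A `correlation_result`.
#' @export
cohort_correlation <- function(pairs, min_depth = 10000, min_maf = 0.003) {
  m <- cohort_mean_profile(pairs, min_depth, min_maf)
  if (nrow(m) < 3) stop("fewer than 3 positions pass the cohort thresholds")
  paired_correlation(m$wbc_mean, m$cfdna_mean,
                     labels = paste0(m$contig, ":", m$pos))
}

#' Within-individual cfDNA vs WBC correlation
#'
#' Raw per-position correlation for one pair (no cohort averaging), with
#' the same both-members inclusion thresholds.
#'
#' @param wbc,cfdna `sample_profile`s from the same individual.
#' @inheritParams cohort_mean_profile
#' @return A `correlation_result`.
#' @export
individual_correlation <- function(wbc, cfdna, min_depth = 10000,
                                   min_maf = 0.003) {
  j <- join_positions(wbc, cfdna, c("_wbc", "_cf"))
  pass <- j$depth_wbc > min_depth & j$maf_wbc > min_maf &
    j$depth_cf > min_depth & j$maf_cf > min_maf
  j <- j[pass, , drop = FALSE]
  if (nrow(j) < 3) stop("fewer than 3 positions pass in both members")
  paired_correlation(j$maf_wbc, j$maf_cf,
                     labels = paste0(j$contig, ":", j$pos))
}

#' Technical-replicate concordance
#'
#' Correlates per-position MAFs of two technical replicates of the same
#' sample, restricted to positions passing the depth and MAF inclusion
#' thresholds in *both* replicates.
#'
#' @param rep1,rep2 `sample_profile`s of the two replicates (same panel).
#' @inheritParams cohort_mean_profile
#' @return A `correlation_result` (rep1 as x, rep2 as y).
#' @export
replicate_concordance <- function(rep1, rep2, min_depth = 10000,
                                  min_maf = 0.003) {
  j <- join_positions(rep1, rep2, c("_1", "_2"))
  pass <- j$depth_1 > min_depth & j$maf_1 > min_maf &
    j$depth_2 > min_depth & j$maf_2 > min_maf
  j <- j[pass, , drop = FALSE]
  if (nrow(j) < 3) {
    stop("fewer than 3 shared positions pass the thresholds in both replicates")
  }
  paired_correlation(j$maf_1, j$maf_2, labels = paste0(j$contig, ":", j$pos))
}
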