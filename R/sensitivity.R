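#' Spike-in dilution design
#'
#' Describes a spike-in sensitivity experiment: a set of reference variants
#' carried at known nominal allele fractions (dilution levels), sequenced
#' in replicate at a target depth. The default variant set mirrors a
#' six-variant reference standard (EGFR L858R and T790M, KRAS G12D, NRAS
#' Q61K and A59T, PIK3CA E545K) at replica panel coordinates.
#'
#' @param variants data.frame `contig position ref alt` (+ optional `name`)
#'   of the spiked variants.
#' @param levels Nominal allele fractions, each in (0, 1). Default
#'   `c(0.0005, 0.001, 0.005, 0.01)`.
#' @param replicates Repeated experiments per level (default 5).
#' @param depth Target sequencing depth (default 30000).
#' @return A `dilution_design` list.
#' @export
dilution_design <- function(variants,
                            levels = c(0.0005, 0.001, 0.005, 0.01),
                            replicates = 5L, depth = 30000L) {
  stopifnot(all(levels > 0), all(levels < 1), replicates >= 1, depth >= 1)
  if (is.null(variants$name)) {
    variants$name <- paste0(variants$contig, ":", variants$position,
                            variants$ref, ">", variants$alt)
  }
  structure(list(variants = variants, levels = levels,
                 replicates = as.integer(replicates),
                 depth = as.integer(depth)),
            class = "dilution_design")
}

#' Detect a low-frequency variant against the sequencing-error background
#'
#' One-sided exact binomial test of the alternate-allele count against the
#' error-only null Binomial(depth, error_rate / 3): the per-base miscall
#' rate is split uniformly over the three possible alternates. A site is
#' detected when the tail p-value falls below `alpha` *and* at least
#' `min_alt` alternate reads support it (the floor prevents detections
#' driven by one or two error reads). With `error_rate = 0` the p-value is
#' 0 for any positive count and the floor alone decides.
#'
#' @param column One pileup row (or any list with `ref`, `depth` and base
#'   counts).
#' @param alt_base Alternate base to test (must differ from `ref`).
#' @param error_rate Total per-base miscall rate in \[0, 1).
#' @param alpha Significance level (default 0.05).
#' @param min_alt Minimum alternate read count (default 3).
#' @return List with `detected`, `p_value`, `observed_vaf`, `alt_count`.
#' @export
detect_variant <- function(column, alt_base, error_rate, alpha = 0.05,
                           min_alt = 3L) {
  if (alt_base == column$ref) stop("alt_base equals the reference base")
  stopifnot(error_rate >= 0, error_rate < 1)
  depth <- as.numeric(column$depth)
  if (depth <= 0) stop("cannot test at zero depth")
  k <- as.numeric(column[[alt_base]])
  p0 <- error_rate / 3
  # exact one-sided tail P(X >= k) under Binomial(depth, p0)
  p_value <- if (k == 0) 1 else
    stats::pbinom(k - 1, depth, p0, lower.tail = FALSE)
  list(detected = (p_value < alpha) && (k >= min_alt),
       p_value = p_value, observed_vaf = k / depth, alt_count = k)
}

#' Summarize a dilution series
#'
#' Per (variant, level): mean observed VAF over replicates, standard error
#' (sample SD / sqrt(replicates)), and detection rate. Per level: the
#' fraction of variant-by-replicate combinations detected. Cells with no
#' observations are reported as absent, not imputed.
#'
#' @param observations data.frame with columns `variant`, `level`,
#'   `replicate`, `observed_vaf`, `detected` (as produced by
#'   [simulate_spikein_series()]).
#' @param design The `dilution_design`.
#' @return A `sensitivity_report`: list with `cells` (per variant x level)
#'   and `levels` (per level) data.frames.
#' @export
summarize_series <- function(observations, design) {
  need <- c("variant", "level", "replicate", "observed_vaf", "detected")
  stopifnot(all(need %in% names(observations)))
  grid <- expand.grid(variant = design$variants$name, level = design$levels,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    obs <- observations[observations$variant == grid$variant[i] &
                          observations$level == grid$level[i], , drop = FALSE]
    n <- nrow(obs)
    data.frame(
      variant = grid$variant[i], level = grid$level[i], n_replicates = n,
      mean_vaf = if (n > 0) mean(obs$observed_vaf) else NA_real_,
      se_vaf = if (n >= 2) stats::sd(obs$observed_vaf) / sqrt(n) else NA_real_,
      detection_rate = if (n > 0) mean(obs$detected) else NA_real_,
      stringsAsFactors = FALSE)
  }))
  levels <- do.call(rbind, lapply(design$levels, function(l) {
    obs <- observations[observations$level == l, , drop = FALSE]
    data.frame(level = l, n = nrow(obs),
               detection_rate = if (nrow(obs)) mean(obs$detected) else NA_real_,
               mean_vaf = if (nrow(obs)) mean(obs$observed_vaf) else NA_real_)
  }))
  structure(list(cells = cells, levels = levels),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n")
  print(x$levels, row.names = FALSE)
  invisible(x)
}

#' Binomial limit of detection
#'
#' The smallest true allele fraction detectable with probability at least
#' `power` under the [detect_variant()] rule at the given depth and error
#' rate. The detection rule reduces to a critical alternate count
#' k* = max(k_alpha, min_alt), where k_alpha is the smallest count whose
#' error-only tail probability is below `alpha`; the LOD is the smallest f
#' on a 1e-5 grid with P(X >= k*) >= power for X ~ Binomial(depth, f).
#' Non-increasing in depth, non-decreasing in error rate.
#'
#' @param depth Sequencing depth (>= 1).
#' @param error_rate Total per-base miscall rate.
#' @param alpha Significance level of the detection test.
#' @param power Required detection probability (default 0.95).
#' @param min_alt Minimum alternate count floor.
#' @param grid_max Upper end of the searched fraction grid (default 0.05).
#' @return List with `lod`, `critical_count`, `depth`, `error_rate`.
#' @export
limit_of_detection <- function(depth, error_rate = 0, alpha = 0.05,
                               power = 0.95, min_alt = 3L,
                               grid_max = 0.05) {
  stopifnot(depth >= 1)
  p0 <- error_rate / 3
  if (p0 == 0) {
    k_alpha <- 1L  # any positive count has p-value 0 < alpha
  } else {
    k_alpha <- stats::qbinom(1 - alpha, depth, p0) + 1L
    while (stats::pbinom(k_alpha - 1, depth, p0, lower.tail = FALSE) >= alpha) {
      k_alpha <- k_alpha + 1L
    }
  }
  k_star <- max(k_alpha, as.integer(min_alt))
  grid <- seq(1e-5, grid_max, by = 1e-5)
  pow <- stats::pbinom(k_star - 1, depth, grid, lower.tail = FALSE)
  hit <- which(pow >= power)
  if (length(hit) == 0) {
    stop(sprintf(
      "power %.2f unreachable by fraction %.3g at depth %d (error rate %g)",
      power, grid_max, depth, error_rate))
  }
  list(lod = grid[hit[1]], critical_count = k_star,
       depth = depth, error_rate = error_rate)
}
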