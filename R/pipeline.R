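#' Validate a run manifest
#'
#' A manifest is a data.frame (or TSV path) with columns `sample_id`,
#' `material` (cfDNA/WBC/tumor), `path` (pileup file), and optional
#' `pair_id` and `replicate_id`. Every problem is reported at once.
#'
#' @param manifest data.frame or TSV path.
#' @return Character vector of problems; empty means valid.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) return(paste("manifest file not found:", manifest))
    manifest <- tryCatch(
      utils::read.delim(manifest, stringsAsFactors = FALSE),
      error = function(e) NULL)
    if (is.null(manifest)) return("manifest is not parseable as TSV")
  }
  problems <- character(0)
  need <- c("sample_id", "material", "path")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    return(paste("manifest lacks column(s):", paste(missing, collapse = ", ")))
  }
  if (nrow(manifest) == 0) problems <- c(problems, "manifest is empty")
  dup <- manifest$sample_id[duplicated(manifest$sample_id)]
  if (length(dup) > 0) {
    problems <- c(problems, paste("duplicate sample_id:", unique(dup)))
  }
  bad_mat <- !manifest$material %in% c("cfDNA", "WBC", "tumor")
  if (any(bad_mat)) {
    problems <- c(problems, paste("invalid material for sample",
                                  manifest$sample_id[bad_mat]))
  }
  gone <- !file.exists(manifest$path)
  if (any(gone)) {
    problems <- c(problems, paste("missing file:", manifest$path[gone]))
  }
  if ("pair_id" %in% names(manifest)) {
    for (p in unique(stats::na.omit(manifest$pair_id[manifest$pair_id != ""]))) {
      mem <- manifest[!is.na(manifest$pair_id) & manifest$pair_id == p, ]
      if (nrow(mem) != 2 ||
          !setequal(mem$material, c("cfDNA", "WBC"))) {
        problems <- c(problems, paste0(
          "pair ", p, " must have exactly one cfDNA and one WBC member"))
      }
    }
  }
  problems
}

#' Run the profiling pipeline over a manifest
#'
#' For every sample: read its pileup, compute per-position VAFs, apply the
#' locus filters, and rank genes; for every cfDNA/WBC pair: correlate the
#' paired MAFs and call + background-subtract hotspot mutations. A failure
#' in one sample is recorded in the report and does not abort the others.
#' Deterministic given inputs.
#'
#' @param manifest data.frame (see [validate_manifest()]).
#' @param panel A `panel_def` (with hotspots for calling).
#' @param config A [filter_config()].
#' @param min_maf Correlation inclusion MAF threshold.
#' @return A `run_report` list: `samples` (per-sample position/filter
#'   tallies), `gene_ranking`, `correlations` (per pair), `calls` (per
#'   pair, after WBC subtraction), `errors`, `config`.
#' @export
run_pipeline <- function(manifest, panel, config = filter_config(),
                         min_maf = 0.003) {
  problems <- validate_manifest(manifest)
  if (length(problems) > 0) {
    stop("manifest invalid:\n  ", paste(problems, collapse = "\n  "))
  }
  profiles <- list()
  samples <- list()
  errors <- list()
  for (i in seq_len(nrow(manifest))) {
    sid <- manifest$sample_id[i]
    res <- tryCatch({
      cols <- read_pileup(manifest$path[i])
      prof <- profile_from_pileup(cols, sid, manifest$material[i])
      filt <- filter_positions(prof, config$min_locus_depth)
      list(profile = filt, log = attr(filt, "log"))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[sid]] <- conditionMessage(res)
      next
    }
    profiles[[sid]] <- res$profile
    samples[[sid]] <- c(list(sample_id = sid,
                             material = manifest$material[i],
                             mean_depth = res$profile$mean_depth),
                        res$log)
  }
  cf_profiles <- Filter(function(p) p$material == "cfDNA", profiles)
  ranking <- if (length(cf_profiles) > 0) {
    rank_genes(cf_profiles, panel)
  } else NULL

  correlations <- list()
  calls <- list()
  if ("pair_id" %in% names(manifest)) {
    pair_ids <- unique(stats::na.omit(
      manifest$pair_id[!is.na(manifest$pair_id) & manifest$pair_id != ""]))
    for (p in pair_ids) {
      mem <- manifest[!is.na(manifest$pair_id) & manifest$pair_id == p, ]
      wbc_id <- mem$sample_id[mem$material == "WBC"]
      cf_id <- mem$sample_id[mem$material == "cfDNA"]
      if (is.null(profiles[[wbc_id]]) || is.null(profiles[[cf_id]])) next
      correlations[[p]] <- tryCatch(
        individual_correlation(profiles[[wbc_id]], profiles[[cf_id]],
                               min_depth = config$min_locus_depth,
                               min_maf = min_maf),
        error = function(e) conditionMessage(e))
      if (nrow(panel$hotspots) > 0) {
        cf_calls <- call_hotspots(profiles[[cf_id]], panel$hotspots)
        calls[[p]] <- subtract_wbc_background(cf_calls, profiles[[wbc_id]])
      }
    }
  }
  structure(list(samples = samples, gene_ranking = ranking,
                 correlations = correlations, calls = calls,
                 errors = errors,
                 config = unclass(config),
                 n_samples = length(profiles)),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d samples (%d failed), %d pairs correlated\n",
              x$n_samples, length(x$errors), length(x$correlations)))
  if (!is.null(x$gene_ranking)) {
    cat("top genes:\n")
    print(utils::head(x$gene_ranking, 5), row.names = FALSE)
  }
  invisible(x)
}

#' Write a run report as JSON
#'
#' @param report A `run_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$correlations <- lapply(out$correlations, function(cr) {
    if (is.character(cr)) return(list(error = cr))
    cr$labels <- NULL
    unclass(cr)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
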