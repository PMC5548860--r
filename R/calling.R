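#' Hotspot mutation calling
#'
#' Calls a mutation at a hotspot site when the hotspot's specific alternate
#' allele exceeds `min_vaf` (strictly) and the site's retained depth exceeds
#' `min_depth` (strictly) in this sample. Calls are per alternate allele,
#' keyed by (contig, position, alt). Hotspots outside the profile's covered
#' positions are skipped with a warning.
#'
#' @param profile A `sample_profile`.
#' @param hotspots data.frame `contig position ref alt` (0-based), e.g.
#'   `panel$hotspots`.
#' @param min_vaf Minimum per-allele VAF, strict (default 0.01).
#' @param min_depth Minimum site depth, strict (default 5000).
#' @return data.frame of calls: `contig pos ref alt vaf depth sample_id
#'   material`, ordered by (contig, pos, alt).
#' @export
call_hotspots <- function(profile, hotspots, min_vaf = 0.01,
                          min_depth = 5000) {
  pos <- profile$positions
  key_prof <- paste(pos$contig, pos$pos)
  key_hs <- paste(hotspots$contig, hotspots$position)
  idx <- match(key_hs, key_prof)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    warning(n_missing, " hotspot site(s) not covered by profile ",
            profile$sample_id, "; skipped")
  }
  covered <- !is.na(idx)
  hs <- hotspots[covered, , drop = FALSE]
  row <- pos[idx[covered], , drop = FALSE]
  alt_count <- vapply(seq_len(nrow(hs)),
                      function(i) as.numeric(row[[hs$alt[i]]][i]), numeric(1))
  vaf <- alt_count / row$depth
  called <- vaf > min_vaf & row$depth > min_depth
  n_called <- sum(called)
  out <- data.frame(contig = hs$contig[called], pos = hs$position[called],
                    ref = hs$ref[called], alt = hs$alt[called],
                    vaf = vaf[called], depth = row$depth[called],
                    sample_id = rep(profile$sample_id, n_called),
                    material = rep(profile$material, n_called),
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove calls explained by the WBC background
#'
#' Somatic background mutations from blood cells dominate cfDNA; a
#' cfDNA/tumor call whose site already shows the same alternate allele
#' above `wbc_max_vaf` in the paired WBC sample is treated as blood-derived
#' background and removed. Sites absent from the WBC profile cannot be
#' checked: those calls are retained and flagged `wbc_uncovered`.
#'
#' @param calls Calls data.frame from [call_hotspots()].
#' @param wbc_profile WBC `sample_profile` from the same individual.
#' @param wbc_max_vaf WBC per-allele VAF above which a call is removed
#'   (default 0.01; `1.0` disables subtraction, `0` removes every call with
#'   a single WBC alternate read).
#' @return Retained calls with extra columns `wbc_vaf` and `wbc_uncovered`;
#'   removed calls attached as attribute `removed`.
#' @export
subtract_wbc_background <- function(calls, wbc_profile, wbc_max_vaf = 0.01) {
  if (nrow(calls) == 0) {
    calls$wbc_vaf <- numeric(0)
    calls$wbc_uncovered <- logical(0)
    return(calls)
  }
  wpos <- wbc_profile$positions
  idx <- match(paste(calls$contig, calls$pos),
               paste(wpos$contig, wpos$pos))
  wbc_vaf <- rep(NA_real_, nrow(calls))
  covered <- !is.na(idx)
  wbc_vaf[covered] <- vapply(which(covered), function(i) {
    r <- wpos[idx[i], , drop = FALSE]
    as.numeric(r[[calls$alt[i]]]) / r$depth
  }, numeric(1))
  remove <- covered & wbc_vaf > wbc_max_vaf
  calls$wbc_vaf <- wbc_vaf
  calls$wbc_uncovered <- !covered
  kept <- calls[!remove, , drop = FALSE]
  rownames(kept) <- NULL
  message(sprintf("subtract_wbc_background [%s]: %d calls in, %d removed, %d kept (%d wbc-uncovered)",
                  if (nrow(calls)) calls$sample_id[1] else "?", nrow(calls),
                  sum(remove), nrow(kept), sum(!covered)))
  attr(kept, "removed") <- calls[remove, , drop = FALSE]
  kept
}

call_key <- function(calls) paste(calls$contig, calls$pos, calls$alt)

#' Partition two call sets into shared and private mutations
#'
#' Calls are keyed by (contig, position, alt). Duplicate keys within one
#' list are an error (calls must be unique per site/alternate).
#'
#' @param calls_a,calls_b Call data.frames from [call_hotspots()].
#' @return List with `shared` (rows of `calls_a` whose key appears in both),
#'   `only_a`, `only_b`, and integer `counts`.
#' @export
shared_mutations <- function(calls_a, calls_b) {
  ka <- call_key(calls_a)
  kb <- call_key(calls_b)
  if (anyDuplicated(ka)) stop("duplicate call keys in calls_a")
  if (anyDuplicated(kb)) stop("duplicate call keys in calls_b")
  shared <- calls_a[ka %in% kb, , drop = FALSE]
  only_a <- calls_a[!ka %in% kb, , drop = FALSE]
  only_b <- calls_b[!kb %in% ka, , drop = FALSE]
  list(shared = shared, only_a = only_a, only_b = only_b,
       counts = c(shared = nrow(shared), only_a = nrow(only_a),
                  only_b = nrow(only_b)))
}

#' Write calls as a minimal VCF
#'
#' Emits VCFv4.2 with `AF` and `DP` INFO keys and 1-based positions.
#'
#' @param calls Calls data.frame.
#' @param path Output path.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Retained depth\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g;DP=%d",
                       calls$contig, calls$pos + 1L, calls$ref, calls$alt,
                       calls$vaf, as.integer(calls$depth)), con)
  }
  invisible(path)
}
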