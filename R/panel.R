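#' Panel definitions: amplicons, genes, hotspots
#'
#' A panel definition ties together the genes of a targeted amplicon panel,
#' the amplicon intervals on the reference, and the pre-specified hotspot
#' sites. All internal coordinates are 0-based half-open; conversion to the
#' 1-based mpileup convention happens only at the I/O boundary.
#'
#' @name panel
NULL

new_panel <- function(amplicons, hotspots = NULL) {
  stopifnot(is.data.frame(amplicons),
            all(c("gene", "contig", "start", "end") %in% names(amplicons)))
  if (is.null(hotspots)) {
    hotspots <- data.frame(contig = character(), position = integer(),
                           ref = character(), alt = character())
  }
  structure(list(
    genes = sort(unique(amplicons$gene)),
    amplicons = amplicons[order(amplicons$contig, amplicons$start), , drop = FALSE],
    hotspots = hotspots
  ), class = "panel_def")
}

#' Load a panel definition from a TSV file
#'
#' The panel file is tab-separated with header `gene contig start end` and
#' 0-based half-open amplicon intervals. Overlapping or bookended amplicons
#' of the same gene are merged at load time, so the total covered length is
#' well defined.
#'
#' @param path Path to the panel TSV.
#' @param hotspot_path Optional path to a hotspot TSV with header
#'   `contig position ref alt` (0-based positions).
#' @return A `panel_def` object with elements `genes` (character vector),
#'   `amplicons` (data.frame `gene contig start end`), and `hotspots`
#'   (data.frame `contig position ref alt`).
#' @examples
#' panel <- load_panel(system.file("extdata", "replica_panel.tsv",
#'                                 package = "cfbackground"),
#'                     system.file("extdata", "replica_hotspots.tsv",
#'                                 package = "cfbackground"))
#' panel
#' @export
load_panel <- function(path, hotspot_path = NULL) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  need <- c("gene", "contig", "start", "end")
  if (!all(need %in% names(raw))) {
    stop("panel file must have columns gene/contig/start/end, got: ",
         paste(names(raw), collapse = ", "))
  }
  start <- suppressWarnings(as.integer(raw$start))
  end <- suppressWarnings(as.integer(raw$end))
  bad <- which(is.na(start) | is.na(end) | raw$gene == "" | raw$contig == "")
  if (length(bad) > 0) {
    stop("malformed panel row at line ", bad[1] + 1L,
         " of ", path, " (non-integer coordinates or empty fields)")
  }
  bad <- which(start >= end | start < 0)
  if (length(bad) > 0) {
    stop("invalid amplicon interval at line ", bad[1] + 1L,
         ": require 0 <= start < end")
  }
  amp <- data.frame(gene = raw$gene, contig = raw$contig,
                    start = start, end = end, stringsAsFactors = FALSE)
  amp <- merge_amplicons(amp)

  hotspots <- NULL
  if (!is.null(hotspot_path)) hotspots <- load_hotspots(hotspot_path, amp)
  panel <- new_panel(amp, hotspots)
  message(sprintf("panel: %d genes, %d amplicons, %d bp covered, %d hotspots",
                  length(panel$genes), nrow(panel$amplicons),
                  panel_total_bp(panel), nrow(panel$hotspots)))
  panel
}

# Merge overlapping/bookended amplicons within each gene (union of intervals).
merge_amplicons <- function(amp) {
  parts <- split(amp, paste(amp$gene, amp$contig, sep = "\r"))
  merged <- lapply(parts, function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(start = d$start + 1L, end = d$end))
    data.frame(gene = d$gene[1], contig = d$contig[1],
               start = IRanges::start(ir) - 1L, end = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, unname(merged))
  out[order(out$contig, out$start), , drop = FALSE]
}

#' @rdname load_panel
#' @param amplicons Amplicon data.frame used to check that each hotspot falls
#'   inside a covered interval.
#' @export
load_hotspots <- function(hotspot_path, amplicons = NULL) {
  if (!file.exists(hotspot_path)) stop("hotspot file not found: ", hotspot_path)
  hs <- utils::read.delim(hotspot_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("contig", "position", "ref", "alt")
  if (!all(need %in% names(hs))) {
    stop("hotspot file must have columns contig/position/ref/alt")
  }
  hs$position <- as.integer(hs$position)
  if (any(is.na(hs$position))) stop("non-integer hotspot position")
  if (any(hs$ref == hs$alt)) stop("hotspot with ref == alt")
  if (any(!hs$ref %in% c("A", "C", "G", "T")) ||
      any(!hs$alt %in% c("A", "C", "G", "T"))) {
    stop("hotspot ref/alt must be A/C/G/T")
  }
  if (!is.null(amplicons)) {
    inside <- positions_in_amplicons(hs$contig, hs$position, amplicons)
    if (!all(inside)) {
      stop(sum(!inside), " hotspot(s) fall outside all panel amplicons")
    }
  }
  hs[order(hs$contig, hs$position, hs$alt), need]
}

positions_in_amplicons <- function(contig, position, amplicons) {
  q <- GenomicRanges::GRanges(contig,
                              IRanges::IRanges(position + 1L, width = 1L))
  s <- GenomicRanges::GRanges(amplicons$contig,
                              IRanges::IRanges(amplicons$start + 1L,
                                               amplicons$end))
  IRanges::overlapsAny(q, s)
}

#' Panel summary quantities
#'
#' @param panel A `panel_def`.
#' @return `panel_total_bp`: total covered length in bp (sum of merged
#'   amplicon lengths). `panel_positions`: data.frame of every covered
#'   position (`gene contig pos`, 0-based).
#' @export
panel_total_bp <- function(panel) {
  sum(panel$amplicons$end - panel$amplicons$start)
}

#' @rdname panel_total_bp
#' @export
panel_positions <- function(panel) {
  amp <- panel$amplicons
  n <- amp$end - amp$start
  data.frame(
    gene = rep(amp$gene, n),
    contig = rep(amp$contig, n),
    pos = unlist(lapply(seq_len(nrow(amp)),
                        function(i) seq.int(amp$start[i], amp$end[i] - 1L))),
    stringsAsFactors = FALSE
  )
}

#' @export
print.panel_def <- function(x, ...) {
  cat(sprintf("<panel_def> %d genes, %d amplicons, %d bp, %d hotspots\n",
              length(x$genes), nrow(x$amplicons), panel_total_bp(x),
              nrow(x$hotspots)))
  invisible(x)
}

#' Load a reference FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of uppercase sequences, one per contig.
#'   Contigs containing ambiguous (non-ACGT) bases are flagged with a warning.
#' @export
load_reference <- function(path) {
  if (!file.exists(path)) stop("reference not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("reference FASTA is empty: ", path)
  nm <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(nm)) stop("duplicate contig names in reference: ",
                              nm[duplicated(nm)][1])
  out <- toupper(as.character(seqs))
  names(out) <- nm
  ambig <- vapply(out, function(s) grepl("[^ACGT]", s), logical(1))
  if (any(ambig)) {
    warning("ambiguous bases in contig(s): ",
            paste(names(out)[ambig], collapse = ", "))
  }
  out
}

#' Write panel / hotspot / reference files
#'
#' Counterparts to [load_panel()] and [load_reference()], used by the
#' synthetic-data generator.
#' @param panel A `panel_def`.
#' @param path Output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel$amplicons[, c("gene", "contig", "start", "end")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
write_hotspots <- function(panel, path) {
  utils::write.table(panel$hotspots, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @param reference Named character vector of sequences.
#' @export
write_reference <- function(reference, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(reference), path, width = 70L)
  invisible(path)
}
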