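#' Pileup columns
#'
#' Per-position retained allele counts are carried as a data.frame with
#' columns `contig`, `pos` (0-based), `ref`, `A`, `C`, `G`, `T`, `depth`
#' (= A+C+G+T). Quality-masked bases contribute to neither the counts nor
#' the depth.
#'
#' @name pileup
NULL

BASES <- c("A", "C", "G", "T")

pileup_frame <- function(contig = character(), pos = integer(),
                         ref = character(),
                         A = integer(), C = integer(),
                         G = integer(), T = integer()) {
  data.frame(contig = contig, pos = pos, ref = ref,
             A = A, C = C, G = G, T = T,
             depth = A + C + G + T, stringsAsFactors = FALSE)
}

check_pileup <- function(columns) {
  stopifnot(all(c("contig", "pos", "ref", BASES, "depth") %in% names(columns)))
  if (any(columns$depth != columns$A + columns$C + columns$G + columns$T)) {
    stop("pileup depth does not equal the sum of base counts")
  }
  invisible(columns)
}

#' Write pileup columns as mpileup-dialect text
#'
#' Six tab-separated columns per line: contig, 1-based position, reference
#' base, retained depth, base string, quality string. The base string uses
#' `.` for reference-matching bases and the uppercase base for alternates;
#' qualities are written as a constant placeholder since counts are
#' post-filtering. [read_pileup()] inverts the encoding exactly.
#'
#' @param columns Pileup data.frame sorted by (contig, pos).
#' @param path Output file.
#' @export
write_pileup <- function(columns, path) {
  check_pileup(columns)
  if (nrow(columns) > 0) {
    o <- order(columns$contig, columns$pos)
    if (!identical(o, seq_len(nrow(columns)))) {
      stop("pileup columns must be sorted by (contig, position)")
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(columns) == 0) return(invisible(path))
  bases <- vapply(seq_len(nrow(columns)), function(i) {
    cnt <- vapply(BASES, function(b) as.integer(columns[[b]][i]), integer(1))
    ref <- columns$ref[i]
    alt <- setdiff(BASES, ref)
    paste0(strrep(".", cnt[[ref]]),
           paste(rep(alt, cnt[alt]), collapse = ""))
  }, character(1))
  quals <- strrep("I", columns$depth)
  quals[quals == ""] <- "*"
  bases[bases == ""] <- "*"
  writeLines(sprintf("%s\t%d\t%s\t%d\t%s\t%s",
                     columns$contig, columns$pos + 1L, columns$ref,
                     columns$depth, bases, quals), con)
  invisible(path)
}

#' Read mpileup-dialect text into pileup columns
#'
#' Accepts the 6-column samtools mpileup text dialect. `.`/`,` count toward
#' the reference allele; `A/C/G/T` (either case) toward the corresponding
#' alternate; `*`, `N` and indel/start/end decorations (`+n...`, `-n...`,
#' `^x`, `$`) are skipped.
#'
#' @param path mpileup text file.
#' @return Pileup data.frame (0-based `pos`).
#' @export
read_pileup <- function(path) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(pileup_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 5)) {
    stop("malformed pileup line (need >= 5 tab-separated fields)")
  }
  contig <- vapply(fields, `[[`, character(1), 1)
  pos <- as.integer(vapply(fields, `[[`, character(1), 2)) - 1L
  ref <- toupper(vapply(fields, `[[`, character(1), 3))
  basestr <- vapply(fields, `[[`, character(1), 5)
  # strip read-start markers (^ plus mapq char), read-end markers, indels;
  # ultra-deep base strings are long, so counting is vectorized over lines
  # with fixed-pattern deletions rather than per-character splits
  basestr <- gsub("\\^.", "", basestr)
  basestr <- gsub("$", "", basestr, fixed = TRUE)
  has_indel <- grepl("[+-][0-9]+", basestr)
  basestr[has_indel] <- vapply(basestr[has_indel], strip_indels, character(1),
                               USE.NAMES = FALSE)
  nch <- nchar(basestr)
  count_char <- function(chars) {
    total <- integer(length(basestr))
    for (ch in chars) {
      total <- total + (nch - nchar(gsub(ch, "", basestr, fixed = TRUE)))
    }
    total
  }
  counts <- vapply(BASES, function(b) count_char(c(b, tolower(b))),
                   integer(length(basestr)))
  if (length(basestr) == 1) counts <- matrix(counts, 1)
  ref_cnt <- count_char(c(".", ","))
  for (b in BASES) {
    sel <- ref == b
    counts[sel, match(b, BASES)] <- counts[sel, match(b, BASES)] + ref_cnt[sel]
  }
  pileup_frame(contig, pos, ref,
               counts[, 1], counts[, 2], counts[, 3], counts[, 4])
}

# Remove indel runs (+n<seq> / -n<seq>) from one mpileup base string.
strip_indels <- function(s) {
  while (grepl("[+-][0-9]+", s)) {
    n <- as.integer(sub("[+-]", "", regmatches(s, regexpr("[+-][0-9]+", s))))
    s <- sub(paste0("[+-][0-9]+[ACGTNacgtn*#]{", n, "}"), "", s)
  }
  s
}
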