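#' Simulation configuration
#'
#' Captures the data-generating assumptions the synthetic cohort emulates:
#' ultra-deep targeted sequencing (~40000x) of paired WBC/cfDNA samples
#' over an amplicon panel, where cfDNA largely re-samples the blood-cell
#' somatic background (`shared_weight`, default 0.9 — most cfDNA is debris
#' of blood cells), with per-base sequencing error, germline heterozygous
#' sites near 0.5 AF, and a gene-specific background elevation (NPM1-like).
#'
#' The per-position true background frequency is a two-component mixture:
#' most positions draw from Exponential(mean `background_scale` times the
#' gene's elevation factor); a fraction `clonal_fraction` of positions
#' carry larger clones from Exponential(mean `clonal_scale`), emulating
#' clonal hematopoiesis and recurrent error-prone sites — the positions
#' that populate the 0.3%-10% window the correlation analyses select on.
#' All true frequencies are capped at 0.05.
#'
#' @param panel A `panel_def` (see [simulate_reference_and_panel()]).
#' @param reference Named character vector of contig sequences.
#' @param seed Integer seed; together with the config it fully determines
#'   every generated dataset.
#' @param n_pairs Number of WBC/cfDNA pairs in the synthetic cohort.
#' @param mean_depth Mean sequencing depth (Poisson per position).
#' @param base_error_rate Total per-base miscall rate.
#' @param quality_mean,quality_sd Phred quality model for emitted reads.
#' @param background_scale Mean of the bulk per-position background
#'   frequency (exponential).
#' @param gene_elevation Named multipliers on `background_scale` for
#'   specific genes (default: one NPM1-like gene at x10).
#' @param shared_weight Fraction of the cfDNA true frequency inherited from
#'   the paired WBC background; the remainder is an independent draw.
#' @param germline_het_density Fraction of panel positions set to 0.5 AF in
#'   both members of a pair.
#' @param clonal_fraction,clonal_scale Heavy-tail mixture component (see
#'   above).
#' @param overdispersion Beta-binomial rho; 0 means pure binomial counts.
#' @param spikein Optional [dilution_design()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(panel, reference, seed = 1L, n_pairs = 20L,
                       mean_depth = 40000L, base_error_rate = 1e-4,
                       quality_mean = 35, quality_sd = 4,
                       background_scale = 2e-4,
                       gene_elevation = c(NPM1 = 10),
                       shared_weight = 0.9,
                       germline_het_density = 0.002,
                       clonal_fraction = 0.05, clonal_scale = 0.01,
                       overdispersion = 0, spikein = NULL) {
  stopifnot(shared_weight >= 0, shared_weight <= 1,
            base_error_rate >= 0, base_error_rate <= 1,
            germline_het_density >= 0, germline_het_density <= 1,
            clonal_fraction >= 0, clonal_fraction <= 1,
            overdispersion >= 0, overdispersion < 1,
            mean_depth >= 1, n_pairs >= 1)
  if (length(gene_elevation) > 0) {
    unknown <- setdiff(names(gene_elevation), panel$genes)
    if (length(unknown) > 0) {
      warning("gene_elevation for gene(s) not in panel: ",
              paste(unknown, collapse = ", "))
    }
  }
  structure(list(panel = panel, reference = reference,
                 seed = as.integer(seed), n_pairs = as.integer(n_pairs),
                 mean_depth = mean_depth,
                 base_error_rate = base_error_rate,
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 background_scale = background_scale,
                 gene_elevation = gene_elevation,
                 shared_weight = shared_weight,
                 germline_het_density = germline_het_density,
                 clonal_fraction = clonal_fraction,
                 clonal_scale = clonal_scale,
                 overdispersion = overdispersion, spikein = spikein),
            class = "sim_config")
}

# Derived per-call seed, kept within 32-bit integer range.
sub_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

# Fifty cancer-associated gene symbols for the replica panel.
PANEL_GENES <- c(
  "ABL1", "AKT1", "ALK", "APC", "ATM", "BRAF", "CDH1", "CDKN2A", "CSF1R",
  "CTNNB1", "EGFR", "ERBB2", "ERBB4", "EZH2", "FBXW7", "FGFR1", "FGFR2",
  "FGFR3", "FLT3", "GNA11", "GNAQ", "GNAS", "HNF1A", "HRAS", "IDH1",
  "IDH2", "JAK2", "JAK3", "KDR", "KIT", "KRAS", "MET", "MLH1", "MPL",
  "NOTCH1", "NPM1", "NRAS", "PDGFRA", "PIK3CA", "PTEN", "PTPN11", "RB1",
  "RET", "SMAD4", "SMARCB1", "SMO", "SRC", "STK11", "TP53", "VHL")

#' Simulate a replica reference and panel
#'
#' Builds a synthetic single-contig reference and an amplicon panel with
#' the study cardinalities: 50 genes, 207 amplicons partitioning a 22027 bp
#' covered region (each amplicon at least 50 bp), and 2800 hotspot
#' (position, ref, alt) sites placed uniformly within amplicons. The
#' NPM1-like gene gets exactly one amplicon. Deterministic per seed.
#'
#' @param seed Integer seed.
#' @param n_genes,n_amplicons,total_bp,n_hotspots Panel cardinalities.
#' @return List with `reference` (named character vector) and `panel`
#'   (`panel_def`).
#' @export
simulate_reference_and_panel <- function(seed = 1L, n_genes = 50L,
                                         n_amplicons = 207L,
                                         total_bp = 22027L,
                                         n_hotspots = 2800L) {
  if (n_amplicons < n_genes) stop("need at least one amplicon per gene")
  if (total_bp < n_amplicons * 50L) {
    stop("infeasible partition: total_bp < 50 bp per amplicon")
  }
  set.seed(sub_seed(seed, 1L))
  genes <- if (n_genes <= length(PANEL_GENES)) {
    sort(PANEL_GENES[seq_len(n_genes)])
  } else {
    sort(c(PANEL_GENES, sprintf("GENE%03d", seq_len(n_genes - length(PANEL_GENES)))))
  }
  # assign amplicons to genes: every gene >= 1; the NPM1-like gene exactly 1
  npm1 <- if ("NPM1" %in% genes) "NPM1" else genes[1]
  others <- setdiff(genes, npm1)
  extra <- n_amplicons - n_genes
  extra_counts <- if (extra > 0) {
    tabulate(sample.int(length(others), extra, replace = TRUE),
             nbins = length(others))
  } else rep(0L, length(others))
  amp_gene <- c(npm1, rep(others, 1L + extra_counts))
  # partition total_bp into n_amplicons near-equal lengths (each >= 50 by
  # the feasibility check); the remainder goes one bp to random amplicons
  base <- total_bp %/% n_amplicons
  lens <- rep(as.integer(base), n_amplicons)
  rem <- total_bp - base * n_amplicons
  if (rem > 0) {
    bump <- sample.int(n_amplicons, rem)
    lens[bump] <- lens[bump] + 1L
  }
  stopifnot(sum(lens) == total_bp)
  # lay out consecutively on one contig with 20 bp gaps
  gap <- 20L
  starts <- 100L + cumsum(c(0L, lens[-n_amplicons] + gap))
  ends <- starts + lens
  contig <- "chrP"
  ref_len <- ends[n_amplicons] + 100L
  refseq <- paste(sample(BASES, ref_len, replace = TRUE), collapse = "")
  reference <- stats::setNames(refseq, contig)
  amp <- data.frame(gene = amp_gene, contig = contig,
                    start = starts, end = ends, stringsAsFactors = FALSE)
  # hotspots: unique (position, alt) pairs inside amplicons
  covered <- unlist(lapply(seq_len(n_amplicons),
                           function(i) seq.int(starts[i], ends[i] - 1L)))
  hs_pos <- integer(0); hs_alt <- character(0)
  while (length(hs_pos) < n_hotspots) {
    need <- n_hotspots - length(hs_pos)
    p <- sample(covered, need * 2L, replace = TRUE)
    a <- sample(BASES, need * 2L, replace = TRUE)
    ref_b <- substring(refseq, p + 1L, p + 1L)
    ok <- a != ref_b
    key <- paste(p, a)
    keep <- ok & !duplicated(key) & !key %in% paste(hs_pos, hs_alt)
    hs_pos <- c(hs_pos, p[keep]); hs_alt <- c(hs_alt, a[keep])
  }
  hs_pos <- hs_pos[seq_len(n_hotspots)]
  hs_alt <- hs_alt[seq_len(n_hotspots)]
  hotspots <- data.frame(contig = contig, position = hs_pos,
                         ref = substring(refseq, hs_pos + 1L, hs_pos + 1L),
                         alt = hs_alt, stringsAsFactors = FALSE)
  hotspots <- hotspots[order(hotspots$position, hotspots$alt), ]
  rownames(hotspots) <- NULL
  list(reference = reference, panel = new_panel(amp, hotspots))
}

# Per-position truth scaffold shared by the generators: background class,
# designated alternate allele, gene elevation factor.
truth_scaffold <- function(config) {
  pp <- panel_positions(config$panel)
  refseq <- config$reference
  pp$ref <- vapply(seq_len(nrow(pp)), function(i)
    substring(refseq[[pp$contig[i]]], pp$pos[i] + 1L, pp$pos[i] + 1L),
    character(1))
  elev <- rep(1, nrow(pp))
  for (g in names(config$gene_elevation)) {
    elev[pp$gene == g] <- config$gene_elevation[[g]]
  }
  pp$elevation <- elev
  # designated alternate allele per position; at hotspot sites use the
  # hotspot alt so spiked/clonal signal is callable
  alt_idx <- sample.int(3L, nrow(pp), replace = TRUE)
  pp$alt <- vapply(seq_len(nrow(pp)), function(i)
    setdiff(BASES, pp$ref[i])[alt_idx[i]], character(1))
  hs <- config$panel$hotspots
  if (nrow(hs) > 0) {
    first_alt <- hs[!duplicated(paste(hs$contig, hs$position)), ]
    m <- match(paste(pp$contig, pp$pos),
               paste(first_alt$contig, first_alt$position))
    pp$alt[!is.na(m)] <- first_alt$alt[m[!is.na(m)]]
  }
  pp$germline <- stats::runif(nrow(pp)) < config$germline_het_density
  pp
}

# Draw one set of true background frequencies on a scaffold. Each draw
# picks its own clonal positions, so independent draws (e.g. the cfDNA
# component not shared with the WBC) are genuinely independent.
draw_background <- function(scaffold, config, clonal_fraction = NULL) {
  n <- nrow(scaffold)
  if (is.null(clonal_fraction)) clonal_fraction <- config$clonal_fraction
  f <- stats::rexp(n, rate = 1 / (config$background_scale * scaffold$elevation))
  cl <- stats::runif(n) < clonal_fraction
  f[cl] <- stats::rexp(sum(cl), rate = 1 / config$clonal_scale)
  list(f = pmin(f, 0.05), clonal = cl)
}

# Observe allele counts at given true frequencies: depth ~ Poisson,
# signal ~ (beta-)binomial on the designated alt, miscalls spread
# uniformly over the three alternates.
observe_counts <- function(scaffold, f_true, config, depth = NULL) {
  n <- nrow(scaffold)
  if (is.null(depth)) depth <- stats::rpois(n, config$mean_depth)
  p <- f_true
  rho <- config$overdispersion
  if (rho > 0) {
    nu <- (1 - rho) / rho
    pos <- p > 0 & p < 1
    p[pos] <- stats::rbeta(sum(pos), p[pos] * nu, (1 - p[pos]) * nu)
  }
  err <- stats::rbinom(n, depth, config$base_error_rate)
  signal <- stats::rbinom(n, depth, p)
  signal <- pmin(signal, depth - err)
  e1 <- stats::rbinom(n, err, 1 / 3)
  e2 <- stats::rbinom(n, err - e1, 1 / 2)
  e3 <- err - e1 - e2
  counts <- matrix(0L, n, 4, dimnames = list(NULL, BASES))
  ri <- match(scaffold$ref, BASES)
  ai <- match(scaffold$alt, BASES)
  # remaining two alternates in base order
  oth <- t(vapply(seq_len(n), function(i)
    match(setdiff(BASES, c(scaffold$ref[i], scaffold$alt[i])), BASES),
    integer(2)))
  counts[cbind(seq_len(n), ri)] <- depth - signal - err
  counts[cbind(seq_len(n), ai)] <- signal + e1
  counts[cbind(seq_len(n), oth[, 1])] <- e2
  counts[cbind(seq_len(n), oth[, 2])] <- e3
  pileup_frame(scaffold$contig, scaffold$pos, scaffold$ref,
               counts[, "A"], counts[, "C"], counts[, "G"], counts[, "T"])
}

#' Simulate one paired WBC/cfDNA sample
#'
#' The WBC true background frequency is drawn per position from the mixture
#' law of [sim_config()]; the cfDNA true frequency is
#' `shared_weight * wbc + (1 - shared_weight) * independent draw` from the
#' same law. Germline heterozygous positions are set to 0.5 in both.
#' Observed counts are (beta-)binomial at Poisson-distributed depth.
#'
#' @param config A `sim_config`.
#' @param pair_index Index of the pair within the cohort (determines the
#'   pair's sub-seed).
#' @return List with `wbc` and `cfdna` `sample_profile`s and `truth`
#'   (data.frame of true frequencies and flags per position).
#' @export
simulate_pair <- function(config, pair_index = 1L) {
  set.seed(sub_seed(config$seed, 100000L + pair_index))
  sc <- truth_scaffold(config)
  wbc <- draw_background(sc, config)
  indep <- draw_background(sc, config)
  wbc_f <- wbc$f
  cf_f <- config$shared_weight * wbc_f + (1 - config$shared_weight) * indep$f
  wbc_f[sc$germline] <- 0.5
  cf_f[sc$germline] <- 0.5
  truth <- data.frame(sc[, c("contig", "pos", "gene", "ref", "alt")],
                      wbc_f = wbc_f, cf_f = cf_f,
                      germline = sc$germline, clonal = wbc$clonal,
                      stringsAsFactors = FALSE)
  wbc <- profile_from_pileup(observe_counts(sc, wbc_f, config),
                             sprintf("pair%03d_wbc", pair_index), "WBC")
  cfdna <- profile_from_pileup(observe_counts(sc, cf_f, config),
                               sprintf("pair%03d_cf", pair_index), "cfDNA")
  list(wbc = wbc, cfdna = cfdna, truth = truth)
}

#' Simulate a synthetic cohort of pairs
#'
#' @param config A `sim_config`; `config$n_pairs` pairs are generated.
#' @return List of pair lists (see [simulate_pair()]).
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_pairs), function(i) simulate_pair(config, i))
}

#' Simulate two technical replicates of one sample
#'
#' One truth draw, two independent count draws — the split-sample design
#' used to separate biological signal from PCR/sequencing noise.
#'
#' @param config A `sim_config`.
#' @param material `"WBC"` or `"cfDNA"`.
#' @param replicate_seed Sub-seed offset so several replicate pairs can be
#'   drawn from one config.
#' @return List with `rep1`, `rep2` (`sample_profile`s) and `truth`.
#' @export
simulate_replicates <- function(config, material = "WBC",
                                replicate_seed = 1L) {
  material <- match.arg(material, c("WBC", "cfDNA", "tumor"))
  set.seed(sub_seed(config$seed, 200000L + replicate_seed +
                      50000L * (match(material, c("WBC", "cfDNA", "tumor")) - 1L)))
  sc <- truth_scaffold(config)
  bg <- draw_background(sc, config)
  f <- bg$f
  f[sc$germline] <- 0.5
  truth <- data.frame(sc[, c("contig", "pos", "gene", "ref", "alt")],
                      f = f, germline = sc$germline, clonal = bg$clonal,
                      stringsAsFactors = FALSE)
  rep1 <- profile_from_pileup(observe_counts(sc, f, config),
                              paste0(material, "_rep1"), material)
  rep2 <- profile_from_pileup(observe_counts(sc, f, config),
                              paste0(material, "_rep2"), material)
  list(rep1 = rep1, rep2 = rep2, truth = truth)
}

#' Simulate a tumor trio (WBC, cfDNA, two tumor sections)
#'
#' Emulates the paired-sample design used to trace tumor mutations into
#' plasma: two sections of one solid tumor share `n_truncal` truncal
#' variants and carry `n_private_per_section` private variants each, all at
#' hotspot sites; `n_cf_detectable` of the truncal variants leak into the
#' cfDNA at `cf_leak_af`. The cfDNA otherwise mirrors the WBC background
#' exactly (blood-derived background plus tumor spikes); the WBC carries
#' only background.
#'
#' The trio background uses the bulk exponential law only (the clonal
#' heavy-tail component is off): hotspot calling at the 1% threshold is
#' then separated from the background (mean 2e-4) by construction, so
#' truth-table comparisons of called/shared/subtracted mutations are exact
#' rather than knife-edge. Germline heterozygous sites are constitutional
#' and appear at 0.5 in all four samples; like the real study's calls,
#' section and cfDNA call sets are meant to be filtered against the WBC
#' profile, which removes them.
#'
#' @param config A `sim_config`.
#' @param n_truncal Truncal variants shared by both sections.
#' @param n_private_per_section Private variants per section.
#' @param n_cf_detectable Truncal variants leaking into cfDNA.
#' @param tumor_af True AF of tumor variants in the sections.
#' @param cf_leak_af True AF of the leaked variants in cfDNA.
#' @return List with `wbc`, `cfdna`, `tumor1`, `tumor2` profiles and
#'   `truth` (per-variant table with origin flags).
#' @export
simulate_trio <- function(config, n_truncal = 6L, n_private_per_section = 5L,
                          n_cf_detectable = 3L, tumor_af = 0.1,
                          cf_leak_af = 0.02) {
  hs <- config$panel$hotspots
  n_need <- n_truncal + 2L * n_private_per_section
  if (n_need > nrow(hs)) stop("requested variant counts exceed hotspot set")
  if (n_cf_detectable > n_truncal) {
    stop("n_cf_detectable cannot exceed n_truncal")
  }
  set.seed(sub_seed(config$seed, 300000L))
  sc <- truth_scaffold(config)
  # pick distinct hotspot sites (one alt per site) for the tumor variants
  hs1 <- hs[!duplicated(paste(hs$contig, hs$position)), , drop = FALSE]
  pick <- hs1[sample.int(nrow(hs1), n_need), , drop = FALSE]
  grp <- rep(c("truncal", "private1", "private2"),
             c(n_truncal, n_private_per_section, n_private_per_section))
  # tumor variant sites use the hotspot alt as designated alt
  m <- match(paste(pick$contig, pick$position), paste(sc$contig, sc$pos))
  stopifnot(!anyNA(m))
  sc$alt[m] <- pick$alt
  bg <- draw_background(sc, config, clonal_fraction = 0)$f  # bulk only; see Details
  bg[sc$germline] <- 0.5
  wbc_f <- bg
  cf_f <- bg
  t1_f <- bg
  t2_f <- bg
  idx_truncal <- m[grp == "truncal"]
  idx_p1 <- m[grp == "private1"]
  idx_p2 <- m[grp == "private2"]
  t1_f[c(idx_truncal, idx_p1)] <- tumor_af
  t2_f[c(idx_truncal, idx_p2)] <- tumor_af
  idx_leak <- idx_truncal[seq_len(n_cf_detectable)]
  cf_f[idx_leak] <- cf_f[idx_leak] + cf_leak_af
  truth <- data.frame(contig = pick$contig, pos = pick$position,
                      ref = pick$ref, alt = pick$alt, group = grp,
                      cf_detectable = seq_len(n_need) %in%
                        which(grp == "truncal")[seq_len(n_cf_detectable)],
                      stringsAsFactors = FALSE)
  mk <- function(f, id, material)
    profile_from_pileup(observe_counts(sc, f, config), id, material)
  list(wbc = mk(wbc_f, "trio_wbc", "WBC"),
       cfdna = mk(cf_f, "trio_cf", "cfDNA"),
       tumor1 = mk(t1_f, "trio_t1", "tumor"),
       tumor2 = mk(t2_f, "trio_t2", "tumor"),
       truth = truth)
}

#' Simulate a spike-in dilution series
#'
#' For every (variant, level, replicate) cell, draws a pileup column at the
#' design depth with the variant at its nominal AF plus sequencing error;
#' background alternates carry error only. Each cell is scored with
#' [detect_variant()].
#'
#' @param design A [dilution_design()].
#' @param config A `sim_config` (supplies error rate and seed).
#' @param alpha Significance level for detection.
#' @param min_alt Alternate count floor for detection.
#' @return List with `observations` (one row per cell: counts, observed
#'   VAF, p-value, detected flag) and `design`.
#' @export
simulate_spikein_series <- function(design, config, alpha = 0.05,
                                    min_alt = 3L) {
  set.seed(sub_seed(config$seed, 400000L))
  v <- design$variants
  grid <- expand.grid(vi = seq_len(nrow(v)), level = design$levels,
                      replicate = seq_len(design$replicates),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  depth <- stats::rpois(n, design$depth)
  err3 <- config$base_error_rate / 3
  alt_count <- stats::rbinom(n, depth, grid$level + err3)
  obs <- data.frame(
    variant = v$name[grid$vi], level = grid$level,
    replicate = grid$replicate,
    contig = v$contig[grid$vi], pos = v$position[grid$vi],
    ref = v$ref[grid$vi], alt = v$alt[grid$vi],
    depth = depth, alt_count = alt_count,
    observed_vaf = alt_count / depth, stringsAsFactors = FALSE)
  scored <- lapply(seq_len(n), function(i) {
    col <- stats::setNames(as.list(rep(0, 4)), BASES)
    col$ref <- obs$ref[i]
    col[[obs$ref[i]]] <- obs$depth[i] - obs$alt_count[i]
    col[[obs$alt[i]]] <- obs$alt_count[i]
    col$depth <- obs$depth[i]
    detect_variant(col, obs$alt[i], config$base_error_rate, alpha, min_alt)
  })
  obs$p_value <- vapply(scored, `[[`, numeric(1), "p_value")
  obs$detected <- vapply(scored, `[[`, logical(1), "detected")
  list(observations = obs, design = design)
}

#' Default spike-in variants on a replica panel
#'
#' Picks six hotspot sites to stand in for the reference-standard variants
#' EGFR L858R, EGFR T790M, KRAS G12D, NRAS Q61K, NRAS A59T, PIK3CA E545K:
#' two from the EGFR-like gene, one from KRAS-like, two from NRAS-like, one
#' from PIK3CA-like (deterministic: the first hotspots inside each gene's
#' amplicons).
#'
#' @param panel A replica `panel_def` containing genes EGFR, KRAS, NRAS,
#'   PIK3CA.
#' @return data.frame `contig position ref alt name`.
#' @export
spikein_variants <- function(panel) {
  want <- c(EGFR = 2L, KRAS = 1L, NRAS = 2L, PIK3CA = 1L)
  labels <- c("EGFR_L858R", "EGFR_T790M", "KRAS_G12D", "NRAS_Q61K",
              "NRAS_A59T", "PIK3CA_E545K")
  rows <- list()
  for (g in names(want)) {
    amp <- panel$amplicons[panel$amplicons$gene == g, , drop = FALSE]
    if (nrow(amp) == 0) stop("panel lacks gene ", g)
    inside <- rep(FALSE, nrow(panel$hotspots))
    for (i in seq_len(nrow(amp))) {
      inside <- inside | (panel$hotspots$contig == amp$contig[i] &
                            panel$hotspots$position >= amp$start[i] &
                            panel$hotspots$position < amp$end[i])
    }
    hs <- panel$hotspots[inside, , drop = FALSE]
    hs <- hs[!duplicated(hs$position), , drop = FALSE]
    if (nrow(hs) < want[[g]]) stop("too few hotspots in gene ", g)
    rows[[g]] <- hs[seq_len(want[[g]]), , drop = FALSE]
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$name <- labels[c(1, 2, 3, 4, 5, 6)]
  out
}

#' Simulate aligned reads over a panel
#'
#' Small-scale read-level generator feeding the read-filter tests and SAM
#' round-trips: reads start uniformly within amplicons, carry miscalls at
#' `error_rate` (uniform over the other three bases), Phred qualities from
#' a clipped normal quality model, and a configurable admixture of
#' high-mismatch reads (emulating mis-mapped or chimeric reads the per-read
#' mutant-fraction filter exists to remove) and duplicate-flagged reads.
#'
#' @param config A `sim_config`.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (clipped at amplicon/contig ends).
#' @param mutant_read_rate Fraction of reads given ~10% mismatches.
#' @param duplicate_rate Fraction of reads flagged as duplicates.
#' @param seed_offset Sub-seed offset.
#' @return List of `aligned_read` objects.
#' @export
simulate_reads <- function(config, n_reads = 200L, read_length = 160L,
                           mutant_read_rate = 0.02, duplicate_rate = 0,
                           seed_offset = 1L) {
  set.seed(sub_seed(config$seed, 500000L + seed_offset))
  amp <- config$panel$amplicons
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    a <- sample.int(nrow(amp), 1L)
    contig <- amp$contig[a]
    refseq <- config$reference[[contig]]
    start <- sample(seq.int(amp$start[a], amp$end[a] - 1L), 1L)
    len <- min(read_length, nchar(refseq) - start)
    rpos <- seq.int(start, start + len - 1L)
    rbase <- strsplit(substring(refseq, start + 1L, start + len), "")[[1]]
    qbase <- rbase
    err_rate <- if (stats::runif(1) < mutant_read_rate) 0.1
                else config$base_error_rate
    flip <- which(stats::runif(len) < err_rate)
    for (j in flip) qbase[j] <- sample(setdiff(BASES, rbase[j]), 1L)
    qual <- as.integer(pmax(2, pmin(40, round(
      stats::rnorm(len, config$quality_mean, config$quality_sd)))))
    reads[[i]] <- aligned_read(
      sprintf("simread%05d", i), contig,
      data.frame(qbase = qbase, qual = qual, rpos = rpos, rbase = rbase,
                 stringsAsFactors = FALSE),
      duplicate = stats::runif(1) < duplicate_rate)
  }
  reads
}
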