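---
title: "Profiling the blood-cell somatic background in cfDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling the blood-cell somatic background in cfDNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model

In healthy plasma, the large majority of cell-free DNA is shed by blood
cells. At ultra-deep targeted depth (tens of thousands of reads per
position) every position shows a nonzero mutant allele fraction, composed
of sequencing/PCR error, clonal hematopoiesis, germline heterozygosity,
and — in cancer patients — a small tumor-derived admixture. This package
treats the separation of those components as a sequence of small, exactly
specified statistical operations, each testable against an independent
oracle, rather than as one opaque caller.

The quantities of interest are:

* per-position **total mutant allele frequency** (MAF): the fraction of
  retained bases differing from the reference,
  $F_i = (\text{depth}_i - \text{ref}_i)/\text{depth}_i$, with per-allele
  fractions kept alongside for hotspot work;
* per-gene frequency $F_A = (F_1 + \dots + F_n)/n$, the mean over the
  gene's amplicon positions with $n$ the gene's designed amplicon length;
* paired least-squares regressions (cfDNA on WBC; replicate 2 on
  replicate 1), summarized by Pearson $r$ and adjusted
  $R^2 = 1-(1-R^2)(n-1)/(n-2)$ (one predictor);
* an exact one-sided binomial detection test for low-frequency variants
  against an error-only null.

## Filters and their boundaries

Three filters precede every statistic, with thresholds read as strict
inequalities exactly as worded, so the boundary cases are retained:

| filter | rule | boundary |
|---|---|---|
| per-read | discard the whole read if its mismatch fraction over aligned bases is > 0.05 | 0.05 kept |
| per-base | mask bases with Phred quality < 30 | Q30 kept |
| per-locus | remove positions with retained depth < 10000× | 10000× kept |

The per-read fraction is computed on *all* aligned (non-clipped,
non-indel) bases before quality masking: being mutant-rich is a property
of the read, not of its surviving bases, and the filter exists to remove
mis-mapped or chimeric reads whose high-quality mismatches would otherwise
survive masking. Bases paired to an ambiguous reference (N) are excluded
from numerator and denominator everywhere. Insertions and deletions carry
no aligned pair and are invisible to all MAF computations — the analysis
is SNV-only by design, and the worked MAF arithmetic only makes sense for
substitutions. Overlapping mate pairs are counted as two observations (no
overlap-consensus rule is applied). Duplicate-flagged reads are skipped by
default (`keep_duplicates` reverses this); the pipeline takes no stance on
upstream deduplication beyond honoring the flag.

Positions with MAF > 0.1 are removed before background analysis: at
ultra-deep depth the only plausible sources of a >10% allele are germline
heterozygosity (~50%) or homozygous differences (~100%), neither of which
is somatic background. The cap is applied per sample, before any cohort
averaging (a flag could defer it, but per-sample application is the
default because the cap's target — constitutional variation — is a
per-individual property).

## Gene-level frequency

$F_A$ divides by the gene's *designed* amplicon length, not by the number
of covered positions: a position filtered out for poor depth contributes
zero signal but still counts in $n$. This matches the definition of the
statistic as "mean per-nucleotide mutant frequency of the designed
region" and keeps $F_A$ comparable across samples with different
coverage; `covered_only = TRUE` gives the alternative normalization. Ties
in the ranking break lexicographically so results are deterministic.

## Paired correlation

Inclusion thresholds (depth > 10000× and MAF > 0.003, i.e. 0.3%) are
applied in *both* members of a pair; a position failing in either member
is dropped from that pair. The cohort-level analysis first averages each
position's MAF over the pairs in which it passes, then regresses the
cfDNA means on the WBC means; the within-individual analysis regresses
raw positions of one pair. Slope and intercept are reported for the
y-on-x direction; $r$ is symmetric. One wording in the source protocol
says such positions were "excluded" where the figure legends say
"included"; the legends are followed (include MAF > 0.003), since a
correlation study over only sub-0.3% positions would correlate pure
counting noise.

## Hotspot calling and WBC subtraction

Calls are per alternate allele at pre-specified (position, ref, alt)
sites: per-allele VAF > 1% and site depth > 5000×, both strict. The depth
rule is applied as the site's own retained depth in the sample (the
alternative reading — panel-average depth — would let a poorly covered
site be called on the strength of its neighbors). Background subtraction
removes a cfDNA or tumor call when the same alternate exceeds
`wbc_max_vaf` (default 1%) in the paired WBC sample; the protocol this
models states WBC filtering without a numeric rule, so the default mirrors
the calling threshold and is configurable. Sites the WBC profile does not
cover cannot be checked and are retained with a `wbc_uncovered` flag
rather than silently trusted or dropped.

## Detection test and limit of detection

A variant at a site is detected when the alternate count $k$ at depth $D$
is improbable under the error-only null $X \sim \mathrm{Bin}(D, e/3)$
(one-sided exact tail, $\alpha = 0.05$) *and* $k \ge 3$. The $e/3$ null
splits the total per-base miscall rate $e$ uniformly over the three
alternates — a documented simplification; real miscall spectra are
skewed. The ≥3-read floor prevents "detections" carried by one or two
error reads at extreme depth. With $e = 0$ the tail p-value degenerates
to 0 for any $k>0$ and the floor alone decides.

The limit of detection is the smallest true fraction $f$ (on a $10^{-5}$
grid) whose detection probability reaches the requested power (default
0.95) under that rule; the rule reduces to a critical count
$k^* = \max(k_\alpha, 3)$, so the LOD is a binomial CDF scan. At 30000×
and $e = 10^{-4}$ the LOD is 0.00026 — comfortably below the 0.001
dilution level, which is why the simulated series detects 0.001 in
essentially every replicate while per-replicate *quantification* at that
level still scatters by tens of percent (expected counts of ~30).

## The synthetic-data generator

The generator emulates the study conditions end to end and is itself
first-class, tested code. Defaults are the study's stated conditions:
mean depth 40000× (Poisson per position), per-base error $10^{-4}$,
cfDNA inheriting 90% of its true frequency from the paired WBC background
(`shared_weight = 0.9`), a 50-gene/207-amplicon/22027-bp panel with 2800
hotspot sites, one NPM1-like gene elevated tenfold, spike-in series at
0.0005/0.001/0.005/0.01 with five replicates at 30000×.

Where a value had to be chosen, it was chosen once, on realism grounds:

* **Background law.** The bulk of positions draw their true somatic
  frequency from an exponential with mean `background_scale` = 2×10⁻⁴
  (heavy mass near zero, occasional larger clones). A pure exponential at
  that scale, however, leaves the 0.3%–10% window — exactly the window
  the correlation analyses select on — essentially empty
  ($P(f > 0.003) = e^{-15}$), which contradicts what paired-cohort
  scatter plots actually show: a populated cloud of positions between
  0.3% and a few percent. Real panels have that cloud because clonal
  hematopoiesis and recurrent error-prone sites are heavy-tailed. The
  generator therefore adds a mixture component: each draw marks a
  fraction `clonal_fraction` = 0.05 of positions as carrying a larger
  clone drawn from an exponential with mean `clonal_scale` = 0.01. All
  true frequencies are capped at 0.05 (anything larger is not plausibly
  somatic background and would be near the 0.1 cap's territory). Each
  background draw picks its own clonal positions, so draws that must be
  independent (a `shared_weight = 0` cfDNA) really are.
* **Gene elevation** multiplies the bulk component only: the NPM1-like
  elevation models a gene-specific mutational propensity of blood cells,
  while the clonal mixture is panel-wide.
* **Germline heterozygote density** is 0.002 (~44 sites on 22 kb) — a
  plausible count of common SNPs inside a small cancer panel; the exact
  value only needs to exercise the 0.1 cap, which removes them.
* **Counts** are binomial at the drawn truth (optionally beta-binomial
  via `overdispersion`, the rho of the usual mean/rho parameterization,
  default 0). The error channel adds miscalls at rate $e$ split
  uniformly over the three alternates. Signal lands on one designated
  alternate per position (the hotspot alternate at hotspot sites), which
  is what per-allele calling needs.
* **Reads**, when emitted (`simulate_reads`), are fixed-length 160 bp
  single-end — the modal cfDNA fragment size — with clipped-normal Phred
  qualities (mean 35, sd 4) and an admixture of high-mismatch reads to
  exercise the per-read filter. Large cohorts are generated at the
  count/pileup level: a 40000× × 22 kb sample would be ~5.5 million
  reads, and nothing downstream of the pileup distinguishes the two
  routes by construction.
* **Tumor trios** use the bulk background only (no clonal mixture).
  The trio questions — how many calls are shared between tumor sections,
  which cfDNA calls survive WBC subtraction — are set-exact questions,
  and the calling and subtraction thresholds coincide at 1%, so
  clonal-hematopoiesis sites near 1% would sit on a knife edge where the
  answer depends on sampling noise rather than design. With the bulk law
  (mean 2×10⁻⁴) the background cannot reach the calling threshold and
  truth-table comparisons are exact. Both tumor-section and cfDNA call
  sets are WBC-filtered before sharing/counting, matching the protocol
  this scenario models (all reported mutations were WBC-filtered); this
  also removes germline heterozygous hotspot sites, which appear at 0.5
  in every sample of the individual.

What passing tests on this generator do **not** show: the generator's
binomial noise understates real PCR jackpot/overdispersion (the
`overdispersion` knob emulates, but is not calibrated to, the
super-binomial scatter real dilution series show at 0.001); amplicon
depth is homogeneous by default; miscall spectra are uniform; there are
no strand biases, UMI families, or indels. Headline cohort statistics
from the real study (adjusted R² of 0.92 over 309 pairs, NPM1 mean MAF
0.12%) depend on the real data's background composition and are not
reproduced numerically — the synthetic cohort reproduces the *regimes*
(high paired correlation that collapses without sharing; an elevated gene
ranking first; detection at 0.001).

## Numerical and coordinate conventions

Internal coordinates are 0-based half-open; the mpileup text dialect
(1-based) converts only at the I/O boundary, and the conversion is a
bijection. Overlapping amplicons of one gene merge at load time so the
covered length is well defined. Pileup base strings encode
reference-matching bases as `.` and alternates as their uppercase base;
reading accepts the general samtools dialect (case, `^`/`$` markers,
indel runs) and counts at C speed via vectorized fixed-pattern deletion,
since ultra-deep base strings run to tens of kilobytes per line.
Replica-panel amplicon lengths partition the covered total near-equally
(each ≥ 50 bp); hotspot sites are unique per (position, alternate) and
always consistent with the reference base. All generators are pure
functions of (config, seed); sub-seeds are derived per operation and per
pair/replicate index and kept within 32-bit range.

## Problem sizes used in the shipped analyses

The analysis scripts and the acceptance checks run: a 20-pair cohort at
full panel width (22027 positions) and 40000× — about one second per
simulated sample; 100 random read-filter instances of ≤ 250 reads against
a naive double-loop oracle; a 6-variant × 4-level × 5-replicate dilution
series at 30000×; 1000 error-only columns for the type-I rate; and a
16-variant trio at 200000×/zero error, where exactness is the point.
These sizes make every headline behavior measurable with comfortable
statistical margins while keeping a full run in minutes on one CPU.

## Known limitations

SNV-only; single-contig replica coordinates rather than hg19 (the real
primer set is not public); no confidence intervals on correlation
statistics (none are used downstream); WBC subtraction is a threshold
rule, not a likelihood test of cfDNA-vs-WBC allele fractions; the
run-level pipeline consumes pileups, with SAM/BAM supported at the
reading/filtering layer.
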