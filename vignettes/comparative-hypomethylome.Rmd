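---
title: "Comparative hypomethylome analysis of a transplanted chromosome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative hypomethylome analysis of a transplanted chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transhmr)
library(dplyr)
```

## The question and the measurement

DNA methylation is absent from discrete hypomethylated regions (HMRs) --
mostly CpG islands (CGIs) at promoters, plus distal regulatory elements. When
the *same* DNA sequence resides in two different host nuclear environments
(a transchromosomic animal carrying a foreign chromosome, or a BAC
transplanted across species), comparing where HMRs form separates what the
DNA sequence itself encodes from what depends on host trans-acting factors.

The raw measurement is BioCAP sequencing: a ZF-CxxC domain captures DNA
fragments containing *non-methylated* CpGs, so sequencing coverage is high
exactly where CpG-dense, unmethylated DNA lies. `transhmr` implements the
full comparative analysis of such data -- and, because the original
experiments required animal sequencing data, it ships a synthetic
composite-genome generator that reproduces the study design with planted
ground truth, making every stage testable end to end.

## The synthetic study design

`sim_config()` fixes the simulated conditions; `simulate_composite_genome()`
builds one transplanted 2 Mb contig (`chrT`) plus a background host contig
and two synthetic 10 kb spike-in contigs for bisulfite-conversion QC. Three
element classes are planted, mirroring the three mechanistic classes the
comparative design distinguishes:

* **60 shared CGIs** (1--2 kb, 0.10 CpG/bp, GC-rich): hypomethylated in both
  host contexts -- the sequence-encoded default state.
* **Young CpG-rich repeats** (800 bp, 0.12 CpG/bp; 10 per context): CpG
  density *above* the CGI level, as in recently expanded repeat families
  whose CpGs have not yet decayed. Each is hypomethylated only in the host
  context that lacks a co-evolved repeat-defence pathway, i.e. planted
  *mechanistically* as species-specific. Their annotated divergence
  (milliDiv ~ U(0, 50)) marks them young; old repeats (milliDiv
  ~ U(150, 300)) are annotated at the centres of a subset of shared CGIs so
  the shared class also yields summit-in-repeat age samples.
* **TF-protected elements** (600 bp, 0.04 CpG/bp -- intermediate, GC-poorer;
  10 per context): hypomethylated only where a transcription factor (CEBPA,
  HNF4A or CTCF in the annotation) is bound, emulating occupancy-dependent
  protection of distal regulatory DNA. The TF peak annotation is
  context-specific at exactly these elements and shared elsewhere.

Per-CpG methylation probabilities are drawn independently per host context:
Beta(17, 3) (mean 0.85, concentrated) outside hypomethylated elements and
Beta(0.025, 0.475) (mean 0.05, strongly bimodal) inside them. The bimodal
inside-element distribution reflects how per-CpG methylation behaves in real
tissue -- most CpGs of an HMR are essentially unmethylated while a small
fraction retain methylation -- and it is the regime in which per-CpG
bisulfite estimates at moderate depth can be expected to fall within a few
percentage points of truth (see *Numerical choices*). A concentrated
background is equally deliberate: a bimodal background would scatter fully
unmethylated CpG clusters through background sequence, which are genuine
micro-HMRs and would be called as unplanned peaks.

BioCAP capture is modelled at the fragment level. Fragment lengths are
Normal(200, 50) truncated at 50 bp and discretised to 10 bp; a fragment is
sampled with weight proportional to its expected number of unmethylated
CpGs, $\sum_i (1 - m_i)$ over covered CpGs, plus a small non-specific
carry-over (0.05 per fragment). The linear capture weight is a modelling
choice -- capture chemistry is not quantitatively characterised -- but it
preserves the property every downstream inference relies on: expected
coverage increases monotonically with unmethylated CpG content. Alignment
is bypassed entirely (the pipeline consumes coverage), fragment sampling is
seed-deterministic, and an input control samples fragments uniformly.

At the defaults (30x depth), desk arithmetic fixes the expected signal:
roughly three quarters of fragments land in the ~5% of the contig occupied
by planted elements, giving ~8x background coverage, ~430x at CGIs, ~520x at
young repeats and ~170x at TF elements, with residual capture at elements
methylated in the assayed context (~80x at the other context's repeats).
Window counts at every planted element exceed the Poisson significance
threshold against the input-derived local rate by an order of magnitude,
while background stays far below it.

### What the generator does *not* emulate

Sequencing errors, PCR duplicates, mappability structure, alignment
artifacts, diploid genotypes, copy-number noise, and spatial correlation of
methylation beyond element boundaries. Passing tests therefore demonstrate
that the analysis recovers the *designed* signal under fragment-sampling
noise -- not that it is robust to alignment or library artifacts real data
would add.

## HMR detection

`call_peaks()` is a self-contained Poisson local-background caller in the
MACS tradition, operating on fragment coverage:

1. Every `bandwidth` (300 bp) window is converted to a fragment count:
   coverage sum divided by `fragment_length` (200 bp).
2. Windows with count at least `mfold_low` (10) times the genome-background
   rate `total_reads * bandwidth / effective_genome_size` seed candidates.
   With the default effective genome size (4.8e8 bp, matching composite-
   genome analyses where the track's contig is a small fraction of the
   mapped genome) this gate is permissive, and specificity comes from the
   input control -- the same division of labour as running MACS with an
   input. `mfold_high` is retained for interface completeness; an upper
   bound only matters for tag-shift model building, which fragment-level
   coverage does not need.
3. Each window is scored with the upper Poisson tail
   $P(X \ge \mathrm{obs})$ against
   $\lambda_{local} = \max(\lambda_{BG}, \lambda_{1k}, \lambda_{5k},
   \lambda_{10k})$, the control rates measured in windows centred on the
   scoring window, scaled by the treatment/control depth ratio. Tail
   probabilities are computed and compared in log space; no multiple-testing
   correction is applied (fixed p <= 1e-5, as such callers are
   conventionally run).
4. Significant windows are merged when closer than `merge_gap` (100 bp);
   each peak reports its minimum window p-value and its summit, the
   *leftmost* maximum of treatment coverage (a deterministic tie-break).

Windows are scored individually *before* merging. Merging candidate windows
first and scoring merged candidates would degenerate when the mfold gate is
permissive (the whole contig would fuse into one candidate), whereas
score-then-merge behaves identically in both regimes and agrees with an
exhaustive every-window reference implementation, which the test suite
checks on constructed and simulated tracks.

Replicate handling and host-genome corrections follow the comparative
design: `intersect_replicates()` keeps only peaks reproduced (>= 1 bp) in
both biological replicates, and `apply_rearrangement_map()` drops HMRs over
breakpoints or deleted intervals and divides read counts by copy number in
duplicated regions.

## Differential classification

`merge_union()` merges the two contexts' HMR sets into maximal union
intervals -- the unit of classification, so partially overlapping peaks are
not double counted. `classify_hmrs()` estimates fragment counts per union
interval from each context's coverage (coverage sum / fragment length),
normalises for depth, and applies the fold rule: a greater-than-2-fold
difference in normalised counts labels the HMR specific to the context with
more BioCAP signal; otherwise it is shared.

One numerical subtlety: a pseudocount (default 1) prevents infinite folds,
but a pseudocount added after scaling context B onto context A's depth makes
the labels depend on which context is called "A" when depths differ. The
fold is therefore computed on counts scaled to the *geometric mean* of the
two depths, which makes swapping the contexts mirror the labels exactly; the
reported `n_a`/`n_b_normalized` columns keep the conventional B-onto-A
scaling. Raw overlapping-fragment counts (not length-normalised) feed the
ratio.

`tissue_specificity()` reports, per label and tissue, the fraction of
species-specific HMRs with no same-label overlap in any other tissue, and
`replicate_r2()` is the squared Pearson correlation used for replicate
agreement.

## Feature profiling and repeat age

`cpg_density()` reports CpGs per 100 bp -- the unit is stated explicitly
because "CpG density" is often plotted unitless; `gc_content()` is the
(G+C)/(A+C+G+T) fraction. Both are case-insensitive and skip non-ACGT
letters. `shifted_background()` builds the matched control by uniformly
re-placing each interval (same length, same contig) with rejection sampling
(10,000 tries per interval) against an exclusion set, preserving the
interval-length multiset exactly.

Repeat age = (milliDiv / 1000) / mutation rate, with the mammalian
2.2e-9 substitutions/site/year default; milliDiv 220 is 100 My.
`summit_repeat_ages()` queries the single summit base against the repeat
annotation (an any-overlap mode is available) and compares label groups with
a two-sided Mann--Whitney U test -- exact for group sizes up to 20 without
ties, normal approximation otherwise, matching figure-legend statistics at
desk scale.

A known limitation, relevant to interpreting feature distributions: called
peak boundaries extend roughly one fragment length beyond a planted element
on each side, so density measured over called coordinates dilutes short
elements more than long ones. Directionality checks of sequence features in
the test suite are therefore made on planted element footprints carrying the
pipeline-assigned labels.

## Annotation and signal matrices

`classify_tss_proximity()` partitions HMRs by any-overlap with TSS +/- 500 bp
windows, inclusive of both endpoints (a 1001-position footprint), strand
ignored. `species_specific_peaks()` intersects TF peaks across contexts
*within each factor* -- a CEBPA peak is never matched by an HNF4A peak.
`multiway_overlap_summary()` produces the up-to-4-way Venn pattern counts
and the headline percentage of targets overlapping at least one feature set,
rounded half-up to an integer as such percentages are conventionally
reported. `aggregate_matrix()` builds the centre-aligned, length-ranked
(descending, ties by start) heatmap matrix with NA padding at contig edges;
`fold_change_by_location()` compares fold changes at vs away from TSSs by
Welch's t test on log2 folds (degenerate zero-variance-in-both-groups input
is an error, not a silent 0/0).

## Bisulfite validation

`simulate_bisulfite_counts()` draws methylated read counts
Binomial(depth, $m_i + (1-m_i)(1-c)$) per CpG at conversion rate $c$, and
emits two spike-in call sets from synthetic control contigs generated with
$m = 0$ and $m = 1$ -- the in-silico counterpart of unmethylated/methylated
control DNA spiked into conversion reactions. `conversion_efficiency()`
pools the unmethylated spike-in for the conversion estimate (QC threshold
0.98, a conventional bound) and the methylated spike-in as an
over-conversion proxy. `methylation_percent()`, `summarize_amplicons()` and
`average_replicates()` provide the per-CpG and per-amplicon summaries; CpG
dyads are always keyed by the forward-strand C.

## Numerical choices

* All coordinates are 0-based half-open (BED convention) everywhere
  internally; a single convention removes off-by-one drift.
* Poisson tails via `ppois(lower.tail = FALSE, log.p = TRUE)`; the test
  suite checks agreement with brute-force pmf summation to 1e-12 relative
  error.
* Window counts are rounded to integers before the Poisson test; the
  exhaustive-oracle comparison uses the same rounding.
* Per-CpG recovery arithmetic: at depth $d$, the binomial standard error
  of a percentage is $100\sqrt{p(1-p)/d}$; estimates fall within +/-5 points
  of truth for ~95% of CpGs only when $p$ is within ~0.03 of 0 or 1 at
  d = 50--100. This is what motivates the bimodal inside-element methylome;
  at the default bisulfite depth (100) the expected fraction within 5 points
  over hypomethylated amplicons is ~0.97.
* Rejection sampling in `shifted_background()` errors after 10,000 failed
  tries, naming the interval, rather than degrading silently.
* Fragment lengths are discretised to 10 bp so each distinct length's start
  distribution is sampled exactly against its own weight profile.
* Problem sizes in the test suite: module tests run on a 200 kb contig with
  10 planted elements; recovery, replicate-agreement and directionality
  checks run on the full default design (2 Mb, 100 elements, 30x, two
  contexts, duplicate replicates). These sizes give per-element counts in
  the hundreds-to-thousands, where the design's expected contrasts dominate
  sampling noise.

## A worked run

```{r pipeline, eval = FALSE}
run <- run_pipeline(sim_config(seed = 1), outdir = "hmr_run")
glance(run)
#> # A tibble: 1 x 7
#>   n_hmrs_a n_hmrs_b n_union fraction_shared fraction_a_recapitulated_in_b
#>      <int>    <int>   <int>           <dbl>                         <dbl>
#> 1       90       90     100            0.6                          0.889
#> # i 2 more variables: fraction_b_recapitulated_in_a <dbl>,
#> #   bisulfite_conversion <dbl>
```

Ninety HMRs per context (60 shared CGIs, the context's own 20 specific
elements, and residual capture at the other context's 10 CpG-rich repeats),
100 union intervals, and ~89% of context-A HMRs recapitulated in context B
-- the simulated analogue of the high cross-context recapitulation the
comparative design is built to quantify. The classified scatter, heatmap
matrices and feature distributions are available through `autoplot()` and
`plot_*()` helpers on the returned objects.

## Reproducing the headline number

`scripts/acceptance.R` regenerates the default simulation from a seed,
simulates two independent BioCAP replicates at 30x, counts fragments over
every planted element, and writes the squared Pearson correlation between
the replicate count vectors as JSON -- the replicate-agreement statistic
summarising that independent capture experiments measure the same
hypomethylome.
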