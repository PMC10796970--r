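---
title: "Detecting isoform switching with transcript compatibility counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting isoform switching with transcript compatibility counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tccsplice)
```

## The problem

SR-family splicing factors autoregulate through unproductive splicing: a
"poison" cassette inside an intron carries a premature termination codon, and
isoforms that retain it are routed to nonsense-mediated decay instead of
producing protein. A regulator that shifts splicing from the productive to
the poison-containing isoforms can therefore change a cell's protein output
while leaving the gene's *total* mRNA almost unchanged — the signature that
motivates this package: a gene-level differential expression test sees
nothing, while an isoform-aware test sees a dramatic switch.

`tccsplice` implements an alignment-free pipeline for this signature in both
bulk and single-cell RNA-seq, together with a fully ground-truthed synthetic
data generator used to validate every statistical claim the pipeline makes.
The analysis unit throughout is the *equivalence class* (EC): the set of
transcripts compatible with a read under pseudoalignment, defined by
intersecting the transcript sets of the read's k-mers. The count of reads
(or deduplicated molecules) per EC per sample/cell is the *transcript
compatibility count* (TCC).

## The synthetic transcriptome

`make_toy_transcriptome()` builds a deterministic single-chromosome genome.
Its centrepiece is an SR-family-like gene ("SRSF5L") with seven 120-nt exons
separated by 90-nt introns and nine isoforms, of which exactly three
(`biotype = "poison_retained"`, suffixes 207/211/212) retain intron 5 — the
poison cassette — as part of a merged exon; the six productive isoforms
never touch that interval. With the default read length (90 nt) and k-mer
size (21 nt) every read lies within one exon or spans exactly one
junction/boundary, so the EC structure is auditable by hand: a read inside a
constitutive exon is compatible with all nine isoforms, a read crossing the
exon-5/intron-5 boundary with exactly the three poison isoforms, and a read
across the exon-5/exon-6 junction with exactly the productive isoforms that
splice it.

Two design points deserve justification:

* **Identifiability.** The nine exon chains are chosen so that the mixture
  is identifiable from single-junction reads: the two non-canonical poison
  isoforms carry *private* splice-site variants (an alternative donor on
  exon 2, an alternative acceptor on exon 3) instead of reusing the
  productive skip events. If the poison trio instead mirrored the productive
  skip events, the position-level EC matrix would have rank 7 for 9
  isoforms — the joint of two distant binary splicing choices is invisible
  to reads that span at most one junction, and no estimator could recover
  the proportions. This is worth remembering with real annotations too:
  quantification bias on paralogous isoform ladders is often a rank problem,
  not an algorithm problem.
* **Replicate noise.** Between-replicate biological noise is an independent
  gamma multiplier per transcript (shape `1/phi`, mean 1), so per-transcript
  counts are marginally negative-binomial with dispersion `phi` — the
  standard generator matched to the bulk test's overdispersion assumption.
  Making the multiplier common to all isoforms of a gene looks harmless but
  induces ~0.98 correlation between isoform-level null statistics, which
  invalidates any independence-based p-value aggregation; the per-transcript
  form keeps the Lancaster combination honest.

Bulk reads are single-end, fixed-length, uniform-start, forward-strand, with
i.i.d. substitution errors (default 0.005/base) — no positional or GC bias,
no indels, because none of the tested statistics model them. Single-cell
reads carry a configurable cell barcode (12 nt) and UMI (10 nt); per-cell
gene totals are Poisson, isoform identity per molecule is multinomial in the
condition's proportions, and PCR duplicates are emitted geometrically at a
configurable rate. When totals are conserved, the per-cell totals of a
switching gene are drawn from the same distribution in both conditions, so
the gene-level contrast is null *by construction*.

## Pseudoalignment, TCCs and quantification

`build_index()` indexes every k-mer of every transcript (k = 21 by default;
no skipping heuristic, no canonical-strand collapsing — exactness over
speed at this scale). `pseudoalign()` intersects the transcript sets of a
read's indexed k-mers; an exhaustive oracle test verifies the EC of every
read position on a small transcriptome against brute force. EC ids are
assigned in order of first observation and live with the index, so matrices
and registries stay consistent within a run.

`count_tccs()` builds the units-by-ECs sparse matrix. Single-cell mode
first drops reads whose EC spans more than one gene, then collapses
duplicate (cell, UMI) molecules; conflicting copies keep the EC of the
lexicographically first read id (deterministic, logged, and rare at the
simulated error rates). `filter_sc()` applies the cell-quality filter
(total UMIs) and then the EC filter: an EC is removed only when it is both
detected in fewer than 1% of cells and below 0.01 mean count — passing
either criterion keeps it.

`em_quantify()` runs the equivalence-class EM,
`alpha_t <- sum_e c_e (alpha_t w_et / l_t) / sum_{t' in e} (alpha_t' w_et' / l_t')`,
from a uniform start until the molecule proportions move less than `1e-8`
(at most 1000 iterations). `l_t = max(1, len - L + 1)` is the effective
length. The weights `w_et` (how many start positions of transcript `t` fall
in EC `e`) are enumerated exactly from the index by default
(`position_weights = TRUE`); unit weights give the classic width-free EC
EM. The width-aware likelihood matters because wide shared classes (the
all-isoform EC) cover different numbers of positions on different isoforms;
ignoring that skews estimates on short-transcript toy geometries.
`est_counts` sums to the assigned reads; `proportion` is the
length-normalized molecule fraction. `bootstrap_abundances()` resamples the
EC counts multinomially (default B = 100, matching the quantification
bootstrap depth of the study design) with replicate streams derived
deterministically from `(seed, b)`.

## Bulk differential testing

`transcript_wald_test()` works on `y = ln(est_counts + 0.5)`. The
*inferential* variance is the mean bootstrap variance of the log counts;
the pooled within-group variance of `y` estimates the total. The Wald
statistic is `beta / se` with
`se = sqrt((sigma2_bio + sigma2_inf) (1/nA + 1/nB))` and a two-sided
standard-normal p-value.

With four samples per group the pooled variance has six degrees of freedom,
and a normal tail on a 6-df-variance statistic is anticonservative exactly
when the variance fluctuates low. The default therefore applies a
*one-sided* moderation: the total variance is floored at the df-corrected,
mean-dependent prior trend estimated by `limma::squeezeVar()` (its
`var.prior`), and never lowered below the raw value. Because the trend is a
consistent estimate of the true variance at a given abundance, clipping the
low fluctuations makes the statistic behave like a known-variance z. In the
packaged simulation study (200 genes, 20 switches, 4 vs 4, dispersion 0.1)
this brings the realized false-discovery proportion of the gene-level calls
from ~27% (no moderation) to ~2.5% at a nominal 5% FDR, without losing the
true switches. Two-sided empirical-Bayes squeezing is *not* appropriate
here: lowering high variances while keeping a normal reference re-inflates
the tail. `shrink = FALSE` disables moderation and gives the plain
estimator.

Gene-level inference comes in two deliberately contrasting flavours:

* `gene_count_test()` sums estimated counts (and bootstrap sums) within
  genes and applies the same Wald machinery — sensitive to overall up/down
  regulation, blind to switching at conserved totals.
* `lancaster_gene_test()` aggregates transcript p-values by the Lancaster
  method, `T = sum_i Qchisq(w_i, 1 - p_i)` against `chisq(sum w_i)`, with
  weights equal to each transcript's mean estimated counts; transcripts
  below one mean count are excluded (their p-values are dominated by the
  log-offset and the zero-df limit of the chi-square quantile is
  degenerate). With all weights 2 the method reduces exactly to Fisher's
  combination — a property the tests verify to 1e-10.

`bh_adjust()` (the standard step-up, via `stats::p.adjust`) controls FDR at
the 5% level used throughout.

## Splicing events and inclusion levels

`enumerate_events()` compares exon chains pairwise within each gene and
reports de-duplicated events of the five canonical types (SE, RI, A5SS,
A3SS, MXE), classifying *every* isoform of the gene into the inclusion set
(carries the variable region), the skipping set (carries the direct
junction) or neither. Counting is EC-based: a read supports a form when its
EC is a non-empty subset of that form's isoform set, everything else is
ambiguous — no genome alignment is ever needed. Effective lengths are the
mean, over a form's isoforms, of the per-isoform count of read start
positions whose EC resolves uniquely to the form; the per-isoform mean (as
opposed to pooling distinct reads across the form) is what makes `I / l_I`
proportional to the form's molecule abundance, and the choice is verified
against an exhaustive oracle. The inclusion level is the length-normalized
`psi = (I/l_I) / (I/l_I + S/l_S)`.

`event_group_lrt()` models per-unit inclusion counts as binomial in the
read-scale inclusion probability `theta(psi) = psi l_I / (psi l_I + (1 -
psi) l_S)` and compares a common-psi null against per-group psi by a 1-df
likelihood ratio (for the binomial the ML estimate of `theta` is the pooled
inclusion fraction, so the "optimization" has a closed form). Replicate
overdispersion is intentionally not modelled; the type-I simulations in the
test suite verify the 5% level holds in its absence, and the hierarchical /
paired extensions of alignment-based event tools are out of scope.

## Single-cell switching inference

`select_gene_tccs()` keeps the ECs that map within one gene and exceed 0.05
mean count in *both* conditions. `tcc_logistic_test()` then fits
`condition ~ intercept + ln(1 + c_ce)` over the gene's E retained ECs by
IRLS with a ridge stabilizer of 1e-8 (numerical conditioning only; the test
is the unpenalized likelihood ratio against the intercept-only model on
`chisq(E)`). Complete separation is flagged rather than silently penalized.
Bonferroni correction spans the genes tested in the run, and
`gene_total_test()` runs the identical machinery on the single feature
`ln(1 + per-cell gene total)` — the pair of tests reproduces the headline
contrast: under pure switching at conserved totals the TCC test is
overwhelmingly significant while the gene-level test stays null. Counts
enter untransformed beyond `log1p` because simulated depths are equal
across cells; a per-10k depth scaling option exists for unequal depths.

`ec_bootstrap_ci()` resamples cells with replacement within condition
(default B = 1000) and reports percentile 95% intervals for per-EC mean
TCCs — the standard error-bar construction for per-class mean displays.

## Orchestration and reproducibility

`run_pipeline()` chains `simulate`, `index`, `quant`, `diff-bulk`,
`events` and `diff-sc` under a single structured configuration
(`default_run_config()`, YAML round-trip via `read_run_config()`), writes
FASTA/GFF3/FASTQ/MTX/TSV artifacts with seed-echoing headers, logs
checksums, and fails with the name of the producing stage when an upstream
artifact is missing. A thin command-line wrapper lives at
`inst/cli/tccsplice.R`. Every stochastic step takes an explicit seed;
bootstrap and replicate streams are derived deterministically from it, and
the end-to-end determinism of result tables is part of the test suite.

## Problem sizes used in the validation suite

The packaged simulation study uses: a 200-gene transcriptome (199
background genes plus the SRSF5-like gene) with 20 switching background
genes, 4 vs 4 bulk samples, dispersion 0.1 and 100 bootstrap replicates for
false-discovery calibration (100,000 reads per sample in the test suite;
500,000 in the acceptance script); 500 cells per condition at ~3 SRSF5L
UMIs per cell across 20 seeds for the single-cell contrast; 1000 null and
100 alternative replicates for the event LRT calibration and power; 500
repetitions with B = 1000 for bootstrap CI coverage. These sizes make each
claim measurable with Monte-Carlo error well inside the stated tolerances.

## What passing tests do and do not show

The generator emulates isoform switching at conserved totals, NB replicate
noise, uniform-coverage reads and UMI duplication — but not positional or
GC bias, intron signal from unspliced pre-mRNA, ambient RNA, doublets,
UMI sequencing errors, or strand ambiguity. Passing acceptance tests
therefore establishes the statistical machinery (EC assignment, EM
identifiability and recovery, test calibration, CI coverage) under the
stated model, not robustness to the full messiness of real libraries. The
k-mer index is forward-strand only; real data would be reverse-complement
collapsed upstream. The event counting is EC-subset-based and is not
claimed to match junction-BAM counting modes of alignment-based tools
exactly.
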