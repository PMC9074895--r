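---
title: "Models and methods behind tailscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tailscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

tailscape implements the computational stages of a neuronal
poly(A)-tail / translation study as a tested pipeline: tail-length
calling from per-cycle sequencing intensities, 3′-end annotation from tag
coordinates, translational-efficiency (TE) quantification and its
sequence correlates, miRNA-repression statistics, a stepwise linear model
of TE, and classification of stimulation-induced tail changes. Every
stage can be exercised on synthetic data with planted truth
(`synth_config()` and the `simulate_*()` generators), which is how the
test suite and `scripts/acceptance.R` score it. This vignette records the
models, the parameter choices, and the reasoning behind decisions that
the method descriptions leave open.

## Tail-length calling from intensities

Tail-profiling reads are sequenced into a poly(A) stretch, so tail length
is measured not from base calls but from the per-cycle fluorescence of
the four channels. For each cycle the **T signal** is formed by dividing
each channel by its normalization factor (the mean read-1 intensity of
that channel when reading that base) and then dividing the normalized T
channel by the sum of the other three. The working value is the natural
logarithm of this ratio. The method descriptions this package follows
say only "logarithm"; we fix the natural log as the package-wide
convention, and the simulator and caller share it, so emission parameters
are always interpreted in the same units.

Positions where all four channels read zero carry no information; the
log T-signal there is imputed as the mean of the five valid values
upstream and five downstream. A trace with more than five such positions
is discarded. A position where the T-signal is zero or negative (possible
after background subtraction upstream of this package) cannot be logged
and is routed through the same imputation path.

Two routes produce calls:

* **Direct route.** Reads whose base calls never show ≥10 T within an
  11-nt window starting in the first 30 nt are not tail reads in the GHMM
  sense; if such a read begins with ≥4 contiguous T, the leading-run
  length is the tail call (necessarily <10 nt). Otherwise the tag is
  discarded.
* **GHMM route.** Screened reads are decoded with a 3-state Gaussian
  hidden Markov model over the log T-signal: an initiation state, a
  poly(A) state, and a non-poly(A) state, with left-to-right topology
  (1→{1,2}, 2→{2,3}, 3→{3}). Emissions are initialized at means
  (100, 1, −1) with variances (1, 0.25, 0.25), and initial state
  probabilities at (0.998, 0.001, 0.001). The numeric transition entries
  of the published initialization table are not recoverable from the text
  we worked from, so the packaged defaults (`ghmm_params_default()`)
  use 0.99 self-transition for states 1 and 2 and an absorbing state 3;
  they are documented as package defaults, and training makes the final
  parameters data-driven in any case.

Training is standard Baum–Welch on 10,000 randomly selected tags
(uniform, without replacement, seeded), with tolerance 1e-4 on the total
log-likelihood, at most 100 iterations, and an emission-variance floor of
1e-6 to prevent degenerate fits. Structural zeros in the transition
matrix are preserved exactly: a zero expected transition count keeps the
entry at zero, so the topology cannot be lost during EM. Decoding uses
the Viterbi path (the description says only "decode"); posterior decoding
is available behind `method = "posterior"`. The tail call is the number
of cycles in the poly(A) state. Per-gene mean tails use only genes with
≥50 tail measurements.

The 5-state variant used for the alternative sequencing chemistry reuses
the same machinery with a 5×5 left-to-right topology (initiation,
poly(A), poly(A)-transition, non-poly(A)-transition, non-poly(A)).
Whether the transition states count toward tail length is not stated in
the descriptions we follow; we count **only** the pure poly(A) state, on
the view that the transition states absorb boundary blur, and note that
counting the poly(A)-transition state as well would lengthen calls by a
few cycles.

One physical oddity is inherited deliberately: the initiation-state
emission mean of 100 is surprising for a log-scale signal, but it is what
the published initialization states, and nothing in the pipeline depends
on its physical plausibility — it simply makes initiation cycles
unmistakable.

## 3′-end annotation

Tags are piled up by the genomic coordinate of the 3′-UTR nucleotide
closest to the tail, using only tags with tails ≥11 nt. Annotation is
iterative greedy peak assignment: the coordinate with the most tags
becomes a 3′ end, every tag within ±10 nt (a 21-nt window) is assigned to
it and removed, and the process repeats until no tags remain. Ends are
retained when they carry ≥10% of the gene's 3′-UTR-mapping tags; the
denominator is all of the gene's tags (pre-filter), matching the wording
of the rule, not the tags remaining after earlier ends were consumed.
Ties on the maximal count are broken toward the 5′-most coordinate in
transcript orientation, which makes the algorithm deterministic. Note
that while the *peak heights* picked by successive iterations are
non-increasing, the *window totals* assigned to them need not be — a
secondary peak can accumulate a larger ±10-nt neighborhood than an
earlier, sharper peak.

## TE quantification and correlates

TE is `log2(RPF RPM / RNA RPM)` per gene, with RPM = reads per million
mapped reads. Counts are expected over the ORF excluding its first 50 nt
(a counting rule applied upstream; the package treats the supplied counts
as already following it). The expression cutoff of ≥10 RPM applies to the
RNA-seq side only — RPF additionally requires a nonzero count, since TE
is undefined otherwise; such genes are dropped with a warning rather than
imputed.

The spread of TE values is summarized as the fold range between the 1st
and 99th percentiles of the median-centered log2 values, `2^(P99 − P01)`.
Percentiles use linear interpolation between order statistics
(`quantile` type 7); the method texts are silent on this, and the choice
only matters in the far tails, but it must be fixed for reproducibility.

Codon–TE correlations are Pearson correlations between each sense
codon's frequency (count over non-stop codons) and TE, computed per
sample and aggregated as mean ± SD across samples; the amino-acid variant
pools synonymous codons first. A-site occupancy places the ribosomal
A site at the footprint 5′ end + 15 nt (the field convention for
29–31-nt footprints; configurable), computes per-codon enrichment over
the transcriptome background, and optionally reports the OLS R² of the
codon–TE correlations on those enrichments. The tail–TE relationship is
a Spearman correlation (large-sample t approximation for p; ties make the
exact p unavailable anyway), and the subset analysis compares a subset's
correlation against `n_perm` equally sized random subsets, reporting the
add-one-corrected empirical p.

## miRNA repression

Seed-match site types follow the canonical hierarchy: 8mer (match to
miRNA positions 2–8 plus an A opposite position 1), 7mer-m8 (2–8),
7mer-A1 (2–7 plus A1), 6mer (2–7); the strongest site in the 3′ UTR is
reported. "No site" additionally requires that no 6-nt seed match occurs
anywhere in the transcript; genes with a 6mer outside the 3′ UTR but no
UTR site belong to neither cohort and are returned as `NA`.

Because longer 3′ UTRs accumulate larger secondary effects of a miRNA
perturbation, fold changes are first residualized against UTR length: an
OLS of no-site log2 fold change on log10(UTR length) is fitted, and the
slope component (centered at the no-site mean log-length, preserving the
intercept) is subtracted from *every* gene. The log base is irrelevant to
the residualization; log10 is used. The operation is idempotent and
forces the refitted no-site slope to zero at numerical precision.

The cohort effect is the **mean** normalized fold change of the targets
minus the **median** normalized fold change of the no-site genes — the
asymmetry is retained deliberately because it is how the quantity is
defined in the analyses this package re-implements. Significance of
repression is a one-tailed Welch t-test (targets more repressed than
no-site genes); the RNA-versus-RPF comparison is an unpaired t-test,
taken as two-tailed since its sidedness is unstated. Top targets are the
predicted targets whose reference-experiment expression dropped to ≤75%
(boundary inclusive).

## The TE linear model

The model is built in two rounds of forward stepwise regression:

1. Round 1 selects from the full feature menu, at each step adding the
   feature that most decreases the AIC of the Gaussian linear model
   (`stats::AIC`, k = parameters + 1), stopping when no addition
   decreases it.
2. Features whose sequential inclusion added less than 0.003 to the
   adjusted R² are removed from the menu; poly(A)-tail length is always
   retained because it is a quantity of scientific interest even when
   uninformative. Round 2 reruns the stepwise selection on this reduced
   menu; if tail length is not picked by AIC it is appended at the end of
   the model.

"Complex" features (codon composition, 5′-UTR 6-mer motifs) are
sub-feature models: a linear model of TE on the sub-feature matrix,
trained on training rows only, whose predictions become one scalar
column of the main design. Rank-deficient or wide designs fall back to
ridge regression, with the penalty chosen by 5-fold cross-validation on
the training rows (a fixed penalty had two failure modes: too small and
the complex feature interpolates its own training data, dominating the
AIC selection spuriously; too large and it is needlessly weakened — and
generalized cross-validation collapses to interpolation on these
heavy-tailed spectra). When the sub-feature matrix is wider than the
training set, all linear algebra runs in the dual (kernel) form, which is
algebraically identical and far cheaper. The published
menu of 17 round-1 features is not fully enumerated in the text we
follow, so the packaged default menu is a documented reconstruction
covering every named feature (CDS/UTR lengths, expression, tail length,
GC contents, folding energies, codon composition, 5′-UTR motifs), and
user columns are accepted.

Evaluation trains and tests the final model 100 times with fresh random
80/20 train/test splits (the split fraction is unstated in the source
descriptions; 80/20 is the package default and configurable). Sub-feature
models are refit inside each training split so the held-out R² carries no
leakage — the descriptions are silent on leakage control, and this is the
conservative reading. Within a split, the training rows of a complex
feature column carry out-of-fold (cross-fitted) predictions rather than
the sub-feature model's own fitted values: without this, a wide
sub-feature model partially interpolates its training data, and the AIC
selection — which sees the complex feature as a single column with two
parameters — would prefer it spuriously. Cross-fitting is standard
stacking practice and matters most when genes are few relative to the
sub-feature count. Because "trained and evaluated" is ambiguous about
which R² is reported, the package reports the held-out mean as the
headline number and exposes the training R² alongside. For multi-isoform
genes, 3′-UTR length and folding energy are expression-weighted means,
and 3′-UTR folding energy is normalized per nt.

## Stimulation responses

Per-gene differential tail length is a Welch t-test on per-replicate gene
mean tails (the source says only "t-test"; unequal variances is the safe
choice at n = 4), with Δ = stimulated − control. If both cohorts are
variance-free the test degenerates and is short-circuited (p = 1 on equal
means, p = 0 flagged otherwise).

Differential expression across replicate tag counts is a self-contained
negative-binomial test defined by the package (so the pipeline is
reproducible without an external differential-expression caller):
median-of-ratios size factors; per-gene method-of-moments dispersions
(Var = μ + αμ²) pooled across cohorts; a mean–dispersion trend
α(μ) = a₀ + a₁/μ fitted across genes and substituted for the noisy
per-gene values; a Wald statistic on the log2 ratio of normalized cohort
means referred to a t distribution on the within-cohort degrees of
freedom; Benjamini–Hochberg adjustment. The t reference (rather than
normal) compensates for the small replicate number and keeps the test
conservative on nulls, which the test suite verifies as an average
false-discovery fraction ≤0.05 at the nominal 0.05.

Mechanism classification is a pure function of the two test outcomes:
significant tail increase with significant expression increase →
transcriptional burst (young, long-tailed transcripts); with significant
expression decrease → short-tailed-isoform decay; with no significant
expression change → cytoplasmic polyadenylation; anything else → none.
Thresholds default to tail p < 0.05 and adjusted expression p < 0.05 and
are configurable. A complementary check, `short_tail_depletion()`,
compares the fraction of a gene's tags below the control 25th-percentile
tail length between cohorts, since the decay mechanism predicts a deficit
of short-tailed molecules; the exact computation behind the published
check is unstated, and this quantile comparison is our definition.

CPE motifs default to the TTTTAT / TTTTAAT classes; the motif definitions
in the literature this package follows are themselves imported from
earlier oocyte and striatum work, so the defaults are flagged as
configurable reconstructions. The association between CPE presence and
tail increases is Fisher's exact test with the odds ratio reported.
Global distribution effects are assessed with per-sample histograms at
2-nt bins and a one-way ANOVA of per-sample mean tail on treatment.

## The synthetic-data generators

`synth_config()` fixes the study conditions; its defaults are chosen once
to describe a typical neuronal tail-profiling experiment and are not
tuned per analysis:

* tail lengths: gamma, mean 90 nt, shape 4 (right-skewed, mode below the
  mean, essentially no mass below 10 nt — typical of somatic tissue);
* traces: 250 cycles; the generating GHMM uses the emission parameters
  above with a short geometric initiation dwell (mean 5 cycles, i.e.
  a11 = 0.8) and a poly(A) exit rate of 1/mean-tail;
* counts: negative binomial with dispersion 0.05 and library size 2×10⁷,
  log-normal expression;
* miRNA experiment: per-gene fold-change noise 0.3 log2 units, TE-level
  noise 0.15 log2 units, tail noise 2 nt; site repression −0.1/−0.2/
  −0.3/−0.4 log2 for 6mer/7mer-A1/7mer-m8/8mer; planted tail change zero
  (the no-tail-effect finding is the default scenario and overridable);
* stimulation: 4 replicates per cohort, replicate tail SD 4.5 nt,
  planted tail increase 20 nt, expression fold 8, mechanism fractions
  5/5/5/85%;
* spike-in standards at 10/50/100/160 nt in equal input fractions.

Intensity traces are generated with the planted tail occupying exactly L
poly(A)-state cycles (truncated at the trace length), the initiation
dwell drawn from the HMM's own geometric law, and raw channels
back-computed so `compute_t_signal()` round-trips the sampled log
T-signal exactly: the three non-T channels are fixed at 1.0 and the T
channel at 3·exp(logT), with unit norms. Baum–Welch recovery checks use
`ghmm_simulate()` instead, which draws full state paths from the model's
own law, because EM can only be expected to recover parameters of data it
actually generated.

What the generators deliberately do **not** emulate: base-calling errors
and quality decay along the read, alignment artifacts, fragment-length
distributions, correlated feature structure (real codon usage, UTR
length, and expression co-vary in ways the independent draws here do
not), and cell-type mixtures. Passing tests therefore demonstrate that
the implementations are correct under their stated models — not that the
models capture every property of real libraries.

## Numerical choices and degenerate inputs

All HMM computation is in log space with row-wise log-sum-exp guards;
Viterbi ties break toward the lower-numbered state (deterministic under
the left-to-right topology). Quantities that consume randomness take
explicit seeds, and fixed config + seed reproduces outputs byte for byte.
Degenerate inputs are handled explicitly rather than by error where a
defined answer exists: empty pileups return empty annotations, all-equal
UTR lengths make the confound normalization a no-op, identical cohorts
give exactly zero fold change, empty contingency margins give p = 1 with
a warning, and F = 0 ANOVA is reported as p = 1.

The test suite runs the pipeline at the sizes the analyses are designed
for — 10,000 tags for decoding accuracy and Baum–Welch recovery, 1,000
random pileups against a brute-force annotator, n = 4,000 genes for the
linear model with a planted 40% variance share, 4,000 null genes for
test calibration, and one end-to-end run at 500 genes / 100,000 tags —
sizes chosen so the whole suite completes on a single CPU in minutes
while keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

* The packaged transition initialization is a reconstruction (see above);
  conclusions about trained models are unaffected, but exact numerical
  agreement with the original initialization cannot be claimed.
* The NB differential-expression test is a stand-in with a simple
  mean–dispersion trend; it is calibrated on nulls but less powerful than
  shrinkage-based callers at very low counts.
* Feature definitions imported from prior work (5′-UTR motif scores,
  precomputed folding energies) are represented by sub-feature models and
  supplied columns, not regenerated.
* The mechanism classifier inherits the error rates of its two input
  tests; near-threshold genes flip labels under resampling.
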