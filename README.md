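# tailscape

Poly(A)-tail lengths, translational efficiency (TE), miRNA effects, and
stimulation responses in neuronal transcriptomes — implemented as a
tested, reusable R pipeline and exercised end to end on synthetic data
with planted ground truth.

## The problem

In neurons, post-transcriptional control is unusually rich: poly(A)
tails can be extended in the cytoplasm after stimulation, miRNAs shape
target mRNA levels, and the translational efficiency of an mRNA —
TE = log2(RPF RPM / RNA RPM), the density of ribosome-protected
fragments over the mRNA's abundance — varies tens-of-fold between genes.
Measuring tails at scale requires decoding per-cycle sequencing
*intensities* rather than base calls: during the poly(A) stretch the
thymidine channel dominates, so the per-cycle **T signal**
(normalized T intensity over the sum of the other three channels, taken
in log) switches between characteristic levels as the sequencer reads
through the tail. tailscape implements the computational stages of such
a study for anyone who wants to run, score, or extend them:

* **tail calling** — T-signal preprocessing (imputation of dead cycles,
  discard rule), a direct rule for short tails (leading-T runs), and a
  3-state (or 5-state) Gaussian hidden Markov model over the log
  T-signal: Baum–Welch training on 10,000 random tags, Viterbi decoding,
  tail length = cycles in the poly(A) state, per-gene means over ≥50
  measurements, spike-in standard recovery;
* **3′-end annotation** — iterative greedy peak assignment of tag
  3′-coordinates (21-nt windows, ≥10% retention rule, tails ≥11 nt);
* **TE quantification** — the ≥10 RPM expression cutoff, 1–99 percentile
  fold ranges, codon/amino-acid TE correlations, ribosomal A-site
  occupancy, footprint periodicity QC, tail–TE Spearman correlations
  with a subset permutation test;
* **miRNA repression** — canonical seed-match site classes (8mer >
  7mer-m8 > 7mer-A1 > 6mer), 3′-UTR-length confound normalization, and
  cohort effects (mean of targets minus median of no-site genes) with
  one-tailed tests and an RNA-vs-RPF comparison;
* **TE linear model** — two rounds of forward stepwise AIC selection
  with an adjusted-R² ≥ 0.003 filter, forced retention of tail length,
  cross-fitted complex features (codon composition, 5′-UTR motifs), and
  100-fold bootstrap evaluation on held-out genes;
* **stimulation responses** — per-gene Welch t-tests on replicate tail
  means, a self-contained negative-binomial expression test with BH
  adjustment, and a mechanism classifier separating transcriptional
  bursts, short-tailed-isoform decay, and cytoplasmic polyadenylation;
* **synthetic data** — generators for every input above with the truth
  written alongside, so each stage is scorable.

The methods vignette (`vignettes/tailscape-methods.Rmd`) documents the
models, parameter defaults, and the design decisions in detail.

## Worked example

The `analysis/` directory holds the pipeline as numbered drivers; run
them in order from the repository root (`Rscript analysis/01_simulate.R`
and so on). Stage 2, for instance, trains the tail-calling GHMM on the
simulated intensity traces and prints:

```
Trained GHMM ( 3 EM iterations ):
Gaussian HMM with 3 states
pi: 1 0 0
transition matrix:
       [,1]   [,2]    [,3]
[1,] 0.8014 0.1986 0.00000
[2,] 0.0000 0.9890 0.01098
[3,] 0.0000 0.0000 1.00000
emission means: 100 0.9996 -1
emission variances: 1.002 0.2501 0.2501
Called 46997/47000 tags (99.9% ghmm, 0.1% direct); 99.98% within 2 nt of truth.
222 genes pass the 50-tag cutoff; grand mean tail 90.2 nt.
```

The trained transition matrix recovers the generating values (the
simulation plants a mean initiation dwell of 5 cycles, so a11 ≈ 0.80,
and a mean tail of 90 nt, so a23 ≈ 1/90 ≈ 0.011), the emission
parameters match the planted Gaussians, and 99.98% of 47,000 decoded
tails land within 2 nt of the planted lengths. Stage 3 then reports

```
Annotated 381 3' ends across 300 genes; 100.0% within 1 nt of a planted isoform end.
Genes with two annotated ends: 81 (planted: 81).
```

every planted 3′-end isoform is recovered at the right coordinate, at
the planted one-or-two ends per gene. Later stages print the TE fold
range, the codon–TE correlation table, the miRNA cohort effects (a
planted −0.4 log2 mRNA repression appears on RNA and RPF alike, with a
non-significant RNA-vs-RPF test — repression without a TE component),
the stepwise model's selected features with held-out R², and the
stimulation mechanism confusion table. Outputs land under `results/`.

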