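---
title: "Detecting circadian miRNA primary transcripts: methods and design"
author: "circaprime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting circadian miRNA primary transcripts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circaprime)
```

## The problem

Mature miRNAs are long-lived: with a mammalian average half-life around
119 hours, a miRNA pool turns over far more slowly than one circadian
cycle. A primary transcript (pri-miRNA) that is strongly rhythmically
transcribed therefore feeds a mature pool whose oscillation is almost
completely flattened — which is why surveys of circadian miRNAs at the
mature level disagree with each other. The remedy implemented here is to
detect circadian miRNAs at the *primary transcript* level, where
oscillations are intact, using two independent nascent-transcription
time courses (GRO-seq- and Nascent-seq-style RPKM matrices) and
requiring agreement between them.

`circaprime` implements that detection pipeline and its downstream
analyses, and ships a synthetic-data generator with planted ground truth
so every stage is testable end to end without any external download.

## Rhythm detection model

For each transcript and dataset we fit the fixed-period cosinor model

$$ y(t) = m + a\cos(\omega t) + b\sin(\omega t), \qquad
   \omega = 2\pi/24\,\mathrm{h}, $$

by ordinary least squares. This linear parameterisation is exactly
equivalent to fitting $m + A\cos(\omega (t-\phi))$ over all phase
shifts: $A = \sqrt{a^2+b^2}$ and the peak phase is
$\phi = \operatorname{atan2}(b, a)/\omega$. The tests prove this
equivalence against an explicit 0.01-h phase-grid fit. Significance is
the F-test of the two harmonic terms against the intercept-only model
(2 and $n-3$ degrees of freedom), which is exact for Gaussian noise;
replicates and multi-day samples enter through the periodic regressors
with no special handling.

The two datasets are combined into the significance score

$$ S = -\log_2 p_1 - \log_2 p_2 \quad\text{(bits)}, $$

and a transcript is called circadian when $S > 9$ **and** the circular
phase difference between the two fits is below 4 h. Both comparisons
are strict inequalities. The reported phase is the
$-\log_2 p$-weighted circular mean of the two per-dataset phases — the
weighting is this package's choice, made so that the better-determined
fit dominates; an alternative reading, a joint fit with one shared
phase across both datasets, is available as `joint_phase_fit()` but is
not the default pipeline.

Numerical choices: p-values are floored at $10^{-300}$ before the log2
transform so the score stays finite (and the flooring is flagged);
constant series return $A = 0,\ p = 1$ rather than an error; fewer
than four distinct sampling times modulo the period is an error because
the three-parameter fit is underdetermined.

Mature-level series, being dampened, are tested with relaxed criteria
(`mature_rhythm_test()`): one-way ANOVA across time groups **and** a
cosinor fit, both at $p < 0.05$.

## Permutation FDR

The false discovery rate of the $S > 9,\ \Delta\phi < 4$ classifier is
estimated by permutation: each transcript's values are shuffled across
samples independently within each dataset, the whole pipeline is
re-run, and

$$ \widehat{\mathrm{FDR}} =
   \frac{\text{mean permuted pass count}}{\text{real pass count}}. $$

"Shuffling the gene" admits more than one reading; the default here
shuffles time labels within each transcript (destroying both the
rhythm and the cross-dataset phase agreement while preserving each
transcript's value distribution), and a whole-row swap of transcript
identities in the second dataset is available via
`method = "gene_swap"`. Per-permutation sub-seeds are derived from one
master seed, so runs are reproducible and would parallelise
reproducibly. With zero real passes the estimate is reported as
undefined rather than thrown.

## Over-expression analysis

The miRNA over-expression experiment is a 2 (CT10/CT22) x 2
(over-expression/control) factorial with replicate animals per cell.
Per gene we fit the main-effects model
`log2(x + 1) ~ time + treatment` and F-test each factor. The model
deliberately omits the interaction (a 2x2 design with two replicates
leaves five residual degrees of freedom; an interaction model is
available behind a flag), applies **no** multiple-testing correction
(the raw $p < 0.05$ convention of this analysis, documented rather than
silently "improved"), and uses `log2(x + 1)` because the input is
nonnegative normalised expression. "Peaking around CT10 vs CT22" is
read off the control arm only, so a treatment that reshapes the rhythm
cannot flip a gene's peak-side label.

Doubly significant genes are partitioned into Group I (CT10-peaking,
repressed), II (CT10, induced), III (CT22, repressed) and IV (CT22,
induced); Groups I and III form the "circadian target" set. Enrichment
statistics use Fisher's exact test (sample odds ratio $ad/bc$, Haldane
0.5 correction only when a zero cell occurs, flagged) or the pooled
two-proportion z-test without continuity correction, matching the
conventions of the original analyses these statistics mirror.

## Relative amplitude and kinetics

With only two time points the oscillation of a gene is summarised by
its relative amplitude $RA = \log_2(\bar x_{CT10}/\bar x_{CT22})$.
Changes between conditions are classified against a 0.5 log2-unit
threshold; the boundary $|\Delta RA| = 0.5$ counts as *unchanged*
(change requires a strictly larger difference). Because $RA$ is signed,
the difference is oriented by each gene's peak side so that "increased"
always means a larger-magnitude oscillation.

The kinetic link between primary and mature levels is the steady state
of $dP/dt = s(t) - kP$ with sinusoidal synthesis: the product
oscillates with relative amplitude scaled by $k/\sqrt{k^2+\omega^2}$
and lags by $\arctan(\omega/k)/\omega$ hours, $k = \ln 2 /
t_{1/2}$. At $t_{1/2} = 119$ h and a 24-h period the attenuation is
`r round(kinetic_attenuation(119)$attenuation, 4)` with a
`r round(kinetic_attenuation(119)$phase_lag, 2)`-h lag. The closed form
is verified against numerical ODE integration in the tests. Note the
model's own tension with observation: measured mature amplitudes are
reported only ~2–3-fold below primary ones, far less attenuated than a
119-h half-life predicts; the module asserts only its mathematics and
leaves the discrepancy (shorter effective half-lives, active turnover)
open. Note also that the phase lag can flip the *sign* of a near-zero
two-point RA (genes peaking halfway between the sampled times), so
"mature RA magnitude below nascent" holds for genes whose RA actually
captures their oscillation, not degenerate ones.

## Promoter and network analysis

Intervals follow the BED convention (0-based half-open on disk,
converted at the I/O layer; `GRanges` internally). The regulator search
window runs from 5,000 bp upstream of the 5' end to the 3' end of the
transcript, strand-aware and clipped at the chromosome start. An
overlap of at least one base suffices (no minimum is stated anywhere
authoritative; one base is the least arbitrary choice).

5' ends are validated against H3K4me3 and Pol II marks within a
configurable `tss_flank` (default 1,000 bp — the evidence radius is not
specified by the source analyses, so it is an explicit parameter).
Transcripts with neither mark get their 5' end moved to the center of
the nearest H3K4me3 peak (Pol II as fallback; a flag pools both),
distance measured peak-center to 5' end, ties broken toward upstream,
with a 10-kb default search limit. The correction is idempotent and
never touches strand or 3' end.

Regulator edges require the peak's dataset-support count to meet the
regulator's rule — at least 2 of 6 datasets for BMAL1, at least 1 for
all others — and binding enrichment on circadian promoters is tested by
the proportion test against all transcripts. Motifs combine a TF
binding edge, a functional flag (knockout evidence, consumed as an
input column because the underlying knockout data are
accession-bound), and a miRNA-target edge: type 1 pairs BMAL1/CLOCK
with Group I targets, type 2 pairs REV-ERBα/β with Group III targets.

## What the synthetic data emulates — and what it does not

`simulate_nascent_pair()` plants, for a configurable fraction of
transcripts, a cosine rhythm shared between two datasets:
`value(t) = exp(b)(1 + a cos(2π(t-φ)/24))` times multiplicative
lognormal noise. Defaults are the study conditions: dataset A sampled
every 4 h over 48 h (12 points), dataset B every 3 h over 24 h (8
points, proving the fitter handles unequal designs), phases uniform on
[0, 24), planted log2 peak-to-trough folds 1–3 (at least 2-fold),
noise σ = 0.2. Lognormal noise is a modelling choice — nascent RPKM is
positive and right-skewed and the noise model of real RPKM is not
documented — and is therefore a flagged assumption, not a fact about
the assays. The two datasets share phases exactly by default;
`phase_noise_sd` adds inter-dataset jitter for sensitivity analyses.

`simulate_overexpression()` generates the 2x2xr design directly on the
log2 scale (the ANOVA operates on logs, avoiding an unstated
count-model choice), with repressive effects outnumbering inductions
8:1 and repressed genes annotated as targets at 1.8-fold odds.
`simulate_mature()` applies the kinetic attenuation and lag exactly;
`simulate_binding()` plants promoter peaks with elevated odds on
circadian transcripts and BMAL1 support counts spread over 1–6
datasets.

None of the generators simulate reads, sequence content, mappability,
library-size artefacts, or count noise; passing tests demonstrate that
the *methods* recover what they model, not that real sequencing data
are this well behaved.

## Problem sizes and checks

The package's own acceptance checks run at these sizes, chosen to make
Monte-Carlo statements stable while staying desk-scale: 1,000
transcripts (20% rhythmic) with 500 permutations for
sensitivity/FDR/phase accuracy; 2,000 null cosinor fits and 5,000 null
ANOVA genes for calibration; 2,000 genes for group and
amplitude-class recovery; five half-lives (0.5–1,000 h) against a
numerical ODE oracle; 400 transcripts per binding-enrichment
simulation. Observed behaviour at defaults: sensitivity ≈ 0.98,
permutation FDR ≈ 0.02–0.03 against a true false-positive fraction of
the same size, median phase error ≈ 0.3 h, group agreement ≈ 0.97.

## Known limitations

* The consistency score assumes the two datasets are independent;
  shared technical structure would make $S$ anticonservative.
* The F-test calibration is exact under Gaussian noise; heavy-tailed
  expression noise inflates small p-values slightly (the KS calibration
  check uses Gaussian nulls deliberately).
* With two time points the RA conflates amplitude with phase; genes
  peaking near CT16/CT4 are nearly invisible to it.
* Group labels depend on raw per-gene 0.05 cutoffs and inherit their
  multiplicity behaviour by design.
* The permutation FDR estimates a global, not per-transcript, error
  rate.
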