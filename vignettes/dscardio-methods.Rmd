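---
title: "Models and measurement conventions in dscardio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and measurement conventions in dscardio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscardio)
```

dscardio phenotypes segmental-trisomy mouse models of Down syndrome along
three axes: surface electrocardiography, genotype transmission, and
gene-dosage expression. This vignette is the package's own account of the
models behind each stage — what is assumed, which parameters matter, and
what the synthetic data do and do not emulate.

## The synthetic ECG model

### Waveform

Each beat is a sum of asymmetric Gaussian lobes (independent left and right
widths) for the P, R, S, J and T waves. Asymmetric Gaussians were chosen
because they are smooth, cheap to evaluate, and give *analytic* ground
truth: wave onsets and offsets are defined as the 5%-of-peak crossings of
each lobe, so every nominal event time is known exactly and the
delineation stage can be validated against it to sub-sample precision.

The QRS geometry places the onset 35% of the QRS duration before the R
peak, the S nadir 35% after it, and the offset at 65%; lobe widths are set
so the 5% crossings land exactly on those times. The J wave (the second
deflection adjoining the QRS, characteristic of mouse ECG) peaks 3 ms
after the QRS offset. The delayed T wave is rendered on the Vms lead only:
in this preparation the T is elusive on other leads but constantly present
and positive on Vms, which is therefore the QT lead. Its right flank is
broad; the width is set so that the steepest-descent tangent of the flank
meets the baseline exactly at the nominal T offset (`QRS onset + QT`),
matching the delineation's extrapolated T-offset convention (below).

### The frontal dipole and the precordial templates

The frontal plane is a two-component dipole: DI and aVF are rendered from
the preset amplitude table and the remaining limb leads follow from the
Einthoven/Goldberger identities (DIII = aVF − DI/2, DII = DI + DIII,
aVR = −(DI+DII)/2, aVL = (DI−DIII)/2), which therefore hold *exactly*
before noise injection — a standing invariant of the test suite. A
consequence worth stating plainly: only DI and aVF can carry arbitrary
reference amplitudes; the derived leads' amplitudes are linear
combinations, and the published group means for DII, DIII and aVR are not
exactly consistent with the identities. The preset table still records the
published values for those leads (as reference metadata), but
amplitude-recovery guarantees apply to DI, aVF and the four precordial
leads, which are rendered as independent templates against the Wilson
terminal (chest potentials cannot be derived from limb potentials alone).
aVL has no published reference mean and carries `NA` in the table.

The frontal-axis target is not a free parameter: it is implied by the
DI/aVF net QRS amplitudes (wild type ≈ −42°, leftward; trisomic ≈ +61°,
inferior-rightward), and the delineation recovers it via
`atan2(aVF_net, DI_net)` on the measured mean R+S sums. An absent S
contributes 0 to the net sum.

### Genotype presets

The five built-in presets carry the published group means as their
parameters: wild type (RR 89.96 ms = 667 bpm, PR 35.3, QRS 9.02, QT
67.5 ms), Ts65Dn (99.01 ms = 606 bpm, PR 44.6, QRS 9.89, QT 73.0), the
compound Ts65Dn/Ms5Yah (RR 97.8, PR 39.3, QT derived from the reported
QTc 65.5 at that RR: 64.8 ms; precordial amplitudes rescued to wild-type
values except the V1 S wave, frontal amplitudes not rescued), Ms5Yah
(no adult ECG phenotype reported; modelled as wild type) and Ts65Dn under
20 mg/kg flecainide (all intervals prolonged, from the published table).
Values the study does not print were fixed once: the wild-type P duration
(10 ms, a typical murine value; the trisomic preset uses the printed
11.75 ms), the within-animal RR jitter (SD 2 ms), the additive noise
(0.02 mV — realistic for a 1–500 Hz amplified subcutaneous-lead chain),
and the J/T amplitudes (chosen to match the published tracings
qualitatively; they are not printed as numbers).

### Anomaly injection

The three qualitative features are injected per beat and per lead as
independent Bernoulli events, the simplest model consistent with
fragmentation being lead-class specific:

* **notch** (inferior limb leads, via the dipole): the S nadir splits into
  two narrow sub-lobes with a prominent valley that stays below the
  baseline — an S-wave notch;
* **RSR'** (V1): a secondary positive lobe after the S nadir returning
  above baseline, with the S halved (low-voltage S);
* **slurr** (V1, Vms): a monotone time warp slows the upstroke to 20% of
  its nominal velocity for 2.5 ms starting at 45% of the onset-to-peak
  limb, catching up by the S nadir — the R peak is rendered slightly late,
  as on a genuinely slurred complex;
* **S absence** (V1, Vms, Vs): the S lobe is suppressed so the post-R
  minimum is non-negative.

The trisomic presets inject each anomaly with probability 0.9 per beat,
wild type 0.03, and the compound model 0.45 (calibrated so that
majority-vote animal-level calls give an intermediate affected fraction,
mirroring the partial rescue). The study quantifies neither notch depth
nor slurr slope; these generator parameters are package constants
documented here, not values inferred from data.

## Delineation conventions

* **Beat detection**: the trace is smoothed (1 ms moving average), a 25 ms
  moving average is subtracted (baseline and slow-wave suppression), and
  complexes above 45% of the filtered maximum are reduced to their local
  maxima under a 30 ms refractory period. A trace whose filtered amplitude
  never reaches 0.15 mV raises an error rather than returning noise peaks.
* **Isoelectric level**: mouse ECG has no true electrical zero; each
  beat's zero is the mean of five consecutive samples of the working
  (smoothed) trace starting 15 ms before the QRS onset — between the end
  of the P wave and the QRS for every preset geometry.
* **Edges**: wave onsets/offsets are 5%-of-own-peak threshold crossings on
  a 1.2 ms-smoothed trace. PR is measured from the P onset to the QRS
  onset on DII (largest P among leads that carry no T wave; the search
  window extends 65 ms before the QRS onset to accommodate the prolonged
  flecainide PR). Amplitudes are read from the raw trace at the located
  extremum — smoothing is for localisation only, so peak attenuation does
  not bias them.
* **T offset and QT**: the terminal T fuses with the next beat's P wave at
  these heart rates (QT ≈ RR − 25 ms while the next P begins ≈ RR − 40 ms),
  so no forward threshold crossing on the measured trace can mark the QT
  endpoint. The T offset is therefore *extrapolated*: the T peak is the
  last prominent positive lobe within 30 ms of the R peak (the J wave,
  adjoining the QRS, comes earlier), the downslope is fitted with a
  Gaussian flank over the clean segment ending at the T–P valley, and the
  offset is taken where the steepest-descent tangent of the fitted flank
  meets the isoelectric line (peak + 2σ). Because the flank is only a few
  tens of µV/ms, QT is additionally measured on a *signal-averaged* beat
  (the five beats of each checkpoint aligned on their R peaks), not on
  single beats. Noise-free accuracy is ~0.5% with a worst case near 2%
  when a short RR truncates the flank early; under the default noise the
  cohort-mean QT recovers within ~3% for every preset.
* **Cadence**: measurements follow the study's reporting scheme — at every
  20 s checkpoint five consecutive beats are delineated and averaged, and
  the animal summary is the mean over checkpoints. The heart-rate mode is
  the mode of 10 s-window mean heart rate binned at 5 bpm.

## Morphology detectors

* **Fragmented QRS**: local extrema inside the QRS window with prominence
  ≥ max(0.05 mV, 5% of R) (iterative zigzag pruning). A below-baseline
  minimum followed by a positive deflection above baseline is RSR'; a
  further below-baseline deflection makes it RSR'S'; prominent extrema
  that do not cross the baseline are a notch. The window end is derived
  from the R upstroke width (onset-to-peak span ÷ 0.35) because
  fragmentation corrupts the S-based QRS offset itself.
* **Slurring**: on the limb between 8% and 70% of the R amplitude — the
  clean upstroke's slope maximum sits at ~61% of the amplitude, so the
  derivative is quasi-monotone there — slurring is called when the
  smoothed derivative falls below 50% of its running maximum for ≥ 1 ms
  (rolling 80% occupancy, tolerating isolated noise flips).
* **S absence**: the post-R minimum, measured as a ±1 ms local mean of the
  smoothed trace (a bare one-sample minimum is biased negative under
  noise), is ≥ −0.03 mV relative to the isoelectric level. The 0.03 mV
  tolerance absorbs residual noise on a suppressed S while staying far
  below any genuine S amplitude (the smallest preset S is −0.119 mV).
* **Scoring**: per-lead calls are majority votes over the measured beats;
  an animal's anomaly count is the number of distinct feature *types*
  present on at least one lead of the precordial set (V1, Vms, Vs, V4 —
  the set the feature figure legend names), and "affected" means at least
  two types. An option extends the counted set to the inferior limb
  leads, where notches are most frequent; whether those notches fed the
  published three-feature count is not stated, so the precordial default
  was chosen and the option left to the user.

Against the generator's anomaly ledger the detectors achieve per-beat
sensitivity ≥ 0.93 and specificity ≥ 0.98 at noise SD up to 0.03 mV (the
test suite asserts ≥ 0.9 / ≥ 0.95).

## Statistics

* `fisher_exact()` computes the exact hypergeometric tail directly, with
  the tail an explicit argument, because the published tables mix
  conventions: the trisomy-vs-compound comparison matches the two-sided
  sum-of-small-point-probabilities convention (1.85×10⁻⁴), while the
  wild-type-vs-compound value (0.444) matches a lower-tail computation.
  The two-sided definition uses a 1e-7 relative slack for floating-point
  ties; the test suite checks exact agreement with a binomial-coefficient
  enumeration oracle and with `stats::fisher.test`.
* `chi_square_gof()` is plain Pearson (optionally Yates-corrected) with
  per-class contributions. The chi-square values printed in the source
  transmission table are not reproducible by standard Pearson under any
  expectation model tried, so a documented default mattered more than
  matching them; the observed percentages (34.0, 16.7, 24.9) and the
  independence model for compound-cross expectations reproduce exactly.
* Angular-interval membership (frontal-axis test) is computed on the
  directed arc between the endpoints that passes through −90°, with closed
  endpoints — this makes the published wrapped interval −7°…−124°
  unambiguous.
* `compare_groups()` provides the pooled-variance t-test and one-way
  ANOVA with Student–Newman–Keuls (step-down studentized range, with
  non-significance blocking) or Tukey HSD post hocs, starred at
  0.05/0.01/0.001. A caveat found while testing: at the published QT
  group means and SEMs (n = 30 per group), the two-sided t-test's power
  is only ≈ 2/3 at α = 0.05 — the published P = 0.004 sits in the lucky
  tail of that distribution — so the test suite asserts detection in at
  least half of seeded replicates rather than near-certain detection.

## Dosage-group classification

Direction calls per aneuploid genotype use the fold-change band: up if
ratio > 1.2, down if < 0.8, normal otherwise ("close to 1.0" is
operationalized as the complement of the thresholds). The seven groups are
defined by the *subset* of genotypes deregulated — {Ts65Dn, compound} = G1
(trisomy-driven, persistent), {Ts65Dn, Ms5Yah} = G2 (dosage-compensated),
{Ts65Dn} = G3, {Ms5Yah} = G4, {Ms5Yah, compound} = G5, all three = G6,
{compound} = G7, none = unclassified. Subset-based grouping was chosen
over direction-specific prose definitions because it is total and
non-overlapping across all 27 direction triples (an exhaustive test) while
reproducing every described example, including the down-in-trisomy /
up-in-monosomy compensated genes.

Two classification modes exist because the published tables need both: by
default directions are fold-change-only (the deregulated-gene table lists
unstarred ratios beyond the thresholds, and 94% of its rows match this
rule); with `require_significance = TRUE` an excursion also needs its
significance flag, which is what makes all five qPCR-validated genes land
on the described patterns (one of them has an unstarred 0.74 that the
study treated as normal). Mismatches are reported, never silently
reassigned.

Other conventions: multiple probes per gene are collapsed upstream by the
generator (one row per gene); the trisomic minichromosome is modelled
simply as copy-number-3 annotation regions on Mmu16 and Mmu17 with the
App–Runx1 sub-interval deleted in Ms5Yah (restored to two copies in the
compound); RMA normalization is upstream and out of scope — the module
consumes already-normalized log2 matrices and says so in its I/O
validation.

## The expression generator

Baseline log2 abundances are uniform on [6, 12] for expressed genes and
[2, 5.5] for the below-threshold stratum (default expressed fraction
0.406, the study's observed fraction). Expected ratios versus wild type
are 1.5 for three copies and 0.5 for one copy — the primary dosage effect —
with multiplicative log-normal noise (`sd_log2 = sqrt(log(1+cv²))/log 2`,
default CV 0.1, a typical array replicate CV) and five replicate arrays
per genotype. A configurable fraction of background genes carries trans
effects drawn log-uniformly from [0.6, 1.7] in each aneuploid genotype.
What this emulates well: dosage-proportional shifts, compensation in the
compound, a null background for screen calibration. What it does not:
probe-level effects, correlated co-regulation, batch structure, or
heavy-tailed biological variance — so a green test suite demonstrates
correctness of the computations, not robustness to every pathology of
real arrays.

## Problem sizes and determinism

All randomness flows through explicit integer seeds; identical seeds give
bit-identical recordings, litters and matrices (asserted). The test suite
and the acceptance script size their simulations for a laptop-scale run:
20 s recordings for cohort tests, 60 s for the acceptance cohorts (30
animals per genotype), 5 s recordings for the 20-replicate
cohort-discrimination property, and 1000-gene matrices for screen
calibration. Checkpoint cadence and measurement rules are unchanged by
recording length.

## Known limitations

* The delineation's guarantees are stated for the generator's waveform
  family; real mouse ECG adds baseline wander, electrode artefacts and
  beat-to-beat morphology drift that the generator does not model (the
  optional 1–500 Hz Butterworth band-limit only mimics the acquisition
  bandwidth).
* Vms P- and J-wave amplitudes are biased by the broad T tail of the
  preceding beat (an unavoidable consequence of the published interval
  geometry, QT ≈ RR − 25 ms); their recovery tolerances are documented as
  looser, and P-dependent intervals are measured on DII instead.
* With heavy fragmentation the measured QRS offset (and hence QRS
  duration) reflects the corrupted morphology; interval recovery is
  validated with anomalies disabled, which is a statement about the
  delineator, not about fragmented complexes.
* The frontal-axis recovery under anomaly injection shifts with the
  notch-altered S amplitudes — qualitatively the published picture
  (fragmentation and axis rotation co-occur), but the recovered trisomic
  axis should not be read as an unbiased estimate of the preset target.
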