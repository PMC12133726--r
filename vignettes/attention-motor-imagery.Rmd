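---
title: "Attention-modulated motor-imagery EEG: models, indices and statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-modulated motor-imagery EEG: models, indices and statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnmi)
```

## The problem

During motor imagery (MI), sensorimotor rhythms over the vertex
desynchronize: alpha-band (8–13 Hz) power at Cz drops relative to a
pre-stimulus baseline. How strongly it drops depends on the subject's
attentional state. `attnmi` implements an analysis pipeline for a
key-press paradigm that labels every MI trial as *Attention* (correct
key press) or *Inattention* (incorrect), and quantifies the attentional
modulation three ways:

* **ERD** — event-related desynchronization, the mean of the
  baseline-referenced time–frequency map (ERSP) over the alpha band and
  the 1–5 s imagery window; more negative means stronger
  desynchronization;
* **AMI** — the alpha modulation index
  \((\alpha_{AR}-\alpha_{AW})/(\alpha_{AR}+\alpha_{AW})\), a normalized
  contrast of FFT alpha power at right-frontal F4 between correct- and
  incorrect-response trials;
* **TBR** — the theta/beta energy ratio \(E_\theta / E_\beta\), a
  per-second attention index computable in real time; attention lowers
  it.

Because no public recordings accompany the design, the package ships a
first-class synthetic-data generator whose injected effect sizes are the
ground truth every downstream stage is tested against.

## Paradigm and preprocessing

Each 9-s trial runs Ready (−2 to −1 s), Start (−1 to 0 s), a Select cue
with an arrow key press (0 to 1 s), guided lower-limb imagery (1 to
5 s), and Rest (5 to 7 s); \(t = 0\) at the Select cue. A session is 4
sets of 20 trials. Preprocessing follows the conventional chain:
resample 1,000 → 200 Hz (anti-aliased, zero-phase), band-pass 1–30 Hz
with a forward–backward Butterworth filter (zero phase, so ERD latencies
are not shifted), epoch −2 to +7 s around each cue, and subtract the
−1–0 s baseline mean per trial and channel. Trials with an invalid
response are dropped, never imputed. Where class counts must match (the
AMI contrast), the majority class is subsampled without replacement,
deterministically under a seed.

## Spectral model

Spectral estimates use a periodized orthogonal **wavelet-packet
transform** with the Daubechies "db4" filters and maximum decomposition
level 8, implemented from scratch and verified coefficient-for-
coefficient against an independent reference implementation. Terminal
packet nodes are frequency-ordered; at 200 Hz and level 8 each node
spans 0.39 Hz. Band energies (for the TBR and the invariants) are sums
of squared packet coefficients over the nodes inside the band, after
zero-padding to a dyadic length — the transform is orthonormal, so
energy is conserved exactly.

The ERSP map tiles each epoch with 0.5-s Hann-tapered windows stepped by
0.25 s (a 100-sample window padded to 128 samples reaches level 7,
0.78-Hz rows). Per-trial node energies are averaged across trials and
converted to dB relative to the mean power, per frequency row, of the
windows lying wholly inside the baseline second. ERD averages the map
over the alpha rows and the time bins whose windows lie wholly inside
1–5 s; the same support rule as for the baseline keeps bins straddling
the imagery onset/offset from diluting the mean. Window length trades
time resolution against variance: 1-s windows smear the 1 s and 5 s
transitions enough to bias the window mean by about half a decibel
against the closed-form \(10\log_{10}(1-d)^2\) target, which is why
0.5 s is the default.

Two practical properties of the db4 packet bank are worth knowing.
First, deep-level packet nodes have leaky frequency responses: a pure
10-Hz tone puts only ~76–82% of its energy into the 8–13 Hz rows (the
reference implementation gives the identical figure), with the
remainder mirrored mostly into 14–17 Hz. Sharper `db16`/`db20` banks
(>90% / >95% concentration) are available via the `wavelet` argument
everywhere. Second, because the dB conversion is a per-row *ratio*,
stationary leakage cancels, which is what makes the ERD recoverable at
its closed-form value despite the leakage.

## The synthetic generator

Each channel carries combs of random-phase sinusoids spanning the alpha
(8–13 Hz, 0.25-Hz spacing), theta (4–8 Hz) and beta (13–30 Hz) bands,
riding on \(1/f\) noise scaled so the alpha-band oscillation-to-noise
ratio is `snr_db` (default 20 dB). A comb rather than a single tone is
essential: the ERD window mean covers every alpha row, so the injected
suppression must span the band. Ground-truth effects:

* at Cz the alpha comb is multiplied by \(1-d\) during 1–5 s, with
  per-condition depths \(d\) and a truncated-normal between-subject
  offset (sign flips allowed, mirroring the large spread and occasional
  ERD reversals seen in real cohorts);
* at F4 the alpha comb gets a per-condition gain, generating the AMI;
* theta/beta comb amplitudes are per-condition, setting the target TBR.

Amplitude realism matters less than *statistical stability*: a narrow
band seen through a 1-s window has only a handful of spectral degrees of
freedom, so raw tone interference makes per-window band energy swing by
tens of percent. The generator therefore renormalizes each comb so its
realized band RMS is exact — per second for theta/beta (with fresh
phases per second, joined by 50-ms raised-cosine crossfades to avoid
broadband clicks), per trial for alpha (per-second crossfades would put
amplitude dips inside imagery windows but never baseline windows,
biasing the ERD). These choices mimic the burst-like amplitude and
phase drift of real rhythms while keeping the small calibrated
condition effects resolvable at cohort size.

**Calibration.** The default effect sizes are fitted so that the full
pipeline, run on a default cohort, reproduces the group statistics of
the bundled 14-subject reference tables (`reference_indices()`):
attention ERD ≈ −1.77 dB against ≈ 0 dB for inattention, AMI ≈ −0.042,
TBR ≈ 2.55 vs 2.58. The fit accounts for the measured db4 cross-band
leakage (alpha→beta ≈ 21%, beta→alpha ≈ 3%, theta→alpha ≈ 2%) and the
\(1/f\) noise floor: for example, the per-condition theta amplitudes
solve the band-energy balance including the condition-suppressed alpha
energy that leaks into the beta denominator. Because the depths enter
through a ratio contaminated by unsuppressed leak-in, the calibrated
attention depth (0.254) is larger than the leak-free closed form would
suggest. The generator is *not* a forward head model: channels share
oscillation waveforms (volume-conduction-like correlation) but there is
no dipole geometry, no ocular or muscle artifacts, and no non-
stationarity beyond the per-second amplitude bursts — so passing tests
demonstrate the correctness of the analysis machinery, not robustness
to artifact-laden field recordings.

## The AMI's one-contrast subtlety

Under the key-press rule, "right/wrong selection" coincides with the
Attention/Inattention labels, so only one balanced alpha-power contrast
exists per subject; `subject_ami()` returns that single value and the
cohort tables carry it once. Published per-condition AMI columns cannot
be derived from this labelling without additional, unstated structure,
and the package does not invent one.

## Statistics

Paired t-tests (df = n−1), Pearson correlations with the exact
t-transform p-value, and Shapiro–Wilk normality checks delegate to R's
reference routines. Summary tables print a population-SD row (divisor
N), the convention that reproduces the reference tables' "SDT" rows
exactly.

The **cluster-based permutation test** controls family-wise error over
time–frequency bins (or electrodes): bin-wise paired t-tests, two-sided
forming threshold \(p < 0.05\), clusters of 4-connected (grid) or
graph-adjacent (electrodes) bins of the same t-sign, cluster mass = sum
of t-values, and a null distribution of the maximum |mass| over random
within-subject condition flips (sign flips of the paired differences —
the exact within-subject exchange). Corrected p-values use the
\((1+\#\{null \ge |mass|\})/(n_{perm}+1)\) estimator, so they are
slightly conservative and monotone in |mass|. Zero-variance bins are
assigned t = 0 rather than NaN. The significance mask zeroes
non-significant bins, the standard display rule for masked difference
maps. Electrode adjacency comes from flattened 10/20 coordinates with a
distance threshold chosen to link immediate grid neighbours (mean
degree ≈ 4, single connected component); the edge list is inspectable
via `electrode_adjacency()`.

Per-second online testing Bonferroni-corrects the five 1-s windows
(corrected p = raw p × 5, flagged at 0.01, i.e. α = 0.01/5 on the raw
scale).

One reference-data quirk is reproduced deliberately: the published
offline TBR contrast reports t(13) = 5.12, but the per-subject TBR
columns printed alongside give t(13) ≈ −1.50; `paired_t()` reports what
the data give, and the acceptance suite asserts the discrepancy rather
than reconciling it. Likewise the second reference table's ERD "Mean"
row repeats the first table's value rather than its own column mean;
`build_summary_table()` always recomputes summary rows.

## Online mode

`tbr_online()` consumes 1-s buffers in arrival order with no look-ahead
and routes each through the same band-energy code path as the offline
series, so replaying an epoch's non-overlapping windows reproduces the
offline values bit-for-bit (an exact contract, tested as such). Short
or malformed buffers are skipped with a warning, leaving a gap at that
second. Offline series allow an arbitrary stride for smoother curves;
the online monitor is locked to once per second, matching a 1-s
acquisition buffer.

## Numerical and design choices

* Periodization boundary mode; signals zero-padded to dyadic length
  (adds no energy); effective level `min(maxlevel, log2(n))`.
* Resampling uses an 8th-order zero-phase Butterworth anti-alias filter
  at 80% of the target Nyquist plus linear interpolation onto the new
  grid; only downsampling is supported, and `fs_target = fs` is the
  identity.
* Band membership of packet nodes is half-open \([f_1, f_2)\) on node
  centres; ERSP rows are node centres within the display range.
* ERD time-bin membership is by full window support (see above); an
  empty window errors rather than returning NaN.
* Trial balancing and all permutations take explicit seeds; the
  generator derives one RNG stream per subject so any subject can be
  regenerated alone, and the caller's RNG state is always restored.
* EDF export quantizes to 16 bits with per-channel physical scaling
  (round trip exact to ~1 part in 65,000); events travel in a TSV
  sidecar, and a missing or empty sidecar is a hard error because the
  analysis is trial-based. Processed epochs persist as a plain-text
  TSV + JSON container (`write_epochs()`/`read_epochs()`).

## Validation scales

The shipped validation suite runs at desk scale, chosen to finish in
minutes while leaving the conclusions stable across seeds: the
closed-form ERD recovery uses 14 subjects × 20 trials at 200 Hz with
the theta/beta combs off (an isolated alpha-suppression experiment —
constant theta/beta tones would add an unsuppressed leak-in floor that
biases the closed-form comparison); the permutation-calibration study
uses 200 null cohorts of 14 subjects on a reduced 20 × 13
time–frequency grid with 500 permutations; the electrode-localization
study uses 50 cohorts with spatially correlated (volume-conduction-
like) electrode noise — with independent noise, the probability that no
neighbouring electrode crosses the forming threshold with the effect's
sign is bounded near 86%, so correlated noise is both the physically
realistic model and the one under which exact-set recovery is
achievable.

## Limitations

* No ICA/artifact pipeline: the generator makes artifact-free signals,
  and artifact removal is deliberately out of scope (an optional hook
  can pass data through an external implementation).
* db4 packet leakage caps single-tone band concentration near 80%;
  results that depend on absolute (rather than ratio) band energies
  inherit a leakage-dependent bias that the calibration absorbs but a
  different wavelet choice would change.
* The AMI is a single contrast per subject (see above).
* The electrode "montage" is a schematic flattened layout, adequate for
  adjacency and display, not for source analysis.
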