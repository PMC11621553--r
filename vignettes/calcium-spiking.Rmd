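---
title: "Quantifying nuclear calcium spiking: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear calcium spiking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calspike)
```

`calspike` turns single-nucleus calcium-indicator fluorescence traces into
per-nucleus spiking frequencies and amplitudes, quantifies fluorescence in
regions of interest on confocal stacks, and runs a fixed, auditable
statistical decision procedure on the resulting tables. This vignette is
the package's account of the underlying models, the parameters that
matter, and the choices made where the design was genuinely open.

## The SNR transform and peak calling

A trace is a series $F_t$ sampled at a fixed interval (default
$\Delta t = 5$ s, the typical confocal time-series setting; acquisitions
of 10–15 min are common). For each sample the local baseline averages the
four samples 10 s and 15 s away on both sides,

$$B_t = \tfrac14\,(F_{t-15\,\mathrm{s}} + F_{t-10\,\mathrm{s}} +
F_{t+10\,\mathrm{s}} + F_{t+15\,\mathrm{s}}),$$

and the signal-to-noise ratio is $\mathrm{SNR}_t = (F_t - B_t)/B_t$.
Because the window is symmetric, any locally affine trend cancels exactly:
`compute_snr()` returns identically zero on affine traces, and slow
exponential photobleaching (time constant $\geq 100\,\Delta t$) stays well
below the peak threshold. Two design points:

* **Relative versus absolute.** The quantity is a *difference* divided by
  the baseline. The relative form is the default because the fixed,
  unitless peak threshold of 0.3 only makes sense scale-free; an absolute
  mode ($F_t - B_t$) is kept as an option for users who calibrate
  intensities.
* **Edges.** The first and last three samples (for $\Delta t = 5$ s) have
  no complete baseline window. SNR is undefined there and those samples
  are excluded — no partial-window fallback — to avoid edge artefacts.
  Any $\Delta t$ that divides both 10 s and 15 s exactly is supported;
  other intervals are rejected rather than interpolated.

`detect_peaks()` defines a peak as a *maximal run* of consecutive samples
with $\mathrm{SNR} \geq \theta$ (default $\theta = 0.3$); the apex is the
run maximum, with ties resolved to the earliest sample. The comparison is
inclusive ($\geq$), so a single sample exactly at threshold is a peak.
No prominence or minimum-separation rule is applied beyond the requirement
that distinct runs be separated by at least one sub-threshold sample;
adding one would silently change frequencies, and the simple rule is fully
auditable.

Per nucleus, `summarize_nucleus()` reports the peak count, the frequency
rescaled to a 10-minute window as $n_\text{peaks} \cdot 600 / ((N-1)\Delta t)$
(acquisition lengths vary, so raw counts are not comparable), the
amplitude as the mean of peak apex SNRs (undefined when no peak was
called), and the spiking classification: a nucleus is *spiking* when its
frequency strictly exceeds 2 peaks per 10 min. Non-spiking nuclei stay in
the frequency table with frequency 0 but drop out of the amplitude table,
so the amplitude sample size is always at most the frequency one.

## ROI quantification on stacks

`select_substack()`, `project_stack()`, `threshold_mask()` and
`mean_gray()` implement the standard two-projection protocol for
quantifying a fluorescent fusion in a cytoplasmic region: choose the 4–6
sections that encompass the structure, build the ROI mask by automatic
thresholding of the **maximum** projection (foreground is bright on a dark
background, so the mask is `pixels >= threshold`), then measure the mean
grey value inside that mask on the **mean** projection of the same
sub-stack. The default automatic threshold is isodata (Ridler–Calvard
iterative intermeans, the historical ImageJ default family); Otsu and a
fixed cutoff are available, and the chosen threshold is always attached to
the mask. No morphological clean-up is applied by default. Uniform images
make automatic thresholds undefined and raise an error instead of
guessing. `extract_trace()` applies `mean_gray()` frame-by-frame to a
time-lapse stack, producing a trace ready for `compute_snr()`.

## The statistical decision procedure

`choose_and_run()` fixes the whole test-selection path so that two
analysts cannot reach different tests from the same table:

1. Shapiro–Wilk normality per group at $\alpha = 0.05$. The gate level is
   also used for the variance gate; fixing both at 5 % makes the
   procedure deterministic.
2. If any group fails, a log₁₀ transform is tried, then a Box-Cox power
   transform $(x^\lambda - 1)/\lambda$ with $\lambda$ fitted by profile
   maximum likelihood on the one-way model (a single $\lambda$ shared by
   all groups), re-testing normality after each. Both transforms require
   strictly positive data and are skipped (and logged) otherwise. Log
   first, Box-Cox second: the simpler, parameter-free transform should
   win when both work.
3. Normal data pass a variance gate: F test for two groups, Bartlett for
   more. Two homoscedastic groups get Student's t; heteroscedastic pairs
   get Welch's t; three or more homoscedastic groups get one-way ANOVA
   followed by Tukey HSD (with a compact letter display). Data that stay
   non-normal go to Mann-Whitney (2 groups) or Kruskal–Wallis (≥ 3). The
   parametric menu contains no Welch-type ANOVA, so three or more normal
   but heteroscedastic groups also fall back to Kruskal–Wallis.
4. Groups with $n < 3$ cannot be normality-tested at all; the procedure
   warns and goes nonparametric directly.

Every gate (test, p, outcome, transform and fitted $\lambda$) is recorded
in the result's `audit` table. On null normal data the full procedure —
gates included — holds its nominal 5 % type-I error (checked over 1000
replicates in the test suite).

Conventions worth making explicit:

* **Mann-Whitney.** $W$ is the U statistic of the first-listed group
  (rank sum minus $n_1(n_1+1)/2$). The exact null distribution is used
  when $n_1 + n_2 \leq 50$ and there are no ties — small-sample p-values
  reported alongside small printed $W$ values imply an exact method —
  otherwise the normal approximation with tie correction and (by default,
  toggleable) a continuity correction. `p_from_w()` recomputes a p-value
  from a reported $W$ and the group sizes alone; with no access to the tie
  structure it applies no tie correction, which at a few hundred
  observations per group changes nothing at the printed precision.
* **Two-tailed exact p-values** double the smaller tail and cap at 1
  (Mann-Whitney), or sum all tables at most as probable as the observed
  one (Fisher's exact, the minimum-likelihood rule used by the common
  tools).
* **One-tailed t** is the upper-tail probability of the observed $t$ —
  appropriate when a direction was pre-specified and samples are small.

## The synthetic-data generator

`simulate_trace()` draws from the signal model

$$F(t) = F_0\, e^{-t/\tau_b}\Bigl(1 + \sum_k A\, g(t - t_k)\Bigr) +
\varepsilon_t, \qquad \varepsilon_t \sim N(0, (\sigma F_0)^2),$$

where $g$ rises linearly over `rise_samples` sampling intervals (default
1 — at 5 s sampling, observed calcium transients reach their apex within
about one sample) and decays exponentially with $\tau_d$ = `decay_tau`
(default 15 s, a plausible but uncalibrated value for a red
single-fluorophore calcium sensor in plant nuclei; no published kinetics
exist for this exact setting). Noise is additive and scaled to the resting
fluorescence — adequate at this scale and analytically convenient, though
real photon noise is signal-dependent (see Limitations). Negative values
are clipped at zero, as a detector would.

Spike apex times are a **hard-core point process**: the number of events
is drawn as Poisson with mean `spike_rate · duration / 600`, and apexes
are placed uniformly on the sampling grid under a minimum gap of
`refractory` seconds (default 20 s), by sequential rejection. A simpler
alternative — homogeneous Poisson arrivals thinned by the refractory
period — systematically depresses the realised rate (by ~20 % at 8 spikes
per 10 min), which would break the calibration between the `spike_rate`
parameter and the generated ground truth; drawing the count first keeps
the long-run mean count exactly at `rate · duration / 600` while
preserving the refractory gap. Apexes are snapped to the sampling grid and
restricted to the interior window in which the SNR baseline exists (three
samples from each end): an apex in the first or last 15 s is undetectable
*by construction*, and placing events there would make ground-truth
recovery statements ill-posed rather than informative.

`simulate_cohort()` draws per-nucleus spike rates and amplitudes from
truncated normal distributions and assigns a fixed fraction of spikers;
non-spikers are generated with rate 0. Defaults (rate 8 ± 1 per 10 min,
amplitude 0.6 ± 0.05, noise σ = 0.02, i.e. 2 % of resting fluorescence)
emulate a clearly-spiking cohort under moderate detector noise.
`simulate_stack()` builds constant-background stacks with known foreground
masks for the image pipeline.

What the generator deliberately does **not** emulate: optical blur (PSF),
nuclear movement, signal-dependent (Poisson) photon noise, baseline drift
other than exponential bleaching, and amplitude variation between spikes
of one nucleus. Passing tests therefore demonstrate that the analysis
chain is correct *given* traces of this structure — not that it is robust
to every artefact of real acquisitions.

## Validation problem sizes

The test suite checks the shipped SNR/peak implementation against a naive
direct-loop oracle on 1000 random traces; exact Mann-Whitney against
brute-force enumeration of all labelings for every group-size split with
$n_1+n_2 \leq 10$; Fisher's exact against hypergeometric enumeration;
spike recovery over 100 seeded traces (rate 8 per 10 min, amplitude 0.6,
noise 2 %); amplitude-difference power over 100 two-cohort replicates
($n = 30$ per group); the decision tree's type-I error over 1000 null
replicates ($n = 30$ per group); and Kruskal–Wallis calibration over 2000
permutations. These sizes give sampling errors comfortably below the
asserted tolerances while keeping the default test run quick.

## Known limitations

* **Near-threshold detection censoring.** A spike whose clean apex SNR
  sits near $\theta = 0.3$ is detected only when noise pushes it over the
  line. With the default decay ($\tau_d = 15$ s), baseline contamination
  makes the apex SNR of an isolated spike
  $0.78\,A/(1 + 0.22\,A)$ — about 0.32 for $A = 0.45$ — so cohorts whose
  amplitudes approach the threshold lose a substantial fraction of their
  spikes, and spikes closer than ~30 s suppress each other's baselines
  enough to be lost even without noise. The measured *frequency* of a
  low-amplitude cohort is therefore biased downward: an amplitude
  difference between groups can masquerade as a frequency difference.
  This is a property of fixed-threshold SNR peak calling itself, not of
  the implementation; interpret frequency comparisons between groups of
  very different amplitude with care.
* **Refractory-scale clustering.** Ground-truth spikes 20–30 s apart can
  merge into one supra-threshold run or suppress one another; one-to-one
  recovery is guaranteed only for spikes separated by more than 30 s
  (twice the baseline half-width).
* **Box-Cox identifiability.** For near-symmetric positive data with a
  small coefficient of variation the profile likelihood is almost flat in
  $\lambda$; the fitted value is then arbitrary within a wide range
  (harmless, since any such $\lambda$ leaves the data close to normal,
  but do not interpret the number).
* The image module quantifies intensities on 2D projections; it does no
  3D segmentation, deconvolution, or learned pixel classification.
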