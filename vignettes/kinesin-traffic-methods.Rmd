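---
title: "Models and methods: kinesin traffic, profile inference, and dynamic instability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: kinesin traffic, profile inference, and dynamic instability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kip2traffic)
```

## The biological problem

The budding-yeast kinesin Kip2 walks along astral microtubules toward
their plus-ends, where it promotes polymerization. Its distribution along
a microtubule in a living cell is shaped by five elementary processes:
entry at the spindle-pole-body (SPB)-anchored minus-end, landing anywhere
on the lattice, detachment from the lattice, stepping toward the
plus-end, and detachment from the plus-end. `kip2traffic` implements this
five-rate traffic model, the fluorescence-profile pipeline that connects
it to line-scan microscopy data, a likelihood-sampling estimator for the
rates, and the 3D dynamic-instability quantification used for astral
microtubule tracks — together with ground-truthed synthetic-data
generators so that every stage is testable without microscopy data.

## The traffic model

The microtubule is a 1-D lattice of 8 nm sites (one tubulin dimer along a
protofilament, the motor's step), with hard exclusion: at most one motor
per site. With free motor concentration $c$ (nM):

* entry at site 1 with propensity $k_{in} c$ if site 1 is empty;
* landing on any empty site with $k_{on} c$ per site;
* hop $i \to i+1$ with $k_{step}$ if site $i+1$ is empty;
* lattice detachment with $k_{off}$;
* plus-end detachment with $k_{out}$, which *replaces* $k_{off}$ at the
  terminal site (the plus-end is a chemically distinct state; an additive
  mode is available via `terminal_additive`).

This is a totally asymmetric simple exclusion process (TASEP) with
Langmuir kinetics, open boundaries, and a finite particle reservoir. The
free concentration obeys conservation of matter,
$c = \max(0,\, T - n_{bound}\, n_{MT} / (N_A V))$, with $T$ the total
concentration, $V$ the effective cytoplasmic pool volume in fL, and
$n_{MT}$ lattices sharing the pool (1 nM in 1 fL is about 0.602
molecules).

Default parameter values are the reference in-silico set:
$k_{on} = 6.1\times10^{-4}$ and $k_{in} = 0.31$ (nM s)$^{-1}$,
$k_{off} = 2.3\times10^{-2}$ s$^{-1}$, $T = 35$ nM. The stepping rate is
fixed from the measured speckle speed, $6.3\,\mu m/min \div 8\,nm =
13.125$ s$^{-1}$; plus-end residence below 0.3 s gives
$k_{out} = 3.3$ s$^{-1}$ in vivo, while the in-vitro residence of ~30 s
corresponds to $k_{out} = 1/30$ s$^{-1}$ — a regime in which the model
predicts motor queues ("traffic jams") at plus-ends, which
`simulate_kymograph()` reproduces.

**Pool volume.** No cytoplasmic volume is printed alongside the reference
rates, so the default is a package choice. We set $V = 3$ fL. The choice
matters: at 1 fL the pool depletes so strongly ($c \approx 2.7$ nM) that
lattice landing gain $k_{on}c(1-\rho)$ almost exactly cancels detachment
loss $k_{off}\rho$ and the shaft density profile is flat — contradicting
the observed rising Kip2 intensity along microtubule shafts and making
$k_{on}$ and $k_{off}$ mutually unidentifiable. At 3 fL the same rates
give rising shaft profiles, a distinct tip accumulation, no traffic jam,
and strong length-dependent pool depletion (free concentration varies
almost two-fold between 0.9 and 2.3 um microtubules), which is the
feature that identifies the total concentration. Much larger volumes push
the lattice toward jamming at these rates. The volume remains a
configuration field.

### Solvers

Three implementations with complementary roles:

* `gillespie_simulate()` — exact stochastic simulation (direct method,
  compiled), with snapshots, time-averaged occupancies, event logs and a
  plus-end residence-time extractor. Exclusion is asserted per event.
* `master_equation_stationary()` — the exact stationary distribution of
  the $2^n$-state Markov chain (sparse generator, null-space solve),
  limited to 14 sites, with the pool held unlimited so the chain has
  fixed rates. This is the oracle the other two are tested against.
* `mean_field_steady_state()` — the first-order (mean-field) closure
  solved to a residual max-norm of `tol` (default 1e-10). The solver runs
  damped Gauss–Seidel sweeps into the basin and then damped Newton on the
  full system; the Jacobian is tridiagonal plus a rank-one pool term and
  is solved by the Thomas algorithm with a Sherman–Morrison correction.
  A pseudo-time integration fallback guards pathological corners. Warm
  starts (previous solutions) are threaded through the likelihood, so an
  MCMC evaluation costs a fraction of a millisecond per lattice.

Mean-field is exact in the dilute limit and accurate to a few percent at
the occupancies relevant here (tested against the master equation); the
parameter estimation uses it as its forward model, as the per-bin mean
profiles it must reproduce are themselves averages over many cells.

## From occupancy to fluorescence profiles

`occupancy_to_profile()` converts per-site occupancies into pixel
intensities on the 133.35 nm grid of the line scans (2 pixels = 266.7 nm,
the length-bin width). Pixel windows are anchored at the plus-end,
mirroring the acquisition convention of scanning from the plus-end toward
the SPB; the tip pixel therefore integrates a full pixel of polymer and
the partial window falls at the minus-end. Intensity is
`background + scale * (motor mass per pixel)`, optionally blurred by a
Gaussian PSF (mass-preserving; default off, because the estimation
operates on mass-per-pixel profiles). The map is linear in occupancy.

Measured line scans are aligned by `align_to_reference_peak()` (mCherry
SPB-marker peak to position 0; the GFP peak defines the plus-end; profile
length is the peak-to-peak distance) and grouped by
`bin_by_length()` into the canonical 266.7 nm length bins
(0.80–1.07, 1.07–1.33, ... 2.13–2.40 um), with per-position means and
95% confidence intervals. `plus_end_regression()` fits the weighted
least-squares line of per-bin plus-end intensity against bin-centre
length.

## Parameter estimation

`log_likelihood()` compares a binned dataset with the mean-field forward
model. Per bin, the model is evaluated at the pixel-quantized measured
member lengths (a mixture over the at most ~3 distinct lengths per bin,
weighted by member counts) rather than a single bin-centre length; pixel
windows follow the plus-end-anchored convention above. The SPB pixel
(aligned position 0) is excluded — it covers a variable partial window of
polymer and coincides with the pole marker — and only the canonical
0.8–2.4 um bins enter the fit.

Residuals are standardized by the per-bin standard error of the mean.
Two covariance subtleties matter:

* **Intensity scale.** The default treats the intensity per motor as a
  known photometric calibration (`scale = 1`, matching data acquired
  without normalization) and profiles only the additive background by
  weighted least squares. With a *free* multiplicative scale the total
  concentration is structurally unidentifiable from below: pool depletion
  is proportional ($c(L) \approx T/(1+\beta(L))$ with $\beta$ independent
  of $T$), so rescaling $T$ is absorbed exactly by the scale. Profiling
  the scale remains available (`scale = NULL`) for relative-intensity
  data, with this caveat documented.
* **Cell-to-cell variability.** Cells differ in expression level; the
  generator models this as a lognormal per-cell scale factor (CV 0.2).
  Within a bin, every position averages the *same* cells, so per-bin mean
  residuals are correlated across positions. The likelihood therefore
  adds a per-bin rank-one covariance term $\lambda u u^T$
  ($\lambda = CV^2/n_{bin}$, $u$ the predicted signal), evaluated with
  Sherman–Morrison. Without it, the independent-Gaussian approximation
  over-resolves coherent bin-amplitude fluctuations and displaces the
  estimate along a soft parameter ridge; in calibration runs this term
  took 95%-interval coverage from roughly 60–90% to 10/10 replicates.
  `scale_cv = 0` restores plain independent Gaussians.

`sample_likelihood()` draws from the likelihood over bounded log-uniform
ranges (at least three decades per rate) with an affine-invariant
ensemble sampler (stretch moves) in log10 space: random search, diverse
multi-start Nelder–Mead, a moderately overdispersed walker ball, burn-in,
then 20,000 retained draws by default. `k_step` and `k_out` stay fixed
unless ranges are supplied for them — plus-end profiles constrain the
landing and exit kinetics far better than the stepping speed, which is
anchored to the measured speckle speed instead. Results carry acceptance
rate, split-chain $\hat R$, and an identifiability ratio per parameter
(posterior 95% width over prior range width, log10 units), since
uncertainty can reflect either noise or limited identifiability.
`summarize_samples()` reports medians, IQR, 1.5 IQR whiskers, 95%
intervals and kernel density estimates; `compare_parameters()` resamples
the difference of medians between two fits; `fit_genotype()` runs the
whole estimation with provenance.

## Dynamic-instability quantification

`length_series()` is the per-frame 3D Euclidean distance between plus-end
and proximal SPB. Cells with spindles longer than 2 um are excluded
(strictly greater); lengths at or below the 666.7 nm detection limit
(5 pixels) are censored, and a never-detectable track reports a maximum
length of 0 um. Lifetime is the longest contiguous detectable span times
the 1.07 s frame interval (isolated single-frame detections are treated
as noise); the acquisition window is 80 frames = 85.6 s.

`segment_phases()` replaces manual phase annotation with exact penalized
piecewise-linear partitioning (dynamic programming on least-squares
segment costs; penalty $3\hat\sigma^2\log n$ per segment, with
$\hat\sigma$ estimated from the MAD of second differences). Adjacent
same-direction segments are merged; direction changes whose
least-squares-fitted displacement is below 0.3 um, or whose duration is
below 3 frames, are not counted (sub-threshold terminal segments are
dropped — a truncated recording tail is not a countable phase — and
interior wiggles are split between their neighbours). Each switch frame
is then refined by a local two-line SSE scan. Growth-to-shrinkage
transitions are catastrophes, the reverse are rescues;
`event_frequencies()` normalizes them per minute of growth and shrinkage
time respectively (a standard convention; frequencies with zero time in
state are reported as absent). On noiseless piecewise-linear tracks the
segmentation recovers switch frames and phase speeds exactly; at 50 nm
per-axis localization noise it recovers 90–98% of switches whose
flanking phases meet the stated conventions to within two frames
(measured across seven 100-track replicates).

## Synthetic data

`generate_profiles()` draws microtubule lengths uniformly over
0.8–2.4 um (the canonical bin span), solves the mean-field steady state
at the true rates, renders pixels through `occupancy_to_profile()`,
applies a lognormal per-cell intensity scale (mean 1, CV 0.2), adds a
constant background (0.2 a.u.) and Gaussian pixel noise (SD 0.05 a.u.,
about 5% of the shaft signal — the scale of residual pixel noise after
averaging over a 5-pixel-wide scan line), attaches a diffraction-limited
mCherry SPB marker at the true sub-pixel pole position, and pads
background margin pixels with a random integer-pixel scan offset so that
alignment is genuinely exercised. `generate_tracks()` draws two-state
telegraph trajectories (growth/shrinkage with exponential switching,
reflecting at zero), embeds them in 3D with a slowly pivoting direction
and a fixed SPB pair, and adds independent Gaussian localization noise
per axis to all three tracked points. Both generators emit the exact CSV
dialects the analysis consumes plus a versioned ground-truth JSON
sidecar, and are byte-deterministic under their seeds.

Track-generator defaults (growth 2.0, shrinkage 3.0 um/min; catastrophe
and rescue 1.0 min$^{-1}$; 50 nm noise; 80 frames at 1.07 s) are chosen
at the scale of in-vivo astral-microtubule measurements. What the
synthetic data do *not* emulate: pivoting-induced tracking failures,
bent microtubules, photobleaching, background structure, or nonuniform
length distributions — so passing tests demonstrate correctness of the
analysis under the stated statistical model, not robustness to every
imaging pathology.

## Study sizes and numerical choices

The package's own validation experiments (in its test suite) use: 500
synthetic cells and 20,000 likelihood samples for the headline
parameter-recovery study; ten 200-cell replicates with 2,000 samples for
interval calibration; 100 tracks per segmentation replicate; stochastic
lattices up to 2.3 um simulated for 600 s with the second half treated
as stationary. Mean-field tolerance is 1e-10 by default and 1e-8 inside
the sampler; the master-equation oracle is used up to 6 sites in tests
(hard limit 14). Ties in peak detection break toward the scan start; the
sub-pixel SPB offset makes alignment exact on the integer-pixel grid.

## Known limitations

* The mean-field forward model is approximate at high occupancy; the
  estimation is therefore calibrated for the no-jam regime it operates
  in (the stochastic simulator covers the jammed regime).
* The ensemble sampler mixes slowly along the soft
  $(k_{on}, k_{in}, k_{off}, T)$ ridge at small sample sizes; split-chain
  $\hat R$ is reported and should be checked before quoting intervals.
* Single-protofilament lattice; no motor-motor interactions beyond
  exclusion; microtubule length is fixed during a traffic simulation.
* The likelihood is a documented reconstruction (Gaussian with a
  rank-one scale term), not a claim of equivalence to any particular
  published fitting code.
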