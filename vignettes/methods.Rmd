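---
title: "Methods: model, FC states, stimulation and prediction in dynastim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model, FC states, stimulation and prediction in dynastim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dynastim` simulates a whole-brain network of oscillatory neural masses,
extracts discrete dynamic functional-connectivity (FC) states from its
resting activity, measures how a phased single pulse shifts ongoing
oscillations or switches the FC state, and quantifies how much knowing the
FC state improves prediction of the induced phase shift. This vignette is
the package's own account of the science and of every choice that was
genuinely open.

## The network model

Each region is an exact mean-field reduction of a large population of
quadratic integrate-and-fire neurons, one excitatory (E) and one
inhibitory (I) population per region, locally wired as a PING loop (E
drives I through `J_ie`, I inhibits E through `J_ei`; the local recurrent
weights `J_ee`, `J_ii` default to 0 — see below). Each population carries
four state variables: firing rate `r`, mean membrane potential `V`, and
its two incoming synaptic activations, eight per region in total. The E
rate of every region reaches all its structural targets instantaneously;
long-range excitation enters both the target's E population (gain `G_ee`)
and its I population (gain `Gamma * G_ee`, `Gamma = 5`), the disynaptic
feed-forward inhibition motif.

Defaults (`nm_params()`): `Delta_e = Delta_i = 1` (Lorentzian
heterogeneity half-width), `eta_e = eta_i = -5` (mean background
currents), `tau_e = tau_i = 10`, `tau_s = 1` (time constants, model time
units), `J_ei = J_ie = 19`, `Gamma = 5`. The two global parameters
explored when mapping regimes are the coupling `G_ee` and the homogeneous
drive `I_ext`; the default working point is `G_ee = 80`, `I_ext = 6`.

Open choices resolved here:

* **`J_ee`, `J_ii`** appear in the synaptic equations but no values are
  given anywhere for them; the canonical pure-PING reading sets both to 0.
  Both are configurable.
* The printed prefactor of the I-population potential equation is read as
  `1/tau_i` (a transcription slip for `1/tau_e`); at the identical default
  time constants this has no numerical effect.
* Long-range coupling is instantaneous; a `(t-1)` decoration on the
  coupling sums is treated as a typographical remnant of a discretized
  implementation.

Integration is the deterministic Heun predictor–corrector at
`dt = 5e-5`, downsampled by 200 (sampling interval 0.01), with a
400-sample transient discarded and 3,000 samples kept per resting run, 13
runs from random initial conditions. The initial-condition distribution is
not specified by the protocol this reproduces; we draw rates uniform on
[0, 0.5], potentials uniform on [-2, 0], synaptic variables 0 — bounded
and regime-agnostic, with every draw seeded. Exact trajectories are
therefore not reproduced, only the ensemble design. The integrator is
compiled (Rcpp); a pure-R derivative function and Heun stepper are
exported and serve as the independent reference implementation in the test
suite (the two paths agree to machine precision). The very small `dt` is
not decorative: at the working point the network generates brief
large-amplitude population spikes, and at `dt = 5e-5` the integration sits
close to its stability edge (scaling the connectome by a further ~40%
produces numerical blow-up unless `dt` is reduced).

## The surrogate connectome and its calibration

The original input is a dense, weighted, directed retrograde-tracing
connectome over 29 macaque areas that we cannot redistribute, so
`generate_connectome()` emulates its statistics: 66% of off-diagonal
entries nonzero, heavy-tailed log-normal weights (`sdlog = 1.5`, spanning
several decades as tracer counts do), asymmetric, zero diagonal. Weights
are row-normalized (incoming sum) like fraction-of-labeled-neurons data
and then scaled by a common total in-strength.

That scale is the one genuinely free number, because no SC normalization
is stated for the original study and the published weights' scale is
unknown. It was calibrated once, before any test was frozen, so that the
prescribed working point reproduces the *described* regime rather than an
arbitrary one: an isolated region here is a damped focus, and the network
only sustains collective oscillations when the effective coupling
`G_ee * in_strength` exceeds a Hopf-like onset near 110. With
`in_strength = 4` (the default), `G_ee = 80` places the model in the
partially synchronized oscillatory regime where the network-average PLV is
about 0.75 — the synchrony-peak "cusp" the working point was chosen on —
while staying clear of the numerical stability edge. The realized
oscillation period at this point is ~36-37 samples (0.36-0.37 time
units), i.e. roughly 3.8 cycles per 140-sample analysis window. The
protocol's claim of "at least 50 cycles" per window would imply 2.8
samples per cycle, which no trough-based phase extraction can resolve;
the two statements cannot both hold, and we keep the resolvable regime.

What the surrogate does not reproduce: the real connectome's geometry and
weight values, and its degree of *metastability*. Our working point's
top-quartile pairs are nearly perfectly locked (PLV_top ≈ 0.97 vs the
reported ≈ 0.89), because the surrogate's transient locking
configurations are deeper attractors — different initial conditions
settle into different configurations, but a configuration de-coheres
little within a run. Two consequences are documented rather than hidden:
PLV_top runs high, and single pulses at amplitude 300, while producing
clear phase shifts, essentially never *cause* state switching beyond the
spontaneous rate (delta-P ≈ 0 in reduced designs; spontaneous switching
does occur and the full exclusion accounting is exercised). Both are
properties of the unavailable connectome's dynamics, not of the pipeline.

## Phases, PLV and regime metrics

Instantaneous phase is anchored at oscillation troughs: 0 at each trough,
linear to 2π at the next, undefined outside the first/last trough. This
removes amplitude modulation by construction. Troughs are strict local
minima at least 3 samples apart. A minimum-prominence filter is available
but defaults to 0: the model is noiseless and deterministic, so every
local minimum is a genuine trough, whereas a range-relative prominence
cutoff (a natural default for noisy data) is poisoned by the rare
population spikes, whose amplitude exceeds typical cycles by orders of
magnitude and which would discard most genuine troughs.

`PLV(j,k)` is the modulus of the time-averaged `exp(i(phi_j - phi_k))`
over commonly valid samples (at least 10 by default). `PLV_all` averages
the 406 unique pairs; `PLV_top` the `ceiling(0.25 * 406) = 102` largest.
Rate metrics use population (divide-by-N) standard deviations, matching
their defining sums; zero means yield `NaN` with a warning, never a
fabricated value. `sweep_regimes()` runs one seeded simulation per grid
point and records blow-ups as failed rows instead of aborting the sweep.

## Windowed FC, hubs, lags and states

Sliding windows are 140 samples at 75% overlap (stride 35; 82 windows per
3,000-sample run, 1,066 across 13 runs). Per window, the PLV matrix is
computed from the run-level phases. A single global link threshold — the
54th percentile (linear interpolation between order statistics,
`quantile` type 7) of the per-link *median* windowed PLV — binarizes every
window; binarization keeps links *at or above* the threshold, so a
threshold that falls exactly on the strong mode of a bimodal distribution
retains that mode. Hubness is the degree in the binarized window graph;
hubs are regions at or above the hub threshold.

The hub threshold is a calibration parameter, not a constant: the
published value 21 was chosen (their supplementary criterion) so that hub
assignment exists but varies across windows. Applied verbatim to the
surrogate — whose 3.8-cycles-per-window PLVs are much more uniform —
threshold 21 leaves three quarters of windows with no hubs at all and
empties the stable-hub set. The same criterion applied to the surrogate's
hubness distribution selects 14 (99% of windows keep at least one hub,
none saturates, across-window variance is maximal), and the working-point
analyses in the tests use it; 21 remains the function default and the
full-scale configuration value.

Phase lags are estimated from the cross-correlogram of the two raw rate
segments: lag = latency of the first off-zero peak divided by the
first-to-second peak interval (the realized period), modulo 1, with
parabolic sub-sample refinement; `lag(x, y)` is the fraction of a period
by which `y` trails `x`. Peaks are located on the raw taper-corrected
correlogram; the Fourier-space low-pass (cutoff 3x the dominant
frequency) is applied only as a fallback when raw detection fails, because
on clean few-cycle segments the smoothing itself shifts peak positions by
up to 0.1 cycles (verified against a brute-force correlogram oracle).
Lags are computed only between *stable hubs* — regions that are a hub at
least once in every hub cluster.

Windows are clustered twice (Ward linkage, Euclidean distance — the
algorithm is named in the protocol, metric and linkage are not): once on
binary hub vectors (5 clusters) and once on lag vectors embedded as
`(cos 2π λ, sin 2π λ)` per pair to respect the 0/1 wrap (4 clusters). A
mean-silhouette report over a configurable range of cluster counts
accompanies each cut. The three most populated cells of the hub-by-lag
contingency table (ties broken by hub id then lag id, logged) become
Psi1–Psi3 in size order; everything else is "None". Window typicality is
the sum of the two silhouette widths (range [-2, 2]); the 100 highest per
state become prototypes (all windows, with a warning, if a state is
smaller). The k-nearest-neighbour classifier (k = 50, capped at the
prototype count) operates in the concatenated hub + lag-embedding space —
the same spaces the clusterings used, since the original feature space is
unstated — with Euclidean distance; ties are broken by smaller mean
neighbour distance, then fixed label order. Undefined lag entries of a
query are imputed with the prototype-set mean embedding and flagged.

## Stimulation

Because the model is deterministic, the phase at which a pulse lands is
known in advance from the unstimulated trajectory. Pulses are rectangular
currents of amplitude 300 (configurable) lasting one sampling interval
(0.01 time units = 200 integration steps; the effective width of the
"Dirac" pulse is unstated, so it is configurable), injected into the
membrane-potential equations of both populations of one region. Each trial
restarts the integration from the stored full network state just before
onset and runs a stimulated and an amplitude-0 member; their pre-pulse
histories are bitwise identical, and tests assert the full null chain
(identical members, zero portraits, zero PRC, zero delta-P) at amplitude
0. The design crosses 10 phases spanning [0, 2π), the 5 most typical
prototype windows per state and 5 consecutive cycles per window (25
trials per region-state-phase cell; 750 per region; 4,500 for the 6-region
design); prototype windows too close to the run end to fit the 500-sample
post-stimulation horizon are skipped in favour of the next most typical.

Phase-shift portraits are `wrap(phi_stim - phi_unstim)` per affected
region and post-stimulation sample, wrapped into [-π/2, π/2) modulo π
(a -0.7π shift *is* a +0.3π shift for an ongoing oscillation). Averages
of wrapped shifts are doubled-angle circular means — the correct complex-
plane average for π-periodic data; the π/2 boundary maps to -π/2 by
convention, and an ordinary 2π-periodic mean is available via
`circ_mean(..., period = "2pi")`. The effective PRC averages each trial's
late-window (samples 361–500) shift over trials whose stimulated member
still classifies to the starting state; excluded (switched) and failed
trials are counted, and empty bins stay `NA`. The starting state is the
catalog label of the stimulated window (ground truth); only end states
use the classifier. SEM is the circular standard deviation over retained
trials divided by sqrt(n). Switching statistics subtract the matched
unstimulated member's spontaneous switch probability; any end label
different from the start — including "None" — counts as a switch, with
"None" landings also reported separately.

## Prediction

The late-window shift of each affected region is embedded as
`(cos Δφ, sin Δφ)` and each output dimension is fit by a random forest
(100 trees — unstated in the protocol, fixed and seeded here — with the
stated depth cap of 5). "Tenfold cross-validation with a training size of
70%" is internally inconsistent with classic 10-fold; we implement 10
repeated stratified random 70/30 splits, which matches both printed
numbers, and provide classic k-fold behind `scheme = "kfold"`. Every
fold's training part must contain every state, or the fold aborts with a
message. The score — also unstated — is the test-set coefficient of
determination averaged over the two output dimensions, with the mean
absolute angular error reported alongside. Feature blocks (stimulation
phase as cos/sin; outgoing structural row; state label; full or
stimulated-region-local PLV and lag vectors) are assembled in a canonical
order so scores cannot depend on how a specification lists them; pairwise
feature-set comparisons pool fold-by-affected-region scores, use
Mann–Whitney rank-sum tests and Bonferroni-correct over all pairwise
comparisons. Because the forest size, score definition and the original
clustering labels all differ from the unavailable originals, the printed
improvement magnitudes (~35–40%) are not reproduction targets; the
reproducible claim, asserted by the tests, is directional — state-aware
feature sets do not trail state-ignorant ones on simulated experiments,
and are significantly better on a planted state-by-phase dependence.

## The planted-synchrony generator

`generate_planted_oscillations()` builds raised-cosine signals
(`1 - cos(phi)`, troughs exactly at phase 0) whose locked groups share one
phase trajectory up to fixed per-region lag offsets; unlocked regions get
private trajectories with a log-frequency detuning drawn from ±[0.3, 0.6]
(bounded away from 0 so no drifter shadows the reference frequency within
a window), a slow phase random walk, and heavy per-sample phase jitter
(sd 1 rad) so their PLV toward anything stays near zero.
`generate_planted_states()` composes three runs sharing a 12-region core
coalition (66 core pairs) plus two of three 3-region peripheral groups
each — chosen so that just under 46% of all links have a high median PLV,
the bimodal shape the 54th-percentile threshold presumes — with distinct
core lag patterns per run. The end-to-end tests require exact recovery:
every window's hub set equals its run's coalition, the stable set equals
the core, the three-state partition equals the run partition with no
"None" windows, lags match the planted offsets within one sampling
interval per period, and held-out windows classify with 100% accuracy.
What passing these fixtures does *not* show: robustness to measurement
noise, volume conduction, or amplitude-dependent coupling — none of which
exist in this deterministic model either.

## Problem sizes and scale

The test suite runs the full 13-run resting design for the synchrony and
stimulation checks, a reduced stimulation design (one region, 10 phases,
2 windows x 2 cycles per state) for the downstream and prediction checks,
and small networks (3–10 regions, hundreds of samples) for the unit-level
oracles; the whole suite completes in a few minutes on one CPU, and
`scripts/acceptance.R` (the full 13-run synchrony computation) in about
two. These sizes are the package's choices for fast, deterministic
verification; `run_study()` defaults to the full-scale protocol.

## Known limitations

* All quantitative results are surrogate-conditional; only the two
  resting-synchrony values have quantitative targets, and PLV_top runs
  ~0.08 high for the reason given above.
* Stimulation-induced switching hotspots (elevated delta-P) do not emerge
  on the surrogate at the default amplitude; the switching machinery is
  validated on constructed cases and the null chain.
* No transmission delays, no stochastic integration, no cross-frequency
  analyses, no t-SNE embedding (visualization only in the original
  workflow), and no automated drawing of regime-boundary lines.
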