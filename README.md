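# kinegate

Kinetic analysis of kinesin-1 head gating from single-molecule and
stopped-flow data.

## The problem

Dimeric kinesin-1 walks hand-over-hand along microtubules, one 8 nm step per
ATP, by keeping the ATPase cycles of its two identical motor heads out of
phase.  The coordination is encoded in the neck linker: in the two-head-bound
state the front head's neck linker points backward and the rear head's points
forward, and these two configurations gate different chemical steps.
Resolving *which* steps requires estimating the elementary rate constants of
the scheme

```
MtK + ATP  <--k+1 / k-1-->  MtK.ATP  --k2-->  K.ADP.Pi + Mt
```

(`k+1`: second-order ATP on-rate, uM^-1 s^-1; `k-1`: ATP off-rate, s^-1;
`k2`: ATP-induced microtubule detachment, s^-1; derived `Kd = k-1/k+1` and
steady-state `kcat`, `Km`) separately for front-like and rear-like heads,
from three very different measurements:

1. **High-speed dark-field trajectories** of a gold-labelled head
   (20,000 frames/s): transient increases in positional fluctuation mark
   microtubule detachment.  Segmenting bound/unbound dwells gives the
   detachment kinetics of the front head, and the ATP dependence of the
   inverse mean bound dwell follows the Michaelis–Menten equation.
2. **smFRET traces** between a dye on the head and a dye-labelled ATP:
   high-FRET dwells are nucleotide-bound intervals; how each dwell ends
   (donor recovery vs. simultaneous loss of both dyes) distinguishes ATP
   dissociation from head detachment; the inverse mean high-FRET dwell is
   `k-1`.
3. **Stopped-flow transients** (mant-ATP fluorescence, turbidity): single
   exponential fits give `kobs`, lines `kobs = k+1[S] + k-1` give the ATP
   on/off rates, and exponential-plus-line "burst" fits of turbidity decays
   give `k2`.

`kinegate` implements all three analysis chains plus generative simulators
of each modality, so every stage is validated end-to-end by parameter
recovery on synthetic data with known ground truth.  It is written for
single-molecule biophysicists who want a tested, scriptable version of this
pipeline rather than one-off analysis code.

## Worked example

Simulate a 60 s gold-probe trajectory of a front head at 1 mM ATP (mean
bound dwell 160 ms, mean unbound dwell 11 ms, 20 kHz) and run the full
segmentation pipeline — rolling 2D standard deviation over ±20 frames,
Gaussian fit of the noise floor, μ+4σ hysteresis thresholding with a
10-frame persistence rule, and step-fit refinement of every transition:

```r
library(kinegate)

sim <- simulate_two_state_trajectory(traj_sim_params(
  frame_rate = 20000, mean_bound_dwell = 0.160, mean_unbound_dwell = 0.011,
  noise_bound = 4, noise_unbound = 12, unbound_on_axis_offset = -8,
  n_frames = 1200000L, seed = 7))

seg <- segment_trajectory(sim$traj)
print(seg)
#> state segmentation: 1200000 frames, 335 bound / 334 unbound dwells
#> noise floor: mu = 5.63 nm, sigma = 0.447 nm, threshold = 7.42 nm
#>   mean bound dwell   : 169.3 ms (n = 333)
#>   mean unbound dwell : 10.28 ms (n = 334)
```

The noise floor sits at μ = 5.63 nm — the 2D s.d. of a bound head with 4 nm
per-axis noise (4·√2) — and the recovered dwell means agree with the
generating 160/11 ms within sampling error.  The inverse mean bound dwell is
the single-molecule detachment rate, and the backward displacement of each
unbound dwell shows the labelled head detached from the *leading* position:

```r
dw <- seg$dwells
rate_from_mean_dwell(dw[dw$state == "bound", ])
#> k2 (inverse mean bound dwell): 5.91 +/- 0.32 s^-1
table(dw$origin[dw$state == "unbound"])
#> ambiguous   leading  trailing
#>        10       322         2
```

Repeating the bound-dwell measurement across ATP concentrations and fitting
the inverse mean dwells recovers the Michaelis–Menten parameters of the
front head:

```r
dwells <- simulate_bound_dwells_mm(mm_dwell_sim_params(
  kcat = 6.3, Km = 43, atp_concs = c(1, 3, 10, 30, 100, 300, 1000),
  n_per_conc = 5000, seed = 1))
agg <- aggregate(dwell_s ~ atp_conc_uM, dwells, mean)
fit <- fit_michaelis_menten(agg$atp_conc_uM, 1 / agg$dwell_s)
#> kcat = 6.31 +/- 0.04 s^-1,  Km = 44.7 +/- 1.2 uM

derive_kd(92, 5.3)      # front-head ATP Kd: 17.4 uM
fold_change(91, 0.65)   # WT vs rear-head ATP off-rate: 140
```

See the methods vignette (`vignettes/kinesin-head-gating.Rmd`) for the
models, parameter choices and known limitations, and `?kinegate` for the
full function index.

## Command line

```sh
Rscript inst/cli/kinegate.R recover  --seed 3 --out run/ --n-frames 500000
Rscript inst/cli/kinegate.R segment  --traj run/trajectory.csv --out seg/
Rscript inst/cli/kinegate.R fret     --trace trace.csv --threshold 0.5 --out fret/
Rscript inst/cli/kinegate.R stoppedflow --mode fit-burst --trace turbidity.csv --out fit.json
```

Exit codes: 0 ok, 1 user error, 2 internal error.

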