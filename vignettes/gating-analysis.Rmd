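---
title: "Gating analysis methods: models, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gating analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvgating)
```

## Scope

`kvgating` implements the equilibrium-gating analysis used for
voltage-gated potassium channels in cut-open-oocyte voltage clamp: sweep
reduction (peaks, conductances, integrated gating charge, inactivation
decay fits), normalized cohort-averaged curves, Boltzmann model fits, and
the conversion of fitted parameters and median charge-movement voltages
into free energies, including the thermodynamic mutant cycle used to test
residue-residue coupling. Because raw oocyte recordings are rarely
shareable, the package includes a synthetic-sweep generator with the
statistical structure the analysis assumes, so every stage is testable.

## Models and their assumptions

**Two-state Boltzmann** (`gv_two_state()`, `qv_two_state()`):
$1/(1+\exp(z(V_{1/2}-V_m)F/RT))$. One voltage-dependent transition with
apparent valence $z$ ($e_0$) and midpoint $V_{1/2}$ (mV). Conductance and
charge share one numerical kernel, so the two fitters are exactly the same
function of $(z, V_{1/2})$.

**Three-state sequential charge curve** (`qv_three_state()`): two lumped
transitions with valences $z_0, z_1$ and midpoints $V_0, V_1$, scale $N$:
$$Q(V_m) = N\,\frac{z_1 + z_0(1+e_1)}{(1+e_1)(1+e_0)},\qquad
e_i=\exp\!\big(z_i(V_i-V_m)F/RT\big).$$
This closed form is what the fitters use. It is not algebraically
identical to the occupancy-weighted mean charge of a strict sequential
three-state scheme (whose partition function is $1+e_1+e_0e_1$ after
clearing fractions); the package also ships that occupancy formulation
(`qv_three_state_sequential()`) as an independent cross-check, but fitting
always uses the closed form above. Both saturate at $N(z_0+z_1)$ and 0.

**Inactivation**: long-pulse decays follow
$y(t)=y_0-A_1e^{-t/\tau_1}-A_2e^{-t/\tau_2}$ with the amplitude-weighted
$\tau_w=(A_1\tau_1+A_2\tau_2)/(A_1+A_2)$; availability curves follow a
descending Boltzmann between free asymptotes $A_1 \le A_2$.

**Energetics**: $G = zFV/1000$ kcal/mol per process; the median voltage of
a saturated normalized Q-V gives the total activation energy with
$z_{total}=13.6\,e_0$ (the consensus total gating charge for Shaker-type
channels, configurable); four channels combine into
$\Delta\Delta G = zF(V_{double}-V_1-V_2+V_{parent})/1000$ with the four
median-voltage SEMs combined in quadrature under the same $zF$ factor.
Significance conventions: 1 kcal/mol for per-process shifts, 1.8 kcal/mol
for the mutant-cycle interaction (both configurable); the interaction
verdict uses $|\Delta\Delta G|$ so a mirrored (negative) coupling is not
missed.

## Physical constants

Voltages are mV throughout; the mV-to-V conversion lives only inside the
energy functions. Default temperature is 291.15 K (17-18 C room
temperature typical of these recordings), giving a thermal voltage
$RT/F = 25.09$ mV. The Faraday constant defaults to
$96485/4180 = 23.0825$ kcal mol^-1 V^-1 per $e_0$, i.e. the rounded
1 cal = 4.18 J conversion in common use in the channel-energetics
literature; published median-voltage energy tables for Shaker reproduce
to their printed two decimals only under this convention, which is why it
is the default. Pass `gating_constants(faraday_kcal = 96485/4184)` for the
thermochemical-calorie value (23.061); the difference is below 0.1% and
never changes a verdict. Exponent arguments are clipped at ±700 before
exponentiation so curves saturate instead of overflowing at absurd
voltages; the clip is unreachable in the physiological range.

## What the simulator emulates — and what it does not

Each simulated sweep walks the protocol's segments (holding, conditioning
pre-pulse, test step, tail). Voltage-sensor charge relaxes first-order
toward the equilibrium of each segment's voltage with a configurable
$\tau(V)$, and the recorded gating current is $Q_{max}\,dq/dt$. This is
deliberately the *minimal* kinetic structure consistent with the analysis:
the pipeline consumes only time-integrated charge, and first-order
relaxation makes the noiseless ON integral equal the closed-form
equilibrium difference exactly (and ON = -OFF, since first-order kinetics
are conservative). The published analyses make no claim about gating
current kinetics, so neither does the generator.

Ionic currents add an activation gate relaxing toward the G-V equilibrium
and an optional two-component slow-inactivation deficit relaxing toward a
voltage-dependent steady-state availability, so sustained depolarizations
decay along a biexponential envelope and a long conditioning step followed
by a fixed test pulse traces out the availability curve. The driving force
is ohmic with the Nernst reversal (no Goldman rectification), the leak is
linear, and noise is additive white Gaussian in current. Residual
capacitive transients default to zero (amplitude per 100 mV of step is
configurable) because the emulated rigs compensate them.

Cohorts draw per-cell $Q_{max}$/$g_{max}$ scale factors from a lognormal
(default sdlog 0.3, matching severalfold expression scatter across
oocytes) with per-cell seeds derived deterministically from one master
seed.

Defaults, chosen once as realistic study conditions: sample interval
0.05 ms for I-V families and 1 ms for 19 s inactivation families
(desk-scale files); conditioning pre-pulse 50 ms at -140 mV (long enough
that sensors fully equilibrate before the test step at the default
$\tau = 2$ ms); test and tail 50 ms; $Q_{max} = 2$ nC;
$g_{max} = 0.05$ uA/mV; noise SD 0.02 uA (20 nA, typical post-filter rig
noise); 6 cells per cohort.

Not emulated: stochastic single-channel (Markov) gating, omega/proton
currents, series-resistance and space-clamp artifacts, P/n leak
subtraction protocols, and drift. Passing tests therefore validate the
estimators against idealized but realistically noisy data; they cannot
certify robustness to instrumentation artifacts real recordings may
carry.

## Sweep reduction

Windows treat protocol segments as half-open intervals $[t_0, t_1)$ so a
boundary sample belongs to the segment it steps into; this matters because
the first tail sample carries the full OFF current. Charge integration is
trapezoidal over the test step after subtracting a baseline estimated from
the final 20% of the immediately preceding segment — the standard
compensation for residual holding current, and what makes charge invariant
to constant offsets. With the default sampling the noiseless integral
matches the model to ~5 per 10^5.

Peak search smooths with a 5-sample boxcar (applied inside the window
only, so neighboring segments cannot smear across its edges) and returns
the smoothed extremum; conductance conversion refuses voltages within
1 mV of the reversal potential (configurable floor) and flags those
sweeps. Decay fits start at the first sample after the absolute peak
(earliest on ties), seed time constants log-spaced between 1/50 and 1/2 of
the window, keep the best of the restarts by SSR, order components
$\tau_1 \le \tau_2$, and fall back to a flagged single exponential if the
biexponential does not converge.

## Curves, fitting, and the free-scale choice

Per-cell values are normalized by the cell's maximum and averaged
pointwise (mean ± SEM) across cells on the shared voltage grid, the
procedure behind published Q-V/G-V/Inac-V figures. Fits are unweighted
least squares to the cohort mean curve (Levenberg-Marquardt with bounds:
valences in (0, 20], midpoints within the grid ± 50 mV), with the midpoint
initialized from the half-maximum crossing, the valence from the 25-75%
slope, three multistarts over scaled valences, lowest SSR winning.
Parameter standard errors come from the Jacobian-based covariance at the
optimum and are fit errors, reported separately from the cohort SEM.

One design point deserves emphasis. Dividing a noisy curve by its own
maximum deflates every point slightly, because the selected maximum
carries the largest positive noise excursion; forcing the Boltzmann
asymptote to exactly 1 then pushes that deflation into $z$ and $V_{1/2}$
(about two standard errors at the default noise). The two-state and
availability fits therefore carry a free amplitude, exactly as the
three-state fit carries its free scale $N$; on noiseless data the
amplitude converges to 1 and the fitted parameters are unchanged. Fixing
the amplitude (`fix_scale = 1`) restores the strict textbook form. In
simulation this choice brings 2-SE coverage of the true parameters from
~20% to ~91% without touching the data or the error model.

Q-V model choice (`model_select_qv()`) uses AIC on the least-squares
deviance, $n\log(SSR/n) + 2p$, penalizing the three extra parameters of
the sequential model; a configuration override always wins, since
published tables sometimes pin the model per mutant. The three-state fit
refuses fewer than six distinct voltages.

## Median voltage

The median voltage splits the area of the normalized Q-V equally: after
rescaling the mean curve to span [0, 1], trapezoidal integration gives
$V_{median} = V_{max} - \int q\,dV$, the point where the cumulative area
balance crosses zero. The estimate is only defined for curves spanning
both saturations; the gate requires the first point at or below 5% and the
last at or above 95% of the maximum (configurable) and is applied to the
mean curve — per-cell medians, used solely for the SEM across cells, are
computed unconditionally since endpoint noise would otherwise veto
individual cells. Against a 0.01 mV brute-force area-balance oracle the
estimator agrees to better than 0.1 mV on both two- and three-state
curves, and it is exactly translation-equivariant.

## Pipeline and provenance

`run_pipeline()` executes simulate → measure → curves → fit → energetics →
cycle from one configuration (list or YAML), each stage reading the
previous stage's serialized outputs (CSV for tables, JSON for curves,
fits, and the cycle), so stage subsets can re-run against an existing
directory and the cycle stage can run standalone on a median-voltage
table, including the packaged one. The resolved configuration, its MD5
hash, and a structured log are written into every run directory; artifact
files carry no timestamps, so identical configuration and seed give
byte-identical outputs.

## Test problem sizes

The suite validates parameter recovery at the study conditions above: the
stochastic recovery check runs 100 seeded replicates of a 6-cell cohort
over a 19-step protocol and requires the fitted $(z, V_{1/2})$ within two
fitted standard errors of truth in at least 90% of replicates; oracle
checks (charge integration, median voltage, noiseless self-consistency at
1e-6 relative) run on single sweep sets or closed-form curves. The full
suite completes in well under a minute on one core.

## Known limitations

* The closed-form three-state curve is fitted as printed in the
  literature it follows; users wanting the strict sequential partition
  function can evaluate `qv_three_state_sequential()` but cannot fit it.
* Per-process energies $zFV_{1/2}$ compare channels through apparent
  two-state projections; for channels whose Q-V was fitted two-state, the
  "second transition" energy uses that single $(z, V_{1/2})$ pair, an
  approximation the shift report inherits (the packaged parameter table
  reproduces the published significance pattern under it).
* The mutant cycle assumes one shared total charge across the four
  channels and errors out otherwise; partial-charge mutants need a
  different estimator.
* Curve SEMs are across-cell standard errors of max-normalized values;
  they understate uncertainty when a cohort has fewer than ~4 cells.
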