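---
title: "Models and methods behind emuflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind emuflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

# The problem

Carbon-13 metabolic flux analysis (MFA) infers intracellular reaction rates
from the labeling patterns that a ¹³C-labeled substrate imprints on
metabolic intermediates. The measurable unit is the mass isotopomer
distribution vector (MDV): for an n-carbon fragment, the length-(n+1)
vector of fractional abundances of the mass shifts M+0 … M+n. At isotopic
steady state a single MDV per fragment carries the flux information; for
autotrophic or C1-fed systems the steady-state pattern becomes
flux-independent and one must instead fit the transient approach to
isotopic steady state (isotopically nonstationary MFA, INST-MFA), which
additionally involves the metabolite pool sizes that set the labeling
timescales.

emuflux implements the full pipeline: atom-mapped network representation,
constraint-based pre-analysis (FBA/FVA, polytope sampling), forward
simulation of MDVs by elementary metabolite unit (EMU) decomposition at
steady state and in time, inverse estimation of fluxes (and pool sizes and
dilution parameters) by multi-start weighted nonlinear least squares, and a
statistics layer (goodness of fit, local and Monte-Carlo confidence
intervals, sensitivity and contribution matrices).

# Network model and total fluxes

Reactions are written with explicit atom transitions
(`v3: B{abc} -> C{bc} + E{a}`). Each reversible reaction is split into a
forward and a backward component; together with the irreversible reactions
these form the *total fluxes* v ≥ 0. Mass balance of the intracellular
(balanced) metabolites defines the feasible flux polytope S·v = 0 with box
bounds. Substrates are metabolites never produced, excreted metabolites are
never consumed; both can be overridden when the inference is wrong for a
model. Net and exchange fluxes of a reversible reaction are
v_net = v_f − v_b and v_xch = min(v_f, v_b).

A symmetric metabolite (e.g. succinate) is written as the same product
twice with its two atom maps and coefficient ½ each, which averages the two
orientations — the standard MFA treatment of molecular symmetry.

# EMU decomposition and steady-state simulation

An EMU is a subset of a metabolite's carbon atoms. Backward traversal from
each measured fragment through the atom maps yields, size by size, linear
balance systems A·X = −B·Y, where X stacks the MDVs of unknown EMUs of one
size and Y the MDVs of substrate EMUs and convolutions of smaller, already
solved EMUs (condensation reactions convolve their precursor MDVs). The
diagonal of A carries each EMU's total consumption flux; off-diagonal and B
entries carry flux-weighted inflows. Excreted sink metabolites have no
consumption; their MDV is the instantaneous flux-weighted mixture of their
inflows. The decomposition is memoized on canonical EMU names and fully
deterministic (sorted canonical order), and `compile_emu_system()` turns it
into an index structure that can be re-evaluated for thousands of flux
vectors cheaply — the estimation inner loop.

Correctness is established against an independent brute-force oracle
(`brute_force_mdvs()`, `brute_force_inst()`) that never touches the EMU
code: it iterates the complete 2ⁿ isotopomer balance of every metabolite to
a fixed point (steady state) or integrates the full isotopomer ODE with
`deSolve::lsoda` at tight tolerances (transient), then marginalizes to
MDVs. On the bundled toy networks the two routes agree to better than
1e−9 at steady state.

# Transient (INST) simulation

With pool sizes c the cascade becomes diag(c)·dX/dt = A·X + B·Y(t), solved
size by size from natural-abundance initial conditions with the tracer
switched on at t = 0. The integrator is a noncausal first-order-hold (FOH)
equivalent: on a uniform internal grid the inhomogeneous term Y(t) is taken
piecewise linear, and each step is advanced with the exact matrix
exponential of the held system (Van Loan block construction; one `expm` per
size, reused across steps since A is time-invariant). Convolution sources
for larger sizes are recomputed on the same internal grid from the stored
smaller-size trajectories; output times are read off the internal grid by
linear interpolation.

Numerical choices:

* internal step Δt = min_i(c_i / outflux_i) / 20 — twenty steps per fastest
  EMU turnover; halved geometrically (up to 8 times) if any trajectory's
  unit-sum invariant drifts beyond 1e−6;
* the integrator is exactly invariant under the joint rescaling
  (c, t) → (c/2, t/2), because Δt is derived from c/outflux — the
  pool-halving identity holds to machine precision, and tests assert 1e−8;
* convergence is second order in Δt (asserted against a 16× finer
  reference);
* for estimation the internal grid is frozen at 1.5× the resolution implied
  by the starting point, so the objective stays smooth across optimizer
  iterations.

Pool sizes are assumed constant over the labeling experiment; time-varying
fluxes or pools are out of scope.

# Constraint-based layer

FBA and FVA are linear programs over the flux polytope, solved with the
two-phase simplex of the `boot` package; fluxes fixed by their bounds are
substituted out first and degenerate ties are broken by a tiny
lexicographic secondary objective (1e−9 weights), which makes LP answers
deterministic. The feasible-polytope sampler is coordinate hit-and-run on
the null-space parameterization of S·v = 0 (burn-in 1000, thinning 10),
started from the average of the FVA vertex solutions.

# Flux estimation

The inverse problem minimizes the weighted residual sum of squares
Φ(θ) = Σ ((predicted − measured)/sd)² over MDV entries and measured net
fluxes. The parameterization guarantees exact mass balance for every
iterate:

* free net fluxes: the non-pivot reactions of the reduced row echelon form
  of the net stoichiometric matrix; dependent fluxes follow linearly.
  Box bounds for the free fluxes come from FVA with measured fluxes
  anchored at ±5 sd; one-sided penalty residuals (weight 1e3) keep
  dependent irreversible fluxes nonnegative;
* exchange fluxes: xch = 20·tan(πu/2) with u ∈ [0, 1) bounded by the
  exchange cap (default 1000). The scale 20 (in units of uptake = 100)
  places the practically identifiable exchange range on a well-conditioned
  stretch of u — an unscaled tan squeezes it against u = 1 and stalls
  gradient-based optimization;
* pool sizes (INST): log-transformed, bounds [1e−3, 1e4];
* dilution G-values: one free parameter in [0, 1] per diluted pool. The
  observable model is G·(simulated MDV) + (1−G)·(natural MDV), applied at
  the measurement for measured pools and at the substrate MDV for source
  pools such as CO₂ — equivalent to the usual pseudo-reaction construction
  but implemented at the measurement model.

Optimization is multi-start Levenberg–Marquardt (`minpack.lm::nls.lm` on
the residual vector, box bounds, ftol = ptol = 1e−9, ≤500 iterations).
Starts are drawn uniformly in the FVA box (rejected until feasible);
exchange starts cover the whole transformed range, which is what reliably
escapes a spurious basin in which large exchange mimics a different flux
split. Defaults are 10 starts (steady state) and 5 (INST). Degenerate
iterates (a pathway flux exactly zero makes an EMU balance singular) return
a large finite misfit so the optimizer backs off rather than aborting.
Measured MDV standard deviations are floored at 0.001 to avoid degenerate
weights.

Reported quantities follow the field convention of normalizing fluxes to a
substrate uptake of 100.

# Statistics

With J the finite-difference Jacobian (forward, relative step 1e−6) of the
weighted residuals at convergence, the Gauss–Newton covariance is
(JᵀJ)⁻¹, pseudo-inverted with singular values below 1e−8·s_max treated as
null directions; quantities with a component in the null space are flagged
unidentifiable and reported with infinite half-width (the futile-cycle
construction in the tests exercises exactly this). The χ² test accepts a
fit when Φ lies in the central 1−α band of χ²(dof), dof = residuals −
parameters; residual normality uses the Shapiro–Wilk statistic plus normal
probability plot quantile pairs. Sensitivities of estimates to measurements
use the generalized-least-squares influence form D·(JᵀJ)⁻¹·Jᵀ·W, and the
contribution matrix is the row-normalized first-order variance
decomposition C_ij = S_ij²σ_j² / Σ_j S_ij²σ_j². Monte-Carlo confidence
intervals refit data perturbed with the declared measurement noise
(warm-started from the base optimum, per-run seeds derived deterministically
from the master seed so parallel and serial execution agree) and report
empirical quantiles.

# The synthetic-data generator: what it emulates

`generate_synthetic_dataset()` reproduces the synthetic validation design:
draw one reference flux distribution from the feasible polytope, simulate
the measured fragments, add 1 mol % Gaussian noise per MDV entry, and
renormalize (renormalization can be disabled; the χ²-calibration study uses
raw Gaussian noise so the declared noise model is exactly correct). The
measured uptake flux receives Gaussian noise with sd 1.

The study conditions are fixed once:

* uptake fixed at 100 (the normalization convention);
* forward/irreversible total fluxes capped at 300, backward (exchange)
  fluxes at 50. Exchange far above the uptake scale produces near-complete
  bidirectional mixing that labeling data genuinely cannot distinguish from
  infinite exchange; MFA practice treats that regime as unidentifiable, and
  a bounded draw keeps the reference inside the regime the method is meant
  to recover;
* noise 1 mol % (sd 0.01 per MDV entry), formal sd 0.01 for noise-free
  data;
* the bundled five-reaction toy network (`toynet1()`) uses a 4:1
  [1-¹³C]:[U-¹³C] tracer mixture. Under a pure 1-position tracer the atoms
  feeding one intermediate never carry label, so its pool size would be
  structurally unidentifiable in INST mode; the mixture (the same design as
  the classic heterotrophic tracer experiments) lights up every position.
  Pools are {B: 15, C: 3, D: 10} with sampling times 0–0.5 in the time unit
  implied by flux = 100 per unit time, giving turnover times between 0.03
  and 0.15 — resolved by, not degenerate on, the grid.

What passing these tests shows — and what it does not: the synthetic
protocol validates the estimator under its own noise model on small
networks with exactly known atom maps. Real data add fragment-specific
systematic errors, imperfect natural-abundance correction, model
misspecification, and metabolite channeling, none of which the generator
emulates; χ² rejection on real data can therefore reflect either
measurement underestimation or genuine model misfit.

# Known limitations

* Networks are core-scale and atom-mapped by hand; SBML/genome-scale import
  and automatic atom mapping are out of scope.
* Only nominal mass-shift MDVs are supported (no tandem-MS positional
  data).
* Confidence intervals are local (Hessian) or Monte-Carlo; profile
  likelihood continuation is not implemented.
* The LP layer relies on a dense two-phase simplex — fine for core
  networks, not intended for genome-scale models.

# Reproducing the validation numbers

`scripts/acceptance.R --seed <int> --out <path>` recomputes every quantity
above from scratch at the problem sizes used throughout this vignette
(4 networks × ~25 flux draws for the oracle comparison; 20 seeds for the
1 mol % protocol; 20 × 200-run Monte-Carlo replications for coverage;
200 replicate fits for χ² calibration) and writes them as JSON.
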