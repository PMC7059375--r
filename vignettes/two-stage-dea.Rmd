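---
title: "Two-stage bootstrap DEA: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage bootstrap DEA: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the estimators, the assumptions behind them, the tunable parameters and
their defaults, what the synthetic generator does and does not emulate,
and the numerical decisions that were genuinely open.

## The production model and the stage-1 estimators

Each decision-making unit (DMU; here, a hospital) converts a vector of
p inputs x into q outputs y. The technology is the set of feasible (x, y)
pairs; its boundary is the production frontier. The **Farrell output
distance** of a unit is the largest proportional expansion of all its
outputs that stays inside the technology,

λ(x₀, y₀) = max { λ : (x₀, λ·y₀) feasible },  λ ≥ 1,

and the Shephard efficiency score is 1/λ ∈ (0, 1]. DEA estimates the
technology by the smallest convex (VRS) or conic (CRS) set enveloping the
observed data, so λ is the optimum of the envelopment linear program

maximise λ  s.t.  Xμ ≤ x₀,  Yμ ≥ λ·y₀,  μ ≥ 0,

with Σμ = 1 added under variable returns to scale (the BCC model), Σμ ≤ 1
under non-increasing returns, and no convexity constraint under constant
returns (the CCR model). Output orientation is the appropriate choice when
units do not control their input endowment (public hospitals receive
staff and budget allocations centrally) and can only expand services.

Technical efficiency te = 1/λ_CRS decomposes exactly as **te = pte × se**
with pte = 1/λ_VRS; se = te/pte isolates the loss from operating away
from the most productive scale. Returns-to-scale classes use the nested
distances: a unit is CRS when λ_CRS = λ_VRS (within `rts_tol`, default
1e-6), otherwise IRS when λ_NIRS = λ_CRS (it sits below its most
productive scale), otherwise DRS. Distances within `snap_tol = 1e-8` of 1
are snapped to exactly 1 so frontier units report clean scores in band
summaries.

**Solver.** The envelopment programs are solved by a dense two-phase
tableau simplex in C++ (only the VRS program needs a phase-1 artificial,
for its equality constraint). Every constraint row is rescaled by the
evaluated unit's own level so all right-hand sides are 0 or 1 — the
distance is invariant to row scaling, and this equilibration is what makes
panels with entries spanning nine orders of magnitude (total expenditure
in 10⁴ RMB next to a near-zero staff count) solvable to 1e-9. Pricing is
Dantzig with a Bland anti-cycling fallback after 2000 pivots; if a run
still stalls, the unit is re-solved with Bland's rule from the first
pivot, which cannot cycle.

## The smoothed homogeneous bootstrap

Because the estimated frontier lies weakly inside the true one, raw
Shephard scores are biased toward 1. The Simar–Wilson smoothed
homogeneous bootstrap estimates that bias under the assumption that
inefficiency is identically distributed across units (homogeneity). Each
replicate:

1. resamples β\* from the estimated distances {λ̂ᵢ};
2. adds kernel noise h·ξ, ξ ~ N(0,1), with h from Silverman's rule on the
   sample reflected about the frontier value 1 (bandwidth
   `0.9 · min(sd, IQR/1.349) · (2n)^(−1/5)`);
3. shrinks deviations by 1/√(1 + h²/var(λ̂)) to undo the kernel's variance
   inflation, **then** folds values below 1 back across the frontier.
   The order matters: folding first and shrinking afterwards pulls every
   draw toward the sample mean and leaves an interval just above 1 with
   zero probability mass, so the pseudo frontier can never approach the
   empirical one and interval coverage collapses. Sampling from the
   variance-matched reflected kernel estimate — smooth, correct, fold
   last — keeps the boundary mass and is the form this package uses;
4. deflates each unit's frontier projection λ̂ⱼ·yⱼ by its drawn distance
   δ\*ⱼ to build a pseudo reference technology (inputs are never
   perturbed: output orientation), and re-solves the DEA for every
   original unit against it.

The replicate distances λ\*ᵢᵦ yield the bias estimate mean(λ\*) − λ̂, the
bias-corrected distance λ̃ = 2λ̂ − mean(λ\*), and percentile confidence
intervals from the quantiles of λ\* − λ̂. On the efficiency scale the
estimated bias is nonnegative for essentially all units and the corrected
mean score always drops below the raw mean. Replicate distances may fall
below 1 for units at the empirical frontier (the pseudo frontier can land
inside them); they are left untouched. Bias-corrected distances below 1,
which can occur when the bias estimate is negative, are clamped to 1 and
flagged — scores outside (0, 1] have no reporting interpretation.
Degenerate inputs (all distances identical) set h = 0 with a flag and the
procedure reduces to naive resampling.

Defaults: B = 2000 replicates (the study-scale choice; tests use 100–200
for speed), α = 0.05, and a mandatory integer seed — every replicate
stream is reproducible, and the full pipeline derives per-stage seeds
deterministically from one root seed.

## Stage two: bootstrap truncated regression

Efficiency scores are bounded, and DEA scores of different units are
correlated by construction (they share an estimated frontier), so naive
second-stage regression inference is invalid. The package implements the
truncated-normal maximum-likelihood regression

λᵢ = zᵢβ + εᵢ,  εᵢ ~ N(0, σ²) truncated so λᵢ ≥ 1,

fitted by BFGS on (β, log σ) with an analytic gradient from a
least-squares start. The design matrix is standardised internally (centre
and scale per covariate) and estimates are mapped back; covariates at
wildly different scales — staff percentages next to logs of near-constant
regional aggregates — otherwise make the likelihood surface too
ill-conditioned to optimise. The Mills-ratio terms of the gradient are
computed on the log scale so observations whose fitted mean sits many
standard deviations below the truncation point do not overflow.

`sw_algorithm2()` is the double bootstrap: (1) DEA distances; (2)
truncated fit on the inefficient units (distances strictly above 1); (3)
L1 parametric replicates drawing δ\* = zβ̂ + ε ≥ 1 to regenerate
pseudo-outputs, re-solve the DEA and bias-correct the distances; (4)
refit on the bias-corrected responses (units clamped at exactly 1 are
excluded, with a count); (5) L2 parametric replicates of the refitted
model, each refitted, giving the bootstrap distribution of (β, σ); (6)
percentile intervals. `sw_algorithm1()` (single bootstrap on the raw
distances) is provided for comparison. Defaults L1 = 100, L2 = 2000,
matching the study-scale replication count for the inference loop.

Two response conventions are exposed because the algorithm is defined on
Farrell distances (≥ 1, left truncation) while applied work often reports
score-scale coefficients: `farrell_ge1` (default; negative coefficients
improve efficiency) and `shephard01` (response 1/λ in (0, 1), two-sided
truncation; signs flip interpretation). Covariates such as population,
GDP per capita, financial subsidy and average income are conventionally
log-transformed; the transform set is configurable per covariate and the
synthetic generator records the transforms it used so recovery fits use
the same design. Inference is reported as percentile CIs plus a
CI-excludes-zero flag only — the procedure does not produce p-values, and
none are invented.

## The synthetic generator

`simulate_panel()` draws inputs and covariates from per-group (mean, sd)
scales on the positive half-line (draws floored at 1e-6 of the mean —
all quantities are physically nonnegative), computes frontier outputs
from a Cobb–Douglas technology g_m(x) = A_m·Πₖ xₖ^αₖ with αₖ ≥ 0 and
Σαₖ ≤ 1, draws Farrell inefficiency δ = max(1, zβ + ε) with ε
left-truncated normal, and deflates outputs by δ. The true δ and frontier
are attached for recovery tests and never read by the estimation path.

`default_table2_config()` mirrors the study population: 33 district-level
and 84 county-level hospitals, five inputs and four outputs at the
published descriptive scales, six covariates (three external, three
internal). Frontier multipliers are calibrated per output channel and
group against a fixed internal draw so simulated *frontier* means land on
the published output means; exponents default to
(0.25, 0.15, 0.15, 0.2, 0.15) — mildly decreasing returns, so scale
inefficiency exists in both directions. The inefficiency coefficients
default to negative effects (on the Farrell scale) of the
health-professional share, trained-worker count and log-subsidy, echoing
the direction of the published associations, with σ = 0.2 giving mean
efficiency in the 0.7–0.9 range typical of this literature.

What the generator deliberately does **not** emulate: survey
non-response and measurement error, geographic or administrative
correlation between hospitals, heteroscedastic or covariate-dependent
inefficiency spread, and quality-of-care dimensions of output. Passing
recovery tests therefore demonstrate internal consistency of the
estimators under the maintained model, not robustness to those realities.
One published quirk is mirrored deliberately: some descriptive SDs are
tiny relative to their means (e.g. population 444 967 ± 197), which makes
the corresponding log-covariates nearly constant and their coefficients
weakly identified — the regressions handle this through the internal
standardisation, and the wide CIs that result are the correct answer.

## Numerical and testing choices

* LP tolerances: pivot/pricing at 1e-9 on row-equilibrated data; scores
  snap to 1 within 1e-8.
* Truncated draws use inverse-CDF sampling with an upper-tail
  parameterisation (and an exponential tail approximation beyond 37 sd)
  so deep truncation never yields draws on the bound.
* Problem sizes in the test suite are chosen to exercise the estimators
  at study scale while keeping the default run to a few minutes: brute
  force grid oracles up to n = 8 units, bootstrap properties at n = 30–50
  with B = 100–200, stage-2 recovery at n = 100 with L1 = 100, L2 = 500
  over 50 Monte-Carlo repetitions, and interval coverage at n = 50,
  B = 200 over 100 repetitions.
* Coverage is verified on the single-input/single-output constant-returns
  generator, where the true distance of every unit is exactly its
  generated δ. Interval coverage of the smoothed bootstrap degrades as
  p + q grows at fixed n — the usual dimensionality behaviour of DEA —
  so multi-input panels of modest size should treat the intervals as
  indicative, not exact.
* Determinism: identical seed and configuration reproduce every result
  file byte-for-byte; wall-clock timings go to a separate `run.log`
  excluded from that contract.

## Known limitations

* The homogeneous bootstrap assumes one inefficiency distribution for the
  whole panel; no heterogeneous or subsampling variant is provided, and
  the NIRS model is not bootstrapped.
* Slack-based or additive efficiency measures, input orientation,
  super-efficiency and Malmquist indices are out of scope.
* Stage-2 significance is interval-based only.
* With five inputs, four outputs and 33 units, raw DEA scores hug the
  frontier (many units are efficient by construction); the bias
  correction moves them in the right direction but cannot recover the
  information the dimensionality has spent. This is a property of the
  method at these sizes, not of the implementation.
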