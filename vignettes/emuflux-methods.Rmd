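---
title: "Flux estimation from 13C labeling data: models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flux estimation from 13C labeling data: models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emuflux)
```

## The inference problem

Steady-state ^13^C metabolic flux analysis infers intracellular reaction
rates from the isotope labeling that defined ^13^C tracers imprint on
downstream metabolites. At metabolic and isotopic steady state the mass
isotopomer distribution (MID) of every metabolite fragment is a deterministic
function of the flux distribution, the carbon atom transitions of the
network, and the substrate labeling. emuflux inverts that map: it simulates
fragment MIDs at candidate flux states and adjusts the fluxes until the
simulated MIDs and measured extracellular rates match the data in a weighted
least-squares sense.

Two assumptions are load-bearing. First, the culture is at metabolic steady
state, so the stoichiometric balance `S v = 0` holds for every intracellular
(balanced) metabolite and the flux space is the affine polytope cut out by
that system, the flux bounds, and any fixed rates. Second, isotopic steady
state has been reached, so labeling of proteinogenic amino acids or free
metabolites reflects the steady-state labeling of their precursors. Neither
transient labeling (INST-MFA) nor tandem-MS positional data are modeled.

## Flux-space parameterization

The fitting variables are not the full flux vector. `free_flux_basis()`
stacks the balance system, one row per fixed flux (conventionally the
substrate uptake pinned to 100, so all results read as mol per 100 mol
substrate), and optional extra linear rows (the ATP balance of the energy
module). A pivoted QR factorization selects a set of dependent reactions;
the remaining free coordinates *are* reactions of the network, so their
bounds are box constraints and the fitted numbers have direct biochemical
meaning (on the toy template the single free coordinate is the branch
split). Each reversible reaction additionally contributes one exchange flux,
with the usual convention

* forward flux = max(net, 0) + exchange,
* backward flux = max(−net, 0) + exchange.

Exchange fluxes are optimized on a log10 scale over [1e−4, 1e3]: their
effect on labeling is multiplicative (a ratio to the net flux), and the log
scale keeps the optimizer well-conditioned across four decades. The lower
cap stands in for zero; at 1e−4 per 100 uptake an exchange is
labeling-inert to well below measurement precision.

## EMU simulation and its oracle

MID simulation uses the elementary-metabolite-unit decomposition: the
smallest set of metabolite atom subsets (EMUs) whose labeling determines the
measured fragments. The decomposition traces each measured fragment backward
through the atom maps; cleavages shrink the traced set, condensations split
it into a convolution of smaller EMUs, and the resulting system is
stratified by EMU size. At each size the steady-state label balance is
linear given the smaller sizes, so simulation is a cascade of small dense
solves — on the central-carbon template a few systems of dimension below
fifty, a few milliseconds per flux state.

Rotationally symmetric metabolites (succinate in the TCA templates) are
handled where their EMUs are produced: each producing reaction contributes
both skeleton orientations at weight 0.5. This is equivalent to scrambling
the molecule's labeling 50/50 at production and is chemically required
whenever a symmetric intermediate sits between measured fragments.

Numerical choices in the solver: level systems are solved by dense LU with
one step of iterative refinement when the residual exceeds 1e−10; an EMU
with zero production flux (a pathway switched off at the current flux
state) would make its row singular, so it is replaced by an inert unlabeled
placeholder — its downstream weight is exactly zero, so the substitution
cannot leak into any result.

Because the EMU engine is the scientific core, the package ships an
independent cross-check: `brute_force_mids()` solves the full positional
isotopomer balance over all 2^n labeling patterns per metabolite by damped
fixed-point iteration (tolerance 1e−12), sharing no code with the EMU path
beyond the network parser. One numerical subtlety is documented here
because it is easy to rediscover the hard way: condensation reactions make
the iteration's error dynamics multiplicative (the product pool's total
mass is the *product* of the source totals), so rounding drift in the
distribution sums is amplified around cycles and the iteration eventually
drains mass even after converging in shape. Each pool is therefore
projected back onto the unit-sum simplex every sweep, which removes the
unstable mode without touching the fixed point. The equivalence test drives
both simulators over random fluxes and random impure tracer mixtures on the
branched toy network and on a cyclic TCA-like fixture with a cleavage, a
condensation, a reversible step and a symmetric metabolite, and requires
agreement to 1e−9.

## Measurement model and MS correction

A measured fragment is described by its backbone carbons and the elemental
formula of everything else in the ion (`fragment_spec`). The correction
matrix has one column per backbone labeling count m: a point mass shifted by
m, convolved with the natural-isotope envelopes of the extra atoms
(binomial for C/H/N, general multinomial collapse for O/Si/S) and with
natural ^13^C on the remaining backbone positions. Raw intensities are
deconvolved by non-negative least squares rather than matrix inversion:
non-negativity is what keeps noisy, truncated spectra from producing
negative mass fractions. Natural abundances default to the IUPAC values
(^13^C 0.0107, ^2^H 0.000115, ^15^N 0.00364, ^17^O/^18^O 0.00038/0.00205,
^29^Si/^30^Si 0.0467/0.0310, ^33^S/^34^S 0.0075/0.0425) and are
user-overridable, since silylated fragments put several Si and up to dozens
of H atoms on every ion.

Tracer impurity uses the standard independent-atom model: within each
mixture component a nominally labeled position is ^13^C with probability
equal to the atom purity, every other position at natural abundance.
Unlabeled inoculum biomass is removed after deconvolution — on the corrected
scale the inoculum contributes exactly the natural-abundance backbone
pattern, making the correction a one-line algebraic inverse with clipping
at zero (default inoculum ratio 0).

## Fitting, goodness of fit, uncertainty

The objective is the variance-weighted SSR over all retained MID channels
and measured rates. Minimization is multi-start bounded quasi-Newton
(`nlminb`, PORT): starts are drawn uniformly in the free-flux bounding box
and rejection-filtered to feasibility; because the feasible polytope can be
a small or even measure-zero subset of the box (after knockouts), the
sampler deterministically contracts the box toward a phase-1 feasibility
point and, as a last resort, projects draws onto the polytope. Dependent
fluxes outside their bounds add a smooth quadratic penalty (weight 1e4)
rather than an error, so the optimizer can cross infeasible corners while
converged solutions are feasibility-checked. Defaults: 10 starts, 500
iterations, relative tolerance 1e−9; ties within 1e−9 of SSR resolve to the
lowest start index so results are reproducible to the bit given a seed.

Degrees of freedom for the chi-squared test count each fragment as its
backbone size — the MID closes to one, so one channel per fragment carries
no information — plus one per measured rate, minus the number of *effective*
parameters: the rank of the weighted residual Jacobian at the solution.
The rank matters because exchange fluxes can be entirely invisible to the
data (on the toy template the reversible isomerization joins two pools with
identical labeling, so its exchange is a perfectly flat direction); charging
such a parameter a degree of freedom systematically shifts the SSR above its
reference distribution. Both the closure-aware data count and the
effective-rank parameter count are needed for the test to calibrate — with
naive counting the simulated pass rate of correct models drifts out of the
nominal band. The test is two-sided at alpha = 0.05 by default;
the upper tail flags lack of fit, the lower tail overestimated measurement
variances; a one-sided variant is available.

Confidence intervals are Monte-Carlo bootstrap: every measured datapoint —
MID channels *and* extracellular rates — is perturbed by Gaussian noise of
its own standard deviation, MIDs are clipped at zero and renormalized, and
the fluxes are refitted warm-starting from the base solution. Intervals are
empirical percentiles (2.5 %/97.5 % at the 95 % level). Perturbing the rates
too is a deliberate choice: when a measured secretion rate carries real
information about a branch flux, leaving it fixed understates the flux
uncertainty and the intervals undercover. Warm starting is what makes
10,000 refits tractable; it assumes the perturbed optimum stays in the base
solution's basin, which holds at realistic noise levels but would need
fresh multi-starts for very flat problems.

## Energy accounting

Cofactor coefficients live on reactions and never touch the carbon
machinery. The account sums substrate-level ATP over non-biomass,
non-maintenance reactions, oxidative ATP as P/O(NADH) x net NADH +
P/O(FADH2) x net FADH2 (FADH2 defaulting to two thirds of the NADH ratio),
and growth-associated consumption from the biomass reaction; the excess is
the maintenance cost. NADPH is treated as biosynthetic currency and excluded
from oxidative ATP — the templates carry no transhydrogenase, and whether
NADPH/NADH interconversion should be allowed is genuinely organism-specific,
so the default is the conservative exclusion.

The P/O scan closes the ATP balance as one extra linear row on the flux
space and refits per ratio. In *unbalanced* mode the explicit maintenance
pseudo-reaction is left genuinely unconstrained, so it absorbs the ATP
excess at any ratio and the carbon flux fit is provably ratio-insensitive
(a negative fitted maintenance flags incomplete cofactor stoichiometry
rather than an error). In *balanced* mode maintenance is fixed to zero,
the ATP row becomes a real constraint on carbon fluxes, and both the fitted
fluxes and the SSR become ratio-dependent — the balanced-mode SSR can never
beat the unbalanced one at the same ratio, which the tests assert.

## What the synthetic generator does and does not emulate

All tests run on synthetic experiments with known ground truth:
`random_flux_state()` samples the steady-state polytope (uptake pinned at
100, exchanges log-uniform on [0.1, 50]), `generate_experiment()` simulates
fragment MIDs, forward-applies each fragment's correction matrix to produce
raw GC-MS-style intensities, and perturbs the corrected MIDs with truncated
Gaussian noise of sd 0.004 mol fraction — a typical precision for replicate
GC-MS MID measurements — with measured rates perturbed by their own sd
(secretion rate sd 1, biomass rate sd 0.2 per 100 uptake). The default
tracers are an equimolar mix of singly and uniformly labeled substrate at
99 % atom purity, the classic design for resolving both relative pathway
usage and condensation fluxes.

The generator reproduces the statistical structure the estimator assumes:
independent Gaussian channel noise, exact correction matrices, a correct
network. Real data violate all three in places — correlated channel errors
from shared baselines, imperfect fragment formulas, missing reactions — so
green tests certify the inference machinery, not any particular biological
model. The packaged central-carbon template is likewise representative
(standard glycolysis/PP/TCA/glyoxylate atom maps with a lumped biomass
equation), not a curated model of a specific organism.

Problem sizes in the shipped tests were chosen to exercise every code path
at desk scale: 50 random flux/tracer settings for the EMU-oracle
equivalence, 100 random fragments for the correction round trip, 200
replicate datasets for the chi-squared calibration, and 100 replicates x
100 bootstrap iterations for the coverage study on the toy template, where
a single objective evaluation costs about a millisecond.

## Known limitations

* No isotopically non-stationary (INST) mode; slow label turnover biases
  steady-state fits.
* Atom maps are single-character labels, capping any one reaction at 52
  mapped carbons.
* The brute-force oracle is exponential in metabolite carbon count
  (hard cap 12) and exists for verification, not production simulation.
* Profile-likelihood intervals are not implemented; bootstrap percentiles
  undercover in strongly non-quadratic directions (exchange fluxes near
  their bounds).
* dof counting treats every exchange flux as a full parameter even when the
  data leave it unidentified, which is conservative for the chi-squared
  upper tail.
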