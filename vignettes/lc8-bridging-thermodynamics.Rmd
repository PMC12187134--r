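---
title: "Models and methods: ITC fitting and speciation of LC8-bridged 53BP1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ITC fitting and speciation of LC8-bridged 53BP1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itcbridge)
```

## The system

53BP1 trimerizes through its oligomerization domain (OD), and each of its
three chains carries up to three LC8 recognition motifs (QT sites; `q`
denotes how many are intact in a construct).  LC8 is a homodimer with two
symmetric grooves, so one LC8 dimer always joins two client chains.  Two
binding geometries follow: *intratrimer* binding joins two chains of the
same trimer, and *bridging* joins chains of two different trimers, producing
a dimer-of-trimers.  The fully occupied complexes have fixed stoichiometry:
a trimer complex binds `q` LC8 dimers (1:q) and the bridged complex `3q`
(2:3q) — per QT register, one intratrimer LC8 on each trimer plus one
bridging LC8.

`itcbridge` implements the quantitative layers needed to work with this
system: composition-to-mass bookkeeping, forward and inverse ITC models,
replicate aggregation, and a mass-action speciation model.  Everything runs
on synthetic or tabulated data; no instrument files are read.

## Thermodynamic identities and masses

Energies are in kcal/mol with `R = 1.987204e-3` kcal/(mol K) and a default
temperature of 298.15 K (the titrations being modeled were run at 25 °C).
`delta_g_from_kd()` returns `ΔG = RT ln Kd` (negative for sub-molar Kd) and
`neg_t_delta_s()` the identity `−TΔS = ΔG − ΔH`.

Masses are additive over components with defaults LBD-OD monomer 17.0 kDa,
LC8 dimer 21.2 kDa and OD monomer 13.2 kDa; `masses_table()` regenerates the
full expected-mass table (292.8/114.6, 229.2/93.4, 165.6/72.2 kDa for
q = 3, 2, 1, and the 51.0 kDa free trimer).  Two small inconsistencies in
commonly quoted numbers are worth noting and are *not* reproduced: an
OD-only trimer is sometimes quoted at 39.5 kDa while 3 × 13.2 = 39.6 (the
monomer mass behind that figure is evidently less rounded than 13.2), and a
two-chain LBD-OD species with 3 LC8 dimers is sometimes quoted at 95 kDa
while 2 × 17.0 + 3 × 21.2 = 97.6.  The package always computes from the mass
table it is given.

## Forward ITC models

**Dilution.** A perfusion cell of volume `V0` keeps its active volume
constant; injected volume `v` displaces cell contents.  The package uses
the symmetric half-volume accounting
`Mt = M0 (1 − v/2V0)/(1 + v/2V0)`, `Xt = X0 (v/V0)/(1 + v/2V0)`,
the convention behind the instrument-vendor fitting software this models.
Any self-consistent convention shifts fitted association constants by well
under 1% at these volumes (≤ 280 µL injected into 1.4 mL).

**One set of sites.** The cumulative heat content is the Wiseman closed
form (see the README for the formula).  Per-injection heat applies the
displacement correction
`ΔQ(i) = Q(i) − Q(i−1) + (dVᵢ/V0)(Q(i) + Q(i−1))/2` — the average-Q form
used by vendor software — and normalized heat divides by the injected moles
`dVᵢ · X0`.  A flag disables the correction for idealized telescoping
tests.  The closed form is verified against an independent bisection
solution of the binding mass balance on 1,000 random parameter draws
(log-uniform Ka over 1e3–1e9 M⁻¹) at 1e-9 relative tolerance.

**Sequential three-event model.** The macromolecule is the *hexamer*
(dimer-of-trimers equivalent: cell trimer concentration ÷ 2), binding three
LC8 dimers with constants `k1..k3` and enthalpies `h1..h3` through the
binding polynomial `P(L) = 1 + Σⱼ βⱼLʲ`, `βⱼ = Πᵢ≤ⱼ kᵢ`.  Free ligand
solves `Xt = L + Mt Σⱼ j Fⱼ(L)` with `Fⱼ = βⱼLʲ/P(L)`; the residual is
monotone in `L`, so a bracketed root on `[0, Xt]` (uniroot plus Newton
polish, residual < 1e-12·Xt) always converges.  Setting `k2 = k3 = 0`
reduces the model exactly to the one-site case, which is tested.  Reversed
titrations (macromolecule in the syringe, LC8 in the cell) reuse the same
heat function with the roles of the concentration curves swapped.

**Isotherm shape.** `curvature_sign_changes()` counts strict sign changes
of the second difference of the normalized-heat curve: a single sigmoid has
one, a two-phase curve with a visible intermediate has two or more.  With a
weak, less exothermic third event (e.g. Kd 0.03 µM vs 0.5 µM, h = −10 vs
−4 kcal/mol) the forward titration is two-phase, while titrating the
macromolecule into 10–15 µM LC8 — the reversed design, with excess LC8 over
the injectant early on — collapses it to a single sigmoid, reproducing the
observed direction-dependence of isotherm shape.  The default curvature
tolerance (1e-6 of the largest second difference) is meant for noiseless
model curves; noisy data need a coarser tolerance.

## Inverse problem

`fit_oss()` and `fit_sequential_constrained()` minimize squared residuals
of normalized heats with Levenberg–Marquardt (`minpack.lm::nls.lm`, ftol =
ptol = 1e-15).  Association constants are parametrized as `exp(θ)` because
they span decades, and N on a log scale for positivity.  Standard errors
come from the Jacobian at the optimum and are propagated first-order
through the reparametrizations (`se(Kd) = Kd · se(log Ka)`).

Initialization (when no start is given) uses standard ITC heuristics: ΔH
from the first-injection plateau, N from the molar-ratio position of the
steepest heat change, and a small grid of Wiseman c-values (1, 10, 100,
1000) for Ka, keeping the best refined start.  A flat isotherm (all heats
≈ 0) is returned flagged ill-conditioned rather than fitted.

The sequential fit enforces the constraint set `k1 = k2`, `h1 = h2`,
`k1 > k3`, `h1 < h3` structurally: equalities by sharing one parameter,
inequalities by the smooth reparametrization `k3 = k1·exp(−δ²)`,
`h3 = h1 + ε²` with `δ, ε` free.  Every returned point is feasible by
construction, and infeasible user starts are projected into the region
before optimization.  Because the sequential surface can have local minima,
the fit runs five jittered starts with a fixed sub-seed (so fits are
deterministic) and keeps the best residual.  Fitting genuinely single-event
data with the sequential model drives `k3` far below `k1` and/or leaves the
`h3` step poorly determined; the large standard error is flagged.

Replicates are fitted individually and aggregated by inverse-variance
weighting.  The aggregate error is implemented verbatim as
`σ̂ = 1/Σ(1/σᵢ²)` — a variance-scale quantity — with
`conventional = TRUE` returning the usual `sqrt` form; both are exposed
because the published form is the reciprocal sum.  Derived ΔG and −TΔS are
computed per replicate and then aggregated, rather than derived from
aggregated primaries; with near-equal replicate weights the two orders
agree to first order.

## Speciation model

`ladder_model()` describes the equilibrium mixture with two affinity
classes: `kd_intra` for intratrimer events and `kd_bridge` for bridging
events, free energies additive over bound LC8.  The geometry is the minimal
one consistent with the fixed 1:q and 2:3q stoichiometries: per QT register
each trimer hosts at most one intratrimer LC8 (occupying two of its three
chains) and the leftover chains host at most one bridging LC8.

Choices that were genuinely open, and how they were resolved:

* **Statistical factors.**  With `degeneracy = TRUE` (default) each
  intratrimer LC8 at an unbridged register carries a factor 3 (the chain
  pair can be chosen three ways); at a bridged register the bridge pins the
  third chain and the factor is 1.  Bridging events carry no extra factor
  and no homodimer symmetry factor is applied — both are absorbed into
  `kd_bridge`, which is how fitted constants are defined anyway.  Disable
  degeneracy when the supplied constants already include it.
* **Dimer-of-trimers association count.**  Assembling 2 trimers and m LC8
  into one complex involves m + 1 association events.  The m bound LC8
  contribute their class constants, and the trimer–trimer junction
  contributes one further bridging factor (the first bridging LC8 engages
  both of its grooves; ring closure by additional bridges is an
  intramolecular step absorbed into `kd_bridge`).  Species terms therefore
  scale as `K_intra^ni · K_bridge^(nb+1) · L^m · T²`, which is
  dimensionally consistent and makes bridged populations concentration-
  dependent, as dilution experiments show.
* **Minimal bridged occupancy.**  Bridged species carry at least one
  bridging LC8 and at least `q` LC8 in total (`m_min = q`, configurable),
  so the q = 3 intermediate ladder spans occupancies 3 through 9 — the
  range between the trimer-complex load and full occupancy.  Registers are
  treated as independent and 53BP1 dimers/tetramers are excluded; the model
  describes the major trimer-derived populations only.

The solver exploits structure: at fixed free LC8 the trimer balance is a
quadratic in free trimer, solved in closed form; the outer LC8 balance is a
bracketed one-dimensional root refined by damped Newton until both
conservation residuals are below 1e-12 of the totals (hard-checked at
1e-9 on every exit).  An independent refining 2-D grid search over (free
trimer, free LC8) confirms the solution in the tests.

`mass_profile()` converts a state to SEC-MALS-like observables: weight
fractions `∝ c·m` and weight-average mass `Σcm²/Σcm`, by default including
the free species.  `assign_composition()` maps a measured mass to the
nearest enumerated composition and reports the distance — deliberately not
asserting identity, since intermediate masses may also reflect unmodeled
oligomeric states.

## Synthetic data and study conditions

The generator emulates the titration design of the experiments being
modeled: 250–400 µM LC8 titrated into 10–35 µM cell protein.  The default
schedule is 28 × 10 µL injections of 300 µM titrant into 20 µM protein in a
1.4 mL cell (final molar ratio 3.0) at 298.15 K; injection count and
volumes are package conventions, since such details are rarely reported.
Noise is i.i.d. Gaussian on the *raw* heats (σ default 0.1 µcal —
instrument-scale noise; no published figure exists for these runs), applied
before normalization so its effect on normalized heats scales with injected
moles, as on the instrument.  First injections are retained by default;
`exclude_first` is available since anomalous first injections are common in
practice.  Replicate r of a set uses seed `seed + r − 1`, making every
replicate individually reproducible.

Presets named after the constructs (`wt-lbd-od`, `qt1-od`, `qt2-od`,
`qt3-od`, `qt12-od`, `qt13-od`, `qt23-od`) carry the tabulated OSS
parameters; `qt2-od` also carries the reported sequential affinity pair
(intratrimer 0.3 µM, bridging 1.1 µM).  Sequential event *enthalpies* were
not reported per construct, so the preset's values (−10, −10, −5 kcal/mol)
are simulation choices, documented as such.

What passing tests on these synthetics do and do not show: they establish
that the estimators recover known ground truth under the stated noise model
and schedule — they do not establish anything about baseline drift,
integration error, concentration mis-calibration or heat-of-dilution
structure in real instrument data, none of which the generator emulates.

## Problem sizes and numerical checks

The test suite fits ~80 synthetic isotherms (40 random draws across the
identifiable Wiseman-c range 5–500, 25 noisy replicates for the recovery
check, plus smaller cases), verifies the OSS closed form against the
bisection oracle on 1,000 draws, and checks speciation conservation on
1,000 random scenarios with the grid oracle on a representative case.
These sizes were chosen to exercise the identifiable regime densely while
keeping the default run short.

Known limitations: the sequential fit supports exactly the bridged-hexamer
constraint topology (the one this system needs); speciation has no
kinetics and no 53BP1 dimer/tetramer states; sedimentation coefficients
are not predicted (compositions are compared by mass only); and no
competition/displacement ITC models are included.
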