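---
title: "Models and methods behind gpcrsel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpcrsel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrsel)
```

# The problem

An agonist can prefer one receptor subtype through *affinity* (it binds more
tightly) or through *efficacy* (bound agonist produces more activation).
Distinguishing the two requires measuring affinity and efficacy separately
and on comparable scales, and — when molecular simulations are involved —
turning trajectories into defensible activation statistics. `gpcrsel`
implements that toolchain: binding-curve models, the operational model of
agonism with expression correction, a ternary-complex equilibrium model
with state free energies, trajectory state classifiers, and the resampling
statistics used to compare simulation conditions. A synthetic-data module
generates every input with known ground truth, so the whole pipeline is
testable offline.

# Binding models

Saturation binding is the one-site hyperbola with a linear nonspecific term,
fitted *globally* to total and nonspecific series with the nonspecific slope
shared. Whether the nonspecific component should be shared or per-curve is
an assay-level choice that published methods rarely state; the shared
convention is the package default and the only one implemented — it is the
stronger constraint and the common Prism workflow.

Competition binding uses the empirical one-site inhibition curve and the
two-site generalization in which a proportion `fraction_high` of sites has
the lower IC50. The two-site equation is symmetric under swapping the two
sites, so after fitting, sites are relabeled so that site 1 is always the
high-affinity one. IC50s convert to pK_i by Cheng–Prusoff using the
radioligand concentration and K_d.

Model choice between one and two sites (`sites = "auto"`) uses AICc, with
one guard: the residual sum of squares entering AICc is floored at
`n · (1e-7 · range(y))²`. On noise-free data both nested models reach
machine-zero RSS and the comparison would otherwise be decided by
floating-point noise; the floor makes the extra parameters count against
the two-site model, so parsimony wins exactly when the data carry no
evidence of a second site. An F-test would be an alternative; AICc was
chosen because it needs no significance threshold and handles the non-nested
reporting (`candidates`) uniformly.

# Operational model of agonism

The response model is

$$Y = \mathrm{Basal} + \frac{E_m - \mathrm{Basal}}
      {1 + \dfrac{10^{\log K_A} + 10^{\log[A]}}{10^{\log\tau}\,10^{\log[A]}}},$$

with the transducer slope fixed at 1 (the generalized slope parameter is
deliberately out of scope). $\tau = R_T/K_E$ is the efficacy index: total
receptor density over the agonist–receptor complex concentration producing
half of $E_m$.

Identifiability drives the fitting interface. From a single curve with
$E_m$ and Basal free, $K_A$ and $\tau$ are *jointly unidentifiable* — the
curve only exposes its bottom, top and EC50. The package therefore (i)
accepts `log_ka_fixed` so $K_A$ can be pinned to the binding-derived pK_i,
which is the standard treatment for high-efficacy agonists; (ii) fits
$E_m$/Basal as *shared* parameters across a ligand panel measured in the
same cells, so partial agonists anchor the system maximum; and (iii) flags
near-unidentifiable joint fits via the $K_A$–$\tau$ correlation (|r| >
0.999) or a singular information matrix. Basal is constrained non-negative
and fitted (fixing it at the vehicle mean is the obvious alternative; the
fitted version uses the replicate structure and degrades gracefully when no
true zero-dose data are present).

## Expression-corrected efficacy

Theory and experiment agree that $\tau$ scales linearly with receptor
density, so efficacies measured in cell lines with different expression are
comparable only after rescaling. The default convention is

$$\tau_C = \tau_\mathrm{target}\cdot
  \frac{\mathrm{expression}_\mathrm{reference}}{\mathrm{expression}_\mathrm{target}},$$

i.e. the target receptor's τ rescaled to the reference receptor's
expression. A published verbal description of this correction multiplies by
the *inverse* ratio; read literally that amplifies rather than normalizes
the expression difference, contradicting the τ ∝ R_T principle it cites.
The package defaults to the physically consistent direction and exposes the
literal one behind `convention = "literal"`. Which receptor serves as
reference is a required argument, never a guess. Because the correction is a
deterministic shift on the log scale, the standard error is unchanged.

# Ternary complex model

Ligand L, receptor R and G protein G form LR, RG and LRG. Binding of G
increases the agonist's affinity α-fold (and, by microscopic reversibility,
vice versa): `pKi_high = pK_L + log10(α)`, and the coupling free energy is
ΔΔG = −RT·ln α.

**Solver.** The six-species equilibrium reduces to two unknowns, free R and
free G: free ligand concentrations are closed-form given (R, G), leaving the
R and G conservation equations. These are solved by a damped fixed-point
sweep (geometric-mean damping, robust globally) followed by a log-space
Newton iteration with elementwise backtracking (quadratic convergence near
the root), and a nested-bisection fallback for any condition that resists —
both conservation residuals are monotone in their own unknown, so bisection
brackets the unique physical root. Converged solutions satisfy mass action
and all three conservation laws to a relative residual below 1e-10; the
test suite checks the solver against an independently written brute-force
nested-bisection oracle on random parameter draws.

**Competition prediction.** The radioligand is modeled as a second ligand
with its own cooperativity, defaulting to α = 1 (a neutral antagonist binds
R and RG equally). Predicted displacement curves are normalized to the
zero-competitor bound signal, matching how such assays are reported.

Two regimes of the model are worth distinguishing, because they determine
what a two-site fit can see. With G in large excess over receptor *and*
fast exchange, every receptor experiences the same free-G level and the
equilibrium displacement curve is strictly one-site at an intermediate
apparent affinity. Genuinely biphasic equilibrium curves require *limiting*
G (g_tot below r_tot with tight G binding): the receptors that hold a G
protein form the high-affinity fraction, so `fraction_high` tracks the G:R
stoichiometry. Experimental two-site curves observed at nominally large G
excess therefore imply that only a small fraction of added G protein is
active/coupled, or that exchange is slow on the assay timescale; the
package treats the effective G concentration as a user-supplied scalar
(`g_tot` per curve) rather than modeling nucleotide state — G is a single
binding species, and no kinetic ternary model is attempted.

**Global fit.** `fit_ternary()` estimates (pK_L, log₁₀α, pK_G) across a
G-titration by least squares on predicted versus observed displacement, with
one global signal scale profiled analytically. α is identifiable only if
some curve approaches G saturation; when it is not (e.g. a single g_tot = 0
curve), the fit attaches a warning with profile-likelihood bounds on log₁₀α
from a coarse grid refit.

**Free energies.** Each binding edge converts as ΔG = −RT·ln10·pK
(association constant 10^pK M⁻¹, 1 M standard state). The cycle
ΔG(L,R) + ΔG(G,LR) = ΔG(G,R) + ΔG(L,RG) closes exactly by construction and
is asserted in tests to 1e-9 kcal/mol. Temperature defaults to 310.15 K
with 298.15 K selectable — binding assays at "room temperature" sit between
the two, and both values round the published worked example to the same one
significant figure. State free-energy differences between receptor subtypes
can be obtained either by direct conversion of fitted two-site pK_i values
(`delta_delta_g()`) or from the full equilibrium fit
(`free_energies(fit$model)`); both paths are exposed because which one a
published figure used is often unstated, and on clean data they agree by
construction of the model.

# Trajectory state classification

Features are computed from a minimal long-format coordinate table (frame,
atom label, x, y, z in Å) — adapters to binary trajectory formats are
intentionally out of scope to keep the core dependency-free. Cα–Cα
distances are Euclidean; χ1 is the signed N–CA–CB–CG dihedral in degrees on
(−180, 180], with the IUPAC sign convention (checked against an independent
vector-algebra oracle and matching MDAnalysis). A Ballesteros–Weinstein
residue map per subtype keeps feature definitions portable across
receptors; the ligand mid-tail atom is a map field, not a constant, because
analogs with different tail lengths need different anchors.

The classifiers are fixed thresholds taken from the source analysis:
channel-open when χ1 of N6.52 lies in (−50°, 100°); receptor-active when
the intracellular TM3–TM6 Cα(3.46–6.37) distance exceeds 10 Å (≈8 Å when
inactive); TM6-outward above 20.7 Å on Cα(4.57–6.55); ligand tail vertical
below 8.9 Å to the ECL2 anchor Cα. All bounds are strict, as the verbal
definitions ("greater than", "less than") suggest; on continuous features
the boundary has measure zero, so the convention is documented rather than
consequential. The χ1 interval does not cross the ±180° seam, so no
wrap-around logic is needed there.

Equilibration exclusion is expressed in nanoseconds (50 ns default for the
channel classifier, 100 ns for the tail metric) and converted through each
simulation's frame times, so mixed frame rates remain correct. State
frequencies are computed per simulation — each simulation is one
independent sample for group statistics — and a simulation with no eligible
frames is reported as missing, never as zero. Conditioning (e.g. "active
frames only") intersects the masks and the conditioning labels before the
denominator is formed. Smoothed traces use a centered 30-ns moving average
with shrinking edge windows, with the raw series retained.

# Group statistics

`bootstrap_ci()` is the plain percentile bootstrap of the mean: endpoints
are order statistics of the resampled means, 68% by default (≈ one
standard error, the plotting-library convention for non-parametric error
bars), 10 000 resamples, seeded. BCa corrections are deliberately not used
— the convention being reproduced is the plain percentile method.

`mann_whitney_u()` computes U from midranks. The p value is exact by
dynamic-programming enumeration of the null distribution when
`n_a·n_b ≤ 400` and the pooled sample has no ties; otherwise a normal
approximation with continuity and tie correction is used, and the method
actually applied is recorded in the result. The exact path is verified
against full combinatorial enumeration in the tests.

# Synthetic data

The generators emulate the *statistical shape* of the source assays, not
their biology: operational-model dose–response curves with additive
homoscedastic Gaussian noise (ordinary least squares in standard curve-fit
software implicitly assumes exactly that); saturation/competition binding
curves from the same equations the fitters use; and two-state hidden Markov
feature traces whose emissions mimic dihedral and distance observables
(dihedrals wrapped onto (−180, 180]). Defaults follow the stated world of
the source analyses where given — 2 μs traces saved every 200 ps
(10 000 frames at 0.2 ns), a 50-ns equilibration window, 8-point
concentration grids with 3 replicates — and otherwise use one fixed
realistic choice: replicate noise defaults to 5% of E_m, a typical
cell-assay scatter, because no replicate-noise magnitude is published; it
is a fixture, not a claim. Every spec carries a single integer seed and
regenerates bit-identically.

What a green test on synthetic data does *not* establish: that real
trajectories are two-state with Gaussian emissions, that real assay noise
is homoscedastic, or that the equilibrium ternary model captures slow
G-protein exchange. The synthetic Markov traces retain their true state
labels precisely so classifier error can be separated from sampling error
(the analytic Gaussian-tail misclassification bound in the tests).

# Numerical choices

All fits are bounded multi-start nonlinear least squares on top of
`stats::optim(method = "L-BFGS-B")`: starting values from data extrema plus
a grid of log-IC50/log-K starts spanning the concentration range, best
solution by RSS. Finite-difference steps are taken relative to parameter
magnitude (`parscale`), which matters when a nonspecific slope of order
1e9 shares a fit with a pK of order 10. Standard errors come from the
column-normalized Gauss–Newton approximation
σ²(JᵀJ)⁻¹ with a central-difference Jacobian; the normalization keeps the
inversion stable across badly scaled parameter sets, and a singular
information matrix is reported (`se = NA`, warning) rather than silently
dropped. Degenerate inputs (flat curves, zero dynamic range, empty groups)
return explicit fit-failure objects or missing values — never silent
defaults.

# Known limitations

* No kinetic binding or kinetic ternary models; everything is equilibrium.
* No biased-signaling (transduction-coefficient) analysis; the efficacy
  scale is τ/τ_C only.
* The operational model's transducer slope is fixed at 1.
* The equilibrium ternary model cannot produce biphasic curves under true
  excess-G fast-exchange conditions (see above); interpreting fitted
  `g_tot` as *effective active* G protein is left to the user.
* Trajectory ingestion is text-table only by design; convert binary
  trajectories upstream.
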