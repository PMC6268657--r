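---
title: "Competitive Al(III) complexation with ciprofloxacin and NADP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive Al(III) complexation with ciprofloxacin and NADP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eqspec)
```

`eqspec` implements the computational chain used to quantify how the
antibiotic ciprofloxacin (CIP) and the coenzyme NADP compete for Al(III) in
aqueous solution: equilibrium speciation from cumulative formation
constants, rank annihilation factor analysis (RAFA) of spectral titration
matrices, and least-squares refinement of formation constants from
pH-potentiometric titrations. This vignette documents the models, the
numerical choices, and the limits of what the synthetic-data experiments
can show.

## The equilibrium model

Everything is built on the cumulative-formation-constant formulation. A
model consists of *components* (Al³⁺, the fully deprotonated ligands CIP⁻
and NADP³⁻, and the proton) and *species* $\mathrm{M}_p\mathrm{L}_q\mathrm{H}_r$,
each defined by signed stoichiometric coefficients over the components and
a constant $\log\beta$ such that

$$[\mathrm{M}_p\mathrm{L}_q\mathrm{H}_r] = 10^{\log\beta}\,
  [\mathrm{M}]^p[\mathrm{L}]^q[\mathrm{H}]^r .$$

Hydroxide-containing species carry negative proton coefficients: OH⁻ itself
is the species $\{H{:}-1\}$ with $\log\beta = -pK_w = -13.78$ (25 °C,
0.2 M KCl), and the Al(III) hydrolysis products Al(OH)$_q$, $q = 1\ldots4$,
have cumulative constants $-5.5$, $-11.1$, $-16.6$, $-23.2$. The proton
component carries a *signed* analytical total: dissolved ligand protons and
strong acid add to it, strong base subtracts from it. This is the standard
bookkeeping of BEST/HySS-class programs, and it makes titration simulation
a pure dilution exercise. The built-in `cip_nadp_model()` carries the full
set of sixteen protonation, binary, and mixed-ligand constants of the
system plus water and hydrolysis.

Two conventions deserve flagging because the source material leaves them
open. First, all tabulated constants are interpreted as *cumulative*
formation constants from free components (e.g. for Al(HL):
$\beta = [\mathrm{AlHL}]/([\mathrm{Al}][\mathrm{L}][\mathrm{H}])$), the
standard output convention of BEST; if they were stepwise constants only
the model-translation layer would change. Second, constants determined at
different ionic strengths (hydrolysis at I = 0.16, the rest at 0.2 M KCl)
are used side by side without activity correction, matching the original
analysis; no Davies or Debye–Hückel module is provided.

## Solving the speciation problem

`solve_speciation()` finds the free concentrations satisfying all mass
balances by a damped Newton iteration on the *natural-log* free
concentrations, which guarantees positivity. Convergence requires every
relative mass-balance residual to fall below `tol` (default `1e-10`,
relative to the larger of the analytical total and the gross species sum)
within `max_iter` (default 200) iterations.

Polynuclear species with large coefficients (Al(H₂NADP)₃ has
$\log\beta = 57.53$ and stoichiometry AlL₃H₆) make the raw residual
astronomically steep far from the solution, where a Newton step with naive
damping stalls. Three safeguards handle this:

* a **log-scaling preconditioner** runs first: for every component with a
  positive total, the free concentration is updated by
  $\Delta\ln[j] = (\ln T_j - \ln \hat T_j)/m_j$ where $\hat T_j$ is the
  positive-coefficient species sum (evaluated in log space, so it cannot
  overflow) and $m_j$ the largest coefficient — the classical fixed-point
  walk of COMICS/HALTAFALL-type solvers, which lands inside Newton's basin;
* the Newton step is capped at 5 natural-log units per component and halved
  while the residual norm grows;
* if Newton still fails and the model contains a proton component, the
  solver falls back to **bisection on pH**: the proton excess is monotone
  in pH, each inner fixed-pH subproblem is benign, and the result seeds a
  final full Newton polish.

Components with an exactly zero total are eliminated before solving (free
concentration and all species containing them set to zero), so a
metal-free sample yields exactly zero complexes rather than a rounding
residue. With `fixed_pH` the free proton concentration is clamped to
$10^{-\mathrm{pH}}$ and the proton balance dropped — the buffered,
conditional-scale convention used throughout the spectroscopic analyses.

`distribution_vs_pH()` and `distribution_vs_metal()` tabulate fractions of
a reference component; the fractions sum to 1 within 1e-8 at every grid
point, which the tests enforce. Warm starts (each grid point seeded with
the previous solution) keep the scans fast and the solution branch
continuous.

## Conditional constants and free energies

At fixed pH the competing hydrolysis of the metal is absorbed into a
side-reaction coefficient

$$\alpha_M(\mathrm{pH}) = 1 + \sum_q 10^{\lg\beta_q}\,[\mathrm{H}^+]^{-q},
\qquad \log K' = \log\beta - \log\alpha_M ,$$

computed by `side_reaction_coefficient()` /`conditional_constant()`. With
the Al(III) constants above, $\log\alpha_{Al} = 4.95$ at pH 7.0.
`gibbs_from_logK()` converts a stability constant to the dissociation free
energy $\Delta G = \ln(10)\,R\,T\,\log K$ in kcal/mol
(R = 1.9872 cal mol⁻¹ K⁻¹): 13.9 kcal/mol for $\log K' = 10.2$ at
298.15 K.

## RAFA: estimating conditional constants from spectra

A spectral titration at fixed ligand total $L_t$ and varying metal total
forms a wavelength × sample matrix that, under Beer–Lambert bilinearity
with two absorbing species, has rank 2:

$$X = \varepsilon_L\,[\mathrm{L}]^\top + \varepsilon_{ML}\,[\mathrm{ML}]^\top + E .$$

`annihilate()` subtracts the free-ligand term with concentrations computed
from the exact 1:1 binding quadratic (`bound_fraction_1to1()`) at a trial
$\log K$; at the true constant the residual collapses to rank 1. The ligand
molar response $\varepsilon_L$ is calibrated from the metal-free sample
divided by $L_t$ unless the user supplies a spectrum. `scan_logK()`
profiles the residual rank over a grid (default 6–14, step 0.05) with the
eigenvalue statistic

$$RSD(n) = \sqrt{ \frac{\sum_{j>n}\lambda_j}{r\,(s-n)} },$$

with $\lambda_j$ the eigenvalues of the uncentered covariance $X^\top X$,
$r$ the wavelength count and $s$ the sample count; `normalize = TRUE`
divides the trailing sum by $\sum_j\lambda_j$ instead. The literature cites
this statistic without printing a formula; any statistic strictly monotone
in the trailing eigenvalues has the same argmin, which is the quantity of
interest, so the choice affects only the RSD scale. Ties on a flat valley
break to the smallest $\log K$ with a warning. No hydrolysis correction is
applied inside the scan: the fitted constant is conditional at the buffer
pH, and `conditional_constant()` converts to the absolute scale when
needed.

### What the micromolar design can and cannot determine

At 20 µM ligand and $\log K' \approx 10$, binding is essentially
stoichiometric ($K'L_t \sim 3\times10^5$): every sub-equimolar sample has
free ligand pinned at $L_t - M_t$ regardless of $K$, and the only
$K$-sensitive observable is the equimolar free-ligand concentration
$\sqrt{L_t/K} \approx 35$ nM. With realistic molar absorptivities
(~3.5 × 10⁴ M⁻¹cm⁻¹) the resulting absorbance signature of a 0.1-unit
change in $\log K$ is ~10⁻³ AU concentrated in one sample, so with
0.002 AU read noise even a maximum-likelihood estimator with both spectra
known has a per-replicate uncertainty near one log unit, and the RSD
argmin — which additionally discards the component of the misfit parallel
to the retained spectra — scatters over several log units. The noise-free
scan is exact (the tests verify the minimum falls on the generating value
for any grid containing it), and Monte-Carlo recovery tightens to
±0.15 at 10⁻⁴ AU noise, which is where the consistency tests operate.
Recovery experiments at 0.002 AU therefore probe the identifiability of
the design, not the correctness of the estimator, and their scatter is
reported as found. The Al–NADP system is close to a second degeneracy:
complexation changes the absorbance intensity but not the band position,
so the ligand and complex responses are nearly collinear and rank
annihilation has almost no leverage.

`residual_spectra()` tests the two-binary-complex description of the
ternary system: synthetic spectra are built from the free ligands and the
two binary complexes with metal partitioned by `competitive_1to1_speciation()`
(no mixed-ligand species, no ligand–ligand interaction), and subtracted
from the observation. A residual band that is consistent across metal
levels — near 290 nm in the simulated data — is the signature of a direct
CIP–NADP interaction outside that model.

## Potentiometric simulation and refinement

`simulate_titration()` reproduces the strong-base titration of a 50.0 mL
sample: at added volume $v$ the totals are rescaled by $V_0/(V_0+v)$, the
base subtracts $C_b v/(V_0+v)$ from the proton total, and the pH is
$-\log_{10}[\mathrm{H}^+]$ from the full speciation solve (the electrode is
taken as calibrated for hydrogen-ion concentration; no activity
correction). Points where the solver fails are flagged and excluded, the
computational analogue of dropping titration points that fail to
equilibrate; ligand-exchange kinetics themselves are not modeled.

`refine_constants()` minimizes the summed squared pH residuals over one or
more datasets with respect to selected $\log\beta$ values:
Gauss–Newton with Levenberg damping, forward-difference Jacobian
(step 10⁻⁴ in $\log\beta$), Marquardt scaling floored at 10⁻⁶ of the
largest normal-equation diagonal so the system stays well-posed when a
parameter loses leverage, and a trust region of 0.5 log units per
parameter per step — without which a near-unidentifiable polynuclear
constant can be flung into a regime that destabilizes the speciation solve.
Steps that increase the residual, or that lose titration points to solver
failure, are rejected and the damping increased. Convergence is declared
when every $|\Delta\log\beta| < 10^{-5}$. Standard deviations come from
$s^2 (J^\top J)^{-1}$ at the solution. A species whose concentration is
zero throughout the data has an exactly zero Jacobian column and is
reported by name as unidentifiable. $\sigma_{fit}$ is the rms pH residual
over the used points; a satisfactory model reaches
$\sigma_{fit} < 0.01$.

`stepwise_model_build()` reproduces the model-building loop: candidate
species are added one at a time, each round refining the constants of the
species added so far and keeping the candidate with the largest
$\sigma_{fit}$ reduction, stopping when $\sigma_{fit} < 0.01$ or when no
candidate improves it by at least 5% relative. Because the loop stops as
soon as the base model already fits to within the threshold, read noise of
0.005 pH units does not trigger spurious additions on data generated
without the candidate species (the negative control in the tests).

On noise-free synthetic titrations the whole chain is exact to well below
0.01 log units: the ternary constants refine from ±1-perturbed starts back
to 26.56 and 32.49, the CIP/NADP protonation constants to 8.60/9.93, and
the six Al–NADP binary constants (from ±0.5 perturbations) to their
generating values, with $\sigma_{fit}$ at the solver-tolerance floor. With
0.005 pH read noise the ternary constants return within ±0.2 and
$\sigma_{fit} \approx 0.005$.

## The synthetic-data generator

The generators exist so that every analysis is testable without instrument
data; they produce exactly the statistical structure the analyses assume.

* **Spectra.** Molar responses are sums of Gaussian bands
  (`band_spec(center, width, amplitude)` in nm and AU M⁻¹ cm⁻¹ or
  counts M⁻¹). The frozen defaults encode the system's qualitative
  spectroscopy: CIP absorbs at 272 nm (ε ≈ 3.5 × 10⁴) with the quinolone
  doublet at 323/335 nm, shifting to 275 nm with a modest hyperchromic
  effect on complexation; NADP absorbs at 261 nm (ε ≈ 1.8 × 10⁴), its Al
  complex hyperchromic (+28%) at an unchanged maximum with a slightly
  narrowed band; CIP emits at 426 nm, the complex at 433 nm with 2.5× the
  intensity. Default grids: 240–360 nm step 0.5 (absorbance), 380–520 nm
  step 1 (emission).
* **Matrices.** `gen_uvvis_titration()` builds the bilinear two-species
  matrix from the 1:1 quadratic; `gen_ternary_titration()` builds the
  four-species competitive matrix from the fixed-pH speciation solve, plus
  an optional interaction band added identically to every column (scaled
  by the smaller ligand total), emulating a constant ligand–ligand
  association signature.
* **Titrations.** `standard_titration_design()` fixes the study frame:
  50.0 mL, ligand 0.001 M dissolved in the fully protonated form (CIP as
  H₂L⁺, NADP as H₃L), a 4 mM strong-acid excess placing the start near
  pH 2.4, KOH 0.1026 M, and a 60-point volume grid sized to pass the last
  equivalence point and reach pH ≈ 11 — matching the reported pH 2–11
  titration window at metal:ligand ratios 0:1, 1:1, 1:2, 1:5, and 1:1:1.
* **Noise.** Homoscedastic Gaussian noise per intensity point or pH
  reading, seeded through `noise_spec()`; identical inputs give
  bit-identical outputs (`withr::with_seed`, no global RNG pollution).

The generators deliberately omit instrument drift, baselines, stray light,
heteroscedastic shot noise, carbonate contamination, junction potentials,
electrode drift, and slow ligand-exchange kinetics. Tests that pass on
this synthetic data therefore establish the *internal* consistency of the
estimators — that they recover the constants generating data that obey the
model assumptions — not robustness to the systematic errors of real
instruments.

## Problem sizes and runtime

All simulations are desk-scale: 5–6-sample spectra on 241-point
wavelength grids, 161-point logK scans, 60-point titrations, 20-seed
Monte-Carlo loops. The full test suite and the analysis scripts each run
in well under a minute on one CPU.
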