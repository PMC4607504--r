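---
title: "Closing an open kinetic model of central carbon metabolism with genome-scale steady-state fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closing an open kinetic model of central carbon metabolism with genome-scale steady-state fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinetigrate)
```

## The modelling problem

A kinetic model of central carbon metabolism simulates the concentrations of
a few dozen intracellular metabolites with mechanistic enzyme rate laws. Cut
out of the full metabolic network, such a model is an *open* system: every
modelled metabolite is also produced and consumed by reactions that the model
does not describe, and growth dilutes all intracellular pools. kinetigrate
implements an integration strategy that closes the subsystem with constants
derived from a genome-scale metabolic network (GSMN) at steady state. The
metabolite balance is

$$\frac{d[m_i]}{dt} = \Big(\sum_j s_{ij}\, r_j([m];p_j) + c_i\Big)\rho_X - \mu\,[m_i],$$

with $r_j$ the mechanistic rate laws (mmol gDCW$^{-1}$ h$^{-1}$), $s_{ij}$
the stoichiometry, $\mu$ the fixed specific growth rate (default 0.2 h$^{-1}$,
the chemostat dilution rate of the reference dataset), $\rho_X$ the cell
density converting gDCW-normalized fluxes into concentration changes (mM/h),
and $c_i$ the *closure constant*: the net steady-state flux of all
"connecting" reactions — GSMN reactions outside the kinetic subnetwork that
touch metabolite $m_i$, including the biomass pseudo-reaction's drain.
Biomass grows exponentially and decouples; external glucose is constant;
cofactor pools (atp, adp, amp, nad(h), nadp(h), coa) are assumed balanced by
the rest of metabolism and enter rate laws as fixed parameters rather than
state variables.

## Pipeline stages and their assumptions

1. **Biomass rebalancing.** Measured biomass composition (µmol/gDCW) replaces
   the reconstruction's coefficients: amounts are converted to molar
   fractions, then to weight fractions of the components' mass share of one
   gram dry weight, then back to mmol/gDCW through molecular weights, so one
   unit of biomass flux yields exactly 1 gDCW.
2. **Strain-specific reparameterization.** Four quantities are free: the
   oxygen uptake bound, the non-growth ATP maintenance flux, the
   growth-associated ATP stoichiometry of the biomass reaction, and the
   proton stoichiometry of ATP synthase (periplasmic count $h_p$, cytoplasmic
   $h_p - 1$; atomic balance fixes the difference at one). They are fitted by
   least squares between model-predicted and measured exchange rates
   (glucose, oxygen, acetate) across dilution rates, with glucose left
   non-limiting (bound 1000) during the fit. The objective is evaluated by
   fixing growth, minimizing glucose uptake, then taking the
   minimal-total-flux distribution; it is piecewise smooth, so a multistart
   Nelder-Mead search (default 120 starts) with one restart per start is
   used. The multistart sampling distributions are uniform over declared
   physiological ranges; they are a package choice, configurable per call.
3. **Glucose-uptake calibration.** The uptake bound reproducing the target
   growth rate is found by bisection (growth is monotone in the bound) inside
   a confidence interval of measured uptake rates.
4. **Projection of measured central fluxes.** With growth fixed, glucose
   uptake minimized and fixed, and acetate secretion then oxygen uptake fixed
   at their flux-variability minima (sequentially, in that order — the order
   is configurable since either convention is defensible), the central
   fluxes measured by carbon-13 flux analysis are projected onto the feasible
   space by a quadratic program minimizing the squared Euclidean distance on
   the central coordinates. The QP is solved in the null space of the
   equality system (stoichiometry plus pinned fluxes), which stays well-posed
   even when the prefit pins the feasible set to a single point; a vanishing
   ridge (1e-8) on non-central coordinates keeps the reduced Hessian positive
   definite.
5. **Connecting fluxes and closure.** With central fluxes fixed, the
   minimal-total-flux distribution (L1, by forward/backward flux splitting —
   this removes futile cycles) supplies the connecting-reaction fluxes; their
   per-metabolite net is $c_i$. A flux-variability report certifies
   uniqueness: on all shipped fixtures the connecting ranges are below 1e-6.
   The biomass pseudo-reaction is included in the connecting set by default
   (`exclude_biomass` flips the convention); the closure invariant
   $\sum_j s_{ij} f_j + c_i = 0$ validates the choice per model. Installed
   into the kinetic model without correction, the reference-state residual
   equals the dilution term $\mu [m_i]$ exactly; `dilution_correction = TRUE`
   shifts $c_i$ by $\mu[m_i]/\rho_X$ so the reference concentrations are an
   exact fixed point — the convention used by the pipeline.
6. **Maximal rates and missing concentrations.** Michaelis constants are
   physical properties of the enzymes and are taken from the model
   definition; maximal rates are recomputed as $v_{max} = f_j / f([m];K_m)$
   from the projected fluxes, or from turnover numbers
   ($v_{max} = k_{cat}\cdot 3600\cdot E/(MW\cdot 1000)$) or specific
   activities ($v_{max} = sa\cdot E\cdot 60/1000$) — both conversions are
   exact rational scalings. Missing steady-state concentrations are solved
   jointly with minimal multiplicative adjustment of maximal rates (and,
   when released, binding constants): the objective is
   $w_1\,\mathrm{obj}_1 + w_2\,\mathrm{obj}_2 + w_3\,\mathrm{obj}_3$ with
   squared, summed terms — a signed difference cannot be minimized, so the
   bare differences of the formulation are squared here. Two weight policies
   are provided: the unbounded-factor policy sets $w_2 = 1$, $w_3 = 0$ and
   finds the minimum $w_1$ driving the flux residual below 1e-8 by a
   geometric/bisection line search; the bounded policy sets $w_1 = 1$,
   $w_2 = w_3 = 0$ and constrains all factors to $[0, 4]$. Shared unknowns
   take a single value across all equations of a subproblem.
7. **Stabilization.** If the reference state is unstable (positive spectral
   abscissa of the finite-difference Jacobian), selected literature-derived
   binding constants are scaled by factors $A_i \in [0.5, 2]$ minimizing
   $\max \mathrm{Re}(\lambda) + 0.01\,\lVert A - 1\rVert$ (L2 by default; the
   norm is configurable since either reading is defensible). The objective is
   non-smooth, so a derivative-free Nelder-Mead/Brent search runs from
   $A = 1$ plus random perturbations. Each touched reaction's maximal rate is
   rescaled in tandem so the reference state remains an exact fixed point;
   without this the spectrum would be evaluated off the fixed point and the
   result would be meaningless. A `method = "minimal"` variant bisects along
   the adjustment ray for the smallest adjustment achieving stability, which
   on one-parameter problems returns the critical (stability-boundary)
   factor; success is only ever reported after an independent eigenvalue
   recomputation (central differences at a different step size) confirms
   $\max\mathrm{Re}(\lambda) \le 0$.
8. **Phase-space scan.** Steady states are located from (default) 2000
   random initial concentration vectors drawn uniformly from $[0, 10]$
   (interpreted as mM — the natural scale of the measured metabolome, whose
   values span roughly 0.01-10 mM). Each search is two-stage: a damped
   Newton root solve, then, if its residual stalls (typical on systems whose
   eigenvalues span $10^0$ to $10^6$), a stiff relaxation (`lsoda`) seeded by
   the best iterate, followed by a Newton polish. In scan mode a root that
   classifies as unstable is replaced by relaxing the *original* initial
   condition under the flow: saddle points have measure-zero basins under the
   dynamics but sizeable ones under Newton iteration, and the scan's question
   is which attractors the metabolism can reach. Distinct states are
   de-duplicated at a relative L∞ distance of 1e-4 — far above the 1e-6
   residual tolerance and far below the separation of genuinely distinct
   metabolic states. Failures are categorized and counted, and the scan
   aborts if more than half the starts fail. Biomass is held constant during
   the scan so states are compared over the same cell volume.
9. **Classification.** Periodic is checked first (all real parts within
   tolerance of zero, some non-zero imaginary part), then unstable (any real
   part above tolerance), else stable; zero real parts count as stable. The
   zero tolerance is 1e-6 *relative to the largest real-part magnitude*
   because the spectra mix magnitudes from $10^0$ to $10^6$ and contain exact
   zeros.

## Rate laws

The law library is data-driven (kind + parameter map + participant roles):
mass action, irreversible and reversible Michaelis-Menten, an ordered bi-bi
mechanism with Monod-Wyman-Changeux (concerted) allosteric inhibition, and
catalogue/custom laws for mechanisms outside those kinds. The ordered bi-bi
MWC law models isocitrate dehydrogenase: nadp binds first as an essential
activator, no substrate-only enzyme complex forms (hence no lone
$icit/K_m$ term in the denominator, with the affinity factor absorbed into
$K_{m,icit}$), and phosphoenolpyruvate inhibits allosterically through
$R = (1+\beta)^n / (L(1+\gamma)^n + (1+\beta)^n)$, $\beta = icit/K_{m,icit}$,
$\gamma = pep/K_{i,pep}$. $R \to 1$ as $L \to 0$ and $R$ is strictly
decreasing in the inhibitor for $n > 0$; both limits are tested. Two
multiplicative adjustment hooks exist on every law: per-parameter factors
(`a1`) and a maximal-rate factor (`a2`); the literature uses clashing symbols
for these, so the package names them by what they touch.

During stiff integration the solver may step a concentration slightly
negative; the state is never modified, but rate evaluation clips negatives to
zero (and counts the events) so binding-constant denominators stay in domain
without distorting solver accuracy.

## Numerical choices

* LP: a dense bounded-variable two-phase simplex with Bland's rule, written
  in the package and checked against a brute-force vertex-enumeration oracle
  on every fixture with few enough free fluxes. Solver tolerances are 1e-9,
  well below the 1e-4 scale at which connecting-flux uniqueness is asserted.
* QP: null-space reduction plus the Goldfarb-Idnani active-set solver.
* Jacobians: forward differences with step 1e-10 (central differences with
  1e-6 for independent confirmation). On linear fixtures the forward scheme
  reproduces the analytic Jacobian to better than 1e-4 per entry.
* Stiff integration: `lsoda` with rtol 1e-8 / atol 1e-10.
* All randomness flows from explicit seeds; multistart counts default to the
  study conditions (120 strain starts, 25 curve-fit starts, 2000 scan
  starts) and are scaled down in the test suite and acceptance script
  (6 / 8-10 / 100-200) — sizes at which every reported property is already
  reproducible bit-for-bit under a fixed seed.

## What the synthetic fixtures emulate — and what they do not

The toy stoichiometric network is an aerobic glucose budget: glycolysis
(2 ATP and 2 carbon intermediates per glucose), acetate overflow (1 ATP),
respiration through a proton-pumping electron chain and ATP synthase (ATP
yield $8/h_p$ per carbon unit), maintenance, and a biomass reaction. It is
small enough for exhaustive vertex enumeration yet has the same identifiable
strain-parameter structure as a genome-scale reconstruction: the oxygen cap
binds only at higher dilution rates, so exchange-rate curves across dilution
rates pin all four strain parameters. The matched toy kinetic model
reproduces the network's dilution-0.2 flux distribution exactly at its
reference concentrations, so every recovery test has a known answer.

The bistable motif realizes the positive-feedback mechanism class behind
metabolic bistability (an autocatalytic, anaplerotic-style loop) as a Hill
autocatalysis whose nullcline is a cubic with roots engineered at 1, 3 and
7 mM — two stable points and a saddle, all in closed form, inside the scan
box. Two passive downstream metabolites relax linearly so the Jacobian keeps
a benign triangular structure.

Passing on these fixtures demonstrates that the machinery is correct, not
that real chemostat data are this kind: real fluxome/metabolome tables carry
correlated, non-Gaussian replicate error, missing values are not missing at
random, genome-scale networks have thousands of degenerate optima (here
degeneracy is exercised only through an engineered futile cycle), and the
full-scale kinetic model couples dozens of nonlinear laws where the fixtures
couple a handful. The full-scale reproduction layer of the acceptance suite
therefore requires the transcribed complete model definition, which is not
redistributable with the package; the corresponding checks are present and
fail cleanly until such a transcription is supplied.

## Known limitations

* Gene regulation, enzyme synthesis/degradation and stochastic kinetics are
  out of scope; results are valid on time scales shorter than regulatory
  dynamics (quasi-steady-state enzyme levels).
* No thermodynamic (Haldane) consistency is enforced across binding-constant
  sets, and reaction thermodynamics enter only as directionality bounds.
* Numerical continuation / bifurcation diagrams over parameters are not
  provided; the scan enumerates coexisting attractors at fixed parameters.
* The simplex is dense and deliberate: adequate for the desk-scale networks
  the package targets, not tuned for genome-scale reconstructions with tens
  of thousands of reactions.
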