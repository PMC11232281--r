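---
title: "Modelling redox cooperativity in multiheme cytochromes with hemeCoop"
author: "hemeCoop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling redox cooperativity in multiheme cytochromes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeCoop)
```

## The scientific problem

When two heme cofactors sit a nanometre or two apart inside a protein, their
midpoint potentials are not independent: removing an electron from one heme
leaves a positive charge that electrostatically destabilizes oxidation of its
neighbour. This *redox cooperativity* splits the macroscopic midpoint
potentials of the pair by an amount ΔE~m~ that can reach 100 mV or more in
transmembrane cytochromes. Two physically distinct contributions make up the
splitting:

1. **Environmental asymmetry** — the two hemes sit in (slightly) different
   electrostatic micro-environments, so their oxidation free energies differ
   even with the partner held reduced.
2. **Heme–heme interaction** — the pairwise electrostatic coupling *w~12~*
   between the two oxidized states.

Because the interaction term is a screened Coulomb energy, the dielectric of
the surroundings controls its size: burying the heme pair in a low-dielectric
membrane amplifies the coupling roughly by the ratio of the dielectric
constants. hemeCoop implements the full modelling chain needed to quantify
this: continuum electrostatics on structures, microstate thermodynamics,
Nernst fitting, the environmental/interaction decomposition, and
Marcus-theory electron-transfer kinetics.

## The microstate Hamiltonian

All thermodynamics derive from the standard reduced-site Hamiltonian over
occupancies $x_i \in \{0, 1\}$ (1 = oxidized for redox sites, protonated for
protonatable sites):

$$G(x) = \sum_i x_i\, g_i + \sum_{i<j} x_i x_j\, w_{ij},$$

with $g_i = E^\circ_i - E_{\mathrm{sol}}$ (meV; oxidation is unfavourable
below the intrinsic midpoint $E^\circ_i$ and favourable above it) and
$g_i = \ln 10\, RT\,(\mathrm{pH} - \mathrm{p}K_{a,i})$ for protonatable
sites. One sign convention is used throughout: curves report *oxidized*
(protonated) fractions, which increase with solution potential (decrease
with pH). RT/F is 25.693 mV at the default 298.15 K.

Two samplers share this Hamiltonian:

* `enumerateOccupancies()` computes exact Boltzmann averages over all $2^n$
  microstates (refused above $n = 20$);
* `mcTitration()` runs Metropolis Monte Carlo with single-site flips plus
  joint pair flips for strongly coupled pairs ($|w| > 2\ln 10\,RT \approx
  118$ meV), where single flips alone mix slowly. Defaults are $10^5$
  sampling steps and $10^4$ equilibration steps per potential — enough that
  sampling error, not bias, dominates for $n \le 10$ at desk scale.

Sampling errors come from block averaging (10 blocks). Block estimates
collapse for rarely visited states (most blocks see no transition), so the
reported error is floored by $\sqrt{2\,p(1-p)/N_\mathrm{eff}}$ with
$N_\mathrm{eff}$ = steps per site; the factor 2 accounts for the entry/exit
correlation of single-flip sampling, under which each visit to a rare state
contributes roughly twice the variance of an independent draw.

## Macroscopic midpoints and ΔE~m~

`macroscopicMidpoints()` reports stepwise macroscopic midpoints: the k-th
midpoint is the solution potential at which the populations of the
k-oxidized and (k−1)-oxidized macrostates are equal. This is the classical
stepwise-equilibrium definition, and for two identical non-interacting sites
it yields the statistical factor $\Delta E_m = 2(RT/F)\ln 2 = 35.6$ mV; an
interaction $w$ between identical sites adds on top of it
($\Delta E_m = w + 35.6$ mV). We deliberately did *not* define midpoints by
where the total-oxidation curve crosses $k - \tfrac12$: that definition is
superficially similar but yields $2(RT/F)\ln 3 = 56.5$ mV for the
independent pair, which is not the statistical factor the stepwise
equilibria imply, and it does not connect to the Nernst fits used for
experimental curves.

`fitNernst()` fits $f(E) = (1 + e^{-n_{app}(E - E_m)/(RT/F)})^{-1}$ by
least squares (with `fixN = 1` for the standard single-electron protocol),
which mirrors how potentiometric titrations are reduced to midpoints in the
laboratory.

## Continuum electrostatics

`computeEnergyTerms()` produces the Hamiltonian's ingredients from a
structure:

* **dg~ox~** — the oxidation free energy of each heme with every other heme
  reduced, computed as a thermodynamic cycle: the heme's oxidation
  charge-difference set (+1 e total) is solved in the full
  protein/solvent/membrane dielectric map and in an isolated-heme aqueous
  reference *on the same grid*, so the singular grid self-energy cancels
  exactly; the difference of reaction fields plus the interaction with all
  fixed background charges is the reported shift (meV, relative scale — no
  absolute calibration is attempted; a model-compound reference can be added
  via `modelFromTerms(reference =)`).
* **w~ij~** — the charge-difference potential of site *i* contracted with
  the charge-difference set of site *j*; symmetric within grid tolerance and
  symmetrized explicitly.

The solver is a finite-difference linearized Poisson–Boltzmann solver:
7-point stencil, harmonic averaging of the dielectric across interface
faces, successive over-relaxation (ω = 1.9) to a relative update tolerance
of 10⁻⁶, Debye–Hückel (or plain Coulomb) monopole boundary values, and
two-level focusing (coarse 1.0 Å over the whole domain with a 15 Å margin,
fine 0.25–0.4 Å box around the hemes). Against closed forms the defaults
give ~0.1% error on the Coulomb potential at 10 Å and ~3% on the Born
transfer energy of a 2 Å ion, comfortably inside the 5% the package's tests
require; the error decreases monotonically under grid refinement.

The dielectric map assigns the protein dielectric to nodes inside the van
der Waals union of atom spheres, the membrane dielectric to exterior nodes
inside the slab (the membrane normal is fixed to z — structures must be
pre-oriented), and the solvent dielectric elsewhere, with optional
Debye screening at non-zero ionic strength (default 0). A true probe-rolled
solvent-excluded surface is not constructed: for the smooth convex fixtures
and oracle geometries used at desk scale the vdW union is exact, and crevice
re-entrance mainly matters for tightly packed experimental structures where
users may prefer to inflate radii.

Three environment presets mirror commonly used settings:
`"aqueous-78.2"`, `"membrane-6.445"` (slab dielectric equal to the protein
interior, aqueous 78.2 beyond a ~30 Å slab) and `"pbmc-20"` (solvent 80 /
protein 20). The membrane dielectric is deliberately configuration, not a
hard-coded constant: reported practice varies (values from 4 to 20 are in
circulation for slab models), so the package takes the value from the
environment object and documents the presets.

The interior protein dielectric can be estimated from heme solvent
exposure: `computeSasa()` implements Shrake–Rupley areas (960 golden-spiral
points by default, probe 1.4 Å) and reports per-site heme exposure (site
SASA in context over site SASA in isolation);
`estimateInteriorDielectric()` maps exposure through a configurable
monotone interpolation bounded by [4, 25] by default. The exact published
calibration for this mapping is not reproduced here; instead two named
presets, `dielectricPreset("4D2")` = 6.776 and `dielectricPreset("CytbX")`
= 6.445, carry the reference values for those scaffolds, and any
user-supplied monotone knot table is accepted.

## Decomposition and its conventions

`decomposeSplitting()` reports env = |dg~ox,1~ − dg~ox,2~|, int = w~12~,
total = env + int, and integer percentages rounded half-up independently
(so they may sum to 99–101; a zero total yields NA percentages). The
high-potential heme is the site with the **larger** oxidation energy: since
$E_m = \Delta G_{ox}/F + \mathrm{const}$, the heme that is harder to
oxidize titrates at the higher potential. The decomposition total relates
to the enumerated ΔE~m~ by the statistical factor: for near-identical
sites, ΔE~m~ ≈ total + 35.6 mV, which the cross-module tests verify.

## Marcus kinetics and hopping current

`marcusRate()` is the non-adiabatic golden-rule rate
$k = (2\pi/\hbar) H_{DA}^2 (4\pi\lambda k_BT)^{-1/2}
\exp[-(\Delta G + \lambda)^2 / 4\lambda k_BT]$. Reorganization energies
default to the Marcus two-sphere continuum expression with 4 Å effective
heme radii and optical dielectric 2.0, all configurable — a deliberate
package choice of method where a standard one was needed.
`assignGenericCoupling()` classifies heme pairs by inter-plane angle
(SVD-fitted ring planes; stacked ≤ 35°, else T-shaped) and returns
configured generic couplings (defaults 8 and 2 meV — configuration values,
not measurements). `steadyStateCurrent()` solves the mean-field
single-occupancy hopping equations (flux
$J_i = k_{f,i} p_i(1-p_{i+1}) - k_{b,i} p_{i+1}(1-p_i)$, boundary injection
and ejection) with a damped Newton iteration; flux conservation across
junctions holds to 10⁻⁹ relative and the single-site closed form
$k_{in}k_{out}/(k_{in}+k_{out})$ is reproduced exactly.

## The synthetic fixture and what passing tests mean

`generateBundle()` emulates an idealized four-helix bundle: Cα-trace ideal
helices (1.5 Å rise, 100°/residue, 2.3 Å local radius) on a 7.5 Å bundle
circle, one or two 13-atom dummy hemes (Fe, four pyrrole-like N, eight
planar ring carbons) on the bundle axis at a configurable Fe–Fe separation
(default 17 Å, of the order of a diheme bundle), bis-His pseudo-ligands at
2.1 Å, and a small seeded coordinate jitter (σ = 0.02 Å) so distinct seeds
give distinct structures. The built-in simplified oxidation charge set
places +0.6 e on Fe and +0.1 e on each pyrrole N; real force-field charge
sets can be supplied as plain-text tables.

The fixture supports site detection, SASA, monopole-level electrostatics
and the full pipeline, but it is *not* a protein: no sequence, no
sidechains, no charged surface groups, no conformational ensemble. Tests
passing on it demonstrate that the machinery is numerically correct
(oracles, closed forms, cross-module consistency) and that the qualitative
membrane-amplification mechanism follows from the physics; they do not
certify quantitative predictions for experimental structures, which
additionally require real charge/radius sets and pre-oriented coordinates.
Conformational averaging over dynamics is likewise out of scope — the
continuum terms are single-structure quantities.

## Numerical choices and degenerate inputs

* Grid: coarse 1.0 Å, fine 0.4 Å default (0.25 Å available), 15 Å margins,
  6 Å focus margin; identical domain and focus boxes are pinned across the
  paired solves of each thermodynamic cycle so self-energies cancel.
* SOR: ω = 1.9, max 10⁴ iterations, convergence = max update < 10⁻⁶ of the
  field maximum; non-convergence raises an error carrying the residual.
* Heme detection: Fe–ligand cutoff 3.0 Å (His-N ≈ 2.0–2.2 Å, Met-S ≈
  2.3–2.5 Å); c-type iff a Cys sulfur lies within 2.2 Å of a heme carbon;
  fewer than two axial candidates → ligation "unassigned" plus a warning;
  unsupported ligand combinations are flagged.
* Nernst fitting requires ≥ 5 points and an oxidized-fraction range ≥ 0.1
  ("transition not spanned" otherwise); `nls` is tried first and
  Levenberg–Marquardt (`minpack.lm`) used as fallback.
* Stepwise midpoints check total-oxidation monotonicity on a grid first and
  refuse non-monotone (negative-coupling) curves.
* Titration grid default −400…+200 mV in 5 mV steps; problems whose
  transitions fall outside (e.g. strongly destabilized membrane fixtures)
  should pass an explicit grid — the pipeline surfaces this as a fit-stage
  error rather than extrapolating.

## Problem sizes used by the test-suite and acceptance runs

Tests run the PB oracles at 0.4 Å focused spacing on single-charge and
two-charge systems (seconds each), the MC-vs-enumeration comparison on 20
seeded random models with up to 10 sites at 10⁵ steps per potential on a
19-point grid, 100-replicate Nernst noise studies, and the full fixture
pipeline (126 atoms, 2 hemes, four PB solves per environment). These sizes
were chosen so that every check is an honest computation of the quantity it
validates while the whole suite stays interactive.

## Known limitations

* Linearized PB only; no nonlinear salt response.
* vdW-union dielectric envelope (see above); no SES.
* Single-structure energetics; no MD-snapshot averaging.
* Mean-field exclusion in the hopping current; no multi-electron
  correlations along the chain.
* The SASA→dielectric mapping is a bounded monotone interpolation plus
  named reference presets, not a published calibration curve.
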