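# hemeCoop

Quantifying **redox cooperativity** in multiheme cytochromes: when two heme
cofactors sit close together in a protein, oxidizing one electrostatically
destabilizes oxidation of the other, splitting the pair's macroscopic
midpoint potentials by ΔE<sub>m</sub>. The splitting has two parts —

* an **environmental** term, the difference of the per-heme oxidation free
  energies dg<sub>ox,i</sub> with the partner reduced, and
* a **heme–heme interaction** term w<sub>12</sub>, the screened Coulomb
  coupling between the two oxidized states —

and the interaction term is amplified when the pair is buried in a
low-dielectric membrane, roughly by the ratio of the dielectric constants.
hemeCoop implements the full modelling chain for this analysis, aimed at
researchers studying natural and de novo designed heme proteins:

* **Structures** — PDB I/O, automatic heme detection (b/c type, His-His vs
  His-Met axial ligation), Shrake–Rupley SASA, and a SASA-based estimate of
  the interior dielectric with named presets.
* **Electrostatics** — a finite-difference linearized Poisson–Boltzmann
  solver (two-level focusing, harmonic interface averaging, Debye–Hückel
  boundaries, optional implicit membrane slab) producing per-heme oxidation
  energies and the pairwise interaction matrix.
* **Microstates** — the joint proton/electron microstate Hamiltonian
  G(x) = Σ x<sub>i</sub>g<sub>i</sub> + Σ x<sub>i</sub>x<sub>j</sub>w<sub>ij</sub>,
  sampled by exact enumeration (n ≤ 20) or Metropolis Monte Carlo, with
  single-electron Nernst fits f(E) = 1/(1+e^(−n(E−E_m)F/RT)) and stepwise
  macroscopic midpoints.
* **Cooperativity** — decomposition of ΔE<sub>m</sub> into environmental and
  interaction contributions with percentage attribution and high/low-potential
  heme assignment, construct-to-construct shift reports, and dielectric
  sensitivity (membrane vs aqueous) analysis.
* **Kinetics** — non-adiabatic Marcus rates, two-sphere continuum
  reorganization energies, orientation-based generic couplings, and
  steady-state hopping redox currents with single-occupancy exclusion.
* **Fixtures** — a synthetic four-helix-bundle generator with one or two
  bis-His heme-like sites, so the whole pipeline runs and is tested without
  any external data.

## Worked example

A synthetic diheme bundle in a membrane-like environment (slab dielectric
6.445, aqueous 78.2 beyond a 30.6 Å slab):

```r
library(hemeCoop)

s     <- generateBundle(bundleSpec(membraneSpan = 30.6))
sites <- detectHemeSites(s)
terms <- computeEnergyTerms(s, sites,
                            environmentPreset("membrane-6.445",
                                              slabZ = c(-15.3, 15.3)))
terms
#> EnergyTerms for 2 site(s)
#>   dg_ox (meV): 413.7, 413.1
#>   w_pair (meV): 47.1

decomposeSplitting(terms)
#> Redox-splitting decomposition: total 47.7 mV
#>   environmental: 0.6 mV (1%)
#>   heme-heme:     47.1 mV (99%)
#>   high-potential site: 0, low-potential site: 1

macroscopicMidpoints(modelFromTerms(terms))$deltaEm
#> [1] 82.68919
```

Reading the numbers: both hemes pay a large, nearly equal desolvation
penalty for oxidation in the low-dielectric slab (dg_ox ≈ 413 meV on the
package's relative scale), so the environmental asymmetry is tiny
(0.6 mV) — the fixture's sites are symmetric by construction. The
oxidized–oxidized interaction is 47.1 meV, and the enumerated stepwise
splitting, ΔE_m = 82.7 mV, is that interaction plus the 35.6 mV statistical
factor of a near-identical pair. Rerunning with
`environmentPreset("aqueous-78.2")` drops the interaction to ~11 meV and
ΔE_m to ~47 mV: membrane burial amplifies the cooperativity through
dielectric screening, which is the package's central analysis.

The same pipeline runs end to end with intermediates persisted to disk:

```r
runPipeline(pipelineConfig(fixture = list(membraneSpan = 30.6),
                           preset  = "membrane-6.445",
                           titration = list(potentials = seq(100, 800, 5))),
            outDir = "run1")
```

which writes `structure.pdb`, `energy_terms.tsv`, `titration.tsv`,
`decomposition.json` and `summary.json`. A thin command-line front end with
subcommands (`fixtures`, `energies`, `titrate`, `fit`, `decompose`,
`rates`, `current`, `run`) is installed at
`system.file("scripts", "hemecoop.R", package = "hemeCoop")`.

See the vignette `vignettes/redox-cooperativity-methods.Rmd` for the model,
its conventions (sign conventions, stepwise-midpoint definition, error
model of the MC sampler) and known limitations.

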