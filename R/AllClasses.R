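#' @import methods
NULL

# ---- physical constants (meV / mV / Angstrom / eV unit system) --------------

# e^2 / (4 pi eps0) in meV * Angstrom (equivalently 332.0637 kcal/mol/e/A)
.kCoulomb <- 14399.645

# Boltzmann constant over elementary charge, mV per K
.kBoverE <- 0.08617333262

#' Thermal voltage RT/F (equivalently k_B T / e) in mV
#'
#' At the default temperature of 298.15 K this is 25.693 mV, the value used
#' throughout for Nernst slopes and Metropolis acceptance.
#'
#' @param temperature Temperature in K.
#' @return Thermal voltage in mV (1 mV per elementary charge = 1 meV).
#' @export
thermalVoltage <- function(temperature = 298.15) .kBoverE * temperature

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' HemeStructure: an atomic structure with charges and radii
#'
#' Thin S4 container around an atom table (one row per atom: serial, name,
#' element, residue name/id, chain, x/y/z in Angstrom, partial charge in e,
#' radius in Angstrom) as parsed from PDB ATOM/HETATM records.
#'
#' @slot atoms data.frame of atoms.
#' @slot title character title.
#' @slot meta list of free-form annotations (e.g. membrane span of a fixture).
#' @export
setClass("HemeStructure",
         representation(atoms = "data.frame", title = "character",
                        meta = "list"),
         prototype(title = "", meta = list()))

setValidity("HemeStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resid", "chain",
            "x", "y", "z", "charge", "radius")
  if (!all(need %in% names(a)))
    return(paste("atoms must contain columns:", paste(need, collapse = ", ")))
  if (nrow(a) < 1) return("structure must contain at least one atom")
  if (anyDuplicated(a$serial)) return("atom serials must be unique")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  if (any(a$radius < 0)) return("radii must be non-negative")
  TRUE
})

#' HemeSite: a detected redox centre
#'
#' @slot siteId 0-based site index.
#' @slot hemeType "b" or "c".
#' @slot ligation "His-His", "His-Met" or "unassigned".
#' @slot feIndex row index of the Fe atom in the parent structure.
#' @slot ringIndices row indices of the heme group atoms (Fe included).
#' @slot chargeReduced,chargeOxidized per-atom charges (e) over ringIndices.
#' @slot redoxState "reduced" or "oxidized".
#' @export
setClass("HemeSite",
         representation(siteId = "integer", hemeType = "character",
                        ligation = "character", feIndex = "integer",
                        ringIndices = "integer",
                        chargeReduced = "numeric", chargeOxidized = "numeric",
                        redoxState = "character"),
         prototype(redoxState = "reduced"))

setValidity("HemeSite", function(object) {
  if (length(object@chargeReduced) != length(object@ringIndices) ||
      length(object@chargeOxidized) != length(object@ringIndices))
    return("charge sets must match ringIndices in length")
  dq <- sum(object@chargeOxidized) - sum(object@chargeReduced)
  if (abs(dq - 1) > 1e-6)
    return("oxidized minus reduced charge set must sum to +1 e")
  if (!object@hemeType %in% c("b", "c")) return("hemeType must be 'b' or 'c'")
  if (!object@ligation %in% c("His-His", "His-Met", "unassigned"))
    return("unknown ligation label")
  if (!object@redoxState %in% c("reduced", "oxidized"))
    return("redoxState must be 'reduced' or 'oxidized'")
  TRUE
})

#' SasaResult: Shrake-Rupley solvent-accessible surface areas
#'
#' @slot perAtomArea per-atom area, Angstrom^2.
#' @slot totalArea total area, Angstrom^2.
#' @slot hemeExposedFraction per-site heme exposure (site SASA in context over
#'   site SASA in isolation), dimensionless between 0 and 1; NA when no sites given.
#' @export
setClass("SasaResult",
         representation(perAtomArea = "numeric", totalArea = "numeric",
                        hemeExposedFraction = "numeric"))

setValidity("SasaResult", function(object) {
  if (any(object@perAtomArea < 0)) return("areas must be non-negative")
  f <- object@hemeExposedFraction
  if (length(f) && any(!is.na(f) & (f < -1e-9 | f > 1 + 1e-9)))
    return("hemeExposedFraction must lie in [0, 1]")
  TRUE
})

#' DielectricEnvironment: dielectric regions for continuum electrostatics
#'
#' @slot epsProtein,epsSolvent,epsMembrane relative dielectric constants
#'   (epsMembrane NA when no membrane slab is present).
#' @slot slabZ numeric(2), z-range of the implicit membrane slab in Angstrom
#'   (NA when absent). The membrane normal is the z axis; structures must be
#'   pre-oriented.
#' @slot ionicStrength mol/L (1:1 salt), linearized Debye-Hueckel screening.
#' @slot temperature K.
#' @slot probeRadius solvent probe radius, Angstrom.
#' @export
setClass("DielectricEnvironment",
         representation(epsProtein = "numeric", epsSolvent = "numeric",
                        epsMembrane = "numeric", slabZ = "numeric",
                        ionicStrength = "numeric", temperature = "numeric",
                        probeRadius = "numeric"))

setValidity("DielectricEnvironment", function(object) {
  eps <- c(object@epsProtein, object@epsSolvent)
  if (any(eps < 1)) return("dielectric constants must be >= 1")
  if (!is.na(object@epsMembrane)) {
    if (object@epsMembrane < 1) return("dielectric constants must be >= 1")
    if (any(is.na(object@slabZ)) || object@slabZ[1] >= object@slabZ[2])
      return("slabZ must satisfy slab_z_min < slab_z_max when membrane present")
  }
  if (object@temperature <= 0) return("temperature must be positive")
  if (object@ionicStrength < 0) return("ionic strength must be >= 0")
  TRUE
})

#' GridSpec: finite-difference grid and solver controls
#'
#' @slot spacing fine (focused) grid spacing, Angstrom.
#' @slot coarseSpacing coarse-level spacing, Angstrom.
#' @slot extent margin beyond the solute bounding box, Angstrom.
#' @slot focusingLevels 1 (single grid) or 2 (coarse then focused).
#' @slot boundary "debye-huckel" or "coulombic" outer boundary condition.
#' @slot tol convergence tolerance (relative max node update).
#' @slot maxit maximum SOR iterations.
#' @slot omega SOR over-relaxation factor.
#' @export
setClass("GridSpec",
         representation(spacing = "numeric", coarseSpacing = "numeric",
                        extent = "numeric", focusingLevels = "integer",
                        boundary = "character", tol = "numeric",
                        maxit = "integer", omega = "numeric"))

setValidity("GridSpec", function(object) {
  if (object@spacing <= 0 || object@coarseSpacing <= 0)
    return("grid spacings must be positive")
  if (object@focusingLevels < 1L) return("focusingLevels must be >= 1")
  if (!object@boundary %in% c("debye-huckel", "coulombic"))
    return("boundary must be 'debye-huckel' or 'coulombic'")
  TRUE
})

#' EnergyTerms: per-site oxidation energies and pairwise interactions
#'
#' The continuum-electrostatic ingredients of the microstate Hamiltonian:
#' dgOx(i) is the oxidation free energy of site i with all other sites
#' reduced (meV, relative scale) and wPair(i, j) the change in that energy
#' when site j is also oxidized.
#'
#' @slot siteIds integer site ids (0-based).
#' @slot dgOx numeric vector, meV (1 meV per e = 1 mV).
#' @slot wPair symmetric matrix, meV, zero diagonal.
#' @slot meta list (environment, grid and provenance echoes).
#' @export
setClass("EnergyTerms",
         representation(siteIds = "integer", dgOx = "numeric",
                        wPair = "matrix", meta = "list"),
         prototype(meta = list()))

setValidity("EnergyTerms", function(object) {
  n <- length(object@siteIds)
  if (length(object@dgOx) != n) return("dgOx length must match siteIds")
  if (!all(dim(object@wPair) == c(n, n)))
    return("wPair must be n x n")
  if (n > 0) {
    if (max(abs(object@wPair - t(object@wPair))) > 1e-6)
      return("wPair must be symmetric within 1e-6")
    if (any(abs(diag(object@wPair)) > 1e-9))
      return("wPair diagonal must be zero")
  }
  TRUE
})

#' EnergyModel: microstate Hamiltonian for joint redox/protonation equilibria
#'
#' @slot nSites number of titratable/redox sites.
#' @slot siteKind per-site "redox" or "protonatable".
#' @slot intrinsic per-site intrinsic midpoint potential (mV, redox sites) or
#'   intrinsic pKa (pH units, protonatable sites).
#' @slot wPair symmetric interaction matrix, meV (protonation terms already
#'   converted to meV via ln10 * RT).
#' @slot temperature K.
#' @export
setClass("EnergyModel",
         representation(nSites = "integer", siteKind = "character",
                        intrinsic = "numeric", wPair = "matrix",
                        temperature = "numeric"))

setValidity("EnergyModel", function(object) {
  n <- object@nSites
  if (n < 1) return("n_sites must be >= 1")
  if (length(object@siteKind) != n || length(object@intrinsic) != n)
    return("siteKind and intrinsic must have length nSites")
  if (!all(object@siteKind %in% c("redox", "protonatable")))
    return("siteKind entries must be 'redox' or 'protonatable'")
  if (!all(dim(object@wPair) == c(n, n))) return("wPair must be n x n")
  if (max(abs(object@wPair - t(object@wPair))) > 1e-6)
    return("wPair must be symmetric")
  if (any(abs(diag(object@wPair)) > 1e-9)) return("wPair diagonal must be 0")
  if (object@temperature <= 0) return("temperature must be positive")
  TRUE
})

#' TitrationCurve: mean site occupancies along a potential grid
#'
#' @slot potential solution potential grid, mV vs reference.
#' @slot ph pH at which the curve was computed.
#' @slot fractions matrix (length(potential) x nSites) of mean oxidized
#'   (redox sites) / protonated (protonatable sites) fractions.
#' @slot se matching matrix of sampling standard errors (zero for exact
#'   enumeration).
#' @slot meta list (method, seed, step counts).
#' @export
setClass("TitrationCurve",
         representation(potential = "numeric", ph = "numeric",
                        fractions = "matrix", se = "matrix", meta = "list"),
         prototype(meta = list()))

setValidity("TitrationCurve", function(object) {
  if (nrow(object@fractions) != length(object@potential))
    return("fractions rows must match potential grid")
  if (any(object@fractions < -1e-9 | object@fractions > 1 + 1e-9))
    return("fractions must lie in [0, 1]")
  TRUE
})

#' NernstFit: single-electron Nernst fit of a titration curve
#'
#' @slot em midpoint potential, mV.
#' @slot nApp apparent number of electrons.
#' @slot rss residual sum of squares of the fit.
#' @slot site site index the fit refers to (1-based column).
#' @export
setClass("NernstFit",
         representation(em = "numeric", nApp = "numeric", rss = "numeric",
                        site = "integer"))

setValidity("NernstFit", function(object) {
  if (object@nApp <= 0) return("n_app must be positive")
  TRUE
})

#' DecompositionResult: environmental vs heme-heme splitting decomposition
#'
#' @slot envMv environmental contribution, mV (difference of the two
#'   per-site oxidation energies).
#' @slot intMv heme-heme interaction contribution, mV (the pairwise term).
#' @slot totalMv envMv + intMv.
#' @slot envPct,intPct integer percentages of total (half-up rounding,
#'   independently rounded; NA when total is 0).
#' @slot lowSite,highSite site ids of the low- and high-potential hemes.
#' @export
setClass("DecompositionResult",
         representation(envMv = "numeric", intMv = "numeric",
                        totalMv = "numeric", envPct = "integer",
                        intPct = "integer", lowSite = "integer",
                        highSite = "integer"))

setValidity("DecompositionResult", function(object) {
  if (abs(object@totalMv - (object@envMv + object@intMv)) > 1e-9)
    return("totalMv must equal envMv + intMv exactly")
  s <- object@envPct + object@intPct
  if (!is.na(s) && !(s %in% 99:101))
    return("independently rounded percentages must sum to 99..101")
  TRUE
})

#' ShiftReport: midpoint-potential shift between two constructs
#'
#' @slot constructA,constructB labels.
#' @slot shiftMv E_m(A) - E_m(B), mV.
#' @export
setClass("ShiftReport",
         representation(constructA = "character", constructB = "character",
                        shiftMv = "numeric"))

#' ETStep: one non-adiabatic electron-transfer step
#'
#' @slot lambda reorganization energy, eV.
#' @slot hDa electronic coupling, eV.
#' @slot dg reaction free energy, eV.
#' @slot temperature K.
#' @export
setClass("ETStep",
         representation(lambda = "numeric", hDa = "numeric", dg = "numeric",
                        temperature = "numeric"),
         prototype(temperature = 298.15))

setValidity("ETStep", function(object) {
  if (object@lambda <= 0) return("reorganization energy must be positive")
  if (object@hDa < 0) return("electronic coupling must be >= 0")
  TRUE
})

#' ChainModel: hopping rates along a heme chain
#'
#' A chain of n sites with forward/backward rate constants across the n-1
#' internal junctions plus electron injection at site 1 and ejection from
#' site n.
#'
#' @slot kf,kb forward/backward junction rates, s^-1 (length n-1).
#' @slot kIn,kOut boundary injection/ejection rates, s^-1.
#' @export
setClass("ChainModel",
         representation(kf = "numeric", kb = "numeric", kIn = "numeric",
                        kOut = "numeric"))

setValidity("ChainModel", function(object) {
  if (length(object@kf) != length(object@kb))
    return("kf and kb must have equal length")
  if (any(c(object@kf, object@kb, object@kIn, object@kOut) < 0))
    return("all rates must be >= 0")
  TRUE
})

#' BundleSpec: synthetic four-helix-bundle fixture specification
#'
#' @slot nHelices number of helices (default 4).
#' @slot helixLength residues per helix.
#' @slot radius bundle radius, Angstrom.
#' @slot nHemeSites 1 or 2 heme-like sites on the bundle axis.
#' @slot feSeparation Fe-Fe separation for the diheme case, Angstrom.
#' @slot membraneSpan implicit-membrane span carried as metadata, Angstrom
#'   (NA for soluble fixtures).
#' @slot seed integer seed for the small random jitter.
#' @export
setClass("BundleSpec",
         representation(nHelices = "integer", helixLength = "integer",
                        radius = "numeric", nHemeSites = "integer",
                        feSeparation = "numeric", membraneSpan = "numeric",
                        seed = "integer"))

setValidity("BundleSpec", function(object) {
  if (object@helixLength < 7) return("helix_length must be >= 7")
  if (!object@nHemeSites %in% 1:2) return("nHemeSites must be 1 or 2")
  if (object@nHemeSites == 2 && object@feSeparation <= 0)
    return("fe_separation must be positive for a diheme fixture")
  TRUE
})
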