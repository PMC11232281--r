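#' Specify a synthetic four-helix-bundle fixture
#'
#' @param nHelices Number of helices (default 4).
#' @param helixLength Residues per helix (>= 7).
#' @param radius Bundle radius (helix axis to bundle axis), Angstrom.
#' @param nHemeSites 1 or 2 heme-like sites.
#' @param feSeparation Fe-Fe separation for the diheme case, Angstrom
#'   (default 17, of the order of a diheme four-helix bundle).
#' @param membraneSpan Membrane span carried as metadata (NA = soluble).
#' @param seed Integer seed for the coordinate jitter.
#' @return A [BundleSpec-class].
#' @export
bundleSpec <- function(nHelices = 4L, helixLength = 24L, radius = 7.5,
                       nHemeSites = 2L, feSeparation = 17,
                       membraneSpan = NA_real_, seed = 1L) {
  new("BundleSpec", nHelices = as.integer(nHelices),
      helixLength = as.integer(helixLength), radius = radius,
      nHemeSites = as.integer(nHemeSites), feSeparation = feSeparation,
      membraneSpan = as.numeric(membraneSpan), seed = as.integer(seed))
}

#' Generate an idealized heme-binding four-helix bundle
#'
#' Builds a Calpha-trace coiled-coil-like bundle along z with one or two
#' reduced-complexity dummy hemes (Fe, four pyrrole-like N, eight planar
#' ring carbons) centred on the bundle axis, flanked by bis-His pseudo
#' ligand atoms at coordination distance. The fixture is deterministic
#' under its seed, detectable by [detectHemeSites()] (His-His, b-type) and
#' writable as PDB. It carries no sequence design or sidechain realism.
#'
#' @param spec A [BundleSpec-class].
#' @return A [HemeStructure-class] with radii assigned; `meta$membraneSpan`
#'   carries the fixture's membrane span when set.
#' @export
generateBundle <- function(spec = bundleSpec()) {
  validObject(spec)
  halfLen <- (spec@helixLength - 1) * 1.5 / 2
  feZ <- if (spec@nHemeSites == 2)
    c(-spec@feSeparation / 2, spec@feSeparation / 2) else 0
  if (max(abs(feZ)) + 2 > halfLen)
    stop("heme sites fall outside the bundle; increase helix_length or ",
         "decrease fe_separation")
  set.seed(spec@seed)
  rows <- list()
  serial <- 0L
  addAtom <- function(name, element, resname, resid, chain, x, y, z,
                      record = "ATOM") {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, element = element, resname = resname,
      resid = resid, chain = chain, x = x, y = y, z = z,
      charge = 0, radius = 0, record = record, stringsAsFactors = FALSE)
  }
  chains <- LETTERS[seq_len(spec@nHelices)]
  for (h in seq_len(spec@nHelices)) {
    ang0 <- 2 * pi * (h - 1) / spec@nHelices
    cx <- spec@radius * cos(ang0)
    cy <- spec@radius * sin(ang0)
    for (r in seq_len(spec@helixLength)) {
      # ideal alpha-helix: 2.3 A local radius, 1.5 A rise, 100 deg/residue
      t <- (r - 1) * 100 * pi / 180
      jit <- stats::rnorm(3, 0, 0.02)
      addAtom("CA", "C", "ALA", r, chains[h],
              cx + 2.3 * cos(t + ang0) + jit[1],
              cy + 2.3 * sin(t + ang0) + jit[2],
              -halfLen + (r - 1) * 1.5 + jit[3])
    }
  }
  hemeResid <- spec@helixLength + 10L
  for (k in seq_along(feZ)) {
    z0 <- feZ[k]
    res <- hemeResid + k
    addAtom("FE", "Fe", "HEM", res, "X", 0, 0, z0, "HETATM")
    # pyrrole-like N in the y-z plane (heme normal along x)
    nPos <- rbind(c(0, 2.05, z0), c(0, -2.05, z0),
                  c(0, 0, z0 + 2.05), c(0, 0, z0 - 2.05))
    nNames <- c("NA", "NB", "NC", "ND")
    for (m in 1:4)
      addAtom(nNames[m], "N", "HEM", res, "X",
              nPos[m, 1], nPos[m, 2], nPos[m, 3], "HETATM")
    # planar ring carbons
    for (m in 1:8) {
      a <- 2 * pi * (m - 0.5) / 8
      addAtom(paste0("C", m), "C", "HEM", res, "X",
              0, 3.4 * sin(a), z0 + 3.4 * cos(a), "HETATM")
    }
    # bis-His pseudo ligands on the two flanking helices (normal +-x)
    addAtom("NE2", "N", "HIS", res, chains[1], 2.1, 0, z0)
    addAtom("NE2", "N", "HIS", res, chains[min(3, spec@nHelices)],
            -2.1, 0, z0)
  }
  atoms <- do.call(rbind, rows)
  s <- new("HemeStructure", atoms = atoms,
           title = sprintf("synthetic %d-helix bundle, %d heme site(s)",
                           spec@nHelices, spec@nHemeSites),
           meta = list(membraneSpan = spec@membraneSpan, seed = spec@seed))
  assignRadii(s)
}

#' Generate a seeded random toy energy model
#'
#' Random intrinsic midpoint potentials in `e0RangeMv` and a symmetric
#' non-negative interaction matrix with entries uniform
#' between 0 and wScaleMeV, for property tests of the microstate machinery.
#'
#' @param nSites Number of redox sites.
#' @param e0RangeMv Range of intrinsic potentials, mV.
#' @param wScaleMeV Upper bound of pairwise interactions, meV.
#' @param seed Integer seed.
#' @param temperature K.
#' @return An [EnergyModel-class].
#' @export
generateToyEnergyModel <- function(nSites, e0RangeMv = c(-250, 50),
                                   wScaleMeV = 30, seed = 1,
                                   temperature = 298.15) {
  set.seed(seed)
  e0 <- stats::runif(nSites, e0RangeMv[1], e0RangeMv[2])
  w <- matrix(0, nSites, nSites)
  if (nSites > 1) {
    up <- upper.tri(w)
    w[up] <- stats::runif(sum(up), 0, wScaleMeV)
    w <- w + t(w)
  }
  energyModel(e0, w, "redox", temperature)
}
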