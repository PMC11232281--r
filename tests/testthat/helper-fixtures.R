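# Shared in-code fixtures: no binary data, everything built at test time.

# A single pseudo-atom row
atomRow <- function(serial, x, y, z, name = "FE", element = "Fe",
                    resname = "HEM", resid = serial, chain = "X",
                    charge = 0, radius = 1.5, record = "HETATM") {
  data.frame(serial = as.integer(serial), name = name, element = element,
             resname = resname, resid = as.integer(resid), chain = chain,
             x = x, y = y, z = z, charge = charge, radius = radius,
             record = record, stringsAsFactors = FALSE)
}

# One-atom redox site whose oxidation places +1 e on that atom (monopole toy)
monopoleSite <- function(id, idx) {
  new("HemeSite", siteId = as.integer(id), hemeType = "b",
      ligation = "His-His", feIndex = as.integer(idx),
      ringIndices = as.integer(idx), chargeReduced = 0, chargeOxidized = 1,
      redoxState = "reduced")
}

# Two (or more) monopole "hemes" on the z axis at the given separations
monopoleToy <- function(zPositions) {
  atoms <- do.call(rbind, lapply(seq_along(zPositions), function(i)
    atomRow(i, 0, 0, zPositions[i])))
  s <- new("HemeStructure", atoms = atoms, title = "monopole toy")
  sites <- lapply(seq_along(zPositions), function(i) monopoleSite(i - 1, i))
  list(s = s, sites = sites)
}

# Uniform-dielectric environment
uniformEnv <- function(eps) {
  dielectricEnvironment(epsProtein = eps, epsSolvent = eps)
}

# A constructed bis-ligated dummy heme: Fe at origin, 4 ring N, 8 ring C,
# two axial ligand atoms whose residue/element are configurable.
ligandToy <- function(lig1 = c("HIS", "N", "NE2", 2.1),
                      lig2 = c("HIS", "N", "NE2", 2.1),
                      extra = NULL) {
  rows <- list(atomRow(1, 0, 0, 0, resid = 1L))
  k <- 1L
  for (m in 1:4) {
    k <- k + 1L
    a <- 2 * pi * (m - 1) / 4
    rows[[k]] <- atomRow(k, 0, 2.05 * cos(a), 2.05 * sin(a),
                         name = paste0("N", LETTERS[m]), element = "N",
                         resid = 1L)
  }
  for (m in 1:8) {
    k <- k + 1L
    a <- 2 * pi * (m - 0.5) / 8
    rows[[k]] <- atomRow(k, 0, 3.4 * cos(a), 3.4 * sin(a),
                         name = paste0("C", m), element = "C", resid = 1L)
  }
  ligs <- list(lig1, lig2)
  for (li in seq_along(ligs)) {
    lig <- ligs[[li]]
    if (is.null(lig)) next
    k <- k + 1L
    d <- as.numeric(lig[4]) * c(1, -1)[li]
    rows[[k]] <- atomRow(k, d, 0, 0, name = lig[3], element = lig[2],
                         resname = lig[1], resid = 100L + k, chain = "A",
                         record = "ATOM")
  }
  if (!is.null(extra)) {
    extra$serial <- k + seq_len(nrow(extra))
    rows[[length(rows) + 1L]] <- extra
  }
  new("HemeStructure", atoms = do.call(rbind, rows), title = "ligand toy")
}

# Rigid-body transform of a structure (rotation about z by ang + shift)
rigidTransform <- function(s, ang = 0.7, shift = c(3, -2, 5)) {
  a <- atoms(s)
  R <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% R
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  initialize(s, atoms = a)
}

# Independent brute-force oracle for two-site mean occupancies: explicit
# four-term Boltzmann sums written out by hand (not via package internals).
twoSiteExact <- function(e0, w, eSol, kT = hemeCoop::thermalVoltage()) {
  g1 <- e0[1] - eSol
  g2 <- e0[2] - eSol
  z00 <- 1
  z10 <- exp(-g1 / kT)
  z01 <- exp(-g2 / kT)
  z11 <- exp(-(g1 + g2 + w) / kT)
  Z <- z00 + z10 + z01 + z11
  c((z10 + z11) / Z, (z01 + z11) / Z)
}

# Independent two-site stepwise midpoints: equal-population conditions on
# the explicit four-term sums above, solved by uniroot.
twoSiteMidpointsExact <- function(e0, w, kT = hemeCoop::thermalVoltage()) {
  p <- function(eSol) {
    g1 <- e0[1] - eSol
    g2 <- e0[2] - eSol
    c(1, exp(-g1 / kT), exp(-g2 / kT), exp(-(g1 + g2 + w) / kT))
  }
  r1 <- stats::uniroot(function(e) {
    z <- p(e); log(z[2] + z[3]) - log(z[1])
  }, c(-2000, 2000), tol = 1e-9)$root
  r2 <- stats::uniroot(function(e) {
    z <- p(e); log(z[4]) - log(z[2] + z[3])
  }, c(-2000, 2000), tol = 1e-9)$root
  sort(c(r1, r2))
}

# Ideal Nernst curve generator (oxidized fraction)
nernstCurve <- function(em, n = 1, E = seq(-400, 200, 5),
                        kT = hemeCoop::thermalVoltage()) {
  data.frame(potential = E, fraction = 1 / (1 + exp(-n * (E - em) / kT)))
}
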