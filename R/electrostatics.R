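#' Construct a dielectric environment
#'
#' Declares the continuum regions used by the Poisson-Boltzmann solver:
#' protein interior, bulk solvent, and optionally an implicit membrane slab
#' parallel to the x-y plane (the membrane normal is fixed to z; structures
#' must be pre-oriented). Outside the slab the solvent dielectric applies.
#'
#' Common settings are available as presets via [environmentPreset()]:
#' an aqueous medium of 78.2, a membranous medium equal to the protein
#' interior (6.445), and a solvent-80/protein-20 configuration used by
#' PB/Monte-Carlo titration workflows.
#'
#' @param epsProtein,epsSolvent,epsMembrane Relative dielectric constants;
#'   `epsMembrane = NA` disables the slab.
#' @param slabZ Numeric(2): z-range of the slab, Angstrom.
#' @param ionicStrength mol/L of 1:1 salt (default 0, no screening).
#' @param temperature K.
#' @param probeRadius Solvent probe radius, Angstrom.
#' @return A [DielectricEnvironment-class].
#' @export
dielectricEnvironment <- function(epsProtein = 6.445, epsSolvent = 78.2,
                                  epsMembrane = NA_real_,
                                  slabZ = c(NA_real_, NA_real_),
                                  ionicStrength = 0, temperature = 298.15,
                                  probeRadius = 1.4) {
  new("DielectricEnvironment", epsProtein = epsProtein,
      epsSolvent = epsSolvent, epsMembrane = as.numeric(epsMembrane),
      slabZ = as.numeric(slabZ), ionicStrength = ionicStrength,
      temperature = temperature, probeRadius = probeRadius)
}

#' Construct a finite-difference grid specification
#'
#' @param spacing Focused (fine) spacing, Angstrom.
#' @param coarseSpacing Coarse-level spacing, Angstrom.
#' @param extent Margin beyond the solute, Angstrom.
#' @param focusingLevels 1 or 2.
#' @param boundary "debye-huckel" (screened monopole sum) or "coulombic".
#' @param tol Convergence tolerance (relative max node update).
#' @param maxit Maximum SOR iterations.
#' @param omega SOR over-relaxation factor.
#' @return A [GridSpec-class].
#' @export
gridSpec <- function(spacing = 0.4, coarseSpacing = 1.0, extent = 15,
                     focusingLevels = 2L, boundary = "debye-huckel",
                     tol = 1e-6, maxit = 10000L, omega = 1.9) {
  new("GridSpec", spacing = spacing, coarseSpacing = coarseSpacing,
      extent = extent, focusingLevels = as.integer(focusingLevels),
      boundary = boundary, tol = tol, maxit = as.integer(maxit),
      omega = omega)
}

# Debye screening: eps*kappa^2 as one coefficient, Angstrom^-2.
# Sum_i c_i z_i^2 = 2 I for 1:1 salt; number density 6.0221408e-4 * I A^-3
# per mol/L.
.screenCoef <- function(env) {
  if (env@ionicStrength <= 0) return(0)
  kT <- thermalVoltage(env@temperature)
  4 * pi * .kCoulomb * (2 * 6.0221408e-4 * env@ionicStrength) / kT
}

# One rectilinear grid level: node dielectrics, screening and geometry.
.makeLevel <- function(lo, hi, h, dielAtoms, env) {
  n <- pmax(as.integer(ceiling((hi - lo) / h)) + 1L, 8L)
  hi <- lo + (n - 1) * h
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  if (is.null(dielAtoms) || nrow(dielAtoms) == 0) {
    inside <- rep(FALSE, nx * ny * nz)
  } else {
    inside <- mark_interior_cpp(as.matrix(dielAtoms[, c("x", "y", "z")]),
                                dielAtoms$radius, 0,
                                lo[1], lo[2], lo[3], h, nx, ny, nz)
  }
  eps <- rep(env@epsSolvent, nx * ny * nz)
  screened <- !inside
  if (!is.na(env@epsMembrane)) {
    z <- lo[3] + (seq_len(nz) - 1L) * h
    inSlab <- rep(z >= env@slabZ[1] & z <= env@slabZ[2], each = nx * ny)
    eps[inSlab & !inside] <- env@epsMembrane
    screened <- screened & !inSlab
  }
  eps[inside] <- env@epsProtein
  scr <- .screenCoef(env)
  kap <- ifelse(screened, scr * h * h, 0)
  list(lo = lo, hi = hi, h = h, nx = nx, ny = ny, nz = nz,
       eps = eps, kap = kap, inside = inside)
}

#' Build the per-node dielectric region map for a grid level
#'
#' Nodes inside the van der Waals envelope of the structure take the protein
#' dielectric; nodes outside the envelope but inside the membrane slab take
#' the membrane dielectric; all remaining nodes take the solvent dielectric
#' (and, at non-zero ionic strength, Debye screening).
#'
#' @param s A [HemeStructure-class] with radii assigned, or NULL for a
#'   uniform solvent.
#' @param env A [DielectricEnvironment-class].
#' @param grid A [GridSpec-class]; the coarse spacing and extent define the
#'   level.
#' @return List with `origin`, `spacing`, `dims`, node vector `eps` and
#'   logical `screened`/`inside` flags (x fastest index order).
#' @export
buildRegionMap <- function(s, env, grid = gridSpec()) {
  dielAtoms <- if (is.null(s)) NULL else s@atoms
  pts <- if (is.null(dielAtoms)) matrix(0, 1, 3) else
    as.matrix(dielAtoms[, c("x", "y", "z")])
  pad <- if (is.null(dielAtoms)) 0 else max(dielAtoms$radius)
  lo <- apply(pts, 2, min) - pad - grid@extent
  hi <- apply(pts, 2, max) + pad + grid@extent
  h <- if (grid@focusingLevels >= 2L) grid@coarseSpacing else grid@spacing
  lv <- .makeLevel(lo, hi, h, dielAtoms, env)
  scr <- .screenCoef(env)
  list(origin = lv$lo, spacing = lv$h, dims = c(lv$nx, lv$ny, lv$nz),
       eps = lv$eps, inside = lv$inside,
       screened = if (scr > 0) lv$kap > 0 else !lv$inside &
         (is.na(env@epsMembrane) | lv$eps == env@epsSolvent))
}

.solveLevel <- function(lv, charges, grid, phi0) {
  src <- spread_charges_cpp(as.matrix(charges[, c("x", "y", "z")]),
                            charges$q, lv$lo[1], lv$lo[2], lv$lo[3],
                            lv$h, lv$nx, lv$ny, lv$nz)
  src <- src * (4 * pi * .kCoulomb / lv$h)
  ans <- pb_sor_cpp(phi0, lv$eps, lv$kap, src, lv$nx, lv$ny, lv$nz,
                    grid@omega, grid@tol, grid@maxit)
  if (!ans$converged)
    stop(sprintf("PB solver did not converge in %d iterations (residual %g)",
                 grid@maxit, ans$residual))
  ans
}

# Focused linearized-PB solve. dielAtoms define the protein envelope (NULL =
# uniform solvent); charges are placed point charges (x, y, z, q in e);
# domain/focus boxes may be supplied to pin the grid geometry so that grid
# self-energies cancel between paired solves.
pbSolve <- function(dielAtoms, charges, env, grid, evalPoints,
                    domain = NULL, focusBox = NULL) {
  evalPoints <- matrix(as.numeric(evalPoints), ncol = 3)
  qpts <- as.matrix(charges[, c("x", "y", "z")])
  if (is.null(domain)) {
    pts <- rbind(qpts, evalPoints,
                 if (!is.null(dielAtoms)) as.matrix(
                   dielAtoms[, c("x", "y", "z")]))
    pad <- if (is.null(dielAtoms) || !nrow(dielAtoms)) 2 else
      max(dielAtoms$radius) + 2
    domain <- list(lo = apply(pts, 2, min) - pad - grid@extent,
                   hi = apply(pts, 2, max) + pad + grid@extent)
  }
  twoLevel <- grid@focusingLevels >= 2L
  hC <- if (twoLevel) grid@coarseSpacing else grid@spacing
  coarse <- .makeLevel(domain$lo, domain$hi, hC, dielAtoms, env)
  kappa <- if (grid@boundary == "debye-huckel")
    sqrt(.screenCoef(env) / env@epsSolvent) else 0
  phiB <- boundary_potential_cpp(qpts, charges$q, .kCoulomb,
                                 env@epsSolvent, kappa,
                                 coarse$lo[1], coarse$lo[2], coarse$lo[3],
                                 coarse$h, coarse$nx, coarse$ny, coarse$nz)
  ansC <- .solveLevel(coarse, charges, grid, phiB)
  lv <- coarse; ans <- ansC
  if (twoLevel) {
    fpts <- rbind(qpts, evalPoints)
    if (is.null(focusBox)) {
      margin <- 6
      focusBox <- list(lo = apply(fpts, 2, min) - margin,
                       hi = apply(fpts, 2, max) + margin)
    }
    # keep the fine box strictly inside the coarse domain
    lof <- pmax(focusBox$lo, coarse$lo + coarse$h)
    hif <- pmin(focusBox$hi, coarse$hi - coarse$h)
    fine <- .makeLevel(lof, hif, grid@spacing, dielAtoms, env)
    phi0 <- grid_interp_cpp(ansC$phi, coarse$lo[1], coarse$lo[2],
                            coarse$lo[3], coarse$h, coarse$nx, coarse$ny,
                            coarse$nz, gridNodeCoords(fine))
    phi0[is.na(phi0)] <- 0
    ansF <- .solveLevel(fine, charges, grid, phi0)
    lv <- fine; ans <- ansF
  }
  phi <- grid_interp_cpp(ans$phi, lv$lo[1], lv$lo[2], lv$lo[3], lv$h,
                         lv$nx, lv$ny, lv$nz, evalPoints)
  if (any(is.na(phi))) {
    out <- grid_interp_cpp(ansC$phi, coarse$lo[1], coarse$lo[2],
                           coarse$lo[3], coarse$h, coarse$nx, coarse$ny,
                           coarse$nz, evalPoints)
    phi[is.na(phi)] <- out[is.na(phi)]
  }
  list(potential = phi, iterations = ans$iterations,
       residual = ans$residual, domain = domain,
       levelSpacing = lv$h)
}

gridNodeCoords <- function(lv) {
  xs <- lv$lo[1] + (seq_len(lv$nx) - 1) * lv$h
  ys <- lv$lo[2] + (seq_len(lv$ny) - 1) * lv$h
  zs <- lv$lo[3] + (seq_len(lv$nz) - 1) * lv$h
  cbind(rep(xs, times = lv$ny * lv$nz),
        rep(rep(ys, each = lv$nx), times = lv$nz),
        rep(zs, each = lv$nx * lv$ny))
}

#' Solve the linearized Poisson-Boltzmann equation for point charges
#'
#' Finite-difference solution with successive over-relaxation, harmonic
#' averaging of the dielectric across interface faces, Debye-Hueckel (or
#' plain Coulombic) Dirichlet boundary values, and optional two-level
#' focusing around the charges and evaluation points.
#'
#' @param charges data.frame with columns x, y, z (Angstrom) and q (e).
#' @param s A [HemeStructure-class] defining the protein envelope, or NULL
#'   for a uniform solvent dielectric.
#' @param env A [DielectricEnvironment-class].
#' @param grid A [GridSpec-class].
#' @param evalPoints Matrix (n x 3) of points at which to report the
#'   potential.
#' @return List with `potential` (mV at `evalPoints`), `iterations` and
#'   `residual` of the final level.
#' @export
solvePotential <- function(charges, s = NULL, env = dielectricEnvironment(),
                           grid = gridSpec(), evalPoints) {
  if (nrow(charges) == 0 || all(charges$q == 0)) {
    evalPoints <- matrix(as.numeric(evalPoints), ncol = 3)
    return(list(potential = numeric(nrow(evalPoints)), iterations = 0L,
                residual = 0))
  }
  pbSolve(if (is.null(s)) NULL else s@atoms, charges, env, grid, evalPoints)
}

# Shared geometry for the thermodynamic-cycle solves of one structure:
# a fixed domain and a fixed focus box covering every heme site.
.cycleBoxes <- function(s, sites, grid) {
  a <- s@atoms
  pts <- as.matrix(a[, c("x", "y", "z")])
  pad <- max(a$radius) + 2
  domain <- list(lo = apply(pts, 2, min) - pad - grid@extent,
                 hi = apply(pts, 2, max) + pad + grid@extent)
  ringIdx <- unique(unlist(lapply(sites, function(x) x@ringIndices)))
  rpts <- pts[ringIdx, , drop = FALSE]
  focus <- list(lo = apply(rpts, 2, min) - 6, hi = apply(rpts, 2, max) + 6)
  list(domain = domain, focus = focus)
}

# Potential of one site's oxidation charge-difference set, in the full
# dielectric map and in the isolated-heme (aqueous) reference, on identical
# grids; evaluated at all atom positions.
.siteCyclePhis <- function(s, site, env, grid, boxes) {
  a <- s@atoms
  ring <- site@ringIndices
  dq <- oxidationChargeDiff(site)
  ch <- data.frame(x = a$x[ring], y = a$y[ring], z = a$z[ring], q = dq)
  evalPts <- as.matrix(a[, c("x", "y", "z")])
  full <- pbSolve(a, ch, env, grid, evalPts,
                  domain = boxes$domain, focusBox = boxes$focus)
  refEnv <- dielectricEnvironment(epsProtein = env@epsProtein,
                                  epsSolvent = env@epsSolvent,
                                  ionicStrength = env@ionicStrength,
                                  temperature = env@temperature,
                                  probeRadius = env@probeRadius)
  ref <- pbSolve(a[ring, , drop = FALSE], ch, refEnv, grid, evalPts,
                 domain = boxes$domain, focusBox = boxes$focus)
  list(full = full$potential, ref = ref$potential, dq = dq, ring = ring)
}

#' Oxidation free energy of one heme with all others reduced
#'
#' Thermodynamic-cycle continuum estimate: the oxidation charge-difference
#' set of the site is solved in the full protein/solvent/membrane dielectric
#' map and in an isolated-heme aqueous reference on the same grid (so grid
#' self-energies cancel). The reported shift is the reaction-field (Born)
#' difference plus the interaction with all fixed background charges, in meV
#' on a relative scale.
#'
#' @param site The [HemeSite-class] being oxidized.
#' @param sites All detected sites (kept reduced).
#' @param s The [HemeStructure-class] (radii assigned; atom charges are the
#'   fixed background).
#' @param env A [DielectricEnvironment-class].
#' @param grid A [GridSpec-class].
#' @return Oxidation energy shift, meV.
#' @export
oxidationEnergy <- function(site, sites, s, env, grid = gridSpec()) {
  boxes <- .cycleBoxes(s, sites, grid)
  ph <- .siteCyclePhis(s, site, env, grid, boxes)
  born <- 0.5 * sum(ph$dq * (ph$full[ph$ring] - ph$ref[ph$ring]))
  bg <- setdiff(seq_len(nrow(s@atoms)), ph$ring)
  back <- sum(s@atoms$charge[bg] * ph$full[bg])
  born + back
}

#' Heme-heme oxidation interaction energy
#'
#' The change in the oxidation energy of site i caused by oxidizing site j
#' (all other sites reduced): the oxidation charge-difference set of site i
#' is solved in the full dielectric map and contracted with the
#' charge-difference set of site j. Symmetric within grid tolerance.
#'
#' @param siteI,siteJ Distinct [HemeSite-class] objects.
#' @param s The [HemeStructure-class].
#' @param env A [DielectricEnvironment-class].
#' @param grid A [GridSpec-class].
#' @return Interaction energy w_ij, meV.
#' @export
interactionEnergy <- function(siteI, siteJ, s, env, grid = gridSpec()) {
  if (siteI@siteId == siteJ@siteId)
    stop("interaction energy requires two distinct sites")
  boxes <- .cycleBoxes(s, list(siteI, siteJ), grid)
  ph <- .siteCyclePhis(s, siteI, env, grid, boxes)
  sum(oxidationChargeDiff(siteJ) * ph$full[siteJ@ringIndices])
}

#' Assemble the full oxidation-energy / interaction-energy terms
#'
#' One focused PB cycle per site yields the per-site oxidation energies
#' (dg_ox, all other sites reduced) and the full symmetric pairwise
#' interaction matrix w_pair, the ingredients of the microstate Hamiltonian.
#'
#' @param s A [HemeStructure-class] with radii assigned.
#' @param sites List of [HemeSite-class] objects (from [detectHemeSites()]).
#' @param env A [DielectricEnvironment-class].
#' @param grid A [GridSpec-class].
#' @return An [EnergyTerms-class].
#' @export
computeEnergyTerms <- function(s, sites, env, grid = gridSpec()) {
  if (!length(sites)) stop("at least one heme site is required")
  n <- length(sites)
  boxes <- .cycleBoxes(s, sites, grid)
  dg <- numeric(n)
  w <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ph <- .siteCyclePhis(s, sites[[i]], env, grid, boxes)
    born <- 0.5 * sum(ph$dq * (ph$full[ph$ring] - ph$ref[ph$ring]))
    bg <- setdiff(seq_len(nrow(s@atoms)), ph$ring)
    dg[i] <- born + sum(s@atoms$charge[bg] * ph$full[bg])
    for (j in seq_len(n)) {
      if (j == i) next
      rj <- sites[[j]]@ringIndices
      w[i, j] <- sum(oxidationChargeDiff(sites[[j]]) * ph$full[rj])
    }
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  new("EnergyTerms",
      siteIds = vapply(sites, function(x) x@siteId, integer(1)),
      dgOx = dg, wPair = w,
      meta = list(epsProtein = env@epsProtein, epsSolvent = env@epsSolvent,
                  epsMembrane = env@epsMembrane, spacing = grid@spacing))
}

#' Write / read EnergyTerms as a delimited text table
#'
#' Tab-separated: one row per site with its id, dg_ox (meV) and the full
#' w_pair row (meV).
#'
#' @param terms An [EnergyTerms-class].
#' @param path File path.
#' @return `writeEnergyTerms` invisibly returns `path`; `readEnergyTerms`
#'   returns an [EnergyTerms-class].
#' @export
writeEnergyTerms <- function(terms, path) {
  n <- length(terms@siteIds)
  df <- data.frame(site = terms@siteIds, dg_ox_meV = terms@dgOx)
  wm <- as.data.frame(terms@wPair)
  names(wm) <- paste0("w_", terms@siteIds)
  utils::write.table(cbind(df, wm), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyTerms
#' @export
readEnergyTerms <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  n <- nrow(df)
  w <- as.matrix(df[, grep("^w_", names(df)), drop = FALSE])
  dimnames(w) <- NULL
  w <- (w + t(w)) / 2
  diag(w) <- 0
  new("EnergyTerms", siteIds = as.integer(df$site), dgOx = df$dg_ox_meV,
      wPair = w)
}
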