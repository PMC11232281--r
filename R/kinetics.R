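# hbar and Boltzmann constant in eV units
.hbar_eVs <- 6.582119569e-16
.kB_eVK <- 8.617333262e-5

#' Non-adiabatic Marcus electron-transfer rate
#'
#' \deqn{k = \frac{2\pi}{\hbar} H_{DA}^2 (4\pi\lambda k_B T)^{-1/2}
#'       \exp\left(-\frac{(\Delta G + \lambda)^2}{4\lambda k_B T}\right)}
#'
#' @param step An [ETStep-class], or (alternatively) `lambda`, `hDa`, `dg`
#'   and `temperature` given directly.
#' @param lambda Reorganization energy, eV (> 0).
#' @param hDa Electronic coupling, eV.
#' @param dg Reaction free energy, eV.
#' @param temperature K.
#' @return Rate constant, s^-1.
#' @export
marcusRate <- function(step = NULL, lambda, hDa, dg, temperature = 298.15) {
  if (!is.null(step)) {
    lambda <- step@lambda; hDa <- step@hDa; dg <- step@dg
    temperature <- step@temperature
  }
  if (any(lambda <= 0)) stop("reorganization energy must be positive")
  kT <- .kB_eVK * temperature
  (2 * pi / .hbar_eVs) * hDa^2 / sqrt(4 * pi * lambda * kT) *
    exp(-(dg + lambda)^2 / (4 * lambda * kT))
}

#' Construct an ETStep
#'
#' @param lambda Reorganization energy, eV.
#' @param hDa Electronic coupling, eV.
#' @param dg Reaction free energy, eV.
#' @param temperature K.
#' @return An [ETStep-class].
#' @export
etStep <- function(lambda, hDa, dg, temperature = 298.15) {
  new("ETStep", lambda = lambda, hDa = hDa, dg = dg,
      temperature = temperature)
}

#' Two-sphere continuum (Marcus) reorganization energy
#'
#' \deqn{\lambda = \frac{e^2}{4\pi\epsilon_0}
#'   \left(\frac{1}{2a_1} + \frac{1}{2a_2} - \frac{1}{R}\right)
#'   \left(\frac{1}{\epsilon_{op}} - \frac{1}{\epsilon_s}\right)}
#'
#' Radii default to a 4 Angstrom effective heme radius and the optical
#' dielectric to 2.0; all configurable.
#'
#' @param donorRadius,acceptorRadius Effective sphere radii, Angstrom.
#' @param separation Centre-to-centre distance R, Angstrom (Inf allowed).
#' @param epsOptical,epsStatic Optical and static dielectric constants.
#' @return Reorganization energy, eV.
#' @export
reorganizationEnergy <- function(donorRadius = 4, acceptorRadius = 4,
                                 separation = Inf, epsOptical = 2.0,
                                 epsStatic = 78.2) {
  if (epsOptical > epsStatic)
    stop("optical dielectric cannot exceed the static dielectric")
  if (is.finite(separation) && separation < donorRadius + acceptorRadius)
    warning("spheres overlap: separation < sum of radii")
  geom <- 1 / (2 * donorRadius) + 1 / (2 * acceptorRadius) -
    ifelse(is.finite(separation), 1 / separation, 0)
  pekar <- 1 / epsOptical - 1 / epsStatic
  (.kCoulomb / 1000) * geom * pekar
}

# Best-fit plane normal of a point cloud; errors on (near-)collinear input.
.planeNormal <- function(pts) {
  if (nrow(pts) < 3) stop("need at least 3 atoms to define a ring plane")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[2] < 1e-6 * sv$d[1])
    stop("degenerate (collinear) ring geometry: plane undefined")
  sv$v[, 3]
}

#' Assign a generic electronic coupling from mutual heme orientation
#'
#' Classifies the pair geometry by the angle between the heme ring planes
#' (folded to the 0-90 degree range): stacked when the angle is at most
#' `stackedAngle`, T-shaped/coplanar otherwise, and returns the configured
#' generic coupling for the class. The class is invariant under rigid-body
#' transforms of the pair. The default values are package configuration,
#' not measured couplings.
#'
#' @param siteI,siteJ [HemeSite-class] objects.
#' @param s The parent [HemeStructure-class].
#' @param stackedCoupling,tShapedCoupling Generic couplings, eV.
#' @param stackedAngle Threshold inter-plane angle, degrees.
#' @return List with `coupling` (eV), `class` and `angle` (degrees).
#' @export
assignGenericCoupling <- function(siteI, siteJ, s,
                                  stackedCoupling = 0.008,
                                  tShapedCoupling = 0.002,
                                  stackedAngle = 35) {
  xyz <- as.matrix(s@atoms[, c("x", "y", "z")])
  ni <- .planeNormal(xyz[siteI@ringIndices, , drop = FALSE])
  nj <- .planeNormal(xyz[siteJ@ringIndices, , drop = FALSE])
  cosang <- abs(sum(ni * nj)) / sqrt(sum(ni^2) * sum(nj^2))
  ang <- acos(pmin(1, cosang)) * 180 / pi
  cls <- if (ang <= stackedAngle) "stacked" else "T-shaped"
  list(coupling = if (cls == "stacked") stackedCoupling else tShapedCoupling,
       class = cls, angle = ang)
}

#' Construct a hopping-chain model
#'
#' @param kf,kb Forward/backward rates across the n-1 internal junctions,
#'   s^-1 (numeric(0) for a single site).
#' @param kIn,kOut Injection rate into site 1 and ejection rate from site n,
#'   s^-1.
#' @return A [ChainModel-class].
#' @export
chainModel <- function(kf = numeric(0), kb = numeric(0), kIn, kOut) {
  new("ChainModel", kf = as.numeric(kf), kb = as.numeric(kb),
      kIn = kIn, kOut = kOut)
}

#' Build a hopping chain from midpoint potentials and Marcus parameters
#'
#' Junction free energies default to \eqn{\Delta G = -(E_{m,acceptor} -
#' E_{m,donor})} eV per mV/1000 convention (downhill when the acceptor
#' midpoint is higher); forward and backward Marcus rates follow detailed
#' balance.
#'
#' @param emMv Site midpoint potentials along the chain, mV.
#' @param lambda Reorganization energy per junction, eV (recycled).
#' @param hDa Electronic coupling per junction, eV (recycled).
#' @param kIn,kOut Boundary rates, s^-1.
#' @param temperature K.
#' @return A [ChainModel-class].
#' @export
chainFromMidpoints <- function(emMv, lambda = 0.7, hDa = 0.003,
                               kIn = 1e9, kOut = 1e9,
                               temperature = 298.15) {
  n <- length(emMv)
  if (n < 1) stop("need at least one site")
  nj <- n - 1
  lambda <- rep_len(lambda, max(nj, 1))
  hDa <- rep_len(hDa, max(nj, 1))
  if (nj == 0) return(chainModel(kIn = kIn, kOut = kOut))
  dg <- -(emMv[-1] - emMv[-n]) / 1000
  kf <- marcusRate(lambda = lambda, hDa = hDa, dg = dg,
                   temperature = temperature)
  kb <- marcusRate(lambda = lambda, hDa = hDa, dg = -dg,
                   temperature = temperature)
  chainModel(kf, kb, kIn, kOut)
}

#' Steady-state redox current through a hopping chain
#'
#' Solves the steady-state single-electron hopping equations with
#' single-occupancy exclusion (mean-field): the flux across junction i is
#' \eqn{J_i = k_{f,i} p_i (1 - p_{i+1}) - k_{b,i} p_{i+1}(1 - p_i)}, with
#' injection \eqn{k_{in}(1-p_1)} and ejection \eqn{k_{out} p_n}; at steady
#' state every junction carries the same flux. A damped Newton iteration on
#' the site occupancies solves the balance equations. The limiting regime is
#' protein-limited when the smallest internal rate is below the boundary
#' rates, diffusive otherwise.
#'
#' @param chain A [ChainModel-class].
#' @return List with `current_e_s` (electrons/s), `current_A` (amperes),
#'   `occupancy`, per-junction `flux` and the limiting `regime`.
#' @export
steadyStateCurrent <- function(chain) {
  n <- length(chain@kf) + 1L
  if (chain@kIn <= 0 && chain@kOut <= 0)
    stop("at least one nonzero boundary rate is required")
  fluxes <- function(p) {
    jIn <- chain@kIn * (1 - p[1])
    jInt <- if (n > 1)
      chain@kf * p[-n] * (1 - p[-1]) - chain@kb * p[-1] * (1 - p[-n])
    else numeric(0)
    jOut <- chain@kOut * p[n]
    c(jIn, jInt, jOut)
  }
  resid <- function(p) {
    j <- fluxes(p)
    j[-length(j)] - j[-1] # net inflow per site
  }
  p <- rep(0.5, n)
  for (iter in 1:200) {
    r <- resid(p)
    if (max(abs(r)) < 1e-12 * max(1, chain@kIn, chain@kOut)) break
    jac <- matrix(0, n, n)
    hstep <- 1e-7
    for (k in seq_len(n)) {
      pk <- p
      pk[k] <- pk[k] + hstep
      jac[, k] <- (resid(pk) - r) / hstep
    }
    dp <- tryCatch(solve(jac, -r), error = function(e) -r / diag(jac))
    lam <- 1
    repeat {
      pn <- pmin(1 - 1e-12, pmax(1e-12, p + lam * dp))
      if (sum(resid(pn)^2) <= sum(r^2) || lam < 1e-6) break
      lam <- lam / 2
    }
    p <- pn
  }
  j <- fluxes(p)
  internalMin <- if (n > 1) min(chain@kf) else Inf
  regime <- if (internalMin < min(chain@kIn, chain@kOut))
    "protein-limited" else "diffusive"
  list(current_e_s = j[length(j)],
       current_A = j[length(j)] * 1.602176634e-19,
       occupancy = p, flux = j, regime = regime)
}
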