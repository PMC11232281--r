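#' Construct a microstate energy model
#'
#' The joint proton/electron microstate Hamiltonian
#' \deqn{G(x) = \sum_i x_i g_i + \sum_{i<j} x_i x_j w_{ij}}
#' with occupancy x_i = 1 meaning oxidized (redox sites) or protonated
#' (protonatable sites). The per-site occupation term is
#' g_i = E\eqn{^\circ}{°}_i - E_solution (meV) for redox sites — oxidation is
#' unfavourable below the intrinsic midpoint and favourable above it — and
#' g_i = ln10 RT (pH - pKa_i) for protonatable sites.
#'
#' @param intrinsic Per-site intrinsic midpoint potential (mV) or pKa.
#' @param wPair Symmetric interaction matrix, meV (zero diagonal); a scalar
#'   0 expands to no interactions.
#' @param siteKind Per-site "redox" (default) or "protonatable".
#' @param temperature K.
#' @return An [EnergyModel-class].
#' @export
energyModel <- function(intrinsic, wPair = 0, siteKind = "redox",
                        temperature = 298.15) {
  n <- length(intrinsic)
  if (length(siteKind) == 1) siteKind <- rep(siteKind, n)
  if (!is.matrix(wPair) && length(wPair) == 1) {
    wPair <- matrix(wPair, n, n)
    diag(wPair) <- 0
  }
  new("EnergyModel", nSites = as.integer(n), siteKind = siteKind,
      intrinsic = as.numeric(intrinsic), wPair = wPair,
      temperature = temperature)
}

#' Build an EnergyModel from continuum-electrostatic EnergyTerms
#'
#' Intrinsic midpoint potentials are the per-site oxidation energies on a
#' relative scale plus a model-compound reference potential (mV); the
#' interaction matrix carries over unchanged.
#'
#' @param terms An [EnergyTerms-class].
#' @param reference Model-compound reference potential, mV.
#' @param temperature K.
#' @return An [EnergyModel-class].
#' @export
modelFromTerms <- function(terms, reference = 0, temperature = 298.15) {
  energyModel(reference + terms@dgOx, terms@wPair, "redox", temperature)
}

.siteG <- function(model, eSolution, ph) {
  kT <- thermalVoltage(model@temperature)
  ifelse(model@siteKind == "redox",
         model@intrinsic - eSolution,
         log(10) * kT * (ph - model@intrinsic))
}

#' Microstate free energy
#'
#' @param occupancy 0/1 vector over sites (1 = oxidized / protonated).
#' @param model An [EnergyModel-class].
#' @param eSolution Solution potential, mV.
#' @param ph pH.
#' @return Free energy of the microstate relative to the all-zero reference
#'   state, meV.
#' @export
microstateEnergy <- function(occupancy, model, eSolution, ph = 7) {
  if (length(occupancy) != model@nSites)
    stop("occupancy length must equal the number of sites")
  if (!all(occupancy %in% c(0, 1))) stop("occupancy entries must be 0 or 1")
  g <- .siteG(model, eSolution, ph)
  sum(occupancy * g) + 0.5 * drop(occupancy %*% model@wPair %*% occupancy)
}

# All 2^n occupancy vectors (rows), n <= 20
.allStates <- function(n) {
  states <- as.matrix(expand.grid(rep(list(0:1), n)))
  dimnames(states) <- NULL
  states
}

# Boltzmann state probabilities at one condition
.stateProbs <- function(states, model, eSolution, ph) {
  g <- .siteG(model, eSolution, ph)
  kT <- thermalVoltage(model@temperature)
  uInt <- 0.5 * rowSums((states %*% model@wPair) * states)
  G <- drop(states %*% g) + uInt
  wgt <- exp(-(G - min(G)) / kT)
  wgt / sum(wgt)
}

#' Exact per-site mean occupancies by full microstate enumeration
#'
#' Boltzmann average over all 2^n microstates; the exact reference that the
#' Monte-Carlo sampler is validated against. Refuses n > 20.
#'
#' @param model An [EnergyModel-class] with at most 20 sites.
#' @param eSolution Solution potential(s), mV.
#' @param ph pH.
#' @return Matrix (length(eSolution) x nSites) of mean occupancies.
#' @export
enumerateOccupancies <- function(model, eSolution, ph = 7) {
  if (model@nSites > 20)
    stop("enumeration is limited to 20 sites (2^n states); use mcTitration")
  states <- .allStates(model@nSites)
  out <- matrix(NA_real_, length(eSolution), model@nSites)
  for (k in seq_along(eSolution)) {
    p <- .stateProbs(states, model, eSolution[k], ph)
    out[k, ] <- drop(p %*% states)
  }
  out
}

#' Exact titration curve by enumeration
#'
#' @param model An [EnergyModel-class].
#' @param potentialGrid Solution potentials, mV (default -400..200 by 5).
#' @param ph pH.
#' @return A [TitrationCurve-class] with zero sampling error.
#' @export
enumerationTitration <- function(model, potentialGrid = seq(-400, 200, 5),
                                 ph = 7) {
  fr <- enumerateOccupancies(model, potentialGrid, ph)
  new("TitrationCurve", potential = potentialGrid, ph = ph, fractions = fr,
      se = matrix(0, nrow(fr), ncol(fr)),
      meta = list(method = "enumeration"))
}

#' Metropolis Monte-Carlo microstate titration
#'
#' Single-site flip moves plus joint pair flips for strongly coupled pairs
#' (|w| > 2 ln10 RT), Metropolis acceptance on the microstate Hamiltonian,
#' occupancies averaged after an equilibration phase, and sampling errors
#' from block averaging (floored by the independent-sampling binomial
#' estimate, which dominates for rarely visited saturated states where the
#' block estimator is unreliable). Reproducible under a fixed seed.
#'
#' @param model An [EnergyModel-class].
#' @param potentialGrid Solution potentials, mV.
#' @param ph pH.
#' @param nSteps Sampling MC steps per potential (default 1e5).
#' @param nEquil Equilibration steps (default 1e4).
#' @param seed Integer seed (recorded in the output).
#' @param nBlocks Blocks for the standard-error estimate.
#' @return A [TitrationCurve-class].
#' @export
mcTitration <- function(model, potentialGrid = seq(-400, 200, 5), ph = 7,
                        nSteps = 1e5, nEquil = 1e4, seed = 1, nBlocks = 10) {
  if (!length(potentialGrid)) stop("potential grid must not be empty")
  if (nSteps < 1) stop("n_steps must be >= 1")
  kT <- thermalVoltage(model@temperature)
  gmat <- vapply(potentialGrid,
                 function(e) .siteG(model, e, ph), numeric(model@nSites))
  gmat <- matrix(gmat, nrow = model@nSites)
  thr <- 2 * log(10) * kT
  prs <- which(abs(model@wPair) > thr & upper.tri(model@wPair), arr.ind = TRUE)
  pairs <- if (nrow(prs)) t(prs) - 1L else
    matrix(integer(0), nrow = 2, ncol = 0)
  set.seed(seed)
  res <- mc_titrate_cpp(gmat, model@wPair, as.integer(nSteps),
                        as.integer(nEquil), as.integer(nBlocks), kT,
                        pairs)
  # block averaging collapses for rarely visited states (most blocks see no
  # transition), so floor the error with a binomial estimate at one update
  # attempt per site, inflated by 2 for the entry/exit correlation of
  # single-flip sampling (each rare-state visit contributes ~2x the variance
  # of an independent draw)
  nEff <- max(1, nSteps / model@nSites)
  pCl <- pmin(pmax(res$mean, 1.5 / nEff), 1 - 1.5 / nEff)
  se <- pmax(res$se, sqrt(2 * pCl * (1 - pCl) / nEff))
  new("TitrationCurve", potential = potentialGrid, ph = ph,
      fractions = t(res$mean), se = t(se),
      meta = list(method = "metropolis-mc", seed = seed, nSteps = nSteps,
                  nEquil = nEquil, nBlocks = nBlocks))
}

#' Fit a titration curve to a single-electron Nernst equation
#'
#' Least-squares fit of the oxidized fraction
#' \deqn{f(E) = 1 / (1 + e^{-n_{app}(E - E_m)/(RT/F)})}
#' for one site of a titration curve. With `fixN = 1` this is the standard
#' single-electron protocol used to report midpoint potentials.
#'
#' @param curve A [TitrationCurve-class] (or data.frame with columns
#'   `potential` and `fraction`).
#' @param site 1-based site column of the curve.
#' @param fixN Fix the apparent electron number (e.g. 1), or NULL to fit it.
#' @param temperature K (defaults to 298.15; RT/F = 25.693 mV).
#' @return A [NernstFit-class].
#' @export
fitNernst <- function(curve, site = 1L, fixN = NULL, temperature = 298.15) {
  if (is(curve, "TitrationCurve")) {
    E <- curve@potential
    f <- curve@fractions[, site]
  } else {
    E <- curve$potential
    f <- curve$fraction
  }
  if (length(E) < 5) stop("need at least 5 points spanning the transition")
  if (diff(range(f)) < 0.1)
    stop("transition not spanned: curve range < 0.1")
  kT <- thermalVoltage(temperature)
  # starting values: half-crossing by interpolation, slope from quartiles
  emStart <- tryCatch(stats::approx(f, E, xout = 0.5, ties = mean)$y,
                      error = function(e) stats::median(E))
  if (is.na(emStart)) emStart <- stats::median(E)
  df <- data.frame(E = E, f = f)
  form <- if (is.null(fixN))
    f ~ 1 / (1 + exp(-n * (E - em) / kT))
  else f ~ 1 / (1 + exp(-fixN * (E - em) / kT))
  start <- if (is.null(fixN)) list(em = emStart, n = 1) else
    list(em = emStart)
  fit <- tryCatch(
    stats::nls(form, data = df, start = start,
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e)
      minpack.lm::nlsLM(form, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)))
  cf <- stats::coef(fit)
  new("NernstFit", em = unname(cf["em"]),
      nApp = if (is.null(fixN)) unname(cf["n"]) else fixN,
      rss = sum(stats::resid(fit)^2), site = as.integer(site))
}

#' Macroscopic stepwise midpoint potentials
#'
#' The k-th macroscopic midpoint is the solution potential at which the
#' k-oxidized and (k-1)-oxidized macrostate populations are equal (the
#' stepwise oxidation equilibrium), computed from exact enumeration. For two
#' identical independent sites this yields the statistical-factor splitting
#' 2 (RT/F) ln 2 = 35.6 mV at 298 K. For a two-site model the splitting
#' \eqn{\Delta E_m} = E_half(2) - E_half(1) is also returned.
#'
#' @param model An [EnergyModel-class] with redox sites only.
#' @param ph pH (for mixed models the protonatable sites equilibrate at
#'   this pH).
#' @param interval Search interval for the midpoints, mV.
#' @return List with `eHalf` (ascending stepwise midpoints, mV) and
#'   `deltaEm` (max minus min, mV; NA for a single site).
#' @export
macroscopicMidpoints <- function(model, ph = 7, interval = c(-1500, 1500)) {
  redox <- which(model@siteKind == "redox")
  if (!length(redox)) stop("model must contain redox sites")
  states <- .allStates(model@nSites)
  nox <- rowSums(states[, redox, drop = FALSE])
  # total-oxidation monotonicity guard (can fail for negative couplings)
  eGrid <- seq(interval[1], interval[2], length.out = 61)
  tot <- vapply(eGrid, function(e)
    sum(drop(.stateProbs(states, model, e, ph) * nox)), numeric(1))
  if (any(diff(tot) < -1e-6))
    stop("total mean oxidation is non-monotone; stepwise midpoints undefined")
  nRedox <- length(redox)
  eHalf <- vapply(seq_len(nRedox), function(k) {
    logRatio <- function(e) {
      p <- .stateProbs(states, model, e, ph)
      log(sum(p[nox == k])) - log(sum(p[nox == k - 1]))
    }
    stats::uniroot(logRatio, interval = interval, tol = 1e-8)$root
  }, numeric(1))
  eHalf <- sort(eHalf)
  list(eHalf = eHalf,
       deltaEm = if (nRedox > 1) max(eHalf) - min(eHalf) else NA_real_)
}

#' Write a titration curve as delimited text
#'
#' Columns: E_mV, then one mean-fraction column and one stderr column per
#' site.
#'
#' @param curve A [TitrationCurve-class].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
writeTitrationCurve <- function(curve, path) {
  n <- ncol(curve@fractions)
  df <- data.frame(E_mV = curve@potential)
  for (i in seq_len(n)) {
    df[[paste0("site", i - 1)]] <- curve@fractions[, i]
    df[[paste0("se", i - 1)]] <- curve@se[, i]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
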