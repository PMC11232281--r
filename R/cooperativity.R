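# round half up to integer percent (base round() is half-even)
.roundHalfUp <- function(x) floor(x + 0.5)

#' Decompose a diheme redox-potential splitting
#'
#' Splits the midpoint-potential separation of a heme pair into (1) the
#' environmental contribution — the difference of the two per-site oxidation
#' energies, i.e. the different electrostatic interactions exerted by the
#' surroundings on each heme in the reduced state — and (2) the heme-heme
#' contribution — the destabilization of one heme's oxidized state by
#' oxidation of its neighbour (the pairwise interaction energy). Percentages
#' of the total are rounded half-up independently, so they can sum to
#' 99-101. The high-potential heme is the site with the larger oxidation
#' energy (harder to oxidize, titrates at higher potential).
#'
#' @param terms An [EnergyTerms-class].
#' @param siteI,siteJ 1-based indices into the terms (default the first
#'   two sites).
#' @return A [DecompositionResult-class].
#' @export
decomposeSplitting <- function(terms, siteI = 1L, siteJ = 2L) {
  if (siteI == siteJ) stop("decomposition requires two distinct sites")
  dg <- terms@dgOx
  env <- abs(dg[siteI] - dg[siteJ])
  int <- terms@wPair[siteI, siteJ]
  total <- env + int
  if (abs(total) < 1e-12) {
    envPct <- intPct <- NA_integer_
  } else {
    envPct <- as.integer(.roundHalfUp(100 * env / total))
    intPct <- as.integer(.roundHalfUp(100 * int / total))
  }
  hi <- if (dg[siteI] >= dg[siteJ]) siteI else siteJ
  lo <- if (hi == siteI) siteJ else siteI
  new("DecompositionResult", envMv = unname(env), intMv = unname(int),
      totalMv = unname(env + int), envPct = envPct, intPct = intPct,
      lowSite = as.integer(terms@siteIds[lo]),
      highSite = as.integer(terms@siteIds[hi]))
}

#' Midpoint-potential shift between two constructs
#'
#' @param fitA,fitB [NernstFit-class] objects (or bare numbers, mV).
#' @param labelA,labelB Construct labels for the report.
#' @return A [ShiftReport-class] with shift = E_m(A) - E_m(B), antisymmetric
#'   under swapping the arguments.
#' @export
compareConstructs <- function(fitA, fitB, labelA = "A", labelB = "B") {
  ea <- if (is(fitA, "NernstFit")) fitA@em else as.numeric(fitA)
  eb <- if (is(fitB, "NernstFit")) fitB@em else as.numeric(fitB)
  new("ShiftReport", constructA = labelA, constructB = labelB,
      shiftMv = ea - eb)
}

#' Splitting decomposition under two dielectric environments
#'
#' Runs the full continuum-electrostatic decomposition of the same
#' structure under a low-dielectric (e.g. membrane) and a high-dielectric
#' (e.g. aqueous) environment and reports the amplification ratio
#' total(low) / total(high) — the screening mechanism by which membrane
#' burial strengthens redox cooperativity.
#'
#' @param s A [HemeStructure-class] with radii assigned.
#' @param sites List of [HemeSite-class] objects (at least two).
#' @param envLow,envHigh [DielectricEnvironment-class] objects, typically
#'   with lower and higher external dielectric.
#' @param grid A [GridSpec-class].
#' @return List with elements `low` and `high` ([DecompositionResult-class]
#'   objects), `ratio` (total splitting amplification) and
#'   `interactionRatio` (pairwise-term amplification).
#' @export
dielectricSensitivity <- function(s, sites, envLow, envHigh,
                                  grid = gridSpec()) {
  tl <- computeEnergyTerms(s, sites, envLow, grid)
  th <- computeEnergyTerms(s, sites, envHigh, grid)
  dl <- decomposeSplitting(tl)
  dh <- decomposeSplitting(th)
  list(low = dl, high = dh,
       ratio = dl@totalMv / dh@totalMv,
       interactionRatio = dl@intMv / dh@intMv)
}

#' Serialize a decomposition result to JSON
#'
#' @param x A [DecompositionResult-class].
#' @param path Optional path; with NULL the JSON string is returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
decompositionJSON <- function(x, path = NULL) {
  obj <- list(env_mV = x@envMv, int_mV = x@intMv, total_mV = x@totalMv,
              env_pct = x@envPct, int_pct = x@intPct,
              low_site = x@lowSite, high_site = x@highSite)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
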