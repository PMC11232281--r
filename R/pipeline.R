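#' Named dielectric-environment presets
#'
#' Three presets mirror commonly used continuum settings for these
#' scaffolds: `"aqueous-78.2"` (bulk water around the protein),
#' `"membrane-6.445"` (an implicit membrane slab with a dielectric equal to
#' the protein interior, aqueous 78.2 beyond the slab) and `"pbmc-20"`
#' (solvent 80 / protein 20, the configuration of PB/Monte-Carlo titration
#' workflows).
#'
#' @param name Preset name.
#' @param epsProtein Interior dielectric (defaults to the preset's choice).
#' @param slabZ Membrane slab z-range, Angstrom (membrane preset only;
#'   default a 30.6 Angstrom slab centred on z = 0).
#' @return A [DielectricEnvironment-class].
#' @export
environmentPreset <- function(name = c("aqueous-78.2", "membrane-6.445",
                                       "pbmc-20"),
                              epsProtein = NULL, slabZ = NULL) {
  name <- match.arg(name)
  switch(name,
    "aqueous-78.2" = dielectricEnvironment(
      epsProtein = if (is.null(epsProtein)) dielectricPreset("4D2")
                   else epsProtein,
      epsSolvent = 78.2),
    "membrane-6.445" = dielectricEnvironment(
      epsProtein = if (is.null(epsProtein)) dielectricPreset("CytbX")
                   else epsProtein,
      epsSolvent = 78.2, epsMembrane = 6.445,
      slabZ = if (is.null(slabZ)) c(-15.3, 15.3) else slabZ),
    "pbmc-20" = dielectricEnvironment(
      epsProtein = if (is.null(epsProtein)) 20 else epsProtein,
      epsSolvent = 80))
}

#' Assemble a validated pipeline configuration
#'
#' All parameters of the structure -> energies -> titration -> decomposition
#' pipeline with defaults; unknown titration options are rejected and file
#' inputs are checked before any computation.
#'
#' @param input Path to a PDB file, or NULL to generate the synthetic
#'   fixture described by `fixture`.
#' @param fixture Named list of [bundleSpec()] arguments for the synthetic
#'   input.
#' @param preset Environment preset name (see [environmentPreset()]).
#' @param epsProtein Interior dielectric: a number, a preset key for
#'   [dielectricPreset()], or "sasa" to estimate it from heme exposure.
#' @param chargeTable Optional charge/radius table path.
#' @param grid Named list of [gridSpec()] arguments.
#' @param titration Named list: `method` ("enumeration" or "mc"),
#'   `potentials` (mV grid), `ph`, `nSteps`, `nEquil`.
#' @param referenceMv Model-compound reference potential added to the
#'   oxidation energies, mV.
#' @param seed Integer seed used for every stochastic stage.
#' @return Validated config (a named list, class "hemeCoopConfig").
#' @export
pipelineConfig <- function(input = NULL, fixture = list(), preset = "aqueous-78.2",
                           epsProtein = NULL, chargeTable = NULL,
                           grid = list(), titration = list(),
                           referenceMv = 0, seed = 1L) {
  tdef <- list(method = "enumeration", potentials = seq(-400, 200, 5),
               ph = 7, nSteps = 1e5, nEquil = 1e4)
  bad <- setdiff(names(titration), names(tdef))
  if (length(bad)) stop("unknown titration option(s): ",
                        paste(bad, collapse = ", "))
  titration <- utils::modifyList(tdef, titration)
  if (!titration$method %in% c("enumeration", "mc"))
    stop("titration method must be 'enumeration' or 'mc'")
  if (!is.null(input) && !file.exists(input))
    stop("input structure not found: ", input)
  if (!is.null(chargeTable) && !file.exists(chargeTable))
    stop("charge table not found: ", chargeTable)
  cfg <- list(input = input, fixture = fixture, preset = preset,
              epsProtein = epsProtein, chargeTable = chargeTable,
              grid = grid, titration = titration,
              referenceMv = referenceMv, seed = as.integer(seed))
  class(cfg) <- "hemeCoopConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys are [pipelineConfig()] arguments.
#' @return Validated config.
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$titration$potentials) &&
      length(vals$titration$potentials) == 3 &&
      !is.null(names(vals$titration$potentials)))
    vals$titration$potentials <- do.call(seq, as.list(
      vals$titration$potentials))
  do.call(pipelineConfig, vals)
}

#' Run the full redox-cooperativity pipeline
#'
#' Stages, in order: structure input (PDB or synthetic fixture), radius and
#' charge assignment, heme-site detection, SASA-based interior dielectric
#' (optional), continuum-electrostatic energy terms, titration (exact
#' enumeration or Metropolis MC), single-electron Nernst fits, macroscopic
#' midpoints, and — for a diheme — decomposition of the splitting.
#' Intermediates are persisted as text files in `outDir` and a single JSON
#' summary is written; a rerun with the same config and seed reproduces the
#' summary bit-for-bit.
#'
#' @param config A [pipelineConfig()] (or [readConfig()]) result.
#' @param outDir Output directory (created if missing).
#' @return Invisibly, the summary list.
#' @export
runPipeline <- function(config, outDir = tempfile("hemecoop")) {
  if (!inherits(config, "hemeCoopConfig"))
    config <- do.call(pipelineConfig, config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  s <- stage("structure", {
    if (is.null(config$input)) {
      spec <- do.call(bundleSpec, utils::modifyList(
        list(seed = config$seed), config$fixture))
      generateBundle(spec)
    } else assignRadii(readPDB(config$input))
  })
  if (!is.null(config$chargeTable))
    s <- stage("charges", assignRadii(s, config$chargeTable))
  sites <- stage("detect", detectHemeSites(s))
  if (!length(sites)) stop("pipeline stage 'detect' failed: no heme sites")
  writePDB(s, file.path(outDir, "structure.pdb"))

  epsP <- config$epsProtein
  sasaFrac <- NA_real_
  if (is.null(epsP)) epsP <- NULL # preset default
  if (identical(epsP, "sasa")) {
    sr <- stage("sasa", computeSasa(s, sites = sites))
    sasaFrac <- mean(sr@hemeExposedFraction)
    epsP <- estimateInteriorDielectric(sasaFrac)
  } else if (is.character(epsP)) epsP <- dielectricPreset(epsP)

  env <- stage("environment", {
    e <- environmentPreset(config$preset, epsProtein = epsP,
                           slabZ = if (!is.null(s@meta$membraneSpan) &&
                                       !is.na(s@meta$membraneSpan))
                             c(-1, 1) * s@meta$membraneSpan / 2 else NULL)
    validObject(e)
    e
  })
  grid <- do.call(gridSpec, config$grid)
  terms <- stage("energies", computeEnergyTerms(s, sites, env, grid))
  writeEnergyTerms(terms, file.path(outDir, "energy_terms.tsv"))

  model <- modelFromTerms(terms, reference = config$referenceMv,
                          temperature = env@temperature)
  tt <- config$titration
  curve <- stage("titration",
    if (tt$method == "mc")
      mcTitration(model, tt$potentials, tt$ph, tt$nSteps, tt$nEquil,
                  seed = config$seed)
    else enumerationTitration(model, tt$potentials, tt$ph))
  writeTitrationCurve(curve, file.path(outDir, "titration.tsv"))

  fits <- stage("fit", lapply(seq_len(model@nSites), function(i)
    fitNernst(curve, i, fixN = 1, temperature = env@temperature)))
  mids <- stage("midpoints", macroscopicMidpoints(model, ph = tt$ph))

  summary <- list(
    seed = config$seed, preset = config$preset,
    eps_protein = env@epsProtein, eps_solvent = env@epsSolvent,
    eps_membrane = env@epsMembrane,
    sasa_heme_exposed_fraction = sasaFrac,
    n_sites = model@nSites,
    dg_ox_meV = as.numeric(terms@dgOx),
    w_pair_meV = if (model@nSites > 1)
      terms@wPair[upper.tri(terms@wPair)] else numeric(0),
    site_em_mV = vapply(fits, em, numeric(1)),
    stepwise_midpoints_mV = mids$eHalf,
    delta_em_mV = mids$deltaEm)
  if (model@nSites >= 2) {
    dec <- stage("decompose", decomposeSplitting(terms))
    decompositionJSON(dec, file.path(outDir, "decomposition.json"))
    summary$decomposition <- list(env_mV = dec@envMv, int_mV = dec@intMv,
                                  total_mV = dec@totalMv,
                                  env_pct = dec@envPct, int_pct = dec@intPct,
                                  low_site = dec@lowSite,
                                  high_site = dec@highSite)
  }
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"),
             file.path(outDir, "summary.json"))
  invisible(summary)
}
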