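#' Accessors for hemeCoop objects
#'
#' Small accessor family: `atoms()` returns the atom table of a
#' [HemeStructure-class], `dgOx()` and `wPair()` the components of an
#' [EnergyTerms-class] or [EnergyModel-class], `em()` and `nApp()` the fitted
#' parameters of a [NernstFit-class].
#'
#' @param x An object.
#' @return The extracted component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("dgOx", function(x) standardGeneric("dgOx"))

#' @rdname accessors
#' @export
setGeneric("wPair", function(x) standardGeneric("wPair"))

#' @rdname accessors
#' @export
setGeneric("em", function(x) standardGeneric("em"))

#' @rdname accessors
#' @export
setGeneric("nApp", function(x) standardGeneric("nApp"))

#' @rdname accessors
#' @export
setMethod("atoms", "HemeStructure", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("dgOx", "EnergyTerms", function(x) {
  stats::setNames(x@dgOx, x@siteIds)
})

#' @rdname accessors
#' @export
setMethod("wPair", "EnergyTerms", function(x) x@wPair)

#' @rdname accessors
#' @export
setMethod("wPair", "EnergyModel", function(x) x@wPair)

#' @rdname accessors
#' @export
setMethod("em", "NernstFit", function(x) x@em)

#' @rdname accessors
#' @export
setMethod("nApp", "NernstFit", function(x) x@nApp)

setMethod("show", "HemeStructure", function(object) {
  cat("HemeStructure:", object@title, "\n")
  cat(" ", nrow(object@atoms), "atoms,",
      length(unique(paste(object@atoms$chain, object@atoms$resid))),
      "residues\n")
  nfe <- sum(object@atoms$element == "Fe")
  if (nfe) cat(" ", nfe, "Fe atom(s)\n")
  invisible(object)
})

setMethod("show", "HemeSite", function(object) {
  cat(sprintf("HemeSite %d: type %s, ligation %s, %d atoms, state %s\n",
              object@siteId, object@hemeType, object@ligation,
              length(object@ringIndices), object@redoxState))
  invisible(object)
})

setMethod("show", "EnergyTerms", function(object) {
  n <- length(object@siteIds)
  cat("EnergyTerms for", n, "site(s)\n")
  cat("  dg_ox (meV):", paste(sprintf("%.1f", object@dgOx), collapse = ", "),
      "\n")
  if (n > 1) {
    off <- object@wPair[upper.tri(object@wPair)]
    cat("  w_pair (meV):", paste(sprintf("%.1f", off), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "EnergyModel", function(object) {
  cat("EnergyModel:", object@nSites, "site(s) at", object@temperature, "K\n")
  cat("  kinds:", paste(object@siteKind, collapse = ", "), "\n")
  cat("  intrinsic:", paste(sprintf("%.1f", object@intrinsic),
                            collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "TitrationCurve", function(object) {
  cat("TitrationCurve:", length(object@potential), "potentials x",
      ncol(object@fractions), "site(s), pH", object@ph, "\n")
  if (!is.null(object@meta$method))
    cat("  method:", object@meta$method, "\n")
  invisible(object)
})

setMethod("show", "NernstFit", function(object) {
  cat(sprintf("NernstFit: E_m = %.2f mV, n_app = %.3f (rss %.3g)\n",
              object@em, object@nApp, object@rss))
  invisible(object)
})

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("Redox-splitting decomposition: total %.1f mV\n",
              object@totalMv))
  cat(sprintf("  environmental: %.1f mV (%s%%)\n", object@envMv,
              ifelse(is.na(object@envPct), "NA", object@envPct)))
  cat(sprintf("  heme-heme:     %.1f mV (%s%%)\n", object@intMv,
              ifelse(is.na(object@intPct), "NA", object@intPct)))
  cat(sprintf("  high-potential site: %d, low-potential site: %d\n",
              object@highSite, object@lowSite))
  invisible(object)
})

setMethod("show", "ShiftReport", function(object) {
  cat(sprintf("E_m shift %s - %s: %+.1f mV\n", object@constructA,
              object@constructB, object@shiftMv))
  invisible(object)
})
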