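#' Shrake-Rupley solvent-accessible surface area
#'
#' Classic point-on-sphere SASA: each atom is expanded by the probe radius,
#' `nSpherePoints` quasi-uniform (golden-spiral) test points are placed on
#' the expanded sphere, and the exposed fraction is the share of points not
#' buried inside any neighbouring expanded sphere.
#'
#' When `sites` is supplied, the per-site heme exposure is also computed as
#' SASA(site atoms in the full structure) / SASA(the same atoms in
#' isolation), the quantity used to estimate the interior dielectric with
#' [estimateInteriorDielectric()].
#'
#' @param s A [HemeStructure-class] with radii assigned (see [assignRadii()]).
#' @param probeRadius Solvent probe radius, Angstrom (default 1.4).
#' @param nSpherePoints Test points per atom, >= 92 (default 960).
#' @param sites Optional list of [HemeSite-class] objects.
#' @return A [SasaResult-class].
#' @export
computeSasa <- function(s, probeRadius = 1.4, nSpherePoints = 960,
                        sites = NULL) {
  a <- s@atoms
  if (any(a$radius <= 0))
    stop("all radii must be positive; call assignRadii() first")
  if (nSpherePoints < 92) stop("n_sphere_points must be >= 92")
  per <- shrakeRupley(as.matrix(a[, c("x", "y", "z")]), a$radius,
                      probeRadius, nSpherePoints)
  frac <- NA_real_
  if (!is.null(sites) && length(sites)) {
    frac <- vapply(sites, function(site) {
      idx <- site@ringIndices
      inContext <- sum(per[idx])
      sub <- a[idx, , drop = FALSE]
      isolated <- sum(shrakeRupley(as.matrix(sub[, c("x", "y", "z")]),
                                   sub$radius, probeRadius, nSpherePoints))
      if (isolated <= 0) return(0)
      min(1, inContext / isolated)
    }, numeric(1))
  }
  new("SasaResult", perAtomArea = per, totalArea = sum(per),
      hemeExposedFraction = frac)
}

# Golden-spiral points on the unit sphere
spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

shrakeRupley <- function(xyz, radius, probe, npts) {
  n <- nrow(xyz)
  pts <- spherePoints(npts)
  rext <- radius + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    nb <- which(d2 < (rext[i] + rext)^2 & seq_len(n) != i)
    sp <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      exposed <- rep(TRUE, npts)
      for (j in nb) {
        if (!any(exposed)) break
        dj2 <- (sp[exposed, 1] - xyz[j, 1])^2 + (sp[exposed, 2] - xyz[j, 2])^2 +
               (sp[exposed, 3] - xyz[j, 3])^2
        exposed[exposed] <- dj2 > rext[j]^2
      }
      fexp <- sum(exposed) / npts
    } else fexp <- 1
    area[i] <- 4 * pi * rext[i]^2 * fexp
  }
  area
}

#' Map heme solvent exposure to an interior dielectric constant
#'
#' Monotone non-decreasing interpolation from heme exposed fraction
#' 0..1 to a dielectric in epsMin..epsMax. The default mapping is linear
#' between the declared bounds; any user mapping can be supplied as a set of
#' (fraction, epsilon) knots interpolated monotonically. Named presets carry
#' reference interior dielectrics for the two published de novo scaffolds:
#' `dielectricPreset("4D2")` = 6.776 and `dielectricPreset("CytbX")` = 6.445.
#'
#' @param frac Heme exposed fraction between 0 and 1.
#' @param epsMin,epsMax Bounds of the mapping (defaults 4 and 25).
#' @param knots Optional two-column matrix/data.frame (fraction, epsilon)
#'   of a user calibration; must be monotone non-decreasing.
#' @return Dielectric constant between epsMin and epsMax.
#' @export
estimateInteriorDielectric <- function(frac, epsMin = 4.0, epsMax = 25.0,
                                       knots = NULL) {
  if (any(frac < 0 | frac > 1)) stop("heme exposed fraction must be in [0,1]")
  if (is.null(knots)) knots <- cbind(c(0, 1), c(epsMin, epsMax))
  knots <- as.matrix(knots)
  if (is.unsorted(knots[, 1]) || is.unsorted(knots[, 2]))
    stop("dielectric mapping must be monotone non-decreasing")
  stats::approx(knots[, 1], knots[, 2], xout = frac, rule = 2)$y
}

.dielectricPresets <- c("4D2" = 6.776, "CytbX" = 6.445)

#' Named interior-dielectric presets
#'
#' @param name Preset key ("4D2" or "CytbX"); with no argument, the whole
#'   preset table is returned.
#' @return Dielectric constant(s).
#' @export
dielectricPreset <- function(name) {
  if (missing(name)) return(.dielectricPresets)
  if (!name %in% names(.dielectricPresets))
    stop("unknown dielectric preset: ", name)
  unname(.dielectricPresets[name])
}
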