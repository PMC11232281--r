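#' Detect heme sites, their type and axial ligation
#'
#' Finds Fe-containing cofactors, classifies each heme as b- or c-type
#' (c iff a Cys S sits within covalent distance of a heme carbon, i.e. a
#' thioether link), and assigns the axial ligation from the residue types of
#' the two nearest non-porphyrin N/S atoms within `feLigandCutoff` of the
#' iron (His N -> His, Met S -> Met). Sites with fewer than two axial
#' candidates are returned with ligation "unassigned" and a warning; any
#' other ligand combination is likewise flagged as unsupported.
#'
#' Each site carries reduced/oxidized per-atom charge sets. The built-in
#' simplified set places the +1 e oxidation charge difference 0.6 on Fe and
#' 0.1 on each of four pyrrole nitrogens (falling back to Fe when fewer
#' nitrogens are present); user tables can be applied with [assignRadii()]
#' before detection to override the reduced-state background charges.
#'
#' @param s A [HemeStructure-class].
#' @param feLigandCutoff Fe-ligand distance cutoff, Angstrom (default 3.0,
#'   covering His-N at ~2.0-2.2 and Met-S at ~2.3-2.5).
#' @param thioetherCutoff Cys S - heme C distance for c-type detection,
#'   Angstrom.
#' @return List of [HemeSite-class] objects (possibly empty), site ids
#'   0-based in order of Fe serial.
#' @export
detectHemeSites <- function(s, feLigandCutoff = 3.0, thioetherCutoff = 2.2) {
  a <- s@atoms
  feIdx <- which(toupper(a$element) == "FE")
  if (!length(feIdx)) return(list())
  feIdx <- feIdx[order(a$serial[feIdx])]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  sites <- vector("list", length(feIdx))
  for (k in seq_along(feIdx)) {
    fe <- feIdx[k]
    ring <- which(a$chain == a$chain[fe] & a$resid == a$resid[fe] &
                  a$resname == a$resname[fe])
    # b/c classification: any Cys S covalently close to a heme carbon
    cysS <- which(a$resname == "CYS" & toupper(a$element) == "S")
    hemeC <- ring[toupper(a$element[ring]) == "C"]
    isC <- FALSE
    if (length(cysS) && length(hemeC)) {
      dmin <- min(apply(xyz[cysS, , drop = FALSE], 1, function(p)
        min(sqrt(colSums((t(xyz[hemeC, , drop = FALSE]) - p)^2)))))
      isC <- dmin <= thioetherCutoff
    }
    # axial ligands: nearest non-ring N/S within cutoff
    cand <- which(toupper(a$element) %in% c("N", "S"))
    cand <- setdiff(cand, ring)
    dFe <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[fe, ])^2))
    keep <- dFe <= feLigandCutoff
    cand <- cand[keep]; dFe <- dFe[keep]
    ord <- order(dFe)
    cand <- cand[ord][seq_len(min(2L, length(cand)))]
    ligation <- "unassigned"
    if (length(cand) < 2L) {
      warning("heme site ", k - 1L, ": fewer than two axial ligand ",
              "candidates within ", feLigandCutoff, " A; ligation unassigned")
    } else {
      res <- a$resname[cand]
      el <- toupper(a$element[cand])
      lab <- ifelse(res == "HIS" & el == "N", "His",
                    ifelse(res == "MET" & el == "S", "Met", "?"))
      lab <- sort(lab)
      if (identical(lab, c("His", "His"))) ligation <- "His-His"
      else if (identical(lab, c("His", "Met"))) ligation <- "His-Met"
      else warning("heme site ", k - 1L, ": unsupported axial ligand ",
                   "combination (", paste(a$resname[cand], collapse = "/"),
                   "); only His-His and His-Met hemes are supported")
    }
    cs <- hemeChargeSets(a, ring, fe)
    sites[[k]] <- new("HemeSite", siteId = k - 1L,
                      hemeType = if (isC) "c" else "b",
                      ligation = ligation, feIndex = fe,
                      ringIndices = ring,
                      chargeReduced = cs$reduced,
                      chargeOxidized = cs$oxidized,
                      redoxState = "reduced")
  }
  sites
}

# Simplified built-in oxidation charge sets: reduced = whatever background
# charges the atoms carry; oxidized = reduced + 0.6 e on Fe + 0.1 e on each
# of the four pyrrole N nearest the iron (remainder onto Fe when fewer N).
hemeChargeSets <- function(a, ring, fe) {
  red <- a$charge[ring]
  oxi <- red
  feLocal <- match(fe, ring)
  nIdx <- which(toupper(a$element[ring]) == "N")
  if (length(nIdx) > 4) {
    d <- sqrt((a$x[ring][nIdx] - a$x[fe])^2 + (a$y[ring][nIdx] - a$y[fe])^2 +
              (a$z[ring][nIdx] - a$z[fe])^2)
    nIdx <- nIdx[order(d)][1:4]
  }
  oxi[nIdx] <- oxi[nIdx] + 0.1
  oxi[feLocal] <- oxi[feLocal] + (1 - 0.1 * length(nIdx))
  list(reduced = red, oxidized = oxi)
}

#' Per-atom oxidation charge difference of a heme site
#'
#' @param site A [HemeSite-class].
#' @return Numeric vector over the site's ring atoms summing to +1 e.
#' @export
oxidationChargeDiff <- function(site) {
  site@chargeOxidized - site@chargeReduced
}
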