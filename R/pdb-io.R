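#' Read a PDB file into a HemeStructure
#'
#' Parses ATOM/HETATM records (via bio3d) into the atom table of a
#' [HemeStructure-class]. Coordinates are in Angstrom; partial charges are
#' initialized to 0 and radii to 0 pending assignment with [assignRadii()].
#'
#' @param path Path to a PDB file.
#' @param dialect "strict" validates every ATOM/HETATM record (fixed-width
#'   numeric fields) and fails with the offending line number; "permissive"
#'   accepts whatever bio3d can parse.
#' @return A [HemeStructure-class].
#' @seealso [writePDB()], [assignRadii()], [detectHemeSites()]
#' @export
readPDB <- function(path, dialect = c("permissive", "strict")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read PDB file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  if (dialect == "strict") {
    for (i in which(rec)) {
      ln <- lines[i]
      if (nchar(ln) < 54)
        stop("malformed record at line ", i, ": too short")
      for (fld in list(c(31, 38), c(39, 46), c(47, 54))) {
        v <- suppressWarnings(as.numeric(substr(ln, fld[1], fld[2])))
        if (is.na(v))
          stop("malformed record at line ", i, ": non-numeric coordinate")
      }
    }
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  elem <- a$elesy
  blank <- is.na(elem) | trimws(elem) == ""
  if (any(blank)) elem[blank] <- inferElement(a$elety[blank])
  elem <- normalizeElement(elem)
  atoms <- data.frame(
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    element = elem,
    resname = trimws(a$resid),
    resid = as.integer(a$resno),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    x = a$x, y = a$y, z = a$z,
    charge = 0, radius = 0,
    record = a$type,
    stringsAsFactors = FALSE
  )
  title <- sub("^TITLE\\s+\\d*\\s*", "", lines[grepl("^TITLE", lines)][1])
  if (is.na(title)) title <- basename(path)
  new("HemeStructure", atoms = atoms, title = title)
}

#' Write a HemeStructure to a PDB file
#'
#' Standard fixed-width ATOM/HETATM records (%8.3f coordinates), so a
#' write/read round trip preserves coordinates to 1e-3 Angstrom and atom
#' order exactly.
#'
#' @param s A [HemeStructure-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePDB <- function(s, path) {
  a <- s@atoms
  type <- if ("record" %in% names(a)) a$record else
    ifelse(a$resname %in% c("HEM", "HEC"), "HETATM", "ATOM")
  bio3d::write.pdb(file = path,
                   type = type,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resid, resid = a$resname, eleno = a$serial,
                   elety = a$name, chain = a$chain,
                   o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                   elesy = toupper(a$element))
  invisible(path)
}

# Guess the element from a PDB atom name ("FE" -> Fe, "NE2" -> N, "1HB" -> H)
inferElement <- function(name) {
  nm <- toupper(trimws(name))
  nm <- sub("^[0-9]+", "", nm)
  vapply(nm, function(x) {
    if (x %in% c("FE", "FE2", "FE3")) return("FE")
    if (startsWith(x, "SD") || startsWith(x, "SG") || x == "S") return("S")
    substr(x, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# "FE" -> "Fe", "N" -> "N"
normalizeElement <- function(el) {
  el <- trimws(el)
  long <- nchar(el) > 1
  el[long] <- paste0(substr(el[long], 1, 1),
                     tolower(substr(el[long], 2, nchar(el[long]))))
  toupper2 <- nchar(el) >= 1
  el[toupper2] <- paste0(toupper(substr(el[toupper2], 1, 1)),
                         substr(el[toupper2], 2, nchar(el[toupper2])))
  el
}

# Bondi-like radii by element, Angstrom
.defaultRadii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                   P = 1.80, FE = 1.30, Fe = 1.30)

#' Assign per-atom radii (and optionally charges) from a table
#'
#' With no table, element-based van der Waals radii are used and charges are
#' left untouched. A user table is whitespace-delimited text with columns
#' `resname atomname charge radius`; rows match atoms by residue and atom
#' name, unmatched atoms keep element defaults.
#'
#' @param s A [HemeStructure-class].
#' @param table Optional path to a charge/radius table.
#' @return The structure with radii (and charges, if a table was given) set.
#' @export
assignRadii <- function(s, table = NULL) {
  a <- s@atoms
  r <- .defaultRadii[toupper(a$element)]
  r[is.na(r)] <- 1.70
  a$radius <- unname(r)
  if (!is.null(table)) {
    tb <- readChargeTable(table)
    key <- paste(a$resname, a$name)
    idx <- match(key, paste(tb$resname, tb$atomname))
    hit <- !is.na(idx)
    a$charge[hit] <- tb$charge[idx[hit]]
    a$radius[hit] <- tb$radius[idx[hit]]
  }
  initialize(s, atoms = a)
}

#' Read a whitespace-delimited charge/radius table
#'
#' Format: four columns `resname atomname charge radius`, `#` comments
#' allowed.
#'
#' @param path Path to the table.
#' @return data.frame with columns resname, atomname, charge, radius.
#' @export
readChargeTable <- function(path) {
  tb <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("resname", "atomname", "charge",
                                        "radius"),
                          stringsAsFactors = FALSE)
  if (any(tb$radius <= 0)) stop("radii in a charge table must be positive")
  tb
}
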