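# Structure I/O, heme detection, SASA and the interior-dielectric mapping

test_that("readPDB parses minimal records and preserves serials", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "END"), p)
  s <- readPDB(p)
  a <- atoms(s)
  expect_equal(nrow(a), 2)
  expect_equal(a$serial, c(1L, 2L))
  expect_equal(a$x, c(0, 3.8))
  expect_equal(a$charge, c(0, 0))
})

test_that("readPDB rejects empty files and malformed strict records", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(character(0), p)
  expect_error(readPDB(p), "no ATOM/HETATM")
  expect_error(readPDB(file.path(tempdir(), "no-such-file.pdb")),
               "cannot read")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00",
    "ATOM      2  CA  ALA A   2       3.8xx   0.000   0.000  1.00  0.00"), p)
  expect_error(readPDB(p, dialect = "strict"), "line 2")
})

test_that("PDB round trip preserves coordinates to PDB precision and order", {
  s <- generateBundle(bundleSpec(seed = 3L))
  p <- withr::local_tempfile(fileext = ".pdb")
  writePDB(s, p)
  s2 <- readPDB(p)
  a1 <- atoms(s); a2 <- atoms(s2)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a1$serial, a2$serial)
  expect_equal(a1$name, a2$name)
  expect_lt(max(abs(a1$x - a2$x), abs(a1$y - a2$y), abs(a1$z - a2$z)), 1e-3)
})

test_that("heme detection classifies ligation and b/c type", {
  sHH <- assignRadii(ligandToy())
  sites <- detectHemeSites(sHH)
  expect_length(sites, 1)
  expect_equal(sites[[1]]@hemeType, "b")
  expect_equal(sites[[1]]@ligation, "His-His")

  sHM <- assignRadii(ligandToy(lig2 = c("MET", "S", "SD", 2.4)))
  expect_equal(detectHemeSites(sHM)[[1]]@ligation, "His-Met")

  # thioether-linked Cys within covalent distance of a ring carbon -> c-type
  ringC <- atoms(sHH)[6, c("x", "y", "z")]
  cys <- atomRow(99, ringC$x, ringC$y + 1.9, ringC$z, name = "SG",
                 element = "S", resname = "CYS", resid = 50L, chain = "A",
                 record = "ATOM")
  sC <- assignRadii(ligandToy(extra = cys))
  expect_equal(detectHemeSites(sC)[[1]]@hemeType, "c")
})

test_that("isolated Fe yields unassigned ligation with a warning", {
  s <- new("HemeStructure", atoms = atomRow(1, 0, 0, 0), title = "bare Fe")
  expect_warning(sites <- detectHemeSites(s), "unassigned")
  expect_equal(sites[[1]]@ligation, "unassigned")
})

test_that("detection is invariant under rigid-body transforms", {
  s <- generateBundle(bundleSpec(seed = 11L))
  a <- detectHemeSites(s)
  b <- detectHemeSites(rigidTransform(s))
  expect_equal(length(a), length(b))
  for (i in seq_along(a)) {
    expect_equal(a[[i]]@hemeType, b[[i]]@hemeType)
    expect_equal(a[[i]]@ligation, b[[i]]@ligation)
    expect_equal(a[[i]]@ringIndices, b[[i]]@ringIndices)
  }
})

test_that("oxidation charge-difference sets sum to +1 e", {
  s <- generateBundle(bundleSpec())
  for (site in detectHemeSites(s))
    expect_equal(sum(oxidationChargeDiff(site)), 1, tolerance = 1e-9)
})

test_that("SASA matches analytic closed forms", {
  one <- new("HemeStructure",
             atoms = atomRow(1, 0, 0, 0, element = "C", radius = 1.7),
             title = "one")
  r <- computeSasa(one, probeRadius = 1.4, nSpherePoints = 960)
  expect_equal(r@totalArea, 4 * pi * 3.1^2, tolerance = 0.01)

  two <- new("HemeStructure",
             atoms = rbind(atomRow(1, 0, 0, 0, element = "C", radius = 1.7),
                           atomRow(2, 100, 0, 0, element = "C", radius = 1.7)),
             title = "two far")
  r2 <- computeSasa(two)
  expect_equal(r2@totalArea, 2 * 4 * pi * 3.1^2, tolerance = 0.01)
})

test_that("a fully enclosed atom has zero SASA and adding atoms never adds area", {
  # central atom buried under a dense shell of overlapping spheres
  pts <- hemeCoop:::spherePoints(60) * 2.2
  shell <- do.call(rbind, lapply(seq_len(nrow(pts)), function(i)
    atomRow(i + 1, pts[i, 1], pts[i, 2], pts[i, 3], element = "C",
            radius = 1.7)))
  buried <- new("HemeStructure",
                atoms = rbind(atomRow(1, 0, 0, 0, element = "C",
                                      radius = 1.5), shell),
                title = "buried")
  rb <- computeSasa(buried)
  expect_equal(rb@perAtomArea[1], 0)

  # monotone occlusion: per-atom areas never increase as atoms accumulate
  set.seed(4)
  xyz <- matrix(stats::runif(18, 0, 6), ncol = 3)
  prev <- NULL
  for (n in 2:6) {
    a <- do.call(rbind, lapply(seq_len(n), function(i)
      atomRow(i, xyz[i, 1], xyz[i, 2], xyz[i, 3], element = "C",
              radius = 1.7)))
    cur <- computeSasa(new("HemeStructure", atoms = a, title = "grow"))
    if (!is.null(prev))
      expect_true(all(cur@perAtomArea[seq_len(n - 1)] <= prev + 1e-6))
    prev <- cur@perAtomArea
  }
})

test_that("SASA requires assigned radii and enough sphere points", {
  s <- new("HemeStructure", atoms = atomRow(1, 0, 0, 0, radius = 0),
           title = "no radii")
  expect_error(computeSasa(s), "radii")
  expect_error(computeSasa(assignRadii(s), nSpherePoints = 50), "92")
})

test_that("interior-dielectric mapping is bounded, monotone and presettable", {
  expect_equal(estimateInteriorDielectric(0), 4)
  expect_equal(estimateInteriorDielectric(1), 25)
  fr <- seq(0, 1, 0.05)
  eps <- estimateInteriorDielectric(fr)
  expect_true(all(diff(eps) >= 0))
  expect_error(estimateInteriorDielectric(1.2), "0,1")
  expect_equal(dielectricPreset("4D2"), 6.776)
  expect_equal(dielectricPreset("CytbX"), 6.445)
  expect_error(dielectricPreset("nope"), "unknown")
  # user-supplied monotone calibration
  eps2 <- estimateInteriorDielectric(0.5, knots = cbind(c(0, 0.5, 1),
                                                        c(2, 10, 40)))
  expect_equal(eps2, 10)
  expect_error(estimateInteriorDielectric(0.5,
    knots = cbind(c(0, 1), c(10, 4))), "monotone")
})

test_that("charge/radius tables override element defaults", {
  p <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# resname atom charge radius", "HEM FE 0.25 1.456"), p)
  s <- assignRadii(ligandToy(), table = p)
  a <- atoms(s)
  fe <- which(a$name == "FE")
  expect_equal(a$charge[fe], 0.25)
  expect_equal(a$radius[fe], 1.456)
  expect_equal(a$radius[a$element == "N"][1], 1.55)
})
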