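# Finite-difference PB solver vs analytic electrostatics

coulombK <- 14399.645 # e^2/(4 pi eps0), meV*Angstrom

test_that("region map assigns protein, membrane slab and solvent nodes", {
  s <- assignRadii(ligandToy())
  env <- dielectricEnvironment(epsProtein = 6.445, epsSolvent = 78.2,
                               epsMembrane = 6.445, slabZ = c(-15, 15))
  rm <- buildRegionMap(s, env, gridSpec(coarseSpacing = 1, extent = 25))
  nodeEps <- function(p) {
    ijk <- round((p - rm$origin) / rm$spacing)
    rm$eps[1 + ijk[1] + rm$dims[1] * (ijk[2] + rm$dims[2] * ijk[3])]
  }
  expect_equal(nodeEps(c(0, 0, 0)), 6.445)       # protein centre
  expect_equal(nodeEps(c(30, 0, 0)), 6.445)      # lateral, inside slab
  expect_equal(nodeEps(c(0, 0, 22)), 78.2)       # above the slab
  expect_equal(nodeEps(c(30, 0, 22)), 78.2)      # far corner solvent
})

test_that("solver reproduces the Coulomb potential within 5 percent", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  res <- solvePotential(ch, NULL, uniformEnv(78.2), gridSpec(),
                        evalPoints = matrix(c(10, 0, 0), 1))
  expect_equal(res$potential, coulombK / (78.2 * 10), tolerance = 0.05)
})

test_that("zero charge gives an identically zero potential", {
  ch <- data.frame(x = 0, y = 0, z = 0, q = 0)
  res <- solvePotential(ch, NULL, uniformEnv(78.2), gridSpec(),
                        evalPoints = matrix(c(5, 0, 0), 1))
  expect_equal(res$potential, 0)
})

test_that("Born transfer energy matches the analytic expression within 5 percent", {
  ion <- new("HemeStructure", atoms = atomRow(1, 0, 0, 0, radius = 2),
             title = "Born ion")
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  ctr <- matrix(0, 1, 3)
  g <- gridSpec()
  pOut <- solvePotential(ch, ion, dielectricEnvironment(4, 80), g, ctr)
  pIn <- solvePotential(ch, ion, uniformEnv(4), g, ctr)
  born <- 0.5 * (pOut$potential - pIn$potential)
  analytic <- (coulombK / (2 * 2)) * (1 / 80 - 1 / 4)
  expect_equal(born, analytic, tolerance = 0.05)
})

test_that("discretization error decreases under grid refinement", {
  ion <- new("HemeStructure", atoms = atomRow(1, 0, 0, 0, radius = 2),
             title = "Born ion")
  ch <- data.frame(x = 0, y = 0, z = 0, q = 1)
  ctr <- matrix(0, 1, 3)
  analytic <- (coulombK / (2 * 2)) * (1 / 80 - 1 / 4)
  errAt <- function(h) {
    g <- gridSpec(spacing = h)
    pOut <- solvePotential(ch, ion, dielectricEnvironment(4, 80), g, ctr)
    pIn <- solvePotential(ch, ion, uniformEnv(4), g, ctr)
    abs(0.5 * (pOut$potential - pIn$potential) - analytic)
  }
  expect_lt(errAt(0.4), errAt(0.8))
})

test_that("the potential is linear in the charges", {
  env <- uniformEnv(78.2)
  g <- gridSpec()
  ep <- rbind(c(6, 2, 1), c(-4, 3, 0))
  q1 <- data.frame(x = 0, y = 0, z = 0, q = 1)
  q2 <- data.frame(x = 3, y = 0, z = 0, q = -0.5)
  dom <- list(lo = c(-20, -18, -18), hi = c(23, 18, 18))
  both <- hemeCoop:::pbSolve(NULL, rbind(q1, q2), env, g, ep, domain = dom)
  a <- hemeCoop:::pbSolve(NULL, q1, env, g, ep, domain = dom)
  b <- hemeCoop:::pbSolve(NULL, q2, env, g, ep, domain = dom)
  expect_equal(both$potential, a$potential + b$potential, tolerance = 1e-4)
})

test_that("symmetric sites get equal oxidation energies; repeated runs are bit-identical", {
  toy <- monopoleToy(c(-5, 5))
  env <- uniformEnv(20)
  g <- gridSpec()
  terms <- computeEnergyTerms(toy$s, toy$sites, env, g)
  dg <- dgOx(terms)
  expect_lt(abs(dg[1] - dg[2]), 2)
  terms2 <- computeEnergyTerms(toy$s, toy$sites, env, g)
  expect_identical(terms@dgOx, terms2@dgOx)
  expect_identical(terms@wPair, terms2@wPair)
})

test_that("a fixed background charge shifts dg_ox by the screened Coulomb value", {
  bare <- monopoleToy(0)
  withQ <- bare
  withQ$s <- initialize(bare$s, atoms = rbind(
    atoms(bare$s),
    atomRow(2, 8, 0, 0, name = "O", element = "O", resname = "ION",
            charge = -1)))
  env <- uniformEnv(20)
  g <- gridSpec()
  dgA <- oxidationEnergy(bare$sites[[1]], bare$sites, bare$s, env, g)
  dgB <- oxidationEnergy(withQ$sites[[1]], withQ$sites, withQ$s, env, g)
  expect_equal(dgB - dgA, -coulombK / (20 * 8), tolerance = 0.10)
})

test_that("interaction energies follow Coulomb screening and its dielectric ratio", {
  toy <- monopoleToy(c(0, 10))
  g <- gridSpec()
  wAq <- interactionEnergy(toy$sites[[1]], toy$sites[[2]], toy$s,
                           uniformEnv(78.2), g)
  expect_equal(wAq, coulombK / (78.2 * 10), tolerance = 0.10)
  wMem <- interactionEnergy(toy$sites[[1]], toy$sites[[2]], toy$s,
                            uniformEnv(6.445), g)
  expect_equal(wMem, coulombK / (6.445 * 10), tolerance = 0.10)
  expect_equal(wMem / wAq, 78.2 / 6.445, tolerance = 0.10)
  # symmetry of the pair term
  wJI <- interactionEnergy(toy$sites[[2]], toy$sites[[1]], toy$s,
                           uniformEnv(78.2), g)
  expect_lt(abs(wAq - wJI), 2)
  expect_error(interactionEnergy(toy$sites[[1]], toy$sites[[1]], toy$s,
                                 uniformEnv(78.2), g), "distinct")
})

test_that("w_pair decreases as any region dielectric increases", {
  toy <- monopoleToy(c(0, 10))
  g <- gridSpec()
  w <- vapply(c(6.445, 20, 78.2), function(eps)
    interactionEnergy(toy$sites[[1]], toy$sites[[2]], toy$s,
                      uniformEnv(eps), g), numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("energy terms compose from pairwise calls and handle one site", {
  toy1 <- monopoleToy(0)
  env <- uniformEnv(40)
  g <- gridSpec(spacing = 0.5)
  t1 <- computeEnergyTerms(toy1$s, toy1$sites, env, g)
  expect_equal(dim(wPair(t1)), c(1L, 1L))
  expect_equal(wPair(t1)[1, 1], 0)

  toy3 <- monopoleToy(c(-9, 0, 9))
  t3 <- computeEnergyTerms(toy3$s, toy3$sites, env, g)
  for (i in 1:2) for (j in (i + 1):3) {
    wij <- interactionEnergy(toy3$sites[[i]], toy3$sites[[j]], toy3$s, env, g)
    expect_equal(wPair(t3)[i, j], wij, tolerance = 0.05)
  }
  expect_equal(wPair(t3), t(wPair(t3)))
  expect_equal(diag(wPair(t3)), rep(0, 3))
})

test_that("energies are invariant under global translation inside the grid", {
  toy <- monopoleToy(c(0, 10))
  env <- uniformEnv(20)
  g <- gridSpec()
  w0 <- interactionEnergy(toy$sites[[1]], toy$sites[[2]], toy$s, env, g)
  shifted <- toy
  a <- atoms(toy$s)
  a$x <- a$x + 1.3; a$y <- a$y - 0.7; a$z <- a$z + 0.4
  shifted$s <- initialize(toy$s, atoms = a)
  w1 <- interactionEnergy(shifted$sites[[1]], shifted$sites[[2]], shifted$s,
                          env, g)
  expect_lt(abs(w1 - w0), 2)
})

test_that("EnergyTerms survive the text round trip", {
  terms <- new("EnergyTerms", siteIds = c(0L, 1L), dgOx = c(85.2, 83.1),
               wPair = matrix(c(0, 11.25, 11.25, 0), 2))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeEnergyTerms(terms, p)
  back <- readEnergyTerms(p)
  expect_equal(back@siteIds, terms@siteIds)
  expect_equal(back@dgOx, terms@dgOx)
  expect_equal(back@wPair, terms@wPair)
})
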