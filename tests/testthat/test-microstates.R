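# Microstate Hamiltonian, enumeration, Metropolis MC and Nernst fitting

test_that("microstate energies follow the Hamiltonian", {
  m <- energyModel(c(-100, -100), 50)
  expect_equal(microstateEnergy(c(0, 0), m, -300), 0)
  expect_equal(microstateEnergy(1, energyModel(-100, 0), -100), 0)
  expect_equal(microstateEnergy(c(1, 1), m, -100), 50)
  expect_error(microstateEnergy(c(1, 0, 0), m, 0), "length")
  expect_error(microstateEnergy(c(1, 2), m, 0), "0 or 1")
})

test_that("enumeration matches hand-computed Boltzmann sums", {
  expect_equal(drop(enumerateOccupancies(energyModel(-125, 0), -125)), 0.5)
  two <- energyModel(c(-100, -100), 0)
  expect_equal(drop(enumerateOccupancies(two, -100)), c(0.5, 0.5))
  # interacting pair vs the explicit four-term oracle
  twoW <- energyModel(c(-100, -100), 100)
  for (e in c(-180, -100, -20)) {
    expect_equal(drop(enumerateOccupancies(twoW, e)),
                 twoSiteExact(c(-100, -100), 100, e), tolerance = 1e-10)
  }
  # asymmetric + interacting
  m <- energyModel(c(-150, -40), 60)
  expect_equal(drop(enumerateOccupancies(m, -80)),
               twoSiteExact(c(-150, -40), 60, -80), tolerance = 1e-10)
  expect_error(enumerateOccupancies(generateToyEnergyModel(21), 0), "20")
})

test_that("protonatable sites titrate at their pKa and couple via w", {
  m <- new("EnergyModel", nSites = 1L, siteKind = "protonatable",
           intrinsic = 7.4, wPair = matrix(0, 1, 1), temperature = 298.15)
  expect_equal(drop(enumerateOccupancies(m, 0, ph = 7.4)), 0.5)
  expect_gt(drop(enumerateOccupancies(m, 0, ph = 5)), 0.99)
  expect_lt(drop(enumerateOccupancies(m, 0, ph = 10)), 0.01)
})

test_that("MC titration is reproducible and accepts downhill moves", {
  m <- generateToyEnergyModel(3, seed = 5)
  pg <- seq(-250, 50, 50)
  c1 <- mcTitration(m, pg, nSteps = 2e4, seed = 9)
  c2 <- mcTitration(m, pg, nSteps = 2e4, seed = 9)
  expect_identical(c1@fractions, c2@fractions)
  c3 <- mcTitration(m, pg, nSteps = 2e4, seed = 10)
  expect_false(identical(c1@fractions, c3@fractions))
  # far above the midpoint every oxidation proposal is downhill and accepted:
  # a handful of sweeps saturates the site
  hot <- mcTitration(energyModel(-100, 0), 400, nSteps = 50, nEquil = 10,
                     seed = 1, nBlocks = 2)
  expect_equal(drop(hot@fractions), 1)
  expect_error(mcTitration(m, numeric(0)), "empty")
})

test_that("MC agrees with enumeration within 3x sampling error (seeded models)", {
  pg <- seq(-350, 100, 25)
  for (k in 1:5) {
    n <- c(2, 4, 6, 8, 10)[k]
    m <- generateToyEnergyModel(n, seed = k)
    mc <- mcTitration(m, pg, nSteps = 1e5, nEquil = 1e4, seed = k + 100)
    ex <- enumerateOccupancies(m, pg)
    nEff <- 1e5 / n
    floorSe <- sqrt(2 * pmax(ex * (1 - ex), 1.5 / nEff) / nEff)
    z <- abs(mc@fractions - ex) / pmax(mc@se, floorSe)
    expect_lt(max(z), 3)
  }
})

test_that("strongly coupled pairs trigger joint flip moves and still converge", {
  m <- energyModel(c(-120, -120), 140) # |w| > 2 ln10 RT ~ 118 meV
  pg <- seq(-300, 150, 25)
  mc <- mcTitration(m, pg, nSteps = 1e5, seed = 3)
  ex <- enumerateOccupancies(m, pg)
  expect_lt(max(abs(mc@fractions - ex)), 0.02)
})

test_that("total oxidation is monotone in potential for non-negative couplings", {
  pg <- seq(-400, 200, 10)
  for (k in 1:8) {
    m <- generateToyEnergyModel(sample(1:6, 1), seed = 20 + k)
    tot <- rowSums(enumerateOccupancies(m, pg))
    expect_true(all(diff(tot) > -1e-9))
  }
})

test_that("curves mirror under sign reversal of potentials and intrinsic terms", {
  m <- energyModel(c(-80, -180), 0)
  mRev <- energyModel(c(80, 180), 0)
  pg <- seq(-300, 300, 20)
  f <- enumerateOccupancies(m, pg)
  fRev <- enumerateOccupancies(mRev, -pg)
  expect_equal(fRev, 1 - f, tolerance = 1e-10)
})

test_that("Nernst fits recover planted parameters", {
  fit <- fitNernst(nernstCurve(-125), fixN = 1)
  expect_equal(em(fit), -125, tolerance = 0.1)
  # on exact enumeration of an isolated site
  cv <- enumerationTitration(energyModel(-125, 0))
  f2 <- fitNernst(cv, 1)
  expect_equal(em(f2), -125, tolerance = 0.1)
  expect_equal(nApp(f2), 1, tolerance = 0.01)
  # two-electron curve with free n
  f3 <- fitNernst(nernstCurve(-50, n = 2))
  expect_equal(nApp(f3), 2, tolerance = 0.05)
  expect_equal(em(f3), -50, tolerance = 0.5)
})

test_that("Nernst fitting rejects flat or underdetermined curves", {
  flat <- data.frame(potential = seq(0, 100, 5),
                     fraction = rep(0.02, 21))
  expect_error(fitNernst(flat), "transition not spanned")
  short <- data.frame(potential = c(-10, 0, 10),
                      fraction = c(0.2, 0.5, 0.8))
  expect_error(fitNernst(short), "5 points")
})

test_that("noisy Nernst fits recover E_m within 2 mV on average", {
  set.seed(77)
  ideal <- nernstCurve(-125)
  ems <- replicate(25, {
    noisy <- ideal
    noisy$fraction <- pmin(1, pmax(0, ideal$fraction +
                                     stats::rnorm(nrow(ideal), 0, 0.02)))
    em(fitNernst(noisy, fixN = 1))
  })
  expect_lt(abs(mean(ems) + 125), 2)
  expect_lt(mean(abs(ems + 125)), 2)
})

test_that("stepwise midpoints reproduce closed forms and the enumeration oracle", {
  kT <- thermalVoltage()
  # statistical factor for two identical independent sites
  m0 <- macroscopicMidpoints(energyModel(c(-100, -100), 0))
  expect_equal(m0$deltaEm, 2 * kT * log(2), tolerance = 0.2 / 35.6)
  # interaction shifts the splitting additively for identical sites
  mW <- macroscopicMidpoints(energyModel(c(-100, -100), 100))
  expect_equal(mW$deltaEm, 100 + 2 * kT * log(2), tolerance = 1 / 135)
  expect_equal(mW$eHalf, twoSiteMidpointsExact(c(-100, -100), 100),
               tolerance = 1e-6)
  # large intrinsic separation, no coupling
  mD <- macroscopicMidpoints(energyModel(c(-200, 0), 0))
  ex <- twoSiteMidpointsExact(c(-200, 0), 0)
  expect_equal(mD$deltaEm, diff(ex), tolerance = 1 / 200)
  expect_equal(mD$deltaEm, 200, tolerance = 1 / 200)
})

test_that("splitting grows monotonically with the pair interaction", {
  dEm <- vapply(c(0, 25, 50, 100, 200), function(w)
    macroscopicMidpoints(energyModel(c(-100, -100), w))$deltaEm, numeric(1))
  expect_true(all(diff(dEm) > 0))
})

test_that("titration curves serialize as delimited text", {
  cv <- enumerationTitration(energyModel(c(-100, -150), 30),
                             seq(-300, 100, 50))
  p <- withr::local_tempfile(fileext = ".tsv")
  writeTitrationCurve(cv, p)
  back <- utils::read.table(p, header = TRUE)
  expect_equal(back$E_mV, cv@potential)
  expect_equal(back$site0, cv@fractions[, 1])
  expect_equal(back$se1, cv@se[, 2])
})
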