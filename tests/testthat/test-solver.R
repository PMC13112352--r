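test_that("mean charge follows the two-state law and saturates", {
  expect_equal(meanCharge(0, "acid"), -0.5)
  expect_equal(meanCharge(0, "base"), 0.5)
  expect_equal(meanCharge(40, "acid"), -1, tolerance = 1e-12)
  expect_equal(meanCharge(40, "base"), 0, tolerance = 1e-12)
  expect_equal(meanCharge(c(1, -1, 0), c("acid", "base", "neutral")),
               c(-plogis(1), plogis(1), 0))
})

test_that("conformation residual reduces to chain entropy for ideal chains", {
  sp <- homopolymer("G", 30)
  pp <- acidParams(7)
  q0 <- rep(0, 30)
  expect_equal(residualX(1, q0, sp, pp), 0)
  expect_equal(residualX(2, q0, sp, pp), -15)   # N(1/x - 1) = -N/2
  expect_error(residualX(-1, q0, sp, pp), "x")
})

test_that("fully charged polyacid forces a swollen root inside the bracket", {
  sp <- polyacid30()
  pp <- acidParams(4, salt = 0.01)   # kappa ~ 0.0328
  qFull <- rep(-1, 30)
  ## sign change between x = 1 and x = 1e3
  expect_gt(residualX(1, qFull, sp, pp), 0)
  expect_lt(residualX(1e3, qFull, sp, pp), 0)
  x <- solveX(qFull, sp, pp)
  expect_gt(x, 1)
  expect_lt(abs(residualX(x, qFull, sp, pp)), 1e-8)
})

test_that("neutral and excluded-volume-only chains behave classically", {
  pp <- acidParams(7)
  spG <- homopolymer("G", 20)
  expect_identical(solveX(rep(0, 20), spG, pp), 1)   # exactly ideal
  spW <- homopolymer("G", 20, omega = 0.8)
  expect_gt(solveX(rep(0, 20), spW, pp), 1)          # EV swells the chain
  st <- selfConsistentSolve(spG, pp)
  expect_true(isConverged(st))
  expect_identical(expansionFactor(st), 1)
  expect_true(all(meanCharges(st) == 0))
})

test_that("quenched alternating polyampholyte contracts at low salt", {
  sp <- sequenceSpec(strrep("EK", 25))
  pp <- physicalParams(pH = 7, salt = 1e-4)
  sigma <- rep(c(-1, 1), 25)
  ## the electrostatic term is net attractive for the +/- alternation
  el <- residualX(1, sigma, sp, pp) - residualX(1, rep(0, 50), sp, pp)
  expect_lt(el, 0)
  expect_lt(suppressWarnings(quenchedSolve(sigma, sp, pp)), 1)
})

test_that("mean-field rhs reduces to the ideal field without interactions", {
  sp <- polyacid30()
  pp <- acidParams(5, salt = 0.01)
  ideal <- log(10) * (5 - 4.0)
  expect_equal(fieldRHS(3, rep(0, 30), 1, sp, pp), ideal)
  ## kl -> infinity: interactions screened out
  ppS <- physicalParams(pH = 5, kappa = 1e6 / 5.8)
  expect_equal(fieldRHS(3, rep(-0.7, 30), 1, sp, ppS), ideal,
               tolerance = 1e-9)
  ## like charges suppress ionization: negative shift from negative charges
  expect_lt(fieldRHS(3, rep(-0.7, 30), 1, sp, pp), ideal)
  expect_error(fieldRHS(2, rep(0, 10), 1, homopolymer("G", 10), pp),
               "not titratable")
})

test_that("self-consistent state satisfies both equations a posteriori", {
  sp <- polyacid30()
  pp <- acidParams(5, salt = 0.01)
  st <- selfConsistentSolve(sp, pp)
  expect_true(isConverged(st))
  tol <- 1e-10
  ## Eq. consistency: residual of the conformation equation at the state
  expect_lt(abs(residualX(expansionFactor(st), meanCharges(st), sp, pp)),
            10 * tol * 30)
  ## field self-consistency and charge-field consistency on every residue
  for (i in c(1, 15, 30)) {
    rhs <- fieldRHS(i, meanCharges(st), expansionFactor(st), sp, pp)
    expect_lt(abs(rhs - fields(st)[i]), 1e-7)
    expect_equal(meanCharges(st)[i], meanCharge(fields(st)[i], "acid"))
  }
})

test_that("strong screening recovers Henderson-Hasselbalch titration", {
  sp <- polyacid30()
  ## kl = 1e6: interactions fully negligible
  st <- selfConsistentSolve(sp, physicalParams(pH = 4, kappa = 1e6 / 5.8))
  expect_lt(max(abs(ionizationProfile(st, sp) - 0.5)), 1e-9)
  expect_equal(expansionFactor(st), 1, tolerance = 1e-9)
  ## kl = 1e3: deviation is small but algebraic, ~3e-6 (kernels decay as
  ## (kl)^-2, not exponentially)
  st3 <- selfConsistentSolve(sp, physicalParams(pH = 4, kappa = 1e3 / 5.8))
  expect_lt(max(abs(ionizationProfile(st3, sp) - 0.5)), 1e-5)
})

test_that("extreme pH reduces to the quenched Sawle-Ghosh limit", {
  sp <- polyacid30()
  pp <- acidParams(16, salt = 0.01)   # pKa + 12
  st <- selfConsistentSolve(sp, pp)
  xq <- quenchedSolve(rep(-1, 30), sp, pp)
  expect_lt(abs(expansionFactor(st) - xq), 1e-8)
  expect_lt(max(abs(meanCharges(st) + 1)), 1e-10)
})

test_that("frozen-conformation titration is a fixed point of the full solve", {
  sp <- polyacid30()
  pp <- acidParams(5, salt = 0.01)
  st <- selfConsistentSolve(sp, pp)
  stF <- fixedConformationSolve(sp, pp, expansionFactor(st))
  expect_lt(max(abs(fields(stF) - fields(st)), na.rm = TRUE), 1e-8)
  expect_identical(expansionFactor(stF), expansionFactor(st))
  ## strong screening at frozen x also gives Henderson-Hasselbalch
  stS <- fixedConformationSolve(sp, physicalParams(pH = 4, kappa = 1e6 / 5.8), 1)
  expect_lt(max(abs(ionizationProfile(stS, sp) - 0.5)), 1e-9)
})

test_that("two-acid toy chain agrees with direct hand iteration", {
  sp <- sequenceSpec("EE")
  pp <- acidParams(5, salt = 0.01)
  xf <- 1.3
  st <- fixedConformationSolve(sp, pp, xf)
  ## brute-force: iterate the two coupled scalar equations directly
  kl <- pp@kappa * pp@kuhn
  Jval <- couplingMatrixJ(2, xf, kl)[1, 2]
  pref <- 2 * pp@bjerrum / (pi * pp@kuhn)
  ideal <- log(10) * (5 - 4.4)
  phi <- c(ideal, ideal)
  for (k in 1:2000) {
    q <- -plogis(phi)
    phi <- c(ideal + pref * q[2] * Jval, ideal + pref * q[1] * Jval)
  }
  expect_equal(fields(st), phi, tolerance = 1e-9)
})

test_that("solution is independent of initialization (uniqueness)", {
  sp <- polyacid30()
  pp <- acidParams(4.5, salt = 0.01)
  ref <- selfConsistentSolve(sp, pp)
  set.seed(11)
  for (k in 1:5) {
    st <- selfConsistentSolve(sp, pp,
      solverOptions(initFields = runif(30, -10, 10)))
    expect_lt(abs(expansionFactor(st) - expansionFactor(ref)), 1e-8)
    expect_lt(max(abs(meanCharges(st) - meanCharges(ref))), 1e-8)
  }
})

test_that("strongly coupled diblock converges via adaptive mixing", {
  sp <- ekSpec(30)
  st <- selfConsistentSolve(sp, ekParams(6))
  expect_true(isConverged(st))
  expect_lt(st@residual, 1e-10)
})
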