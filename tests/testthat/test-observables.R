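test_that("ionization profile of the polyacid is U-shaped and palindromic", {
  sp <- polyacid30()
  st <- selfConsistentSolve(sp, acidParams(4, salt = 0.01))
  th <- ionizationProfile(st, sp)
  expect_equal(th[1], th[30], tolerance = 1e-12)
  expect_gt(th[1], th[15])                    # ends more ionized
  expect_lt(max(abs(th - rev(th))), 1e-10)    # palindrome
  ## suppressed relative to ideal at the midpoint pH
  expect_true(all(th < 0.5))
  ## deprotonation and charged fraction coincide for acids
  expect_equal(th, ionizationProfile(st, sp, "deprotonation"))
})

test_that("net charge saturates at composition limits for (EK)25", {
  sp <- ekSpec(1)
  stLow <- selfConsistentSolve(sp, ekParams(-6))
  expect_equal(netCharge(stLow), 25, tolerance = 1e-4)
  stHigh <- selfConsistentSolve(sp, ekParams(20))
  expect_equal(netCharge(stHigh), -25, tolerance = 1e-4)
  ## near-neutral plateau at physiological pH for the alternating sequence
  st7 <- selfConsistentSolve(sp, ekParams(7))
  expect_lt(abs(netCharge(st7)), 0.5)
})

test_that("end-to-end distance follows the trial-chain law", {
  sp <- polyacid30()
  pp <- acidParams(7)
  st <- new("TrialState", x = 1, phi = rep(NA_real_, 30), meanQ = rep(0, 30),
            iterations = 0L, converged = TRUE, residual = 0)
  expect_equal(endToEnd(st, sp, pp), 5.8 * sqrt(30))
  st2 <- st; st2@x <- 2.5
  expect_gt(endToEnd(st2, sp, pp), endToEnd(st, sp, pp))
  ## more swelling at high pH when salt is low (less screening)
  a <- selfConsistentSolve(sp, acidParams(8, salt = 1e-3))
  b <- selfConsistentSolve(sp, acidParams(8, salt = 1e-1))
  expect_gt(endToEnd(a, sp, pp), endToEnd(b, sp, pp))
})

test_that("titration sweep matches point solves and is warm-start invariant", {
  sp <- polyacid30()
  pp <- acidParams(4, salt = 0.01)
  tab1 <- titrationSweep(sp, pp, 4)
  st <- selfConsistentSolve(sp, pp)
  expect_equal(tableSummary(tab1)$netCharge, netCharge(st), tolerance = 1e-9)
  expect_equal(dim(thetaMatrix(tab1)), c(1L, 30L))

  grid <- seq(3, 6, 0.5)
  warm <- titrationSweep(sp, pp, grid)
  cold <- titrationSweep(sp, pp, grid, warmStart = FALSE)
  expect_lt(max(abs(thetaMatrix(warm) - thetaMatrix(cold))), 1e-8)
  expect_true(all(tableSummary(warm)$converged))
  ## ionization grows monotonically with pH for an acid
  expect_true(all(diff(tableSummary(warm)$netCharge) < 0))
  expect_true(all(apply(thetaMatrix(warm), 2, function(v) all(diff(v) > 0))))
  ## salt grid produces one block per salt value
  tab2 <- titrationSweep(sp, pp, c(4, 5), saltGrid = c(1e-3, 1e-2))
  expect_equal(nrow(tableSummary(tab2)), 4L)
  expect_equal(unique(tableSummary(tab2)$salt), c(1e-3, 1e-2))
})

test_that("isoelectric point sits at the E/K midpoint and errors cleanly", {
  ## ideal (non-interacting) equal-composition chain: pI = (4.4 + 10.4)/2
  sp <- sequenceSpec(strrep("EK", 10))
  pp <- physicalParams(pH = 7, salt = 0.015)
  piIdeal <- isoelectricPoint(sp, pp,
                              options = solverOptions(interactions = FALSE))
  expect_equal(as.numeric(piIdeal), 7.4, tolerance = 1e-4)
  expect_lt(abs(attr(piIdeal, "netCharge")), 1e-6)
  ## homopolyacid never crosses zero
  expect_error(isoelectricPoint(polyacid30(), pp), "negative")
})
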