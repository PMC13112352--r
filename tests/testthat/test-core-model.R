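test_that("Debye parameter follows the screened-electrolyte formula", {
  expect_identical(debyeParameter(0, 7.1), 0)
  ## direct evaluation of sqrt(8 pi lambda_B c N_A 1e-27)
  expect_equal(debyeParameter(0.01, 7.1), 0.03278118, tolerance = 1e-6)
  ## square-root scaling in concentration, exact
  expect_equal(debyeParameter(0.04, 7.1) / debyeParameter(0.01, 7.1), 2)
  ## strictly increasing in both arguments
  salts <- c(1e-4, 1e-3, 1e-2, 1e-1)
  expect_true(all(diff(debyeParameter(salts, 7.1)) > 0))
  expect_true(all(diff(sapply(c(3, 7.1, 12), function(lb)
    debyeParameter(0.01, lb))) > 0))
  expect_error(debyeParameter(-0.1, 7.1), "salt")
  expect_error(debyeParameter(0.1, 0), "bjerrum")
})

test_that("Bjerrum length matches water at room temperature", {
  expect_equal(bjerrumLength(298.15, 78.4), 7.1, tolerance = 0.01)
  ## inverse proportionality in the dielectric constant
  expect_equal(bjerrumLength(298.15, 39.2), 2 * bjerrumLength(298.15, 78.4))
  expect_equal(bjerrumLength(298.15, 1), 7.148716 * 78.4, tolerance = 1e-4)
  expect_error(bjerrumLength(-1, 78.4))
  expect_error(bjerrumLength(298.15, 0))
})

test_that("ideal ionization is Henderson-Hasselbalch with acid/base symmetry", {
  expect_equal(idealIonization(4.4, 4.4, "acid"), 0.5)
  expect_equal(idealIonization(6.4, 4.4, "acid"), 100 / 101)
  ## acid at (pH, pKa) equals base reflected through the pKa
  pHs <- seq(0, 14, 0.5)
  expect_equal(idealIonization(pHs, 6, "acid"),
               idealIonization(2 * 6 - pHs, 6, "base"))
  ## consistency with the two-state law at the ideal field, both kinds
  pKa <- 4.4
  phi <- log(10) * (pHs - pKa)
  expect_lt(max(abs(-meanCharge(phi, "acid") -
                      idealIonization(pHs, pKa, "acid"))), 1e-12)
  expect_lt(max(abs(meanCharge(phi, "base") -
                      idealIonization(pHs, pKa, "base"))), 1e-12)
})

test_that("sequence construction assigns kinds, pKa and omega correctly", {
  sp <- sequenceSpec("AEKGRDH")
  expect_equal(chainLength(sp), 7L)
  expect_equal(unname(residueKinds(sp)),
               c("neutral", "acid", "base", "neutral", "base", "acid", "base"))
  expect_equal(sp@pKa, c(NA, 4.4, 10.4, NA, 12.0, 4.0, 6.3))
  expect_true(all(sp@omega == 0))
  ## scalar, per-type and matrix omega agree where they should
  spU <- sequenceSpec("EKEK", omega = 0.5)
  expect_true(all(spU@omega == 0.5))
  spT <- sequenceSpec("EKEK", omega = c(E = 0.2, K = 0.6))
  expect_equal(spT@omega[1, 2], 0.4)
  expect_equal(spT@omega[1, 3], 0.2)
  expect_equal(spT@omega, t(spT@omega))
  spV <- sequenceSpec("EK", omega = "volumes")
  expect_equal(spV@omega[1, 2], (138.4 + 168.6) / 2 / 5.8^3)
  expect_error(sequenceSpec("EXK"), "unknown residue")
  expect_error(sequenceSpec("E"), "at least 2")
  expect_error(sequenceSpec("EK", pKa = c(K = 10.4)), "no pKa")
  expect_error(defaultPKa(c(Z = 1)), "no default pKa")
  expect_equal(unname(defaultPKa(c(E = 4.25))["E"]), 4.25)
})

test_that("physical parameter construction derives kappa from salt", {
  pp <- physicalParams(pH = 7, salt = 0.01, bjerrum = 7.1)
  expect_equal(pp@kappa, debyeParameter(0.01, 7.1))
  pk <- physicalParams(pH = 7, kappa = 0.1)
  expect_true(is.na(pk@salt))
  expect_error(physicalParams(pH = 7), "either")
  expect_error(physicalParams(pH = 7, salt = 0.1, kappa = 0.1), "only one")
  expect_error(physicalParams(pH = 7, salt = -1))
})

test_that("FASTA sequences round-trip through readSequenceFasta", {
  path <- tempfile(fileext = ".fasta")
  writeLines(c(">a test record", "EKEK", ">b", "GGDD"), path)
  expect_equal(readSequenceFasta(path), "EKEK")
  expect_equal(readSequenceFasta(path, id = "b"), "GGDD")
  expect_error(readSequenceFasta(path, id = "zz"), "no record")
})
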