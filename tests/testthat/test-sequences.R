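test_that("variant library has exact composition and ordered blockiness", {
  lib <- ekVariantLibrary()
  expect_length(lib, 30L)
  expect_true(all(nchar(lib) == 50L))
  comp <- vapply(lib, function(s)
    sum(strsplit(s, "")[[1]] == "E"), integer(1))
  expect_true(all(comp == 25L))
  expect_equal(ekVariant(1), strrep("EK", 25))
  expect_equal(ekVariant(30), paste0(strrep("E", 25), strrep("K", 25)))
  ## blockiness (|SCD|) strictly increases along the library
  scds <- vapply(lib, scd, numeric(1))
  expect_true(all(diff(scds) < 0))
  expect_error(ekVariant(31))
  expect_error(ekVariant(0))
})

test_that("shipped FASTA, generator and round trip all agree", {
  gen <- makeEkVariantLibrary()
  shipped <- system.file("extdata", "ek25_variants_synthetic.fasta",
                         package = "chargereg")
  expect_true(nzchar(shipped))
  expect_equal(readVariantLibraryFasta(shipped), gen)
  path <- tempfile(fileext = ".fasta")
  writeVariantLibraryFasta(path, gen)
  expect_equal(readVariantLibraryFasta(path), gen)
})

test_that("scd agrees with the double-loop oracle on random sequences", {
  set.seed(3)
  for (k in 1:50) {
    s <- paste(sample(c("E", "K", "G", "R", "D", "A"), 25, replace = TRUE),
               collapse = "")
    expect_equal(scd(s), scdLoop(s), tolerance = 1e-12)
  }
  expect_identical(scd("GGGG"), 0)
  ## blockier arrangements are more negative; reversal leaves SCD unchanged
  expect_lt(scd(paste0(strrep("E", 25), strrep("K", 25))),
            scd(strrep("EK", 25)))
  s <- ekVariant(10)
  rev1 <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_equal(scd(s), scd(rev1))
})

test_that("homopolymer builds the expected chains", {
  sp <- homopolymer("E", 30, pKa = c(E = 4.0))
  expect_equal(chainLength(sp), 30L)
  expect_true(all(residueKinds(sp) == "acid"))
  expect_equal(unique(sp@pKa), 4.0)
  spG <- homopolymer("G", 10)
  expect_true(all(residueKinds(spG) == "neutral"))
  expect_error(homopolymer("E", 1))
})

test_that("E and K homopolymers titrate as mirror images", {
  ## with mirrored pKa values (4 and 14 - 4 = 10), the acid at pH equals the
  ## base at 14 - pH: identical |charges| and identical conformation
  spE <- homopolymer("E", 20, pKa = c(E = 4.0))
  spK <- homopolymer("K", 20, pKa = c(K = 10.0))
  for (ph in c(3, 5, 7)) {
    stE <- selfConsistentSolve(spE, acidParams(ph, salt = 0.01))
    stK <- selfConsistentSolve(spK, acidParams(14 - ph, salt = 0.01))
    expect_equal(abs(meanCharges(stE)), abs(meanCharges(stK)),
                 tolerance = 1e-8)
    expect_equal(expansionFactor(stE), expansionFactor(stK),
                 tolerance = 1e-8)
  }
})

test_that("random blocky generator is deterministic with exact composition", {
  s1 <- randomBlockySequence(20, 20, 5, seed = 9)
  s2 <- randomBlockySequence(20, 20, 5, seed = 9)
  expect_identical(s1, s2)
  r <- strsplit(s1, "")[[1]]
  expect_equal(sum(r == "E"), 20L)
  expect_equal(sum(r == "K"), 20L)
  ## block length controls blockiness
  short <- randomBlockySequence(25, 25, 1, seed = 5)
  long <- randomBlockySequence(25, 25, 25, seed = 5)
  expect_lt(abs(scd(short)), abs(scd(long)))
  ## acid-only composition
  expect_identical(randomBlockySequence(6, 0, 2, seed = 1), "EEEEEE")
})
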