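#' @include sequence-spec.R
NULL

## run code with a fixed RNG state, restoring the caller's state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Homopolymer sequence
#'
#' @param label one-letter residue code.
#' @param N chain length (>= 2).
#' @param ... passed to [sequenceSpec()] (pKa overrides, omega).
#' @return a \linkS4class{SequenceSpec} of \code{N} identical residues.
#' @examples
#' homopolymer("E", 30)   # the weak polyacid test chain
#' @export
homopolymer <- function(label, N, ...) {
  stopifnot(N >= 2)
  sequenceSpec(strrep(label, N), ...)
}

#' Sequence charge decoration (SCD) metric
#'
#' \deqn{\mathrm{SCD} = \frac{1}{N}\sum_{m>n} \sigma_m\sigma_n (m-n)^{1/2}}
#' with formal charges \eqn{\sigma} (acid \eqn{-1}, base \eqn{+1}, neutral 0).
#' More negative values indicate blockier arrangements of opposite charges;
#' the metric is invariant under sequence reversal.
#'
#' @param seq sequence in any form accepted by [sequenceSpec()] (formal
#'   charges are assigned from residue identity, not ionization state).
#' @return the SCD value (dimensionless).
#' @examples
#' scd(strrep("EK", 25))                    # near 0: well mixed
#' scd(paste0(strrep("E", 25), strrep("K", 25)))   # strongly negative
#' @export
scd <- function(seq) {
  residues <- .splitResidues(seq)
  kind <- .residueKind(residues)
  sigma <- (kind == "base") - (kind == "acid")
  N <- length(sigma)
  sq <- sqrt(abs(outer(seq_len(N), seq_len(N), "-")))
  sum(sigma * (sq %*% sigma)) / (2 * N)
}

#' Random blocky polyampholyte sequence
#'
#' Builds an E/K sequence of exact composition by laying down alternating
#' acid/base blocks whose lengths are geometric with mean
#' \code{blockLength}, truncated to the remaining composition. Deterministic
#' for a fixed seed; the caller's RNG state is untouched.
#'
#' @param nAcid number of E residues.
#' @param nBase number of K residues.
#' @param blockLength target mean block length (>= 1).
#' @param seed integer seed.
#' @return one-letter sequence string.
#' @export
randomBlockySequence <- function(nAcid, nBase, blockLength, seed = 1L) {
  stopifnot(nAcid >= 0, nBase >= 0, nAcid + nBase >= 2, blockLength >= 1)
  .withSeed(seed, {
    left <- c(E = nAcid, K = nBase)
    cur <- sample(c("E", "K")[c(nAcid, nBase) > 0], 1)
    out <- character(0)
    while (sum(left) > 0) {
      if (left[[cur]] == 0) {
        cur <- if (cur == "E") "K" else "E"
        next
      }
      len <- min(1 + stats::rgeom(1, prob = min(1, 1 / blockLength)),
                 left[[cur]])
      out <- c(out, rep(cur, len))
      left[[cur]] <- left[[cur]] - len
      cur <- if (cur == "E") "K" else "E"
    }
    paste(out, collapse = "")
  })
}

## deterministic annealing of a 25E/25K string toward a target SCD
.annealToSCD <- function(target, seed, nAcid = 25L, nBase = 25L,
                         steps = 6000L, tol = 5e-4) {
  .withSeed(seed, {
    sigma <- sample(c(rep(-1L, nAcid), rep(1L, nBase)))
    N <- length(sigma)
    sq <- sqrt(abs(outer(seq_len(N), seq_len(N), "-")))
    r <- as.numeric(sq %*% sigma)
    val <- sum(sigma * r) / (2 * N)
    for (k in seq_len(steps)) {
      if (abs(val - target) < tol) break
      i <- sample.int(N, 1); j <- sample.int(N, 1)
      if (sigma[i] == sigma[j]) next
      d <- sigma[j] - sigma[i]
      ## scd after swapping values at i and j
      cand <- val + (2 * d * (r[i] - r[j]) - 2 * d^2 * sq[i, j]) / (2 * N)
      if (abs(cand - target) < abs(val - target)) {
        tmp <- sigma[i]; sigma[i] <- sigma[j]; sigma[j] <- tmp
        r <- as.numeric(sq %*% sigma)
        val <- cand
      }
    }
    paste(ifelse(sigma < 0, "E", "K"), collapse = "")
  })
}

.variantCache <- new.env(parent = emptyenv())

#' Synthetic (EK)25 variant library spanning charge blockiness
#'
#' Thirty 50-residue sequences of fixed composition (25 E + 25 K) ordered by
#' increasing charge blockiness, emulating the classic E/K variant set used
#' to study sequence effects in polyampholytes. Variants 1 (strict
#' alternation, the least blocky arrangement possible) and 30 (E25K25
#' diblock, the blockiest) are exact; variants 2-29 are SYNTHETIC stand-ins:
#' deterministic seeded annealing to SCD targets geometrically spaced between
#' the two exact endpoints. Composition and monotone SCD ordering are
#' enforced; the intermediate strings themselves are not transcriptions of
#' any published set.
#'
#' The library ships as a versioned plain-text FASTA
#' (\code{extdata/ek25_variants_synthetic.fasta}); [makeEkVariantLibrary()]
#' regenerates it deterministically and the test suite asserts the two agree.
#'
#' @return character vector of 30 sequences, names \code{sv01}..\code{sv30}.
#' @seealso [ekVariant()], [makeEkVariantLibrary()],
#'   [writeVariantLibraryFasta()]
#' @export
ekVariantLibrary <- function() {
  if (!is.null(.variantCache$lib)) return(.variantCache$lib)
  shipped <- system.file("extdata", "ek25_variants_synthetic.fasta",
                         package = "chargereg")
  lib <- if (nzchar(shipped)) readVariantLibraryFasta(shipped)
         else makeEkVariantLibrary()
  .variantCache$lib <- lib
  lib
}

#' Regenerate the synthetic variant library from scratch
#'
#' Deterministic generator behind [ekVariantLibrary()]; see there for the
#' construction.
#'
#' @return character vector of 30 sequences, names \code{sv01}..\code{sv30}.
#' @export
makeEkVariantLibrary <- function() {
  v1 <- strrep("EK", 25)
  v30 <- paste0(strrep("E", 25), strrep("K", 25))
  s1 <- scd(v1)
  s30 <- scd(v30)
  targets <- -(abs(s1) * (abs(s30) / abs(s1))^((seq_len(30) - 1) / 29))
  lib <- character(30)
  lib[1] <- v1
  lib[30] <- v30
  for (n in 2:29) lib[n] <- .annealToSCD(targets[n], seed = 7000L + n)
  names(lib) <- sprintf("sv%02d", seq_len(30))
  lib
}

#' One variant from the synthetic (EK)25 library
#'
#' @param n variant number in 1..30 (larger = blockier).
#' @return 50-residue sequence string.
#' @examples
#' ekVariant(1)    # "EKEK..."
#' @export
ekVariant <- function(n) {
  if (!(length(n) == 1L && n %in% 1:30))
    stop("'n' must be a single integer in 1..30")
  unname(ekVariantLibrary()[n])
}

#' Write the variant library to FASTA
#'
#' @param path output FASTA path.
#' @param lib sequence library (default [ekVariantLibrary()]).
#' @return the path, invisibly.
#' @export
writeVariantLibraryFasta <- function(path, lib = ekVariantLibrary()) {
  set <- Biostrings::AAStringSet(lib)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a sequence library from FASTA
#'
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readVariantLibraryFasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  structure(as.character(set), names = names(set))
}
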