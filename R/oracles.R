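#' @include solver.R sequences.R
NULL

#' Quadrature oracle for the Gaussian-averaged screened Coulomb interaction
#'
#' Independent brute-force evaluation of
#' \eqn{\langle e^{-\kappa r}/r\rangle} over the 3-D Gaussian distribution of
#' the vector between two residues \code{sep} segments apart in the trial
#' chain (variance \eqn{\mathrm{sep}\cdot l\cdot l_r}), by adaptive radial
#' quadrature. Used to validate the closed-form kernels; at \eqn{\kappa l = 0}
#' it equals \eqn{\sqrt{6/(\pi\,\mathrm{sep}\,x)}} exactly. Related to the
#' ionization coupling matrix by \eqn{J = (\pi/2)\times} this value.
#'
#' @param sep separation \eqn{|m-n|} in segments (>= 1).
#' @param x expansion factor (> 0).
#' @param kl \eqn{\kappa l} (>= 0).
#' @return an \linkS4class{OracleEstimate}; \code{value} in units of
#'   \eqn{1/l}, \code{stdError} 0.
#' @examples
#' gaussianScreenedAverage(1, 1, 0)@value    # sqrt(6/pi)
#' @export
gaussianScreenedAverage <- function(sep, x, kl) {
  stopifnot(sep >= 1, x > 0, kl >= 0)
  d2 <- sep * x
  f <- function(r)
    4 * pi * r^2 * (3 / (2 * pi * d2))^1.5 * exp(-3 * r^2 / (2 * d2)) *
      exp(-kl * r) / r
  q <- stats::integrate(f, 0, Inf, rel.tol = 1e-12, abs.tol = 0,
                        stop.on.error = FALSE)
  if (q$message != "OK")
    stop("quadrature did not converge: ", q$message)
  methods::new("OracleEstimate", value = q$value, stdError = 0,
               nSamples = 0L, seed = NA_integer_)
}

#' Monte Carlo sampling of the trial ensemble
#'
#' Draws independent Gaussian bond vectors (segment variance \eqn{l\,l_r})
#' and independent residue charge states with the two-state probabilities
#' implied by the state's mean-fields -- chain conformation and charges are
#' exactly decoupled under the trial Hamiltonian -- and returns Monte Carlo
#' estimates with standard errors for the squared end-to-end distance, the
#' per-residue mean charges, and (optionally) pairwise screened-Coulomb
#' averages. Deterministic for fixed seed; the caller's RNG state is
#' untouched.
#'
#' @param state a \linkS4class{TrialState}.
#' @param seq the corresponding \linkS4class{SequenceSpec}.
#' @param params the corresponding \linkS4class{PhysicalParams}.
#' @param nSamples number of independent samples (>= 1).
#' @param seed integer seed.
#' @param pairs optional 2-column integer matrix of residue index pairs for
#'   which \eqn{\langle e^{-\kappa r}/r\rangle} is estimated.
#' @return list with elements \code{Re2} (an \linkS4class{OracleEstimate},
#'   \enc{Å}{A}\eqn{^2}), \code{meanQ} (data.frame: residue, value,
#'   stdError), and \code{pairAverages} (data.frame: m, n, value, stdError;
#'   units \eqn{1/l}) when \code{pairs} was given.
#' @export
sampleTrialEnsemble <- function(state, seq, params, nSamples = 1e4,
                                seed = 1L, pairs = NULL) {
  stopifnot(nSamples >= 1)
  N <- chainLength(seq)
  l <- params@kuhn
  x <- expansionFactor(state)
  kl <- params@kappa * l
  n <- as.integer(nSamples)
  .withSeed(seed, {
    ## bond vectors in units of l: component variance x/3, N segments
    se <- function(v) stats::sd(v) / sqrt(length(v))
    bonds <- lapply(1:3, function(k)
      matrix(stats::rnorm(n * N, sd = sqrt(x / 3)), N, n))
    re2v <- Reduce(`+`, lapply(bonds, function(b) colSums(b)^2)) * l^2
    Re2 <- methods::new("OracleEstimate", value = mean(re2v),
                        stdError = se(re2v), nSamples = n,
                        seed = as.integer(seed))
    ## charge states: independent two-state residues
    phi <- fields(state)
    qval <- matrix(0, n, N)
    for (i in seq_len(N)) {
      if (seq@kind[i] == "acid")
        qval[, i] <- -(stats::runif(n) < stats::plogis(phi[i]))
      else if (seq@kind[i] == "base")
        qval[, i] <- (stats::runif(n) < stats::plogis(-phi[i]))
    }
    meanQ <- data.frame(residue = seq_len(N),
                        value = colMeans(qval),
                        stdError = apply(qval, 2, se))
    out <- list(Re2 = Re2, meanQ = meanQ)
    if (!is.null(pairs)) {
      pairs <- matrix(as.integer(pairs), ncol = 2)
      pa <- apply(pairs, 1, function(p) {
        lo <- min(p); hi <- max(p)
        stopifnot(hi - lo >= 1, lo >= 1, hi <= N)
        idx <- (lo + 1):hi   # bonds between monomers lo and hi
        rv <- sqrt(Reduce(`+`, lapply(bonds, function(b)
          colSums(b[idx, , drop = FALSE])^2)))
        v <- exp(-kl * rv) / rv
        c(mean(v), se(v))
      })
      out$pairAverages <- data.frame(m = pairs[, 1], n = pairs[, 2],
                                     value = pa[1, ], stdError = pa[2, ])
    }
    out
  })
}
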