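#' @include kernels.R sequence-spec.R
NULL

#' Mean charge from a mean-field
#'
#' The two-state (logistic) law for a titratable site fluctuating in a local
#' field \eqn{\phi}: acids carry \eqn{\langle q\rangle = -1/(1+e^{-\phi})},
#' bases \eqn{\langle q\rangle = +1/(1+e^{\phi})}; neutral residues carry 0.
#' At the ideal field \eqn{\phi = \ln(10)(pH-pK_A)} this reproduces the
#' Henderson-Hasselbalch charged fraction.
#'
#' @param phi numeric vector of mean-fields (\code{NA} allowed on neutrals).
#' @param kind character vector (recycled if scalar): acid/base/neutral.
#' @return numeric vector of mean charges.
#' @examples
#' meanCharge(0, "acid")    # -0.5
#' meanCharge(0, "base")    # +0.5
#' @export
meanCharge <- function(phi, kind) {
  if (length(kind) == 1L) kind <- rep(kind, length(phi))
  stopifnot(length(kind) == length(phi), kind %in% c("acid", "base", "neutral"))
  q <- numeric(length(phi))
  a <- kind == "acid"; b <- kind == "base"
  q[a] <- -stats::plogis(phi[a])
  q[b] <- stats::plogis(-phi[b])
  q
}

## sum of matrix entries at each separation s = 1..N-1 (upper triangle)
.sepSumsMatrix <- function(m) {
  N <- nrow(m)
  vapply(seq_len(N - 1),
         function(s) sum(m[cbind(seq_len(N - s), seq_len(N - s) + s)]),
         numeric(1))
}

## sum of q_m q_{m+s} at each separation
.sepSumsCharge <- function(q) {
  N <- length(q)
  vapply(seq_len(N - 1),
         function(s) sum(q[seq_len(N - s)] * q[seq_len(N - s) + s]),
         numeric(1))
}

## residual of the expansion-factor equation, from precomputed separation sums
.residualXcore <- function(x, N, evSum, Cs, kl, elPref) {
  s <- seq_len(N - 1)
  el <- if (is.null(Cs)) 0 else
    elPref * x^(-1.5) * sum(Cs * s^2 * .kernelAsep(s, x, kl))
  N * (1 / x - 1) + (3 / (2 * pi))^1.5 * x^(-2.5) * evSum + el
}

.solverContext <- function(seq, params) {
  N <- chainLength(seq)
  Ws <- .sepSumsMatrix(seq@omega)
  list(N = N,
       evSum = sum(Ws / sqrt(seq_len(N - 1))),
       kl = params@kappa * params@kuhn,
       elPref = 2 * params@bjerrum / (9 * pi * params@kuhn),
       fieldPref = 2 * params@bjerrum / (pi * params@kuhn),
       ideal = ifelse(seq@kind == "neutral", NA_real_,
                      log(10) * (params@pH - seq@pKa)))
}

#' Residual of the expansion-factor equation
#'
#' Evaluates the variational balance condition for \eqn{x = l_r/l}:
#' \deqn{N(1/x - 1) + (3/2\pi)^{3/2} x^{-5/2} \sum_{m>n}\omega_{mn}(m-n)^{-1/2}
#'  + \frac{2\lambda_B}{9\pi l} x^{-3/2} \sum_{m>n}\langle q_m\rangle\langle
#'  q_n\rangle (m-n)^2 A_{mn}(x,\kappa l)}
#' whose zero is the self-consistent expansion factor: chain entropy against
#' excluded volume and screened electrostatics.
#'
#' @param x expansion factor (> 0); vectorized.
#' @param meanQ numeric length-N vector of mean charges.
#' @param seq a \linkS4class{SequenceSpec}.
#' @param params a \linkS4class{PhysicalParams}.
#' @return residual value(s); zero at the self-consistent \eqn{x}.
#' @examples
#' sp <- homopolymer("G", 10)
#' pp <- physicalParams(pH = 7, salt = 0.01)
#' residualX(1, rep(0, 10), sp, pp)    # 0: ideal chain
#' residualX(2, rep(0, 10), sp, pp)    # -N/2
#' @export
residualX <- function(x, meanQ, seq, params) {
  if (any(x <= 0)) stop("'x' must be > 0")
  stopifnot(length(meanQ) == chainLength(seq))
  ctx <- .solverContext(seq, params)
  Cs <- .sepSumsCharge(meanQ)
  vapply(x, .residualXcore, numeric(1),
         N = ctx$N, evSum = ctx$evSum, Cs = Cs, kl = ctx$kl,
         elPref = ctx$elPref)
}

## root of the expansion-factor equation. Scans a log-spaced grid for sign
## changes; takes the LARGEST root: when the net interaction is attractive
## the residual always diverges to -Inf as x -> 0 (the x^{-3/2} attraction
## beats the N/x entropy), so a spurious small-x crossing accompanies the
## physical solution, which is the continuation of the ideal x = 1 branch.
.solveXcore <- function(N, evSum, Cs, kl, elPref, bracket, nScan = 121L,
                        hint = NULL) {
  if (evSum == 0 && (is.null(Cs) || all(Cs == 0))) return(1)
  f <- function(x) .residualXcore(x, N, evSum, Cs, kl, elPref)
  if (!is.null(hint) && is.finite(hint)) {
    ## narrow scan around the previous iteration's root first
    lo <- max(bracket[1], hint / 4); hi <- min(bracket[2], hint * 4)
    g <- exp(seq(log(lo), log(hi), length.out = 25L))
    fv <- vapply(g, f, numeric(1))
    i <- which(fv[-25L] * fv[-1] <= 0 & is.finite(fv[-25L]) & is.finite(fv[-1]))
    if (length(i) == 1L)
      return(stats::uniroot(f, lower = g[i], upper = g[i + 1L],
                            tol = 1e-13)$root)
  }
  grid <- exp(seq(log(bracket[1]), log(bracket[2]), length.out = nScan))
  fv <- vapply(grid, f, numeric(1))
  hit <- which(fv[-nScan] * fv[-1] <= 0 & is.finite(fv[-nScan]) & is.finite(fv[-1]))
  if (!length(hit)) {
    stop(sprintf(paste0("no sign change of the conformation residual in ",
                        "[%g, %g]: f(min) = %.4g, f(max) = %.4g, range ",
                        "[%.4g, %.4g]; the chain may be collapsing beyond ",
                        "the validity of the two-body theory"),
                 bracket[1], bracket[2], fv[1], fv[nScan], min(fv), max(fv)))
  }
  if (length(hit) > 1L)
    warning("multiple roots of the conformation equation in the bracket; ",
            "returning the largest (physical branch)")
  i <- hit[length(hit)]
  stats::uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-13)$root
}

#' Solve the expansion-factor equation at fixed mean charges
#'
#' @inheritParams residualX
#' @param options a \linkS4class{SolverOptions} (only \code{xBracket} used).
#' @return the expansion factor \eqn{x} (largest root in the bracket; see
#'   Details of [residualX()] for the equation).
#' @examples
#' sp <- homopolymer("E", 10)
#' pp <- physicalParams(pH = 7, salt = 0.01)
#' solveX(rep(-1, 10), sp, pp) > 1    # charged chain swells
#' @export
solveX <- function(meanQ, seq, params, options = solverOptions()) {
  stopifnot(length(meanQ) == chainLength(seq))
  ctx <- .solverContext(seq, params)
  .solveXcore(ctx$N, ctx$evSum, .sepSumsCharge(meanQ), ctx$kl, ctx$elPref,
              options@xBracket)
}

#' Quenched-charge conformation (Sawle-Ghosh limit)
#'
#' Solves the conformation equation alone with fixed (quenched) charges, the
#' strong-polyampholyte limit the full theory reduces to at extreme pH.
#'
#' @param fixedQ numeric length-N vector of fixed formal charges.
#' @inheritParams solveX
#' @return the expansion factor \eqn{x}.
#' @export
quenchedSolve <- function(fixedQ, seq, params, options = solverOptions()) {
  solveX(fixedQ, seq, params, options)
}

#' Right-hand side of the mean-field equation for one residue
#'
#' \eqn{\phi_i = \ln(10)(pH - pK_{A,i}) + (2\lambda_B/\pi l)\sum_{m\neq i}
#' \langle q_m\rangle J_{mi}(x, \kappa l)}; the second term is the
#' electrostatic pKa shift induced by the rest of the chain.
#'
#' @param i residue index (must be titratable).
#' @param meanQ numeric length-N vector of mean charges.
#' @param x expansion factor at which the coupling matrix is evaluated.
#' @inheritParams residualX
#' @return the updated mean-field value for residue \code{i}.
#' @export
fieldRHS <- function(i, meanQ, x, seq, params) {
  stopifnot(length(i) == 1L, i >= 1, i <= chainLength(seq))
  if (seq@kind[i] == "neutral")
    stop("residue ", i, " (", seq@residues[i], ") is not titratable")
  ctx <- .solverContext(seq, params)
  .fieldRHSall(meanQ, x, ctx)[i]
}

## vectorized mean-field update for all residues (NA on neutrals)
.fieldRHSall <- function(meanQ, x, ctx) {
  s <- seq_len(ctx$N - 1)
  J <- .sepMatrix(ctx$N, .kernelJsep(s, x, ctx$kl))
  ctx$ideal + ctx$fieldPref * as.numeric(J %*% meanQ)
}

#' Solver options
#'
#' @param mixing simple-mixing parameter \eqn{\zeta \in (0,1]}; default 0.5.
#' @param tol convergence tolerance on \eqn{\max_i|\Delta\langle q_i\rangle|}
#'   and \eqn{|\Delta x|}; default 1e-10.
#' @param maxIterations iteration cap; default 10000.
#' @param xBracket search interval for the expansion-factor root.
#' @param initFields numeric(0) for ideal Henderson-Hasselbalch
#'   initialization, or explicit length-N initial fields.
#' @param interactions \code{FALSE} disables residue-residue electrostatics.
#' @return a \linkS4class{SolverOptions} object.
#' @export
solverOptions <- function(mixing = 0.5, tol = 1e-10, maxIterations = 10000,
                          xBracket = c(1e-3, 1e3), initFields = numeric(0),
                          interactions = TRUE) {
  methods::new("SolverOptions", mixing = mixing, tol = tol,
               maxIterations = as.integer(maxIterations),
               xBracket = as.numeric(xBracket),
               initFields = as.numeric(initFields),
               interactions = interactions)
}

.newState <- function(x, phi, meanQ, iterations, converged, residual) {
  methods::new("TrialState", x = x, phi = phi, meanQ = meanQ,
               iterations = as.integer(iterations), converged = converged,
               residual = residual)
}

#' Self-consistent solution of the coupled theory
#'
#' Fixed-point iteration for the coupled equations: starting from the ideal
#' (Henderson-Hasselbalch) mean-fields, alternately (i) solve the
#' conformation equation for the expansion factor \eqn{x} at the current mean
#' charges, (ii) update the mean-fields by simple mixing with parameter
#' \eqn{\zeta}, (iii) recompute the mean charges, until both the mean charges
#' and \eqn{x} change by less than \code{tol}. The default mixing
#' \eqn{\zeta = 0.5} converges for weakly and moderately coupled chains; for
#' strongly coupled (blocky) polyampholytes the plain fixed point can settle
#' into a period-2 oscillation, so whenever the residual fails to improve
#' over 100 consecutive iterations the mixing parameter is halved (down to
#' \eqn{\zeta/2^7}, after which the solver aborts with a diagnostic). The
#' converged solution does not depend on the mixing path.
#'
#' @param seq a \linkS4class{SequenceSpec}.
#' @param params a \linkS4class{PhysicalParams}.
#' @param options a \linkS4class{SolverOptions}.
#' @return a \linkS4class{TrialState}; \code{isConverged()} is \code{FALSE}
#'   (with the last residual recorded) if the iteration cap was reached.
#' @examples
#' sp <- homopolymer("E", 10)
#' pp <- physicalParams(pH = 5, salt = 0.01)
#' st <- selfConsistentSolve(sp, pp)
#' expansionFactor(st); sum(meanCharges(st))
#' @export
selfConsistentSolve <- function(seq, params, options = solverOptions()) {
  ctx <- .solverContext(seq, params)
  N <- ctx$N
  kind <- seq@kind
  chargeable <- kind != "neutral"
  bracket <- options@xBracket

  if (!any(chargeable) || !options@interactions) {
    phi <- ctx$ideal
    q <- meanCharge(phi, kind)
    x <- .solveXcore(N, ctx$evSum, NULL, ctx$kl, ctx$elPref, bracket)
    return(.newState(x, phi, q, 0L, TRUE, 0))
  }

  phi <- if (length(options@initFields) == N) {
    ifelse(chargeable, options@initFields, NA_real_)
  } else ctx$ideal
  q <- meanCharge(phi, kind)
  zeta <- options@mixing
  xPrev <- NA_real_
  res <- Inf
  bestRes <- Inf
  stall <- 0L
  nHalved <- 0L
  it <- 0L

  while (it < options@maxIterations) {
    it <- it + 1L
    x <- .solveXcore(N, ctx$evSum, .sepSumsCharge(q), ctx$kl, ctx$elPref,
                     bracket, hint = if (is.na(xPrev)) NULL else xPrev)
    rhs <- .fieldRHSall(q, x, ctx)
    phi <- ifelse(chargeable, (1 - zeta) * phi + zeta * rhs, NA_real_)
    qNew <- meanCharge(phi, kind)
    res <- max(abs(qNew - q), if (is.na(xPrev)) Inf else abs(x - xPrev))
    q <- qNew
    xPrev <- x
    if (res < options@tol) {
      x <- .solveXcore(N, ctx$evSum, .sepSumsCharge(q), ctx$kl, ctx$elPref,
                       bracket, hint = xPrev)
      return(.newState(x, phi, q, it, TRUE, res))
    }
    if (res < bestRes * (1 - 1e-3)) {
      bestRes <- res
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (stall >= 100L) {
      if (nHalved >= 7L)
        stop(sprintf(paste0("self-consistent iteration stalled after %d ",
                            "iterations (residual %.3g) despite mixing ",
                            "reduced to %.4g"), it, res, zeta))
      zeta <- zeta / 2
      nHalved <- nHalved + 1L
      stall <- 0L
      bestRes <- res
    }
  }
  warning("not converged within ", options@maxIterations,
          " iterations (residual ", signif(res, 3), ")")
  .newState(xPrev, phi, q, it, FALSE, res)
}

#' Titration at frozen chain conformation
#'
#' Iterates only the mean-field equations at a fixed expansion factor
#' (the conformation equation is skipped), i.e. the mean-field limit in
#' which the chain statistics are an input rather than self-consistently
#' determined.
#'
#' @param xFixed the frozen expansion factor (> 0).
#' @inheritParams selfConsistentSolve
#' @return a \linkS4class{TrialState} with \code{expansionFactor == xFixed}.
#' @export
fixedConformationSolve <- function(seq, params, xFixed,
                                   options = solverOptions()) {
  stopifnot(length(xFixed) == 1L, xFixed > 0)
  ctx <- .solverContext(seq, params)
  N <- ctx$N
  kind <- seq@kind
  chargeable <- kind != "neutral"

  if (!any(chargeable) || !options@interactions) {
    phi <- ctx$ideal
    return(.newState(xFixed, phi, meanCharge(phi, kind), 0L, TRUE, 0))
  }
  phi <- if (length(options@initFields) == N) {
    ifelse(chargeable, options@initFields, NA_real_)
  } else ctx$ideal
  q <- meanCharge(phi, kind)
  zeta <- options@mixing
  res <- Inf
  it <- 0L
  while (it < options@maxIterations) {
    it <- it + 1L
    rhs <- .fieldRHSall(q, xFixed, ctx)
    phi <- ifelse(chargeable, (1 - zeta) * phi + zeta * rhs, NA_real_)
    qNew <- meanCharge(phi, kind)
    res <- max(abs(qNew - q))
    q <- qNew
    if (res < options@tol)
      return(.newState(xFixed, phi, q, it, TRUE, res))
  }
  warning("not converged within ", options@maxIterations, " iterations")
  .newState(xFixed, phi, q, it, FALSE, res)
}
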