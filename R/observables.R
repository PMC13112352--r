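#' @include solver.R
NULL

#' Per-residue degree of ionization
#'
#' For \code{type = "charged"} (default, the quantity plotted in
#' monomer-resolved ionization profiles) the charged fraction
#' \eqn{|\langle q_i\rangle|} for acids and bases alike; for
#' \code{type = "deprotonation"} the degree of deprotonation
#' \eqn{\theta_i}: \eqn{-\langle q\rangle} for acids,
#' \eqn{1 - \langle q\rangle} for bases (\code{NA} on neutral residues).
#'
#' @param state a converged \linkS4class{TrialState}.
#' @param seq the \linkS4class{SequenceSpec} it was solved for.
#' @param type \code{"charged"} or \code{"deprotonation"}.
#' @return numeric length-N vector in \eqn{[0, 1]}.
#' @export
ionizationProfile <- function(state, seq, type = c("charged", "deprotonation")) {
  type <- match.arg(type)
  q <- meanCharges(state)
  stopifnot(length(q) == chainLength(seq))
  if (type == "charged") return(abs(q))
  out <- rep(NA_real_, length(q))
  a <- seq@kind == "acid"; b <- seq@kind == "base"
  out[a] <- -q[a]
  out[b] <- 1 - q[b]
  out
}

#' Net average charge
#'
#' @param state a \linkS4class{TrialState}.
#' @return \eqn{\sum_i \langle q_i\rangle} in elementary charges.
#' @export
netCharge <- function(state) sum(meanCharges(state))

#' Root-mean-square end-to-end distance
#'
#' \eqn{R_e = l\sqrt{N x}}: the RMS end-to-end distance of the Gaussian trial
#' chain with renormalized Kuhn length \eqn{l_r = x\,l} over contour
#' length \eqn{N l}.
#'
#' @param state a \linkS4class{TrialState}.
#' @param seq the corresponding \linkS4class{SequenceSpec}.
#' @param params the corresponding \linkS4class{PhysicalParams}.
#' @return end-to-end distance in \enc{Å}{A}.
#' @export
endToEnd <- function(state, seq, params) {
  params@kuhn * sqrt(chainLength(seq) * expansionFactor(state))
}

.rebuildParams <- function(params, pH, salt = NULL) {
  if (is.null(salt)) {
    if (is.na(params@salt))
      physicalParams(pH = pH, kappa = params@kappa,
                     bjerrum = params@bjerrum, kuhn = params@kuhn)
    else
      physicalParams(pH = pH, salt = params@salt,
                     bjerrum = params@bjerrum, kuhn = params@kuhn)
  } else {
    physicalParams(pH = pH, salt = salt,
                   bjerrum = params@bjerrum, kuhn = params@kuhn)
  }
}

#' Titration sweep over pH (and optionally salt)
#'
#' Runs one self-consistent solve per grid point, warm-starting each solve
#' from the converged mean-fields of the previous pH (correct because the
#' solution is unique for the models studied; a cold start gives the same
#' table). Points that fail to converge are flagged in the \code{converged}
#' column, never dropped.
#'
#' @param seq a \linkS4class{SequenceSpec}.
#' @param params base \linkS4class{PhysicalParams} (its pH/salt are replaced
#'   by the grid values).
#' @param pHGrid numeric vector of pH values.
#' @param saltGrid optional numeric vector of salt concentrations (mol/L);
#'   when given, one pH sweep is run per salt value.
#' @param options a \linkS4class{SolverOptions}.
#' @param warmStart logical; warm-start along the pH grid (default TRUE).
#' @return a \linkS4class{TitrationTable}.
#' @export
titrationSweep <- function(seq, params, pHGrid, saltGrid = NULL,
                           options = solverOptions(), warmStart = TRUE) {
  stopifnot(length(pHGrid) >= 1)
  N <- chainLength(seq)
  salts <- if (is.null(saltGrid)) NA_real_ else saltGrid
  rows <- list()
  theta <- NULL
  charge <- NULL
  for (s in salts) {
    opts <- options
    for (ph in pHGrid) {
      p <- .rebuildParams(params, ph, if (is.na(s)) NULL else s)
      st <- tryCatch(selfConsistentSolve(seq, p, opts),
                     error = function(e) NULL)
      if (is.null(st)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pH = ph, salt = if (is.na(s)) p@salt else s,
          netCharge = NA_real_, netChargePerResidue = NA_real_,
          endToEnd = NA_real_, x = NA_real_, iterations = NA_integer_,
          converged = FALSE)
        theta <- rbind(theta, rep(NA_real_, N))
        charge <- rbind(charge, rep(NA_real_, N))
        opts <- options   # drop warm start after a failure
        next
      }
      nc <- netCharge(st)
      rows[[length(rows) + 1L]] <- data.frame(
        pH = ph, salt = if (is.na(s)) p@salt else s,
        netCharge = nc, netChargePerResidue = nc / N,
        endToEnd = endToEnd(st, seq, p), x = expansionFactor(st),
        iterations = nIterations(st), converged = isConverged(st))
      theta <- rbind(theta, ionizationProfile(st, seq, "deprotonation"))
      charge <- rbind(charge, meanCharges(st))
      if (warmStart && isConverged(st)) {
        opts <- options
        opts@initFields <- ifelse(is.na(fields(st)), 0, fields(st))
      }
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  dimnames(theta) <- dimnames(charge) <- NULL
  methods::new("TitrationTable", summary = summary, theta = theta,
               charge = charge)
}

#' Isoelectric point
#'
#' Bisects the net charge (a non-increasing function of pH for acid/base
#' chains) to its zero crossing within \code{pHWindow}, to
#' \eqn{|\mathrm{net}| < 10^{-6}} elementary charges.
#'
#' @param seq a \linkS4class{SequenceSpec}.
#' @param params \linkS4class{PhysicalParams} (pH slot ignored).
#' @param pHWindow numeric length-2 search window, default \code{c(0, 14)}.
#' @param options a \linkS4class{SolverOptions}.
#' @param netTol bisection stops when \eqn{|\mathrm{net}|} falls below this
#'   (default 1e-6 e).
#' @return the crossing pH, with attributes \code{netCharge} (net at the
#'   returned pH) and \code{bracket} (the last bracketing pH values).
#' @export
isoelectricPoint <- function(seq, params, pHWindow = c(0, 14),
                             options = solverOptions(), netTol = 1e-6) {
  stopifnot(length(pHWindow) == 2L, pHWindow[1] < pHWindow[2])
  opts <- options
  evalNet <- function(ph) {
    st <- selfConsistentSolve(seq, .rebuildParams(params, ph), opts)
    if (isConverged(st))
      opts@initFields <<- ifelse(is.na(fields(st)), 0, fields(st))
    netCharge(st)
  }
  lo <- pHWindow[1]; hi <- pHWindow[2]
  nlo <- evalNet(lo); nhi <- evalNet(hi)
  if (nlo * nhi > 0) {
    stop("net charge does not change sign in [", lo, ", ", hi, "]: ",
         sprintf("net(%g) = %.4g, net(%g) = %.4g (chain is ", lo, nlo, hi, nhi),
         if (nlo > 0) "positive" else "negative",
         " throughout the window)")
  }
  mid <- NA_real_; nmid <- NA_real_
  for (k in seq_len(200)) {
    mid <- (lo + hi) / 2
    nmid <- evalNet(mid)
    if (abs(nmid) < netTol) break
    if (sign(nmid) == sign(nlo)) {
      lo <- mid; nlo <- nmid
    } else {
      hi <- mid; nhi <- nmid
    }
  }
  structure(mid, netCharge = nmid, bracket = c(lo, hi))
}
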