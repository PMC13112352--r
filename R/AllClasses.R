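#' @include erfcx.R
NULL

#' PhysicalParams: solution conditions for a titration calculation
#'
#' Holds the physical state of the solution: pH, Bjerrum length
#' \eqn{\lambda_B} (\enc{Å}{A}), bare Kuhn length \eqn{l} (\enc{Å}{A}) and the
#' Debye screening parameter \eqn{\kappa} (\enc{Å}{A}\eqn{^{-1}}), the latter
#' either given directly or derived from a monovalent salt concentration via
#' \eqn{\kappa = \sqrt{8\pi\lambda_B c}}. Energies are implicitly in units of
#' \eqn{k_BT}; the electrostatic coupling enters only through \eqn{\lambda_B}.
#'
#' @slot pH numeric, solution pH (dimensionless).
#' @slot bjerrum numeric, Bjerrum length in \enc{Å}{A} (> 0).
#' @slot kuhn numeric, Kuhn length in \enc{Å}{A} (> 0).
#' @slot kappa numeric, Debye parameter in \enc{Å}{A}\eqn{^{-1}} (>= 0).
#' @slot salt numeric, monovalent salt concentration in mol/L, or \code{NA}
#'   when \code{kappa} was supplied directly.
#' @seealso [physicalParams()], [debyeParameter()], [bjerrumLength()]
#' @export
setClass("PhysicalParams",
  representation(pH = "numeric", bjerrum = "numeric", kuhn = "numeric",
                 kappa = "numeric", salt = "numeric"),
  prototype(pH = 7, bjerrum = 7.1, kuhn = 5.8, kappa = 0, salt = NA_real_),
  validity = function(object) {
    msg <- character()
    for (s in c("pH", "bjerrum", "kuhn", "kappa", "salt"))
      if (length(slot(object, s)) != 1L)
        msg <- c(msg, sprintf("'%s' must have length 1", s))
    if (length(msg)) return(msg)
    if (!is.finite(object@bjerrum) || object@bjerrum <= 0)
      msg <- c(msg, "'bjerrum' must be > 0")
    if (!is.finite(object@kuhn) || object@kuhn <= 0)
      msg <- c(msg, "'kuhn' must be > 0")
    if (!is.finite(object@kappa) || object@kappa < 0)
      msg <- c(msg, "'kappa' must be >= 0")
    if (!is.finite(object@pH))
      msg <- c(msg, "'pH' must be finite")
    if (!is.na(object@salt) && object@salt < 0)
      msg <- c(msg, "'salt' must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' SequenceSpec: a titratable heteropolymer sequence
#'
#' An ordered chain of residues, each neutral, acidic (E, D) or basic
#' (K, R, H), with per-residue pKa values and a symmetric matrix of
#' dimensionless pairwise excluded-volume parameters \eqn{\omega_{mn}}.
#'
#' @slot residues character vector of one-letter residue codes (length N >= 2).
#' @slot kind character vector, each one of \code{"acid"}, \code{"base"},
#'   \code{"neutral"}.
#' @slot pKa numeric vector; \code{NA} exactly for neutral residues.
#' @slot omega symmetric N x N numeric matrix of excluded-volume parameters
#'   (dimensionless, in units of the Kuhn volume \eqn{l^3}).
#' @seealso [sequenceSpec()], [omegaVolumes()]
#' @export
setClass("SequenceSpec",
  representation(residues = "character", kind = "character",
                 pKa = "numeric", omega = "matrix"),
  validity = function(object) {
    n <- length(object@residues)
    msg <- character()
    if (n < 2L) msg <- c(msg, "sequence must contain at least 2 residues")
    if (length(object@kind) != n || length(object@pKa) != n)
      msg <- c(msg, "'kind' and 'pKa' must match the number of residues")
    else {
      if (!all(object@kind %in% c("acid", "base", "neutral")))
        msg <- c(msg, "'kind' entries must be acid/base/neutral")
      bad <- xor(is.na(object@pKa), object@kind == "neutral")
      if (any(bad))
        msg <- c(msg, "pKa must be present exactly for acid/base residues")
    }
    if (!is.numeric(object@omega) || !identical(dim(object@omega), c(n, n)))
      msg <- c(msg, "'omega' must be an N x N numeric matrix")
    else if (!isTRUE(all.equal(object@omega, t(object@omega), tolerance = 1e-12)))
      msg <- c(msg, "'omega' must be symmetric")
    if (length(msg)) msg else TRUE
  })

#' SolverOptions: controls for the self-consistent iteration
#'
#' @slot mixing numeric in (0, 1], the simple-mixing parameter \eqn{\zeta}
#'   used when updating the mean-fields (default 0.5).
#' @slot tol numeric > 0, convergence tolerance on both
#'   \eqn{\max_i|\Delta\langle q_i\rangle|} and \eqn{|\Delta x|}
#'   (default 1e-10).
#' @slot maxIterations integer, cap on outer iterations (default 10000).
#' @slot xBracket numeric length-2, search interval for the expansion-factor
#'   root (default \code{c(1e-3, 1e3)}).
#' @slot initFields numeric, either length 0 (initialize at the ideal
#'   Henderson-Hasselbalch fields) or length N (explicit initial mean-fields;
#'   entries for neutral residues are ignored).
#' @slot interactions logical; \code{FALSE} switches off all residue-residue
#'   electrostatics (ideal titration; conformation from excluded volume only).
#' @seealso [solverOptions()]
#' @export
setClass("SolverOptions",
  representation(mixing = "numeric", tol = "numeric",
                 maxIterations = "integer", xBracket = "numeric",
                 initFields = "numeric", interactions = "logical"),
  prototype(mixing = 0.5, tol = 1e-10, maxIterations = 10000L,
            xBracket = c(1e-3, 1e3), initFields = numeric(0),
            interactions = TRUE),
  validity = function(object) {
    msg <- character()
    if (!(length(object@mixing) == 1L && object@mixing > 0 && object@mixing <= 1))
      msg <- c(msg, "'mixing' must be in (0, 1]")
    if (!(length(object@tol) == 1L && object@tol > 0))
      msg <- c(msg, "'tol' must be > 0")
    if (!(length(object@maxIterations) == 1L && object@maxIterations >= 1L))
      msg <- c(msg, "'maxIterations' must be >= 1")
    if (!(length(object@xBracket) == 2L && all(object@xBracket > 0) &&
          object@xBracket[1] < object@xBracket[2]))
      msg <- c(msg, "'xBracket' must be two increasing positive numbers")
    if (length(msg)) msg else TRUE
  })

#' TrialState: a converged (or attempted) variational solution
#'
#' The state of the uniform-expansion trial ensemble: expansion factor
#' \eqn{x = l_r/l}, per-residue mean-fields \eqn{\phi_i} (\code{NA} for
#' neutral residues) and the mean charges \eqn{\langle q_i\rangle} they imply
#' through the two-state (logistic) law, plus convergence metadata.
#' On every returned state the mean charges are exactly consistent with the
#' mean-fields.
#'
#' @slot x numeric > 0, expansion factor \eqn{l_r/l}.
#' @slot phi numeric length N, mean-field per residue (\code{NA} on neutrals).
#' @slot meanQ numeric length N, \eqn{\langle q_i\rangle}: in \eqn{[-1,0]}
#'   for acids, \eqn{[0,1]} for bases, 0 for neutral residues.
#' @slot iterations integer, outer iterations used.
#' @slot converged logical.
#' @slot residual numeric, last maximum change in \eqn{(\langle q_i\rangle, x)}.
#' @seealso [selfConsistentSolve()], [fixedConformationSolve()]
#' @export
setClass("TrialState",
  representation(x = "numeric", phi = "numeric", meanQ = "numeric",
                 iterations = "integer", converged = "logical",
                 residual = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(length(object@x) == 1L && is.finite(object@x) && object@x > 0))
      msg <- c(msg, "'x' must be a single positive number")
    if (length(object@phi) != length(object@meanQ))
      msg <- c(msg, "'phi' and 'meanQ' lengths differ")
    if (any(abs(object@meanQ) > 1 + 1e-12, na.rm = TRUE))
      msg <- c(msg, "mean charges must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  })

#' TitrationTable: results of a pH (and optionally salt) sweep
#'
#' One row per grid point with scalar observables (net charge in elementary
#' charges and per residue, RMS end-to-end distance in \enc{Å}{A}, expansion
#' factor, iteration count, convergence flag), plus matrices of the
#' per-residue degree of ionization \eqn{\theta_i} and mean charges.
#'
#' @slot summary data.frame with columns pH, salt, netCharge,
#'   netChargePerResidue, endToEnd, x, iterations, converged.
#' @slot theta numeric matrix (grid points x N) of deprotonation degrees.
#' @slot charge numeric matrix (grid points x N) of mean charges
#'   \eqn{\langle q_i\rangle}.
#' @seealso [titrationSweep()], [writeTitrationTable()]
#' @export
setClass("TitrationTable",
  representation(summary = "data.frame", theta = "matrix", charge = "matrix"),
  validity = function(object) {
    if (nrow(object@summary) != nrow(object@theta) ||
        nrow(object@summary) != nrow(object@charge))
      "summary rows and matrix rows must agree"
    else TRUE
  })

#' OracleEstimate: result of an independent numerical oracle
#'
#' @slot value numeric estimate.
#' @slot stdError numeric standard error (0 for deterministic quadrature).
#' @slot nSamples integer number of Monte Carlo samples (0 for quadrature).
#' @slot seed integer seed used (NA for quadrature).
#' @seealso [gaussianScreenedAverage()], [sampleTrialEnsemble()]
#' @export
setClass("OracleEstimate",
  representation(value = "numeric", stdError = "numeric",
                 nSamples = "integer", seed = "integer"),
  prototype(stdError = 0, nSamples = 0L, seed = NA_integer_),
  validity = function(object) {
    if (any(object@stdError < 0)) "'stdError' must be >= 0" else TRUE
  })
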