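#' @include AllClasses.R
NULL

#' Accessors for chargereg objects
#'
#' Small accessor generics so user code never touches slots directly:
#' \code{chainLength} (number of residues), \code{residueKinds},
#' \code{expansionFactor} (\eqn{x = l_r/l}), \code{meanCharges}, \code{fields}
#' (mean-fields \eqn{\phi_i}), \code{isConverged}, \code{nIterations},
#' \code{tableSummary} and \code{thetaMatrix}.
#'
#' @param object a \linkS4class{SequenceSpec}, \linkS4class{TrialState} or
#'   \linkS4class{TitrationTable}.
#' @return the corresponding component (see above).
#' @name accessors
#' @examples
#' seq <- homopolymer("E", 5)
#' chainLength(seq)
#' residueKinds(seq)
NULL

#' @rdname accessors
#' @export
setGeneric("chainLength", function(object) standardGeneric("chainLength"))
#' @rdname accessors
#' @export
setGeneric("residueKinds", function(object) standardGeneric("residueKinds"))
#' @rdname accessors
#' @export
setGeneric("expansionFactor", function(object) standardGeneric("expansionFactor"))
#' @rdname accessors
#' @export
setGeneric("meanCharges", function(object) standardGeneric("meanCharges"))
#' @rdname accessors
#' @export
setGeneric("fields", function(object) standardGeneric("fields"))
#' @rdname accessors
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))
#' @rdname accessors
#' @export
setGeneric("nIterations", function(object) standardGeneric("nIterations"))
#' @rdname accessors
#' @export
setGeneric("tableSummary", function(object) standardGeneric("tableSummary"))
#' @rdname accessors
#' @export
setGeneric("thetaMatrix", function(object) standardGeneric("thetaMatrix"))

#' @rdname accessors
setMethod("chainLength", "SequenceSpec", function(object) length(object@residues))
#' @rdname accessors
setMethod("residueKinds", "SequenceSpec", function(object) {
  structure(object@kind, names = object@residues)
})
#' @rdname accessors
setMethod("expansionFactor", "TrialState", function(object) object@x)
#' @rdname accessors
setMethod("meanCharges", "TrialState", function(object) object@meanQ)
#' @rdname accessors
setMethod("fields", "TrialState", function(object) object@phi)
#' @rdname accessors
setMethod("isConverged", "TrialState", function(object) object@converged)
#' @rdname accessors
setMethod("nIterations", "TrialState", function(object) object@iterations)
#' @rdname accessors
setMethod("tableSummary", "TitrationTable", function(object) object@summary)
#' @rdname accessors
setMethod("thetaMatrix", "TitrationTable", function(object) object@theta)

setMethod("show", "SequenceSpec", function(object) {
  n <- chainLength(object)
  s <- paste(object@residues, collapse = "")
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat("SequenceSpec of length", n, "\n  ", s, "\n")
  k <- table(factor(object@kind, levels = c("acid", "base", "neutral")))
  cat(sprintf("  %d acidic, %d basic, %d neutral; max |omega| = %.3g\n",
              k[["acid"]], k[["base"]], k[["neutral"]], max(abs(object@omega))))
})

setMethod("show", "PhysicalParams", function(object) {
  cat(sprintf(paste0("PhysicalParams: pH = %g, lambda_B = %g A, l = %g A, ",
                     "kappa = %.6g 1/A%s\n"),
              object@pH, object@bjerrum, object@kuhn, object@kappa,
              if (is.na(object@salt)) "" else sprintf(" (salt %g M)", object@salt)))
})

setMethod("show", "TrialState", function(object) {
  cat(sprintf("TrialState: x = %.8g (%s after %d iterations, residual %.3g)\n",
              object@x,
              if (object@converged) "converged" else "NOT converged",
              object@iterations, object@residual))
  cat(sprintf("  net charge = %.6g e over %d residues\n",
              sum(object@meanQ), length(object@meanQ)))
})

setMethod("show", "TitrationTable", function(object) {
  cat("TitrationTable with", nrow(object@summary), "grid points,",
      ncol(object@theta), "residues\n")
  print(utils::head(object@summary, 4))
  if (nrow(object@summary) > 4) cat("  ...\n")
})

setMethod("show", "OracleEstimate", function(object) {
  cat(sprintf("OracleEstimate: %.10g (SE %.3g, n = %d)\n",
              object@value, object@stdError, object@nSamples))
})
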