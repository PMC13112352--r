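#' @include observables.R
NULL

.PROFILE_HEADER <- "# chargereg per-residue profile v1"
.SUMMARY_HEADER <- "# chargereg summary v1"

#' Write a per-residue profile TSV
#'
#' Columns: index, residue, kind, pKA, phi, mean_q, theta (deprotonation
#' degree) and charged_fraction, one row per residue, with a versioned
#' comment header.
#'
#' @param state a \linkS4class{TrialState}.
#' @param seq the corresponding \linkS4class{SequenceSpec}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeProfileTable <- function(state, seq, path) {
  df <- data.frame(index = seq_len(chainLength(seq)),
                   residue = seq@residues,
                   kind = seq@kind,
                   pKA = seq@pKa,
                   phi = fields(state),
                   mean_q = meanCharges(state),
                   theta = ionizationProfile(state, seq, "deprotonation"),
                   charged_fraction = ionizationProfile(state, seq, "charged"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.PROFILE_HEADER, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a titration table to disk
#'
#' Produces \code{<prefix>_summary.csv} (pH, salt, net charge in elementary
#' charges and per residue, end-to-end distance, x, iterations, convergence
#' flag) and \code{<prefix>_theta.tsv} (one row per grid point, per-residue
#' columns \code{theta_1..theta_N}).
#'
#' @param table a \linkS4class{TitrationTable}.
#' @param prefix output path prefix.
#' @return character vector of the two paths, invisibly.
#' @export
writeTitrationTable <- function(table, prefix) {
  summaryPath <- paste0(prefix, "_summary.csv")
  thetaPath <- paste0(prefix, "_theta.tsv")
  con <- file(summaryPath, "w")
  writeLines(.SUMMARY_HEADER, con)
  utils::write.table(tableSummary(table), con, sep = ",", quote = FALSE,
                     row.names = FALSE)
  close(con)
  th <- thetaMatrix(table)
  colnames(th) <- paste0("theta_", seq_len(ncol(th)))
  df <- cbind(tableSummary(table)[, c("pH", "salt")], as.data.frame(th))
  con <- file(thetaPath, "w")
  writeLines(.PROFILE_HEADER, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(c(summaryPath, thetaPath))
}

#' Read / write run configurations
#'
#' A run configuration is a flat named list in YAML: exactly one sequence
#' source (\code{seq}, \code{fasta} or \code{variant}) plus physical
#' parameters (\code{ph} or \code{ph_grid}, \code{salt} or \code{salt_grid},
#' \code{bjerrum}, \code{kuhn}, \code{pka} overrides, \code{omega}) and
#' solver options (\code{mixing}, \code{tol}, \code{max_iter},
#' \code{fixed_x}, \code{no_interactions}, \code{seed}, \code{out}).
#' Writing and re-reading a configuration reproduces identical runs.
#'
#' @param path YAML file path.
#' @param config named list.
#' @return \code{readRunConfig}: named list; \code{writeRunConfig}: the path,
#'   invisibly.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(config) {
  src <- intersect(c("seq", "fasta", "variant"), names(config))
  if (length(src) != 1L)
    stop("config must name exactly one sequence source (seq/fasta/variant), ",
         "found: ", if (length(src)) paste(src, collapse = ", ") else "none")
  if (!is.null(config$ph_grid) && length(config$ph_grid) == 0)
    stop("'ph_grid' must be non-empty")
  config
}
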