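#' @include core-model.R
NULL

.AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V")

## van der Waals residue volumes in A^3 (Zamyatnin), used by omegaVolumes()
.AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
                Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
                L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
                S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

.splitResidues <- function(seq) {
  if (methods::is(seq, "SequenceSpec")) return(seq@residues)
  if (inherits(seq, c("AAString", "BString", "XString")))
    seq <- as.character(seq)
  if (is.character(seq) && length(seq) == 1L)
    seq <- strsplit(seq, "", fixed = TRUE)[[1]]
  seq <- toupper(as.character(seq))
  bad <- setdiff(unique(seq), .AA_CODES)
  if (length(bad))
    stop("unknown residue code(s): ", paste(bad, collapse = ", "))
  seq
}

#' Expand an excluded-volume specification to a pair matrix
#'
#' Accepts a scalar (uniform \eqn{\omega}), a named per-residue-type vector
#' (pair value = mean of the two types), or a full symmetric N x N matrix.
#'
#' @param omega scalar, named numeric vector by residue code, or N x N matrix.
#' @param residues character vector of one-letter codes.
#' @return symmetric N x N matrix.
#' @keywords internal
.expandOmega <- function(omega, residues) {
  n <- length(residues)
  if (is.matrix(omega)) {
    if (!identical(dim(omega), c(n, n)))
      stop("'omega' matrix must be ", n, " x ", n)
    return((omega + t(omega)) / 2)
  }
  if (length(omega) == 1L && is.null(names(omega)))
    return(matrix(as.numeric(omega), n, n))
  if (is.null(names(omega)))
    stop("'omega' must be a scalar, a named per-type vector, or a matrix")
  missing <- setdiff(unique(residues), names(omega))
  if (length(missing))
    stop("'omega' lacks entries for residue(s): ",
         paste(missing, collapse = ", "))
  v <- omega[residues]
  outer(v, v, function(a, b) (a + b) / 2)
}

#' Construct a titratable sequence specification
#'
#' Builds a \linkS4class{SequenceSpec} from a one-letter amino-acid string
#' (or character vector, or \code{Biostrings::AAString}). E and D are treated
#' as weak acids, K, R and H as weak bases, everything else as neutral;
#' titration of terminal groups is not modeled.
#'
#' @param seq one-letter string, character vector, \code{AAString}, or an
#'   existing \code{SequenceSpec} (returned unchanged apart from
#'   \code{pKa}/\code{omega} updates).
#' @param pKa named numeric vector mapping residue codes to pKa values;
#'   defaults to [defaultPKa()].
#' @param omega pairwise excluded-volume specification: scalar (default 0),
#'   named per-type vector, full matrix, or the string \code{"volumes"} for
#'   [omegaVolumes()].
#' @param kuhn Kuhn length in \enc{Å}{A}, used only when
#'   \code{omega = "volumes"}.
#' @return a \linkS4class{SequenceSpec}.
#' @examples
#' sequenceSpec("EKEKEK")
#' sequenceSpec("EEEKKK", omega = "volumes")
#' @export
sequenceSpec <- function(seq, pKa = defaultPKa(), omega = 0, kuhn = 5.8) {
  residues <- .splitResidues(seq)
  kind <- .residueKind(residues)
  pk <- rep(NA_real_, length(residues))
  charged <- kind != "neutral"
  missing <- setdiff(unique(residues[charged]), names(pKa))
  if (length(missing))
    stop("no pKa given for titratable residue(s): ",
         paste(missing, collapse = ", "))
  pk[charged] <- pKa[residues[charged]]
  om <- if (identical(omega, "volumes")) omegaVolumes(residues, kuhn = kuhn)
        else .expandOmega(omega, residues)
  dimnames(om) <- NULL
  methods::new("SequenceSpec", residues = residues, kind = kind,
               pKa = pk, omega = om)
}

#' Excluded-volume parameters from van der Waals residue volumes
#'
#' A simple physical convention for residue-specific two-body parameters:
#' \eqn{\omega_{mn} = (V_m + V_n) / (2 l^3)} with \eqn{V} the van der Waals
#' volume of the residue (Zamyatnin) and \eqn{l} the Kuhn length, i.e. the
#' pair repulsion in units of the Kuhn volume. For E/K chains at
#' \eqn{l = 5.8} \enc{Å}{A} this gives \eqn{\omega \approx 0.7}-0.9. The
#' repulsive \eqn{\omega > 0} term stabilizes strongly attractive
#' polyampholytes, whose conformation equation otherwise has no solution near
#' the isoelectric point.
#'
#' @param seq sequence in any form accepted by [sequenceSpec()].
#' @param kuhn Kuhn length in \enc{Å}{A}.
#' @return symmetric N x N matrix of dimensionless \eqn{\omega_{mn}}.
#' @examples
#' omegaVolumes("EK")[1, 2]   # (138.4 + 168.6) / 2 / 5.8^3
#' @export
omegaVolumes <- function(seq, kuhn = 5.8) {
  residues <- .splitResidues(seq)
  v <- .AA_VOLUME[residues] / kuhn^3
  m <- outer(v, v, function(a, b) (a + b) / 2)
  dimnames(m) <- NULL
  m
}

#' Read a sequence from a FASTA file
#'
#' Reads with \code{Biostrings::readAAStringSet}; by default the first record
#' is used, or the record whose name matches \code{id}.
#'
#' @param path FASTA file path.
#' @param id optional record identifier (matched against the first
#'   whitespace-delimited token of each header).
#' @return one-letter sequence string.
#' @export
readSequenceFasta <- function(path, id = NULL) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  if (!is.null(id)) {
    tokens <- vapply(strsplit(names(set), "\\s+"), `[`, "", 1L)
    hit <- which(tokens == id)
    if (!length(hit)) stop("no record named '", id, "' in ", path)
    set <- set[hit[1]]
  }
  as.character(set[[1]])
}
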