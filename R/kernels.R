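#' @include erfcx.R
NULL

## Both coupling matrices are Gaussian-ensemble averages of the
## Debye-Hueckel interaction between residues m and n, whose separation in
## the uniform-expansion trial chain is Gaussian with <r^2> = |m-n| l l_r.
## Writing z = kl * sqrt(s x / 6), s = |m-n|, all entries reduce to two
## scalar shape functions of z:
##
##   jfun(z) = 1 - sqrt(pi) z erfcx(z)
##     from  <exp(-kr)/r> = sqrt(6/(pi d^2)) * jfun(z),  d^2 = s x l^2,
##   hfun(z) = (3/2)sqrt(pi) - 3 sqrt(pi) z^2 + 3 pi z^3 erfcx(z)
##     from  cov(r^2, exp(-kr)/r) = (2 d^4/3) d<.>/d(d^2),
##
## with asymptotic series beyond the cancellation-safe range (both functions
## decay like z^-2; the difference forms lose all digits for z >~ 1e3/1e2).

.jfun <- function(z) {
  out <- numeric(length(z))
  direct <- z < 1e3
  if (any(direct)) {
    zz <- z[direct]
    out[direct] <- 1 - sqrt(pi) * zz * erfcx(zz)
  }
  if (any(!direct)) {
    zz <- z[!direct]
    z2 <- zz^2
    out[!direct] <- 1 / (2 * z2) - 3 / (4 * z2^2) + 15 / (8 * z2^3) -
      105 / (16 * z2^4)
  }
  out
}

.hfun <- function(z) {
  out <- numeric(length(z))
  direct <- z < 1e2
  if (any(direct)) {
    zz <- z[direct]
    out[direct] <- 1.5 * sqrt(pi) - 3 * sqrt(pi) * zz^2 +
      3 * pi * zz^3 * erfcx(zz)
  }
  if (any(!direct)) {
    z2 <- z[!direct]^2
    out[!direct] <- 3 * sqrt(pi) *
      (3 / (4 * z2) - 15 / (8 * z2^2) + 105 / (16 * z2^3) - 945 / (32 * z2^4))
  }
  out
}

## per-separation kernels; s may be a vector of separations >= 1
.kernelJsep <- function(s, x, kl) {
  z <- kl * sqrt(s * x / 6)
  0.5 * sqrt(6 * pi) / sqrt(s * x) * .jfun(z)
}

.kernelAsep <- function(s, x, kl) {
  z <- kl * sqrt(s * x / 6)
  sqrt(6) * s^(-1.5) * .hfun(z)
}

.sepMatrix <- function(N, values) {
  ## symmetric Toeplitz matrix from per-separation values, zero diagonal
  idx <- abs(outer(seq_len(N), seq_len(N), "-"))
  m <- matrix(0, N, N)
  m[idx > 0] <- values[idx[idx > 0]]
  m
}

#' Ionization coupling matrix J
#'
#' The matrix entering the mean-field equations
#' \eqn{\phi_i = \ln(10)(pH - pK_{A,i}) + (2\lambda_B/\pi l)\sum_{m\neq i}
#' \langle q_m\rangle J_{mi}(x,\kappa l)}: the screened Coulomb interaction
#' between residues \eqn{m} and \eqn{i}, averaged over the Gaussian trial
#' ensemble in which their separation has variance \eqn{|m-i|\,l\,l_r}.
#' Entries depend on \eqn{(m,i)} only through the separation \eqn{|m-i|},
#' are positive, decrease with separation, and vanish (algebraically,
#' \eqn{\propto (\kappa l)^{-2}}) in the strong-screening limit.
#'
#' @param N number of residues (>= 2).
#' @param x expansion factor \eqn{l_r/l} (> 0).
#' @param kl dimensionless screening strength \eqn{\kappa l} (>= 0).
#' @return N x N matrix (dimensionless); the diagonal, which never enters any
#'   sum, is set to 0.
#' @examples
#' couplingMatrixJ(4, 1, 0)[1, 2]   # sqrt(6 * pi) / 2
#' @export
couplingMatrixJ <- function(N, x, kl) {
  .checkKernelArgs(N, x, kl)
  .sepMatrix(N, .kernelJsep(seq_len(N - 1), x, kl))
}

#' Conformation coupling matrix A
#'
#' The matrix entering the electrostatic part of the expansion-factor
#' equation, \eqn{(2\lambda_B/9\pi l)\, x^{-3/2} \sum_{m>n} \langle
#' q_m\rangle\langle q_n\rangle (m-n)^2 A_{mn}(x,\kappa l)}: the covariance
#' of the squared end-to-end distance with the screened pair interaction in
#' the trial ensemble, in the normalization of the printed equation. At zero
#' screening \eqn{A_{mn} = (3/2)\sqrt{6\pi}\,|m-n|^{-3/2}} independent of
#' \eqn{x}; entries vanish \eqn{\propto (\kappa l)^{-2}} as \eqn{\kappa l \to
#' \infty}.
#'
#' @inheritParams couplingMatrixJ
#' @return N x N matrix (dimensionless), zero diagonal.
#' @examples
#' conformationMatrixA(4, 1, 0)[1, 2]   # 1.5 * sqrt(6 * pi)
#' @export
conformationMatrixA <- function(N, x, kl) {
  .checkKernelArgs(N, x, kl)
  .sepMatrix(N, .kernelAsep(seq_len(N - 1), x, kl))
}

.checkKernelArgs <- function(N, x, kl) {
  if (!(length(N) == 1L && N >= 2)) stop("'N' must be >= 2")
  if (!(length(x) == 1L && is.finite(x) && x > 0)) stop("'x' must be > 0")
  if (!(length(kl) == 1L && is.finite(kl) && kl >= 0)) stop("'kl' must be >= 0")
  invisible(TRUE)
}
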