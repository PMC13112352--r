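#' @include AllClasses.R
NULL

## 1 mol/L in units of 1/Angstrom^3 (Avogadro constant x 1e-27)
.MOLAR_TO_A3 <- 6.02214076e-4

#' Debye screening parameter from salt concentration
#'
#' \eqn{\kappa = \sqrt{8\pi\lambda_B c}} for a monovalent salt, with the
#' concentration converted from mol/L to \enc{Å}{A}\eqn{^{-3}}.
#'
#' @param salt monovalent salt concentration in mol/L (>= 0).
#' @param bjerrum Bjerrum length \eqn{\lambda_B} in \enc{Å}{A} (> 0).
#' @return \eqn{\kappa} in \enc{Å}{A}\eqn{^{-1}}.
#' @examples
#' debyeParameter(0.01, 7.1)   # ~ 0.0328 1/A
#' @export
debyeParameter <- function(salt, bjerrum = 7.1) {
  stopifnot(is.numeric(salt), is.numeric(bjerrum))
  if (any(salt < 0)) stop("'salt' must be >= 0")
  if (any(bjerrum <= 0)) stop("'bjerrum' must be > 0")
  sqrt(8 * pi * bjerrum * salt * .MOLAR_TO_A3)
}

#' Bjerrum length from temperature and dielectric constant
#'
#' \eqn{\lambda_B = e^2 / (4\pi\varepsilon_0\varepsilon_r k_B T)}, the
#' separation at which the Coulomb energy of two elementary charges equals
#' \eqn{k_BT}. Water at room temperature (\eqn{T = 298.15} K,
#' \eqn{\varepsilon_r = 78.4}) gives \eqn{\approx 7.1} \enc{Å}{A}, the default
#' coupling used throughout.
#'
#' @param temperature absolute temperature in K (> 0).
#' @param dielectric relative dielectric constant (> 0).
#' @return Bjerrum length in \enc{Å}{A}.
#' @examples
#' bjerrumLength(298.15, 78.4)   # ~ 7.1 A
#' @export
bjerrumLength <- function(temperature = 298.15, dielectric = 78.4) {
  if (any(temperature <= 0)) stop("'temperature' must be > 0")
  if (any(dielectric <= 0)) stop("'dielectric' must be > 0")
  e <- 1.602176634e-19      # C
  eps0 <- 8.8541878128e-12  # F/m
  kB <- 1.380649e-23        # J/K
  e^2 / (4 * pi * eps0 * dielectric * kB * temperature) * 1e10
}

#' Ideal (Henderson-Hasselbalch) degree of ionization
#'
#' The charged fraction of an isolated titratable group: for an acid the
#' deprotonated fraction \eqn{1/(1+10^{pK_A-pH})}, for a base the protonated
#' fraction \eqn{1/(1+10^{pH-pK_A})}. This is the non-interacting limit of the
#' full theory, recovered exactly at the ideal mean-field
#' \eqn{\phi = \ln(10)(pH - pK_A)}.
#'
#' @param pH solution pH.
#' @param pKa pKa of the group.
#' @param kind \code{"acid"} or \code{"base"}.
#' @return ionized fraction in \eqn{[0, 1]}; vectorized over pH/pKa.
#' @examples
#' idealIonization(4.4, 4.4, "acid")    # 0.5
#' idealIonization(7.0, 10.4, "base")   # ~ 1
#' @export
idealIonization <- function(pH, pKa, kind = c("acid", "base")) {
  kind <- match.arg(kind)
  if (kind == "acid") 1 / (1 + 10^(pKa - pH)) else 1 / (1 + 10^(pH - pKa))
}

#' Construct solution conditions
#'
#' Either \code{salt} (mol/L) or \code{kappa} (\enc{Å}{A}\eqn{^{-1}}) must be
#' given; when \code{salt} is given, \code{kappa} is derived with
#' [debyeParameter()].
#'
#' @param pH solution pH.
#' @param salt monovalent salt concentration in mol/L (optional).
#' @param kappa Debye parameter in \enc{Å}{A}\eqn{^{-1}} (optional).
#' @param bjerrum Bjerrum length in \enc{Å}{A}; default 7.1 (water, room
#'   temperature).
#' @param kuhn Kuhn length in \enc{Å}{A}; default 5.8.
#' @return a \linkS4class{PhysicalParams} object.
#' @examples
#' physicalParams(pH = 7, salt = 0.015)
#' @export
physicalParams <- function(pH, salt = NULL, kappa = NULL,
                           bjerrum = 7.1, kuhn = 5.8) {
  if (is.null(salt) && is.null(kappa))
    stop("either 'salt' or 'kappa' must be given")
  if (!is.null(salt) && !is.null(kappa))
    stop("give only one of 'salt' and 'kappa'")
  if (!is.null(salt)) {
    kappa <- debyeParameter(salt, bjerrum)
  } else {
    salt <- NA_real_
  }
  methods::new("PhysicalParams", pH = as.numeric(pH),
               bjerrum = as.numeric(bjerrum), kuhn = as.numeric(kuhn),
               kappa = as.numeric(kappa), salt = as.numeric(salt))
}

#' Default pKa table for titratable side chains
#'
#' Intrinsic side-chain pKa values (Nozaki-Tanford): D 4.0, E 4.4, H 6.3,
#' K 10.4, R 12.0. Glutamate 4.4 and lysine 10.4 are the values used for the
#' E/K polyampholytes. Terminal amine/carboxyl groups are not modeled.
#'
#' @param overrides named numeric vector of per-residue overrides, e.g.
#'   \code{c(E = 4.25)}.
#' @return named numeric vector mapping one-letter codes to pKa values.
#' @examples
#' defaultPKa()
#' defaultPKa(c(E = 4.25))["E"]
#' @export
defaultPKa <- function(overrides = NULL) {
  tab <- c(D = 4.0, E = 4.4, H = 6.3, K = 10.4, R = 12.0)
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("'overrides' must be a named numeric vector")
    unknown <- setdiff(names(overrides), names(tab))
    if (length(unknown))
      stop("no default pKa for residue(s): ", paste(unknown, collapse = ", "),
           " (only D, E, H, K, R are titratable here)")
    tab[names(overrides)] <- overrides
  }
  tab
}

## residue -> acid/base/neutral
.residueKind <- function(residues) {
  kind <- rep("neutral", length(residues))
  kind[residues %in% c("E", "D")] <- "acid"
  kind[residues %in% c("K", "R", "H")] <- "base"
  kind
}
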