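#' Construct an ion species
#'
#' @param x element symbol (\code{"H"}, \code{"He"}, \code{"C"}, \code{"N"},
#'   \code{"O"}, \code{"Ne"}) or atomic number
#' @return an [IonSpec-class]
#' @export
#' @examples
#' ionSpec("C")
ionSpec <- function(x) {
  tab <- supportedIons()
  if (is.character(x)) i <- match(x, tab$name)
  else i <- match(as.integer(x), tab$Z)
  if (is.na(i)) stop("unsupported ion species: ", x, call. = FALSE)
  methods::new("IonSpec", Z = tab$Z[i], A = tab$A[i], name = tab$name[i])
}

#' @describeIn ionSpec table of supported species
#' @export
supportedIons <- function() {
  data.frame(name = c("H", "He", "C", "N", "O", "Ne"),
             Z = c(1L, 2L, 6L, 7L, 8L, 10L),
             A = c(1L, 4L, 12L, 14L, 16L, 20L))
}

setMethod("show", "IonSpec", function(object)
  cat(sprintf("IonSpec: %s (Z = %d, A = %d)\n",
              object@name, object@Z, object@A)))

#' Relativistic speed from kinetic energy per nucleon
#'
#' Uses the atomic mass unit rest energy (931.494 MeV) so that ions of equal
#' energy per nucleon are isotachic.
#'
#' @param E kinetic energy per nucleon (MeV/u); vectorized, must be positive
#' @return beta = v/c in (0, 1)
#' @export
betaFromEnergy <- function(E) {
  if (any(E <= 0)) stop("energy must be positive", call. = FALSE)
  g <- 1 + E / .const$amu
  sqrt(1 - 1 / g^2)
}

#' Barkas effective charge
#'
#' Velocity-dependent reduced charge of a partially screened ion,
#' \eqn{Z_{eff} = Z (1 - e^{-125 \beta Z^{-2/3}})}. The constant 125 and the
#' exponent -2/3 are fixed; they determine the printed low- and high-velocity
#' limits of the scaling and are not user-tunable.
#'
#' @param Z atomic number (>= 1)
#' @param beta speed v/c in (0, 1); vectorized
#' @return effective charge in (0, Z)
#' @export
effectiveCharge <- function(Z, beta) {
  if (any(Z < 1)) stop("Z must be >= 1", call. = FALSE)
  if (any(beta <= 0 | beta >= 1)) stop("beta must be in (0, 1)", call. = FALSE)
  Z * (-expm1(-125 * beta * Z^(-2 / 3)))
}

#' Generalized Barkas scaling factor
#'
#' Ratio of effective charges squared relative to hydrogen at the same speed,
#' \eqn{F(Z,\beta) = Z_{eff}(Z,\beta)^2 / Z_{eff}(1,\beta)^2}. Multiplying
#' hydrogen interaction data (stopping power, IMFP) by F yields the data for
#' an ion of atomic number Z at the same energy per nucleon. The hydrogen
#' denominator makes the scheme exactly self-consistent (F = 1 for Z = 1)
#' and extends its validity to low velocities, where F tends to
#' \eqn{Z^{2/3}}; at high velocities F tends to \eqn{Z^2}.
#'
#' @inheritParams effectiveCharge
#' @return dimensionless factor in \eqn{[Z^{2/3}, Z^2]}
#' @export
#' @examples
#' scalingFactor(6, betaFromEnergy(0.25))
scalingFactor <- function(Z, beta) {
  (effectiveCharge(Z, beta) / effectiveCharge(1, beta))^2
}

.applicabilityFloor <- 0.01  # MeV/u

.asIon <- function(ion) if (methods::is(ion, "IonSpec")) ion else ionSpec(ion)

#' Barkas-scaled stopping power and IMFP
#'
#' Hydrogen baseline value at the same energy per nucleon multiplied by the
#' generalized Barkas factor. For hydrogen the result equals the baseline
#' exactly. Energies below the 0.01 MeV/u applicability floor trigger a
#' warning (the scaling is validated down to about 10 keV/u only).
#'
#' @param ion an [IonSpec-class], element symbol or atomic number
#' @param E energy per nucleon (MeV/u); vectorized, within the baseline span
#' @param baseline a [BaselineTable-class]
#' @return `scaledStopping`: keV/um; `scaledImfp`: 1/um
#' @export
#' @examples
#' scaledStopping("C", 0.25, defaultBaseline())
scaledStopping <- function(ion, E, baseline = defaultBaseline()) {
  ion <- .asIon(ion)
  if (any(E < .applicabilityFloor))
    warning("energies below 0.01 MeV/u are outside the validated applicability of the scaling",
            call. = FALSE)
  stoppingH(baseline, E) * scalingFactor(ion@Z, betaFromEnergy(E))
}

#' @rdname scaledStopping
#' @export
scaledImfp <- function(ion, E, baseline = defaultBaseline()) {
  ion <- .asIon(ion)
  if (any(E < .applicabilityFloor))
    warning("energies below 0.01 MeV/u are outside the validated applicability of the scaling",
            call. = FALSE)
  imfpH(baseline, E) * scalingFactor(ion@Z, betaFromEnergy(E))
}

#' Radiation-quality parameter (Z_eff / beta)^2
#'
#' Square of the Barkas effective charge over the speed; decreases
#' monotonically with energy and approaches \eqn{15625 \, Z^{2/3}} as the
#' energy goes to zero.
#'
#' @inheritParams scaledStopping
#' @return dimensionless; vectorized over `E`
#' @export
zeffOverBetaSq <- function(ion, E) {
  ion <- .asIon(ion)
  b <- betaFromEnergy(E)
  (effectiveCharge(ion@Z, b) / b)^2
}
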