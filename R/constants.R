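#' Model constants for the receptor-array thermodynamic model
#'
#' The model works in the grand-canonical picture: a ligand at molar
#' concentration \eqn{c} has chemical potential \eqn{\mu = kT \ln(c / 1\,M)}.
#' `kT` is the thermal energy in kcal/mol; the default 0.6 kcal/mol
#' corresponds to roughly 302 K, the incubation temperature of the yeast
#' reporter strains the model was developed for.
#'
#' @param kT Thermal energy in kcal/mol. Must be positive.
#' @return An object of class `model_constants`.
#' @examples
#' const <- model_constants()
#' const$kT
#' @export
model_constants <- function(kT = 0.6) {
  if (!is.numeric(kT) || length(kT) != 1L || !is.finite(kT) || kT <= 0) {
    stop("`kT` must be a single positive finite number (kcal/mol)")
  }
  structure(list(kT = kT, concentration_unit = "M"),
            class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Model constants: kT =", x$kT, "kcal/mol; concentrations in",
      x$concentration_unit, "\n")
  invisible(x)
}

#' Chemical potential of a molar concentration
#'
#' \eqn{\mu = kT \ln(c/1\,M)}. A zero concentration maps to `-Inf`, the
#' sentinel used throughout the package for an absent ligand.
#'
#' @param conc Molar concentration(s), `>= 0`.
#' @param const A [model_constants()] object.
#' @return Chemical potential(s) in kcal/mol.
#' @export
mu_from_conc <- function(conc, const = model_constants()) {
  stopifnot(all(conc >= 0))
  ifelse(conc > 0, const$kT * log(conc), -Inf)
}

#' Molar concentration at a chemical potential
#'
#' Inverse of [mu_from_conc()]; `-Inf` maps back to zero concentration.
#'
#' @param mu Chemical potential(s) in kcal/mol.
#' @inheritParams mu_from_conc
#' @return Molar concentration(s).
#' @export
conc_from_mu <- function(mu, const = model_constants()) {
  exp(mu / const$kT)
}
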