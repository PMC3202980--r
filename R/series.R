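#' Dilution series as a ladder of chemical-potential offsets
#'
#' A dilution series is a sequence of measurements at total chemical
#' potentials \eqn{\mu_m = \mu_0 + \sum_{k<m} \Delta\mu_k}. The increments
#' `delta_mu` between consecutive points are known exactly (the
#' experimenter controls the dilution factors); the potential `mu0` at the
#' reference point is known for calibration samples and synthetic data but
#' is an inferred parameter when an unknown mixture is decoded — so that a
#' single scalar reconstructs the whole ladder.
#'
#' @param delta_mu Numeric vector of known chemical-potential increments
#'   (kcal/mol) between consecutive points; length `n_points - 1`.
#' @param mu0 Chemical potential at the reference (first) point, kcal/mol,
#'   or `NA` when it is to be inferred.
#' @return An object of class `dilution_series`.
#' @seealso [series_from_concentrations()], [series_mu()]
#' @export
dilution_series <- function(delta_mu, mu0 = NA_real_) {
  delta_mu <- as.numeric(delta_mu)
  if (any(!is.finite(delta_mu))) stop("`delta_mu` must be finite")
  if (!is.na(mu0) && !is.finite(mu0)) stop("`mu0` must be finite or NA")
  structure(list(n_points = length(delta_mu) + 1L,
                 delta_mu = delta_mu, mu0 = as.numeric(mu0)),
            class = "dilution_series")
}

#' Build a dilution series from known total concentrations
#'
#' @param conc Vector of total molar concentrations, reference point
#'   first. Must be positive.
#' @param const A [model_constants()] object.
#' @return A [dilution_series()] with `mu0` set from the first point.
#' @export
series_from_concentrations <- function(conc, const = model_constants()) {
  stopifnot(all(conc > 0))
  mu <- mu_from_conc(conc, const)
  dilution_series(diff(mu), mu0 = mu[[1L]])
}

#' Default log-spaced dilution ladder
#'
#' Nine total concentrations log-spaced over a million-fold range,
#' `1e-3` M (the reference point) down to `1e-9` M.
#'
#' @param n_points Number of points.
#' @param c_max,c_min Molar concentration range; `c_max` is the reference.
#' @inheritParams series_from_concentrations
#' @return A [dilution_series()].
#' @export
default_series <- function(n_points = 9L, c_max = 1e-3, c_min = 1e-9,
                           const = model_constants()) {
  stopifnot(n_points >= 2L, c_max > c_min, c_min > 0)
  conc <- 10^seq(log10(c_max), log10(c_min), length.out = n_points)
  series_from_concentrations(conc, const)
}

#' Reconstruct total chemical potentials along a series
#'
#' @param series A [dilution_series()].
#' @param mu0 Override for the reference potential (required when the
#'   series stores `NA`).
#' @return Numeric vector of length `n_points`.
#' @export
series_mu <- function(series, mu0 = series$mu0) {
  if (is.na(mu0)) stop("`mu0` is unknown for this series; supply it")
  mu0 + c(0, cumsum(series$delta_mu))
}
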