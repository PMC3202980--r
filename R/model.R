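#' Reporter intensity for one receptor bound by one ligand
#'
#' Grand-canonical two-state occupancy: the receptor is bound with
#' probability \eqn{p = w/(1+w)}, \eqn{w = e^{(\mu - \Delta G)/kT}}, and
#' the normalized reporter intensity is \eqn{I = bg + e\,p} with efficacy
#' \eqn{e}. At \eqn{\mu = \Delta G} the receptor is half occupied.
#'
#' @param dG Binding free energy, kcal/mol (favorable binding `< 0`).
#' @param eff Efficacy in \[0, 1\].
#' @param bg Background intensity, `>= 0`.
#' @param mu Ligand chemical potential, kcal/mol (`-Inf` = ligand absent).
#' @param const A [model_constants()] object.
#' @return Normalized intensity in `[bg, bg + eff]`. Vectorized over `mu`.
#' @examples
#' single_ligand_intensity(-6, 1, 0, mu = -6)   # half occupancy: 0.5
#' @export
single_ligand_intensity <- function(dG, eff, bg, mu,
                                    const = model_constants()) {
  if (!all(is.finite(c(dG, eff, bg))) || any(is.nan(mu))) {
    stop("non-finite model parameters")
  }
  if (any(eff < 0 | eff > 1)) stop("`eff` must lie in [0, 1]")
  w <- exp((mu - dG) / const$kT)
  p <- w / (1 + w)
  p[mu == -Inf] <- 0
  p[w == Inf] <- 1
  bg + eff * p
}

#' Competitive-binding occupancies of one receptor in a mixture
#'
#' With several ligands competing for the same binding site the
#' probability that the receptor is occupied by ligand \eqn{i} is
#' \eqn{p_i = w_i/Z} with \eqn{w_i = e^{(\mu_i - \Delta G_i)/kT}} and
#' partition function \eqn{Z = 1 + \sum_i w_i}; the unbound probability is
#' \eqn{1/Z}. Absent ligands are encoded by `mu = -Inf` and contribute
#' zero occupancy.
#'
#' @param dG_row Binding free energies of this receptor for each ligand,
#'   kcal/mol.
#' @param mu Per-ligand chemical potentials, kcal/mol (`-Inf` allowed).
#' @inheritParams single_ligand_intensity
#' @return A list with `p` (per-ligand occupancies) and `unbound`.
#' @export
mixture_occupancies <- function(dG_row, mu, const = model_constants()) {
  if (length(dG_row) != length(mu)) {
    stop("`dG_row` and `mu` must have the same length")
  }
  w <- exp((mu - dG_row) / const$kT)
  w[mu == -Inf] <- 0
  Z <- 1 + sum(w)
  list(p = w / Z, unbound = 1 / Z)
}

#' Reporter intensity of one receptor exposed to a ligand mixture
#'
#' Sum of fractional occupancies weighted by the corresponding
#' efficacies: \eqn{I_j = bg_j + \sum_i e_{ji} p_{ji}}. With exactly one
#' ligand present this reduces bit-exactly to
#' [single_ligand_intensity()].
#'
#' @param params An [array_params()] object.
#' @param receptor_id Receptor label.
#' @param mu Per-ligand chemical potentials (ordered as
#'   `params$ligand_ids`), kcal/mol.
#' @inheritParams single_ligand_intensity
#' @return Normalized intensity.
#' @export
mixture_intensity <- function(params, receptor_id, mu,
                              const = model_constants()) {
  if (!receptor_id %in% params$receptor_ids) {
    stop("unknown receptor id: ", receptor_id)
  }
  occ <- mixture_occupancies(params$dG[receptor_id, ], mu, const)
  unname(params$bg[[receptor_id]] + sum(params$eff[receptor_id, ] * occ$p))
}

#' Per-ligand chemical potentials of a mixture
#'
#' Splits the total chemical potential \eqn{\mu_{tot}} among the ligands
#' according to the relative concentrations:
#' \eqn{\mu_i = \mu_{tot} + kT \ln(x_i / \sum_k x_k)}. Ligands with
#' \eqn{x_i = 0} map to the `-Inf` sentinel. Exponentiating and summing
#' the implied per-ligand concentrations recovers the total concentration
#' \eqn{e^{\mu_{tot}/kT}}.
#'
#' @param comp A [mixture_composition()].
#' @param mu_total Total chemical potential, kcal/mol.
#' @inheritParams single_ligand_intensity
#' @return Named vector of per-ligand chemical potentials.
#' @export
chemical_potentials <- function(comp, mu_total, const = model_constants()) {
  stopifnot(inherits(comp, "mixture_composition"), is.finite(mu_total))
  x <- comp$x
  if (sum(x) == 0) stop("all relative concentrations are zero")
  mu <- mu_total + const$kT * log(x / sum(x))
  mu[x == 0] <- -Inf
  mu
}

#' Absolute molar concentrations at the series reference point
#'
#' \eqn{c_i = e^{\mu_0/kT}\, x_i / \sum_k x_k}; the concentrations sum to
#' the total \eqn{e^{\mu_0/kT}}. This is the final readout of mixture
#' decoding: relative concentrations plus one inferred total potential
#' give the absolute concentration of every component.
#'
#' @param comp A [mixture_composition()].
#' @param mu0 Total chemical potential at the reference point, kcal/mol.
#' @inheritParams single_ligand_intensity
#' @return Named vector of molar concentrations.
#' @export
absolute_concentrations <- function(comp, mu0, const = model_constants()) {
  stopifnot(inherits(comp, "mixture_composition"), is.finite(mu0))
  x <- comp$x
  if (sum(x) == 0) stop("all relative concentrations are zero")
  exp(mu0 / const$kT) * x / sum(x)
}

#' Model intensities of one receptor along a dilution series
#'
#' Convenience wrapper evaluating [mixture_intensity()] at every point of
#' a series for a fixed composition; used by the generators, the
#' likelihoods and the Hessian engine.
#'
#' @param params An [array_params()] object.
#' @param receptor_id Receptor label.
#' @param comp A [mixture_composition()].
#' @param series A [dilution_series()].
#' @param mu0 Reference-point total chemical potential (defaults to the
#'   series' own).
#' @inheritParams single_ligand_intensity
#' @return Numeric vector of length `series$n_points`.
#' @export
series_intensity <- function(params, receptor_id, comp, series,
                             mu0 = series$mu0, const = model_constants()) {
  mu_tot <- series_mu(series, mu0)
  vapply(mu_tot, function(m) {
    mixture_intensity(params, receptor_id, chemical_potentials(comp, m, const),
                      const)
  }, numeric(1))
}
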