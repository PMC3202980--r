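#' Gaussian log-likelihood of a single receptor-ligand dilution curve
#'
#' Measurements are modelled as Gaussian around the single-ligand response
#' curve: \eqn{\sum_m [-(F_m - I(\mu_m;\theta))^2/(2\sigma^2) -
#' \ln(\sigma\sqrt{2\pi})]} over all points and replicates. The series'
#' potentials are reconstructed from `mu0` plus the known increments, so
#' an unknown absolute concentration scale enters through the single
#' parameter `mu0`.
#'
#' @param curve A [response_dataset()] restricted to one receptor and one
#'   single-ligand mixture.
#' @param theta Named vector/list with `dG`, `eff`, `bg`, `sigma` and
#'   optionally `mu0` (defaults to the series' own reference potential).
#' @param const A [model_constants()] object.
#' @return Log-likelihood (scalar).
#' @export
log_likelihood_single <- function(curve, theta, const = model_constants()) {
  stopifnot(inherits(curve, "response_dataset"))
  rec <- curve$records
  if (nrow(rec) == 0L) stop("empty dataset")
  r <- unique(rec$receptor)
  if (length(r) != 1L || length(unique(rec$mixture_id)) != 1L) {
    stop("`curve` must contain exactly one receptor and one mixture id")
  }
  theta <- as.list(theta)
  if (theta$sigma <= 0) stop("`sigma` must be > 0")
  mu0 <- if (!is.null(theta$mu0) && !is.na(theta$mu0)) theta$mu0
         else curve$series[[r]]$mu0
  mu <- series_mu(curve$series[[r]], mu0)
  I_model <- single_ligand_intensity(theta$dG, theta$eff, theta$bg,
                                     mu[rec$point_index], const)
  resid <- rec$intensity - I_model
  -sum(resid^2) / (2 * theta$sigma^2) -
    nrow(rec) * log(theta$sigma * sqrt(2 * pi))
}

#' Gaussian log-likelihood of the full array's response to a mixture
#'
#' Joint likelihood over every receptor in `data`: each receptor's
#' mixture response (competitive-binding model with the receptor's
#' calibrated \eqn{\Delta G}, efficacies and background) is evaluated
#' along its own dilution ladder at the potentials implied by the
#' composition, and compared with the measured intensities under
#' per-receptor Gaussian noise. Restricting `data` to a receptor subset
#' yields the subset-decoding analyses.
#'
#' @param data A [response_dataset()] (any receptor subset of `params`).
#' @param params Calibrated [array_params()].
#' @param comp_theta List with `x` (named full vector of relative
#'   concentrations, reference entry 1), `mu0` (reference-point total
#'   chemical potential, kcal/mol) and `sigma` (named per-receptor noise
#'   scales; defaults to `params$sigma`).
#' @inheritParams log_likelihood_single
#' @return Log-likelihood (scalar).
#' @export
log_likelihood_array <- function(data, params, comp_theta,
                                 const = model_constants()) {
  stopifnot(inherits(data, "response_dataset"),
            inherits(params, "array_params"))
  receptors <- unique(data$records$receptor)
  if (length(receptors) == 0L) stop("empty dataset")
  missing_r <- setdiff(receptors, params$receptor_ids)
  if (length(missing_r) > 0L) {
    stop("receptor(s) in data missing from params: ",
         paste(missing_r, collapse = ", "))
  }
  x <- comp_theta$x[params$ligand_ids]
  if (any(is.na(x))) stop("`comp_theta$x` must cover every ligand in params")
  sigma <- comp_theta$sigma
  if (is.null(sigma)) sigma <- params$sigma
  kT <- const$kT
  s_norm <- x / sum(x)
  total <- 0
  for (r in receptors) {
    rec <- data$records[data$records$receptor == r, ]
    off <- c(0, cumsum(data$series[[r]]$delta_mu))
    mu_tot <- comp_theta$mu0 + off
    # w[m, i] = exp((mu_tot_m + kT ln s_i - dG_ri)/kT): outer product form
    wi <- s_norm * exp(-params$dG[r, ] / kT)
    w <- exp(mu_tot / kT) %o% wi
    Z <- 1 + rowSums(w)
    I_model <- params$bg[[r]] + as.numeric(w %*% params$eff[r, ]) / Z
    resid <- rec$intensity - I_model[rec$point_index]
    sr <- if (!is.null(names(sigma))) sigma[[r]] else sigma[[match(r, receptors)]]
    if (sr <= 0) stop("sigma must be > 0")
    total <- total - sum(resid^2) / (2 * sr^2) -
      nrow(rec) * log(sr * sqrt(2 * pi))
  }
  total
}

#' Build a fast log-likelihood closure over a single-ligand curve
#'
#' Precomputes the record layout and returns a function of
#' `theta = (dG, eff, bg, sigma)` suitable for [nested_sampling()].
#' `mu0` is fixed: calibration treats total concentrations as exactly
#' known.
#'
#' @param curve A [response_dataset()] with one receptor and one
#'   single-ligand mixture.
#' @param const A [model_constants()] object.
#' @param mu0 Reference potential override (defaults to the series').
#' @return A function `numeric(4) -> log-likelihood`.
#' @export
make_single_loglik <- function(curve, const = model_constants(),
                               mu0 = NULL) {
  rec <- curve$records
  r <- unique(rec$receptor)
  stopifnot(length(r) == 1L)
  if (is.null(mu0)) mu0 <- curve$series[[r]]$mu0
  mu <- series_mu(curve$series[[r]], mu0)[rec$point_index]
  F_obs <- rec$intensity
  M <- length(F_obs)
  kT <- const$kT
  function(theta) {
    w <- exp((mu - theta[1L]) / kT)
    I_model <- theta[3L] + theta[2L] * w / (1 + w)
    -sum((F_obs - I_model)^2) / (2 * theta[4L]^2) -
      M * log(theta[4L] * sqrt(2 * pi))
  }
}

#' Build a fast log-likelihood closure over a mixture dataset
#'
#' Precomputes per-receptor Boltzmann factors, ladder factors and record
#' maps, returning a function of
#' `theta = (x_{i != ref}, mu0, sigma_r ...)` in the order of
#' [decode_priors()]; this is the likelihood [decode_mixture()] samples.
#'
#' @param data A [response_dataset()] of mixture curves.
#' @param params Calibrated [array_params()].
#' @param reference_ligand Ligand whose ratio is pinned at 1.
#' @param const A [model_constants()] object.
#' @return A function `numeric(d) -> log-likelihood`.
#' @export
make_array_loglik <- function(data, params, reference_ligand,
                              const = model_constants()) {
  receptors <- unique(data$records$receptor)
  ligands <- params$ligand_ids
  free_lig <- setdiff(ligands, reference_ligand)
  ref_pos <- match(reference_ligand, ligands)
  free_pos <- match(free_lig, ligands)
  kT <- const$kT
  pre <- lapply(receptors, function(r) {
    rec <- data$records[data$records$receptor == r, ]
    off <- c(0, cumsum(data$series[[r]]$delta_mu))
    list(F_obs = rec$intensity, idx = rec$point_index,
         t = exp(off / kT), A = exp(-params$dG[r, ] / kT),
         e = params$eff[r, ], bg = params$bg[[r]], M = nrow(rec))
  })
  nfree <- length(free_pos)
  nr <- length(receptors)
  function(theta) {
    x <- numeric(length(ligands))
    x[ref_pos] <- 1
    if (nfree > 0L) x[free_pos] <- theta[seq_len(nfree)]
    mu0 <- theta[nfree + 1L]
    sig <- theta[nfree + 1L + seq_len(nr)]
    s_norm <- x / sum(x)
    c0 <- exp(mu0 / kT)
    total <- 0
    for (k in seq_len(nr)) {
      p <- pre[[k]]
      w <- (c0 * p$t) %o% (s_norm * p$A)
      Z <- 1 + rowSums(w)
      I_model <- p$bg + as.numeric(w %*% p$e) / Z
      resid <- p$F_obs - I_model[p$idx]
      total <- total - sum(resid^2) / (2 * sig[k]^2) -
        p$M * log(sig[k] * sqrt(2 * pi))
    }
    total
  }
}
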