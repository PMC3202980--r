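#' Calibrate one receptor-ligand pair from a single-ligand dilution curve
#'
#' Infers the posterior over `(dG, eff, bg, sigma)` by nested sampling of
#' the single-curve Gaussian likelihood. Calibration samples are prepared
#' by the experimenter, so total concentrations — and hence the
#' reference-point chemical potential — are treated as exactly known;
#' only mixture decoding infers the concentration scale.
#'
#' @param curve A [response_dataset()] with one receptor, one
#'   single-ligand mixture, and a series with known `mu0`. At least 3
#'   distinct concentrations are required.
#' @param priors A [prior_set()] over `(dG, eff, bg, sigma)`.
#' @param settings A [sampler_settings()].
#' @param const A [model_constants()] object.
#' @return A `calibration_fit`: the `posterior_summary`, point
#'   `estimates` (posterior means), the receptor/ligand labels and a
#'   provenance note.
#' @export
fit_single_ligand <- function(curve, priors = calibration_priors(),
                              settings = sampler_settings(),
                              const = model_constants()) {
  stopifnot(inherits(curve, "response_dataset"))
  rec <- curve$records
  r <- unique(rec$receptor)
  lig <- unique(rec$mixture_id)
  stopifnot(length(r) == 1L, length(lig) == 1L)
  if (length(unique(rec$point_index)) < 3L) {
    stop("need at least 3 distinct concentrations to calibrate a curve")
  }
  if (is.na(curve$series[[r]]$mu0)) {
    stop("calibration requires a series with known `mu0`")
  }
  ll <- make_single_loglik(curve, const)
  post <- nested_sampling(ll, priors, settings)
  structure(list(receptor = r, ligand = lig,
                 posterior = post,
                 estimates = post$mean,
                 provenance = "single-ligand"),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat("Calibration fit:", x$receptor, "x", x$ligand,
      "(", x$provenance, ")\n")
  print(signif(data.frame(mean = x$posterior$mean, sd = x$posterior$sd), 4))
  invisible(x)
}

#' Calibrate an antagonist from a binary mixture with a known agonist
#'
#' A full antagonist produces no signal of its own, so its single-ligand
#' curve is flat and its binding free energy is unidentifiable. Mixing it
#' at a known composition with a calibrated agonist makes it visible
#' through the suppression of the agonist signal (competitive
#' displacement), from which `(dG, eff)` of the antagonist are inferred.
#' Compound concentrations are fixed to their exact known values; the
#' agonist's parameters are held at their calibrated values. When several
#' candidate agonist partners are supplied, the partner yielding the
#' smallest posterior standard deviation of the antagonist's binding free
#' energy is selected.
#'
#' @param binary_curves A single [response_dataset()] (one receptor, one
#'   binary mixture) or a list of them, one per candidate agonist
#'   partner.
#' @param agonist_params A named list `(dG, eff)` for the agonist, or a
#'   list of such lists matching `binary_curves`.
#' @param compositions A [mixture_composition()] (antagonist and agonist
#'   entries, known exactly) or a list of them matching `binary_curves`.
#' @param antagonist Ligand label of the antagonist.
#' @param bg Known background intensity of the receptor (from its
#'   calibration average).
#' @param priors A [prior_set()] over `(dG, eff, sigma)` of the
#'   antagonist; defaults to the calibration bounds.
#' @param settings A [sampler_settings()].
#' @param const A [model_constants()] object.
#' @return A `calibration_fit` for the antagonist, with `partner` set to
#'   the selected agonist and `candidate_sds` reporting std(dG) per
#'   candidate.
#' @export
fit_antagonist_in_mixture <- function(binary_curves, agonist_params,
                                      compositions, antagonist, bg,
                                      priors = NULL,
                                      settings = sampler_settings(),
                                      const = model_constants()) {
  if (inherits(binary_curves, "response_dataset")) {
    binary_curves <- list(binary_curves)
    agonist_params <- list(agonist_params)
    compositions <- list(compositions)
  }
  stopifnot(length(binary_curves) == length(agonist_params),
            length(binary_curves) == length(compositions))
  if (is.null(priors)) {
    priors <- prior_set(
      prior_spec("dG", "uniform", -16, -1),
      prior_spec("eff", "uniform", 0, 1),
      prior_spec("sigma", "jeffreys", 5e-3, 0.5))
  }
  fits <- vector("list", length(binary_curves))
  for (k in seq_along(binary_curves)) {
    curve <- binary_curves[[k]]
    ag <- agonist_params[[k]]
    comp <- compositions[[k]]
    if (is.null(ag$dG) || is.null(ag$eff)) stop("agonist parameters missing")
    stopifnot(inherits(comp, "mixture_composition"))
    rec <- curve$records
    r <- unique(rec$receptor)
    stopifnot(length(r) == 1L)
    s <- curve$series[[r]]
    if (is.na(s$mu0)) stop("composition/concentrations must be fixed (known mu0)")
    other <- setdiff(comp$ligand_ids, antagonist)
    stopifnot(length(other) == 1L)
    mu_tot <- series_mu(s)[rec$point_index]
    x <- comp$x
    s_norm <- x / sum(x)
    kT <- const$kT
    # fixed pieces of the two-ligand partition function
    c_ant <- exp(mu_tot / kT) * s_norm[[antagonist]]
    w_ag <- exp((mu_tot + kT * log(s_norm[[other]]) - ag$dG) / kT)
    F_obs <- rec$intensity
    M <- length(F_obs)
    ll <- function(theta) {
      w_ant <- c_ant * exp(-theta[1L] / kT)
      Z <- 1 + w_ag + w_ant
      I_model <- bg + (ag$eff * w_ag + theta[2L] * w_ant) / Z
      -sum((F_obs - I_model)^2) / (2 * theta[3L]^2) -
        M * log(theta[3L] * sqrt(2 * pi))
    }
    post <- nested_sampling(ll, priors,
                            settings_with_seed(settings,
                                               settings$seed + k - 1L))
    fits[[k]] <- structure(
      list(receptor = r, ligand = antagonist, posterior = post,
           estimates = post$mean, provenance = "antagonist-in-mixture",
           partner = other),
      class = "calibration_fit")
  }
  sds <- vapply(fits, function(f) f$posterior$sd[["dG"]], numeric(1))
  best <- fits[[which.min(sds)]]
  best$candidate_sds <- stats::setNames(
    sds, vapply(fits, `[[`, character(1), "partner"))
  best
}

#' Per-plate bias refit of efficacy and background
#'
#' Plate-normalized assays show small systematic deviations between
#' plates ("plate bias"). Holding each curve's binding free energy (and
#' hence its occupancy profile) fixed at the calibrated value, the model
#' intensity on a plate is linear in a per-plate multiplicative efficacy
#' scale and additive background shift, so the Gaussian-likelihood
#' maximum is the ordinary least-squares solution, computed per (plate,
#' receptor) from all that receptor's curves on the plate.
#'
#' @param data A [response_dataset()] spanning at least two plates, with
#'   single-ligand curves (one `mixture_id` per ligand) and known series.
#' @param params Calibrated [array_params()] providing fixed `dG`,
#'   calibrated `eff`, `bg`.
#' @param const A [model_constants()] object.
#' @return A data.frame with columns `plate`, `receptor`, `eff_scale`,
#'   `bg_shift`.
#' @export
fit_plate_bias <- function(data, params, const = model_constants()) {
  rec <- data$records
  plates <- unique(rec$plate)
  if (length(plates) < 2L) {
    stop("plate-bias refitting needs at least two plates to contrast")
  }
  out <- list()
  for (pl in plates) {
    for (r in intersect(unique(rec$receptor), params$receptor_ids)) {
      sub <- rec[rec$plate == pl & rec$receptor == r, ]
      if (nrow(sub) == 0L) next
      s <- data$series[[r]]
      mu <- series_mu(s)[sub$point_index]
      # calibrated occupancy signal eff * p per record (ligand = mixture_id)
      signal <- vapply(seq_len(nrow(sub)), function(i) {
        lig <- sub$mixture_id[[i]]
        w <- exp((mu[[i]] - params$dG[r, lig]) / const$kT)
        params$eff[r, lig] * w / (1 + w)
      }, numeric(1))
      fit <- stats::lm(sub$intensity ~ signal)
      out[[length(out) + 1L]] <- data.frame(
        plate = pl, receptor = r,
        eff_scale = unname(stats::coef(fit)[[2L]]),
        bg_shift = unname(stats::coef(fit)[[1L]]) - params$bg[[r]])
    }
  }
  do.call(rbind, out)
}

#' Calibrate a whole array from a set of single-ligand curves
#'
#' Convenience driver: runs [fit_single_ligand()] for every
#' (receptor, ligand) pair present in the data and assembles the point
#' estimates (posterior means) into an [array_params()] object. Each
#' receptor's background and noise are averaged over its ligand curves,
#' mirroring how per-receptor backgrounds are consolidated from all
#' calibration experiments involving that receptor.
#'
#' @param data A [response_dataset()] whose `mixture_id`s are ligand
#'   labels (one single-ligand curve per receptor-ligand pair).
#' @param priors,settings,const As in [fit_single_ligand()].
#' @return A list with `params` ([array_params()]), `fits` (the
#'   individual `calibration_fit`s) and `sd` (matrices/vectors of
#'   posterior standard deviations).
#' @export
calibrate_array <- function(data, priors = calibration_priors(),
                            settings = sampler_settings(),
                            const = model_constants()) {
  rec <- data$records
  receptors <- unique(rec$receptor)
  ligands <- unique(rec$mixture_id)
  dG <- eff <- sd_dG <- sd_eff <- matrix(
    NA_real_, length(receptors), length(ligands),
    dimnames = list(receptors, ligands))
  bg_acc <- sigma_acc <- stats::setNames(
    rep(0, length(receptors)), receptors)
  counts <- stats::setNames(rep(0L, length(receptors)), receptors)
  fits <- list()
  k <- 0L
  for (r in receptors) {
    for (lig in ligands) {
      k <- k + 1L
      curve <- subset_dataset(data, receptors = r, mixtures = lig)
      fit <- fit_single_ligand(curve, priors,
                               settings_with_seed(settings,
                                                  settings$seed + k),
                               const = const)
      fits[[paste(r, lig, sep = ":")]] <- fit
      dG[r, lig] <- fit$estimates[["dG"]]
      eff[r, lig] <- fit$estimates[["eff"]]
      sd_dG[r, lig] <- fit$posterior$sd[["dG"]]
      sd_eff[r, lig] <- fit$posterior$sd[["eff"]]
      bg_acc[[r]] <- bg_acc[[r]] + fit$estimates[["bg"]]
      sigma_acc[[r]] <- sigma_acc[[r]] + fit$estimates[["sigma"]]
      counts[[r]] <- counts[[r]] + 1L
    }
  }
  params <- array_params(receptors, ligands, dG, pmin(pmax(eff, 0), 1),
                         bg = bg_acc / counts, sigma = sigma_acc / counts)
  list(params = params, fits = fits,
       sd = list(dG = sd_dG, eff = sd_eff))
}
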