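# Derive an independent RNG stream key for (seed, receptor, plate) so
# that subsetting receptors or plates never changes other blocks' draws.
# Keyed by receptor *name*, not position, so a receptor keeps its stream
# when the array is subset.
.block_seed <- function(seed, receptor_id, plate) {
  chars <- utf8ToInt(as.character(receptor_id))
  key <- sum(chars * seq_along(chars)) %% 65521
  (as.numeric(seed) * 1009 + key * 10007 +
     as.numeric(plate) * 101) %% 2147483647
}

#' Generate a synthetic mixture-response dataset
#'
#' Evaluates the competitive-binding mixture response of every receptor
#' along its dilution ladder and adds iid Gaussian noise of the
#' receptor's `sigma`. Optional per-plate bias rescales efficacies
#' (multiplicative) and shifts backgrounds (additive), mimicking the
#' systematic plate-to-plate deviations of normalized plate-reader data.
#' Noise is drawn from one RNG stream per (seed, receptor, plate), so
#' generating a receptor subset reproduces exactly the records the full
#' generation would have produced for those receptors.
#'
#' @param params True [array_params()] used as generating truth.
#' @param comp A [mixture_composition()].
#' @param mu0 True total chemical potential at the reference point
#'   (kcal/mol).
#' @param series A single [dilution_series()] shared by all receptors, or
#'   a named per-receptor list.
#' @param replicates Number of replicates (`>= 1`).
#' @param seed Integer seed.
#' @param plates Plate id per replicate (default: all on plate 1).
#' @param plate_bias Optional named list keyed by plate id, each entry a
#'   list with `eff_scale` and `bg_shift`.
#' @param mixture_id Label stored in the records.
#' @param const A [model_constants()] object.
#' @return A [response_dataset()] with `log10_total_conc` filled in.
#' @export
generate_mixture_dataset <- function(params, comp, mu0, series,
                                     replicates = 4L, seed = 1L,
                                     plates = NULL, plate_bias = NULL,
                                     mixture_id = "mixture",
                                     const = model_constants()) {
  stopifnot(inherits(params, "array_params"),
            inherits(comp, "mixture_composition"), replicates >= 1L)
  if (inherits(series, "dilution_series")) {
    series <- stats::setNames(rep(list(series), length(params$receptor_ids)),
                              params$receptor_ids)
  }
  if (is.null(plates)) plates <- rep(1L, replicates)
  stopifnot(length(plates) == replicates)
  recs <- list()
  for (ri in seq_along(params$receptor_ids)) {
    r <- params$receptor_ids[[ri]]
    s <- series[[r]]
    mu_tot <- series_mu(s, mu0)
    clean <- vapply(mu_tot, function(m) {
      mixture_intensity(params, r, chemical_potentials(comp, m, const), const)
    }, numeric(1))
    occ_signal <- clean - params$bg[[r]]
    for (pl in unique(plates)) {
      reps_here <- which(plates == pl)
      bias <- if (!is.null(plate_bias) && !is.null(plate_bias[[as.character(pl)]])) {
        plate_bias[[as.character(pl)]]
      } else list(eff_scale = 1, bg_shift = 0)
      mean_I <- (params$bg[[r]] + bias$bg_shift) + bias$eff_scale * occ_signal
      set.seed(.block_seed(seed, r, pl))
      noise <- matrix(stats::rnorm(s$n_points * length(reps_here),
                                   sd = params$sigma[[r]]),
                      s$n_points, length(reps_here))
      for (j in seq_along(reps_here)) {
        recs[[length(recs) + 1L]] <- data.frame(
          receptor = r, mixture_id = mixture_id,
          point_index = seq_len(s$n_points),
          replicate = reps_here[[j]], plate = pl,
          log10_total_conc = (mu0 + c(0, cumsum(s$delta_mu))) /
            (const$kT * log(10)),
          intensity = mean_I + noise[, j])
      }
    }
  }
  records <- do.call(rbind, recs)
  records <- records[order(records$receptor, records$replicate,
                           records$point_index), ]
  rownames(records) <- NULL
  response_dataset(records, series)
}

#' Generate a synthetic single-ligand calibration curve
#'
#' Single-receptor, single-ligand special case of
#' [generate_mixture_dataset()]: intensities follow the two-state
#' occupancy response plus iid Gaussian noise.
#'
#' @param dG,eff,bg,sigma True curve parameters.
#' @param series A [dilution_series()] with known `mu0`.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @param receptor_id,ligand_id Labels for the emitted records.
#' @inheritParams generate_mixture_dataset
#' @return A [response_dataset()] with `n_points * replicates` records.
#' @export
generate_calibration_curve <- function(dG, eff, bg, sigma, series,
                                       replicates = 4L, seed = 1L,
                                       receptor_id = "R1",
                                       ligand_id = "L1",
                                       const = model_constants()) {
  if (sigma < 0) stop("`sigma` must be >= 0")
  params <- array_params(receptor_id, ligand_id,
                         matrix(dG, 1, 1), matrix(eff, 1, 1),
                         bg = bg, sigma = max(sigma, .Machine$double.xmin))
  comp <- mixture_composition(ligand_id, 1, ligand_id)
  ds <- generate_mixture_dataset(params, comp, mu0 = series$mu0,
                                 series = series, replicates = replicates,
                                 seed = seed, mixture_id = ligand_id,
                                 const = const)
  if (sigma == 0) {
    # regenerate deterministically without noise
    mu <- series_mu(series)
    clean <- single_ligand_intensity(dG, eff, bg, mu, const)
    ds$records$intensity <- clean[ds$records$point_index]
  }
  ds
}

#' All equal-proportion mixtures of a ligand panel
#'
#' Enumerates every non-empty subset of the panel as an equal-proportion
#' mixture (singles included): \eqn{2^L - 1} compositions for `L`
#' ligands.
#'
#' @param ligand_panel Character vector of ligand labels.
#' @param total_concentration Optional total molar concentration attached
#'   to each composition.
#' @return A list of [mixture_composition()] objects.
#' @export
enumerate_equal_mixtures <- function(ligand_panel,
                                     total_concentration = NULL) {
  stopifnot(length(ligand_panel) >= 1L)
  out <- list()
  for (k in seq_along(ligand_panel)) {
    subsets <- utils::combn(ligand_panel, k, simplify = FALSE)
    for (s in subsets) {
      out[[length(out) + 1L]] <-
        equal_mixture(ligand_panel, s, total_concentration)
    }
  }
  out
}

#' Calibration accuracy versus concentration range
#'
#' Repeatedly generates single-ligand calibration curves whose maximum
#' total concentration grows across a grid (minimum fixed), fits each by
#' nested sampling, and reports the mean posterior standard deviation of
#' the binding free energy per range. Wider ranges capture more of the
#' binding curve and tighten the estimate.
#'
#' @param truth Named list with `dG`, `eff`, `bg`, `sigma`.
#' @param c_max_grid Increasing grid of maximum total concentrations (M).
#' @param c_min Fixed minimum concentration (M).
#' @param n_points Points per series.
#' @param replicates Replicates per series.
#' @param n_runs Seeded repeats per grid value (`>= 2`).
#' @param seed Base seed; run `j` of grid value `g` uses a derived seed.
#' @param priors A [prior_set()] over `(dG, eff, bg, sigma)`.
#' @param settings A [sampler_settings()].
#' @param const A [model_constants()] object.
#' @return A data.frame with columns `c_max` and `mean_sd_dG`.
#' @export
range_scan <- function(truth, c_max_grid, c_min = 1e-9, n_points = 9L,
                       replicates = 4L, n_runs = 3L, seed = 1L,
                       priors = calibration_priors(),
                       settings = sampler_settings(),
                       const = model_constants()) {
  if (n_runs < 2L) stop("`n_runs` must be >= 2")
  stopifnot(!is.unsorted(c_max_grid), all(c_max_grid > c_min))
  rows <- lapply(seq_along(c_max_grid), function(g) {
    sds <- vapply(seq_len(n_runs), function(j) {
      s <- default_series(n_points, c_max = c_max_grid[[g]], c_min = c_min,
                          const = const)
      run_seed <- (seed * 7919 + g * 613 + j) %% 2147483647
      curve <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                          truth$sigma, s, replicates,
                                          seed = run_seed, const = const)
      fit <- fit_single_ligand(curve, priors,
                               settings_with_seed(settings, run_seed),
                               const = const)
      fit$posterior$sd[["dG"]]
    }, numeric(1))
    data.frame(c_max = c_max_grid[[g]], mean_sd_dG = mean(sds))
  })
  do.call(rbind, rows)
}

#' Calibration accuracy versus noise level
#'
#' Mirror of [range_scan()] with the series fixed and the generating
#' noise `sigma` varied across a grid; reports the mean posterior
#' standard deviation of the binding free energy per noise level.
#'
#' @param truth Named list with `dG`, `eff`, `bg` (its `sigma` is ignored).
#' @param sigma_grid Increasing grid of noise scales.
#' @param series Fixed [dilution_series()].
#' @inheritParams range_scan
#' @return A data.frame with columns `sigma` and `mean_sd_dG`.
#' @export
noise_scan <- function(truth, sigma_grid, series = default_series(),
                       replicates = 4L, n_runs = 3L, seed = 1L,
                       priors = calibration_priors(),
                       settings = sampler_settings(),
                       const = model_constants()) {
  if (n_runs < 2L) stop("`n_runs` must be >= 2")
  stopifnot(!is.unsorted(sigma_grid), all(sigma_grid > 0))
  rows <- lapply(seq_along(sigma_grid), function(g) {
    sds <- vapply(seq_len(n_runs), function(j) {
      run_seed <- (seed * 6007 + g * 769 + j) %% 2147483647
      curve <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                          sigma_grid[[g]], series,
                                          replicates, seed = run_seed,
                                          const = const)
      fit <- fit_single_ligand(curve, priors,
                               settings_with_seed(settings, run_seed),
                               const = const)
      fit$posterior$sd[["dG"]]
    }, numeric(1))
    data.frame(sigma = sigma_grid[[g]], mean_sd_dG = mean(sds))
  })
  do.call(rbind, rows)
}

#' Copy sampler settings with a different seed
#'
#' @param settings A [sampler_settings()].
#' @param seed New integer seed.
#' @return A [sampler_settings()].
#' @export
settings_with_seed <- function(settings, seed) {
  settings$seed <- as.integer(seed %% 2147483647)
  settings
}
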