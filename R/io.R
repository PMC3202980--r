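#' Write a response dataset as a plate-style CSV
#'
#' Canonical schema: `receptor, mixture_id, point_index, replicate,
#' plate, log10_total_conc, intensity` — one row per measurement.
#'
#' @param data A [response_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(data, path) {
  stopifnot(inherits(data, "response_dataset"))
  utils::write.csv(data$records, path, row.names = FALSE)
  invisible(path)
}

#' Read a plate-style CSV into a response dataset
#'
#' Columns are matched by header name, so column order is free. When
#' `log10_total_conc` is filled, each receptor's dilution series is
#' reconstructed from it; otherwise a `series` list must be supplied
#' (decoding only needs the known increments, not the absolute scale).
#' A plate whose maximum intensity deviates notably from 1 triggers a
#' warning (plate normalization check), never an error.
#'
#' @param path CSV path.
#' @param series Optional named per-receptor list of
#'   [dilution_series()].
#' @param const A [model_constants()] object.
#' @return A [response_dataset()].
#' @export
read_plate_table <- function(path, series = NULL,
                             const = model_constants()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("receptor", "mixture_id", "point_index", "replicate",
                "plate", "intensity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("plate table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(df$intensity)) stop("`intensity` column is not numeric")
  bad <- which(!is.finite(df$intensity))
  if (length(bad) > 0L) {
    stop("non-finite intensity at CSV data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (is.null(series)) {
    if (!"log10_total_conc" %in% names(df) ||
        anyNA(df$log10_total_conc)) {
      stop("`log10_total_conc` unavailable; supply `series` explicitly")
    }
    series <- list()
    for (r in unique(df$receptor)) {
      sub <- df[df$receptor == r, ]
      sub <- sub[!duplicated(sub$point_index), ]
      sub <- sub[order(sub$point_index), ]
      mu <- const$kT * log(10) * sub$log10_total_conc
      series[[as.character(r)]] <- dilution_series(diff(mu), mu0 = mu[[1L]])
    }
  }
  for (pl in unique(df$plate)) {
    mx <- max(df$intensity[df$plate == pl])
    if (abs(mx - 1) > 0.25) {
      warning("plate ", pl, ": maximum intensity ", signif(mx, 3),
              " deviates from 1; check per-plate normalization")
    }
  }
  response_dataset(df, series)
}

#' Write an inference or design result as JSON
#'
#' Stable schema across runs: parameter names, means, standard
#' deviations, log-evidence where available, seed and software version.
#' Timestamps are deliberately excluded so identical seeds give
#' identical files.
#'
#' @param result A `decode_result`, `calibration_fit`, `design_result`,
#'   `posterior_summary`, or a plain list of numbers.
#' @param path Output path.
#' @param seed Seed to record (optional).
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path, seed = NULL) {
  ver <- as.character(utils::packageVersion("arraysense"))
  obj <- if (inherits(result, "decode_result")) {
    list(type = "decode",
         reference_ligand = result$reference_ligand,
         receptor_subset = result$receptor_subset,
         ligand_ids = result$ligand_ids,
         x_mean = as.list(result$x_mean), x_sd = as.list(result$x_sd),
         mu0_mean = result$mu0_mean, mu0_sd = result$mu0_sd,
         sigma_mean = as.list(result$sigma_mean),
         conc_mean = as.list(result$conc_mean),
         conc_sd = as.list(result$conc_sd),
         total_mean = result$total_mean, total_sd = result$total_sd,
         absent = as.list(result$absent),
         log_evidence = result$log_evidence,
         log_evidence_err = result$log_evidence_err)
  } else if (inherits(result, "calibration_fit")) {
    list(type = "calibration", receptor = result$receptor,
         ligand = result$ligand, provenance = result$provenance,
         mean = as.list(result$posterior$mean),
         sd = as.list(result$posterior$sd),
         log_evidence = result$posterior$log_evidence)
  } else if (inherits(result, "design_result")) {
    list(type = "design",
         n_receptors = result$problem$n_receptors,
         n_ligands = result$problem$n_ligands,
         dG = unname(result$dG), eff = unname(result$eff),
         log_det = result$log_det,
         delta = as.list(result$delta),
         discriminates = result$discriminates)
  } else if (inherits(result, "posterior_summary")) {
    list(type = "posterior", mean = as.list(result$mean),
         sd = as.list(result$sd),
         log_evidence = result$log_evidence,
         log_evidence_err = result$log_evidence_err)
  } else {
    result
  }
  obj$seed <- seed
  obj$software_version <- ver
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognized fields: `n_live`, `mcmc_steps`, `stop_tolerance`,
#' `max_iterations`, `seed`, `kT`, and `priors` — a mapping from
#' parameter name to `{kind, lo, hi}` overriding the defaults. Bounds
#' are validated (`lo < hi`, positivity for Jeffreys priors) with the
#' offending parameter named.
#'
#' @param path YAML path.
#' @return A list with `settings` ([sampler_settings()]), `const`
#'   ([model_constants()]) and `priors` (named list of [prior_spec()]
#'   overrides, possibly empty).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  settings <- sampler_settings(
    n_live = cfg$n_live %||% 100L,
    mcmc_steps = cfg$mcmc_steps %||% 20L,
    stop_tolerance = cfg$stop_tolerance %||% 1e-4,
    max_iterations = cfg$max_iterations %||% 200000L,
    seed = cfg$seed %||% 1L)
  const <- model_constants(kT = cfg$kT %||% 0.6)
  priors <- list()
  for (nm in names(cfg$priors %||% list())) {
    p <- cfg$priors[[nm]]
    priors[[nm]] <- tryCatch(
      prior_spec(nm, p$kind %||% "uniform", p$lo, p$hi),
      error = function(e) stop("invalid prior for `", nm, "`: ",
                               conditionMessage(e), call. = FALSE))
  }
  list(settings = settings, const = const, priors = priors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
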