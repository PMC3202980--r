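#' Specification of an array-design optimization problem
#'
#' Describes the setting in which receptor binding free energies and
#' efficacies are optimized: the array size, the mixture composition and
#' total chemical potential at which the information matrix is
#' evaluated, the measurement design (dilution ladder and replicates),
#' the per-receptor noise, and box bounds on the free parameters. With
#' `efficacies_free = FALSE` all efficacies are pinned to 1 (every
#' ligand forced to act as a full agonist).
#'
#' @param n_receptors,n_ligands Array dimensions.
#' @param comp True [mixture_composition()] (default: equal
#'   proportions).
#' @param mu0 True reference-point total chemical potential; defaults to
#'   `kT ln(1e-3)` (1 mM total).
#' @param series A [dilution_series()] (default: 9 points over a
#'   million-fold range).
#' @param replicates Replicates per point (default 4).
#' @param sigma Per-receptor noise (scalar recycled; default 0.02).
#' @param dG_bounds,eff_bounds Box bounds for the optimization.
#' @param efficacies_free If `FALSE`, pin all efficacies at 1.
#' @param const A [model_constants()] object.
#' @return An object of class `design_problem`.
#' @export
design_problem <- function(n_receptors, n_ligands, comp = NULL, mu0 = NULL,
                           series = NULL, replicates = 4L, sigma = 0.02,
                           dG_bounds = c(-16, -1), eff_bounds = c(0, 1),
                           efficacies_free = TRUE,
                           const = model_constants()) {
  stopifnot(n_receptors >= 1L, n_ligands >= 1L, all(sigma > 0),
            all(is.finite(dG_bounds)), all(is.finite(eff_bounds)),
            dG_bounds[1] < dG_bounds[2], eff_bounds[1] < eff_bounds[2])
  ligands <- paste0("L", seq_len(n_ligands))
  receptors <- paste0("R", seq_len(n_receptors))
  if (is.null(comp)) comp <- equal_mixture(ligands)
  stopifnot(length(comp$ligand_ids) == n_ligands)
  if (is.null(mu0)) mu0 <- const$kT * log(1e-3)
  if (is.null(series)) series <- default_series(const = const)
  sigma <- rep_len(sigma, n_receptors)
  structure(list(n_receptors = n_receptors, n_ligands = n_ligands,
                 receptor_ids = receptors, ligand_ids = comp$ligand_ids,
                 comp = comp, mu0 = mu0, series = series,
                 replicates = as.integer(replicates), sigma = sigma,
                 dG_bounds = dG_bounds, eff_bounds = eff_bounds,
                 efficacies_free = isTRUE(efficacies_free), const = const),
            class = "design_problem")
}

# parameter vector <-> array_params for a design problem.
# Layout: dG column-major [nr x nl], then eff column-major when free.
.design_dim <- function(problem) {
  n <- problem$n_receptors * problem$n_ligands
  if (problem$efficacies_free) 2L * n else n
}

.design_params <- function(problem, theta) {
  nr <- problem$n_receptors
  nl <- problem$n_ligands
  n <- nr * nl
  dG <- matrix(theta[seq_len(n)], nr, nl)
  eff <- if (problem$efficacies_free) {
    matrix(pmin(pmax(theta[n + seq_len(n)], 0), 1), nr, nl)
  } else {
    matrix(1, nr, nl)
  }
  array_params(problem$receptor_ids, problem$ligand_ids, dG, eff,
               bg = rep(0, nr), sigma = problem$sigma)
}

.design_objective <- function(problem) {
  force(problem)
  function(theta) {
    p <- .design_params(problem, theta)
    rep <- concentration_hessian(p, problem$comp, problem$mu0,
                                 problem$series, problem$replicates,
                                 problem$const)
    if (!is.finite(rep$log_det)) -Inf else rep$log_det
  }
}

.design_prior_set <- function(problem) {
  nr <- problem$n_receptors
  nl <- problem$n_ligands
  specs <- list()
  for (j in seq_len(nl)) for (i in seq_len(nr)) {
    specs[[length(specs) + 1L]] <- prior_spec(
      sprintf("dG_%d_%d", i, j), "uniform",
      problem$dG_bounds[1], problem$dG_bounds[2])
  }
  if (problem$efficacies_free) {
    for (j in seq_len(nl)) for (i in seq_len(nr)) {
      specs[[length(specs) + 1L]] <- prior_spec(
        sprintf("eff_%d_%d", i, j), "uniform",
        problem$eff_bounds[1], problem$eff_bounds[2])
    }
  }
  prior_set(specs)
}

#' D-optimal design of receptor binding energies and efficacies
#'
#' Maximizes the determinant of the concentration Hessian (equivalently,
#' jointly minimizes the forecast concentration uncertainties) over the
#' binding free energies — and, unless pinned, the efficacies — of every
#' receptor-ligand pair. Nested sampling over the parameter box serves
#' as the global search (the determinant landscape has symmetric
#' multiple optima), followed by a local polish of the best point.
#'
#' @param problem A [design_problem()].
#' @param settings A [sampler_settings()] for the global search; the
#'   default uses 200 live points.
#' @param polish Run the local box-constrained polish (default `TRUE`).
#' @return A `design_result`: optimal `dG` and `eff` matrices, `det` and
#'   `log_det` at the optimum, `delta` uncertainties, the threshold
#'   verdict and the underlying `hessian_report`.
#' @export
optimize_design <- function(problem,
                            settings = sampler_settings(n_live = 200L),
                            polish = TRUE) {
  obj <- .design_objective(problem)
  priors <- .design_prior_set(problem)
  d <- .design_dim(problem)
  ns <- nested_sampling(obj, priors,
                        settings_with_seed(
                          sampler_settings(
                            n_live = settings$n_live,
                            mcmc_steps = settings$mcmc_steps,
                            stop_tolerance = settings$stop_tolerance,
                            max_iterations = min(settings$max_iterations,
                                                 400L * d)),
                          settings$seed))
  best <- as.numeric(ns$map_estimate)
  if (polish) {
    lower <- vapply(priors, `[[`, numeric(1), "lo")
    upper <- vapply(priors, `[[`, numeric(1), "hi")
    # finite floor so box-constrained finite differences never see -Inf
    safe_neg <- function(th) {
      v <- obj(th)
      if (is.finite(v)) -v else 1e12
    }
    fit <- tryCatch(
      stats::optim(best, safe_neg, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 300L)),
      error = function(e) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(
        stats::optim(best, function(th) {
          safe_neg(pmin(pmax(th, lower), upper))
        }, method = "Nelder-Mead", control = list(maxit = 2000L)),
        error = function(e) NULL)
      if (!is.null(fit)) fit$par <- pmin(pmax(fit$par, lower), upper)
    }
    if (!is.null(fit) && is.finite(fit$value) && -fit$value >= obj(best)) {
      best <- fit$par
    }
  }
  p <- .design_params(problem, best)
  report <- concentration_hessian(p, problem$comp, problem$mu0,
                                  problem$series, problem$replicates,
                                  problem$const)
  structure(list(problem = problem, theta = best,
                 dG = p$dG, eff = p$eff,
                 det = report$det, log_det = report$log_det,
                 delta = report$delta, hessian = report,
                 discriminates = meets_threshold(
                   report, problem$comp,
                   discrimination_threshold(const = problem$const))),
            class = "design_result")
}

#' @export
print.design_result <- function(x, ...) {
  cat("Design optimum (", x$problem$n_receptors, "receptor(s) x",
      x$problem$n_ligands, "ligand(s) ): log det =",
      signif(x$log_det, 5), "\n")
  cat("dG (kcal/mol):\n"); print(round(x$dG, 2))
  cat("eff:\n"); print(round(x$eff, 2))
  cat("delta:\n"); print(signif(x$delta, 3))
  cat("meets discrimination threshold:", x$discriminates, "\n")
  invisible(x)
}

# Agonist/antagonist pattern of a design, canonical modulo receptor
# relabelling: efficacies binarized at 0.5, rows sorted lexicographically.
.design_pattern <- function(eff) {
  b <- ifelse(eff >= 0.5, 1L, 0L)
  key <- apply(b, 1L, paste, collapse = "")
  b[order(key), , drop = FALSE]
}

#' Enumerate the optima of the determinant landscape
#'
#' Multi-start design optimization followed by clustering of the found
#' optima modulo receptor-label permutation. Optima are classified by
#' their agonist/antagonist assignment pattern (efficacies binarized at
#' 0.5) and split into global and local maxima by determinant value.
#' Intended for small problems (<= 3 receptors, <= 4 ligands).
#'
#' @param problem A [design_problem()].
#' @param settings Base [sampler_settings()]; start `k` uses seed
#'   `settings$seed + k`.
#' @param n_starts Number of independent searches (>= 2).
#' @param det_log_tol Optima within this log-determinant distance of the
#'   best are labelled global.
#' @return A list of clusters, each with `pattern` (canonical binary
#'   efficacy matrix), `n_found`, `best` (the best `design_result` in
#'   the cluster) and `is_global`.
#' @export
enumerate_optima <- function(problem,
                             settings = sampler_settings(n_live = 100L),
                             n_starts = 20L, det_log_tol = 0.5) {
  if (problem$n_receptors > 3L || problem$n_ligands > 4L) {
    stop("optimum enumeration is supported for <= 3 receptors and <= 4 ligands")
  }
  results <- lapply(seq_len(n_starts), function(k) {
    optimize_design(problem,
                    settings_with_seed(settings, settings$seed + k))
  })
  keys <- vapply(results, function(r) {
    paste(.design_pattern(r$eff), collapse = "")
  }, character(1))
  clusters <- list()
  for (key in unique(keys)) {
    members <- results[keys == key]
    dets <- vapply(members, `[[`, numeric(1), "log_det")
    best <- members[[which.max(dets)]]
    clusters[[length(clusters) + 1L]] <- list(
      pattern = .design_pattern(best$eff),
      n_found = length(members),
      best = best, log_det = best$log_det)
  }
  top <- max(vapply(clusters, `[[`, numeric(1), "log_det"))
  for (i in seq_along(clusters)) {
    clusters[[i]]$is_global <- clusters[[i]]$log_det > top - det_log_tol
  }
  clusters[order(-vapply(clusters, `[[`, numeric(1), "log_det"))]
}

#' Discrimination capacity of optimally designed arrays
#'
#' For each array size, grows the number of mixture components until
#' D-optimal design can no longer bring every forecast uncertainty below
#' the discrimination threshold; the largest passing count is the
#' capacity. With efficacies free the capacity grows as twice the number
#' of receptors (each receptor pairs one agonist with one antagonist);
#' pinning all efficacies at 1 halves it.
#'
#' @param max_receptors Scan 1..`max_receptors`.
#' @param efficacies_free Allow antagonists (`TRUE`) or force all
#'   ligands to be full agonists (`FALSE`).
#' @param threshold A [discrimination_threshold()].
#' @param settings Base [sampler_settings()] for each optimization.
#' @param n_starts Optimization restarts per (receptors, ligands) cell;
#'   the best verdict wins.
#' @param comp_factory Function `n_ligands -> mixture_composition`
#'   giving the composition at which designs are evaluated (default:
#'   equal proportions).
#' @param max_ligands_tested Safety cap per receptor count.
#' @param const A [model_constants()] object.
#' @return A data.frame with columns `n_receptors`, `capacity`.
#' @export
capacity_scan <- function(max_receptors, efficacies_free = TRUE,
                          threshold = discrimination_threshold(),
                          settings = sampler_settings(n_live = 150L),
                          n_starts = 3L,
                          comp_factory = NULL,
                          max_ligands_tested = NULL,
                          const = model_constants()) {
  stopifnot(threshold$x_frac > 0, threshold$mu0_tol > 0)
  if (is.null(comp_factory)) {
    comp_factory <- function(nl) equal_mixture(paste0("L", seq_len(nl)))
  }
  rows <- list()
  for (nr in seq_len(max_receptors)) {
    cap_guess <- if (efficacies_free) 2L * nr else nr
    limit <- if (is.null(max_ligands_tested)) cap_guess + 1L
             else max_ligands_tested
    capacity <- 0L
    for (nl in seq_len(limit)) {
      problem <- design_problem(nr, nl, comp = comp_factory(nl),
                                efficacies_free = efficacies_free,
                                const = const)
      ok <- FALSE
      for (s in seq_len(n_starts)) {
        res <- optimize_design(
          problem, settings_with_seed(settings,
                                      settings$seed + 1000L * nr +
                                        100L * nl + s))
        if (meets_threshold(res$hessian, problem$comp, threshold)) {
          ok <- TRUE
          break
        }
      }
      if (!ok && nl == 1L) {
        warning("threshold unreachable even for a single ligand with ",
                nr, " receptor(s); noise too large or series too short")
      }
      if (ok) capacity <- nl else break
    }
    rows[[nr]] <- data.frame(n_receptors = nr, capacity = capacity)
  }
  do.call(rbind, rows)
}

#' Hessian diagnostics of a calibrated array over candidate mixtures
#'
#' Evaluates the forecast uncertainty report for a calibrated array on a
#' set of candidate mixtures, ranking the mixtures by determinant.
#' Optionally re-optimizes the array while holding the binding free
#' energies fixed (efficacies free), and fully (both free), to show
#' which relaxation most improves the determinant — a guide to whether
#' efficacies or affinities are the binding constraint of the current
#' hardware.
#'
#' @param params Calibrated [array_params()].
#' @param comps A [mixture_composition()] or list of them.
#' @param mu0 Reference-point total chemical potential.
#' @param series Dilution series (shared or per receptor).
#' @param replicates Replicates per point.
#' @param improve Run the constrained re-optimizations (slower).
#' @param settings [sampler_settings()] for the re-optimizations.
#' @param const A [model_constants()] object.
#' @return A list with `table` (per-mixture log-determinant and maximum
#'   uncertainty) and, when `improve = TRUE`, `improvement` (log-dets of
#'   the calibrated, efficacy-relaxed and fully relaxed arrays on the
#'   first mixture).
#' @export
diagnose_array <- function(params, comps, mu0 = NULL,
                           series = default_series(), replicates = 4L,
                           improve = FALSE,
                           settings = sampler_settings(n_live = 100L),
                           const = model_constants()) {
  if (inherits(comps, "mixture_composition")) comps <- list(comps)
  if (is.null(mu0)) mu0 <- const$kT * log(1e-3)
  rows <- lapply(seq_along(comps), function(i) {
    rep_i <- concentration_hessian(params, comps[[i]], mu0, series,
                                   replicates, const)
    xn <- setdiff(rep_i$parameter_names, "mu0")
    data.frame(mixture = paste(comps[[i]]$ligand_ids[comps[[i]]$x > 0],
                               collapse = "+"),
               log_det = rep_i$log_det,
               max_delta_x = if (length(xn)) max(rep_i$delta[xn]) else NA,
               delta_mu0 = rep_i$delta[["mu0"]])
  })
  table <- do.call(rbind, rows)
  out <- list(table = table[order(-table$log_det), ])
  if (improve) {
    comp <- comps[[1L]]
    base <- concentration_hessian(params, comp, mu0, series, replicates,
                                  const)
    nr <- length(params$receptor_ids)
    nl <- length(params$ligand_ids)
    problem <- design_problem(nr, nl, comp = comp, mu0 = mu0,
                              series = series, replicates = replicates,
                              sigma = params$sigma, const = const)
    # efficacies free, binding energies pinned at calibrated values
    eff_obj <- function(ev) {
      p <- array_params(params$receptor_ids, params$ligand_ids,
                        params$dG, matrix(pmin(pmax(ev, 0), 1), nr, nl),
                        bg = rep(0, nr), sigma = params$sigma)
      r <- concentration_hessian(p, comp, mu0, series, replicates, const)
      if (is.finite(r$log_det)) r$log_det else -Inf
    }
    eff_priors <- prior_set(lapply(seq_len(nr * nl), function(k) {
      prior_spec(paste0("eff", k), "uniform", 0, 1)
    }))
    ns <- nested_sampling(eff_obj, eff_priors,
                          settings_with_seed(settings, settings$seed))
    start <- as.numeric(ns$map_estimate)
    fit <- stats::optim(start, function(th) -eff_obj(th),
                        method = "L-BFGS-B", lower = rep(0, nr * nl),
                        upper = rep(1, nr * nl),
                        control = list(maxit = 200L))
    eff_only <- max(-fit$value, eff_obj(start))
    full <- optimize_design(problem,
                            settings_with_seed(settings,
                                               settings$seed + 1L))
    out$improvement <- data.frame(
      relaxation = c("calibrated", "efficacies", "dG+efficacies"),
      log_det = c(base$log_det, eff_only, full$log_det))
  }
  out
}

#' Robustness of a fixed design across mixture compositions
#'
#' A design is optimized at one composition; this evaluates how much of
#' the per-composition optimal determinant the fixed design retains as
#' the relative concentration of one ligand sweeps a range. Retention at
#' the design composition is 1 by construction.
#'
#' @param design A `design_result`.
#' @param vary_ligand Ligand whose relative concentration is swept.
#' @param x_grid Relative concentrations to evaluate (should include the
#'   design value).
#' @param settings [sampler_settings()] for the per-composition
#'   re-optimizations.
#' @param n_starts Restarts per re-optimization.
#' @return A data.frame with `x`, `log_det_fixed`, `log_det_opt`,
#'   `retention` (`det_fixed / det_opt`) and the re-optimized `dG`
#'   values (column-major, comma-separated).
#' @export
robustness_scan <- function(design, vary_ligand,
                            x_grid = 10^seq(-1, 1, length.out = 5L),
                            settings = sampler_settings(n_live = 100L),
                            n_starts = 2L) {
  problem <- design$problem
  stopifnot(vary_ligand %in% problem$ligand_ids,
            vary_ligand != problem$comp$reference_ligand)
  fixed_params <- array_params(problem$receptor_ids, problem$ligand_ids,
                               design$dG, design$eff,
                               bg = rep(0, problem$n_receptors),
                               sigma = problem$sigma)
  x_design <- problem$comp$x[[vary_ligand]]
  rows <- lapply(seq_along(x_grid), function(i) {
    x <- problem$comp$x
    x[[vary_ligand]] <- x_grid[[i]]
    comp_i <- mixture_composition(problem$ligand_ids, x,
                                  problem$comp$reference_ligand)
    fixed_rep <- concentration_hessian(fixed_params, comp_i, problem$mu0,
                                       problem$series, problem$replicates,
                                       problem$const)
    if (isTRUE(all.equal(x_grid[[i]], x_design))) {
      log_det_opt <- fixed_rep$log_det
      dG_opt <- design$dG
    } else {
      problem_i <- problem
      problem_i$comp <- comp_i
      best <- NULL
      for (s in seq_len(n_starts)) {
        res <- optimize_design(
          problem_i, settings_with_seed(settings,
                                        settings$seed + 10L * i + s))
        if (is.null(best) || res$log_det > best$log_det) best <- res
      }
      log_det_opt <- max(best$log_det, fixed_rep$log_det)
      dG_opt <- best$dG
    }
    data.frame(x = x_grid[[i]],
               log_det_fixed = fixed_rep$log_det,
               log_det_opt = log_det_opt,
               retention = exp(fixed_rep$log_det - log_det_opt),
               dG_opt = paste(round(as.numeric(dG_opt), 3),
                              collapse = ","))
  })
  do.call(rbind, rows)
}
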