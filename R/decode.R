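#' Decode a ligand mixture from array readout
#'
#' The central inference: given calibrated array parameters and mixture
#' response curves from any receptor subset, nested sampling infers the
#' relative concentrations of every ligand in the panel (with respect to
#' a chosen reference ligand), the total chemical potential `mu0` at the
#' reference point of the dilution series, and a per-receptor noise
#' scale. The full ligand model is always fitted, even if fewer ligands
#' are actually present: absent ligands are expected to return relative
#' concentrations near the prior floor, so the same run identifies both
#' zero and non-zero concentrations. Relative concentrations and `mu0`
#' are converted, per posterior sample, to absolute molar concentrations
#' of every component at the reference point.
#'
#' Concentration ratios are sampled on the log scale (their Jeffreys
#' prior is uniform in log); means and standard deviations are reported
#' on the linear scale by transforming the weighted samples.
#'
#' @param data A [response_dataset()] of mixture response curves;
#'   per-receptor ladders may differ.
#' @param params Calibrated [array_params()] covering every modelled
#'   ligand.
#' @param receptor_subset Receptors to use (default: all receptors in
#'   `data`); each must be calibrated in `params`.
#' @param reference_ligand Ligand whose relative concentration is pinned
#'   to 1.
#' @param priors Optional [prior_set()]; defaults to [decode_priors()].
#' @param settings A [sampler_settings()].
#' @param absent_fraction A ligand is called absent when its posterior
#'   mean concentration is below this fraction of the total and its 95%
#'   interval touches the prior floor.
#' @param const A [model_constants()] object.
#' @return A `decode_result` with the composition posterior (means and
#'   stds of every `x` and of `mu0` and the per-receptor sigmas),
#'   absolute concentrations with propagated stds, total concentration,
#'   absent-ligand calls, log-evidence, and the receptor subset used.
#' @export
decode_mixture <- function(data, params, receptor_subset = NULL,
                           reference_ligand, priors = NULL,
                           settings = sampler_settings(),
                           absent_fraction = 0.05,
                           const = model_constants()) {
  stopifnot(inherits(params, "array_params"))
  if (!reference_ligand %in% params$ligand_ids) {
    stop("unknown reference ligand: ", reference_ligand)
  }
  if (is.null(receptor_subset)) {
    receptor_subset <- unique(data$records$receptor)
  }
  if (length(receptor_subset) == 0L) stop("receptor subset is empty")
  missing_r <- setdiff(receptor_subset, params$receptor_ids)
  if (length(missing_r) > 0L) {
    stop("receptor subset lacking calibration: ",
         paste(missing_r, collapse = ", "))
  }
  data <- subset_dataset(data, receptors = receptor_subset)
  # canonicalize to the record order so sigma parameters line up with
  # the likelihood's per-receptor layout
  receptor_subset <- unique(data$records$receptor)
  if (is.null(priors)) {
    priors <- decode_priors(params$ligand_ids, reference_ligand,
                            receptor_subset, const)
  }
  ll <- make_array_loglik(data, params, reference_ligand, const)
  post <- nested_sampling(ll, priors, settings)

  ligands <- params$ligand_ids
  free_lig <- setdiff(ligands, reference_ligand)
  nfree <- length(free_lig)
  kT <- const$kT

  # full relative-concentration samples (reference column pinned at 1)
  x_samp <- matrix(1, nrow(post$samples), length(ligands),
                   dimnames = list(NULL, ligands))
  if (nfree > 0L) x_samp[, free_lig] <- post$samples[, seq_len(nfree)]
  mu0_samp <- post$samples[, nfree + 1L]
  w <- post$weights

  conc_samp <- exp(mu0_samp / kT) * x_samp / rowSums(x_samp)
  wmean <- function(m) colSums(m * w)
  wsd <- function(m, mu) sqrt(pmax(colSums(m^2 * w) - mu^2, 0))
  x_mean <- wmean(x_samp); x_sd <- wsd(x_samp, x_mean)
  x_sd[reference_ligand] <- 0
  conc_mean <- wmean(conc_samp); conc_sd <- wsd(conc_samp, conc_mean)
  total_samp <- exp(mu0_samp / kT)
  total_mean <- sum(total_samp * w)
  total_sd <- sqrt(max(sum(total_samp^2 * w) - total_mean^2, 0))

  # absent-ligand calls: tiny share of the total and 95% interval at floor
  floor_x <- vapply(ligands, function(l) {
    if (l == reference_ligand) return(NA_real_)
    priors[[paste0("x_", l)]]$lo
  }, numeric(1))
  absent <- vapply(seq_along(ligands), function(i) {
    l <- ligands[[i]]
    if (l == reference_ligand) return(FALSE)
    q_lo <- posterior_quantile(post, paste0("x_", l), 0.025)
    (conc_mean[[i]] / total_mean < absent_fraction) &&
      (q_lo <= 3 * floor_x[[i]])
  }, logical(1))

  sigma_mean <- post$mean[paste0("sigma_", receptor_subset)]
  sigma_sd <- post$sd[paste0("sigma_", receptor_subset)]

  structure(
    list(reference_ligand = reference_ligand,
         ligand_ids = ligands,
         receptor_subset = receptor_subset,
         x_mean = x_mean, x_sd = x_sd,
         mu0_mean = post$mean[["mu0"]], mu0_sd = post$sd[["mu0"]],
         sigma_mean = stats::setNames(sigma_mean, receptor_subset),
         sigma_sd = stats::setNames(sigma_sd, receptor_subset),
         conc_mean = conc_mean, conc_sd = conc_sd,
         total_mean = total_mean, total_sd = total_sd,
         absent = stats::setNames(absent, ligands),
         log_evidence = post$log_evidence,
         log_evidence_err = post$log_evidence_err,
         posterior = post,
         x_samples = x_samp, mu0_samples = mu0_samp, weights = w,
         const = const),
    class = "decode_result")
}

#' @export
print.decode_result <- function(x, ...) {
  cat("Mixture decode (reference:", x$reference_ligand, "; receptors:",
      paste(x$receptor_subset, collapse = ", "), ")\n")
  tab <- data.frame(x_mean = x$x_mean, x_sd = x$x_sd,
                    conc_M = x$conc_mean, conc_sd = x$conc_sd,
                    absent = x$absent)
  print(signif_df(tab, 4))
  cat(sprintf("total: %.3g +/- %.3g M;  log evidence: %.2f\n",
              x$total_mean, x$total_sd, x$log_evidence))
  invisible(x)
}

signif_df <- function(df, digits) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], digits)
  }
  df
}

#' Re-express a decode result against a different reference ligand
#'
#' The reference ligand in the relative-concentration parametrization is
#' arbitrary; dividing every sampled ratio by the new reference's ratio
#' re-expresses the same posterior, leaving absolute concentrations
#' unchanged up to sampling error.
#'
#' @param result A `decode_result`.
#' @param new_reference_ligand Ligand to pin at ratio 1; re-referencing
#'   onto a ligand called absent is refused (its near-zero ratio would
#'   make the representation degenerate).
#' @return A `decode_result` with transformed `x` summaries.
#' @export
rereference <- function(result, new_reference_ligand) {
  stopifnot(inherits(result, "decode_result"))
  ligands <- result$ligand_ids
  if (!new_reference_ligand %in% ligands) {
    stop("unknown ligand: ", new_reference_ligand)
  }
  if (isTRUE(result$absent[[new_reference_ligand]])) {
    stop("cannot re-reference onto a ligand inferred to be absent: ",
         new_reference_ligand)
  }
  x2 <- result$x_samples / result$x_samples[, new_reference_ligand]
  w <- result$weights
  x_mean <- colSums(x2 * w)
  x_sd <- sqrt(pmax(colSums(x2^2 * w) - x_mean^2, 0))
  x_sd[new_reference_ligand] <- 0
  out <- result
  out$reference_ligand <- new_reference_ligand
  out$x_mean <- x_mean
  out$x_sd <- x_sd
  out$x_samples <- x2
  out
}
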