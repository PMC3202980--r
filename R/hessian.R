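#' Low-noise Hessian of the concentration parameters
#'
#' Fisher-information forecast of decoding uncertainty. In the low-noise
#' (zero-residual) limit the Hessian of the negative log-likelihood at
#' the truth reduces to
#' \deqn{H_{kl} = \sum_r \frac{1}{\sigma_r^2} \sum_m
#'   \frac{\partial I_r(\mu_m)}{\partial \theta_k}
#'   \frac{\partial I_r(\mu_m)}{\partial \theta_l},}
#' with \eqn{\theta = (x_{i \ne ref}, \mu_0)}: the relative
#' concentrations on the linear scale and the reference-point total
#' chemical potential. The derivatives of the competitive-binding
#' response are evaluated in closed form. Replicated measurements enter
#' multiplicatively. Per-parameter uncertainties are
#' \eqn{\delta\theta_k = \sqrt{(H^{-1})_{kk}}}; a singular Hessian yields
#' infinite uncertainties (reported, not an error): if the array response
#' carries no information about a parameter, the corresponding rows and
#' columns vanish.
#'
#' @param params [array_params()] describing the array (its `sigma` sets
#'   the per-receptor noise).
#' @param comp A [mixture_composition()] at which the Hessian is
#'   evaluated (the true composition).
#' @param mu0 True reference-point total chemical potential (kcal/mol).
#' @param series A [dilution_series()] shared by all receptors, or a
#'   named per-receptor list.
#' @param replicates Measurements per series point.
#' @param const A [model_constants()] object.
#' @return A `hessian_report`: `parameter_names`, `H`, `log_det`, `det`,
#'   `delta` (named uncertainties; `Inf` when `H` is singular), and the
#'   reciprocal condition number `rcond`.
#' @export
concentration_hessian <- function(params, comp, mu0, series,
                                  replicates = 4L,
                                  const = model_constants()) {
  stopifnot(inherits(params, "array_params"),
            inherits(comp, "mixture_composition"))
  if (any(params$sigma <= 0)) stop("noise scales must be > 0")
  if (inherits(series, "dilution_series")) {
    series <- stats::setNames(rep(list(series), length(params$receptor_ids)),
                              params$receptor_ids)
  }
  ligands <- params$ligand_ids
  ref <- comp$reference_ligand
  free <- setdiff(ligands, ref)
  theta_names <- c(if (length(free) > 0L) paste0("x_", free), "mu0")
  d <- length(theta_names)
  kT <- const$kT
  x <- comp$x[ligands]
  S <- sum(x)
  H <- matrix(0, d, d, dimnames = list(theta_names, theta_names))
  free_idx <- match(free, ligands)
  for (r in params$receptor_ids) {
    s <- series[[r]]
    if (s$n_points < 1L) stop("empty series for receptor ", r)
    t_m <- exp(series_mu(s, mu0) / kT)
    a <- exp(-params$dG[r, ] / kT)
    e <- params$eff[r, ]
    w <- t_m %o% (a * x / S)              # [point x ligand]
    Z <- 1 + rowSums(w)
    p <- w / Z
    q <- (t_m / (S * Z)) %o% a            # p_i / x_i, finite at x_i = 0
    Ibar <- as.numeric(p %*% e)
    gmu <- p * rep(e, each = length(t_m))
    gmu <- (gmu - p * Ibar) / kT          # p_i (e_i - Ibar) / kT
    G <- rowSums(gmu)
    D <- if (length(free_idx) > 0L) {
      qf <- q[, free_idx, drop = FALSE]
      cbind(qf * outer(rep(1, length(t_m)), e[free_idx]) - qf * Ibar -
              kT * G / S,
            G)
    } else {
      matrix(G, ncol = 1L)
    }
    H <- H + (replicates / params$sigma[[r]]^2) * crossprod(D)
  }
  ld <- determinant(H, logarithm = TRUE)
  log_det <- if (ld$sign > 0) as.numeric(ld$modulus) else -Inf
  delta <- rep(Inf, d)
  rc <- rcond(H)
  # a numerically singular information matrix means an unconstrained
  # parameter combination: report infinite uncertainty, not garbage
  inv <- if (is.finite(rc) && rc > 1e-15) {
    tryCatch(solve(H), error = function(e) NULL)
  } else NULL
  if (!is.null(inv)) {
    dg <- diag(inv)
    delta <- ifelse(is.finite(dg) & dg > 0, sqrt(pmax(dg, 0)), Inf)
  }
  structure(list(parameter_names = theta_names, H = H,
                 log_det = log_det, det = exp(log_det),
                 delta = stats::setNames(delta, theta_names),
                 rcond = rc),
            class = "hessian_report")
}

#' @export
print.hessian_report <- function(x, ...) {
  cat("Hessian report:", length(x$parameter_names), "parameters; log det =",
      signif(x$log_det, 5), "\n")
  print(signif(x$delta, 4))
  invisible(x)
}

#' Discrimination threshold on forecast uncertainties
#'
#' A mixture counts as successfully discriminated when every relative
#' concentration is forecast to within a fraction of its true value and
#' the total chemical potential to within `kT ln 2` (a factor of two in
#' total concentration).
#'
#' @param x_frac Allowed `delta x / x_true` (default 0.3).
#' @param mu0_tol Allowed `delta mu0` in kcal/mol (default `kT ln 2`).
#' @param const A [model_constants()] object.
#' @return A list with the two tolerances.
#' @export
discrimination_threshold <- function(x_frac = 0.3, mu0_tol = NULL,
                                     const = model_constants()) {
  if (is.null(mu0_tol)) mu0_tol <- const$kT * log(2)
  stopifnot(x_frac > 0, mu0_tol > 0)
  list(x_frac = x_frac, mu0_tol = mu0_tol)
}

#' Do forecast uncertainties meet the discrimination threshold?
#'
#' @param report A `hessian_report`.
#' @param comp The true [mixture_composition()] (supplies `x_true`).
#' @param threshold A [discrimination_threshold()].
#' @return Logical scalar.
#' @export
meets_threshold <- function(report, comp,
                            threshold = discrimination_threshold()) {
  delta <- report$delta
  mu_ok <- delta[["mu0"]] < threshold$mu0_tol
  xn <- setdiff(report$parameter_names, "mu0")
  if (length(xn) == 0L) return(mu_ok)
  x_true <- comp$x[sub("^x_", "", xn)]
  # absent ligands (x_true = 0) are judged against the reference scale 1
  ref_scale <- ifelse(x_true > 0, x_true, 1)
  all(delta[xn] < threshold$x_frac * ref_scale) && mu_ok
}
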