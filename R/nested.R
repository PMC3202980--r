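#' Sampler settings for nested sampling
#'
#' @param n_live Number of live points (`>= 2`).
#' @param mcmc_steps Metropolis steps used to draw each replacement point
#'   under the hard likelihood constraint.
#' @param stop_tolerance Terminate when the maximum possible remaining
#'   contribution to the evidence falls below this fraction of the
#'   accumulated evidence.
#' @param max_iterations Hard cap on iterations.
#' @param seed Integer seed; the run is fully reproducible given the seed.
#' @return An object of class `sampler_settings`.
#' @export
sampler_settings <- function(n_live = 100L, mcmc_steps = 20L,
                             stop_tolerance = 1e-4,
                             max_iterations = 200000L, seed = 1L) {
  stopifnot(n_live >= 2L, mcmc_steps >= 1L, stop_tolerance > 0,
            max_iterations >= 1L)
  structure(list(n_live = as.integer(n_live),
                 mcmc_steps = as.integer(mcmc_steps),
                 stop_tolerance = stop_tolerance,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed)),
            class = "sampler_settings")
}

logsumexp <- function(a, b) {
  m <- max(a, b)
  if (m == -Inf) return(-Inf)
  m + log(exp(a - m) + exp(b - m))
}

# Compiled prior transform: theta = a + u * b, exponentiated where the
# prior is log-uniform (Jeffreys).
.transform_coefs <- function(priors) {
  kinds <- vapply(priors, `[[`, character(1), "kind")
  lo <- vapply(priors, `[[`, numeric(1), "lo")
  hi <- vapply(priors, `[[`, numeric(1), "hi")
  is_log <- kinds == "jeffreys"
  a <- lo
  b <- hi - lo
  a[is_log] <- log(lo[is_log])
  b[is_log] <- log(hi[is_log]) - a[is_log]
  list(a = a, b = b, is_log = is_log)
}

.apply_transform <- function(tc, u) {
  th <- tc$a + u * tc$b
  th[tc$is_log] <- exp(th[tc$is_log])
  th
}

#' Nested sampling: posterior samples plus Bayesian evidence
#'
#' Classic nested sampling (Skilling): `n_live` points are drawn from the
#' prior; at each iteration the lowest-likelihood point is removed,
#' assigned the prior mass it statistically encloses, and replaced by a
#' new prior draw subject to the hard constraint that its likelihood
#' exceed the removed one. The constrained draw is obtained by a short
#' Metropolis walk in the unit cube started from a random surviving live
#' point, with step sizes adapted towards ~50% acceptance. The scheme
#' integrates the likelihood over the prior, so it returns the log
#' evidence (marginal likelihood) together with weighted posterior
#' samples.
#'
#' @param loglike Function mapping a parameter vector (natural units,
#'   ordered as `priors`) to a log-likelihood. Returning `-Inf` is
#'   allowed; returning `NaN` at an in-prior point is an error.
#' @param priors A [prior_set()] bounding every parameter.
#' @param settings A [sampler_settings()].
#' @return An object of class `posterior_summary`: weighted `samples`
#'   (matrix) with normalized `weights`, posterior `mean` and `sd` per
#'   parameter, `map_estimate` (highest-likelihood point), `log_evidence`
#'   with `log_evidence_err` (information-based estimator error
#'   \eqn{\sqrt{H/n_{live}}}), and bookkeeping counts.
#' @references Skilling, J. (2006) Nested sampling for general Bayesian
#'   computation. Bayesian Analysis 1:833-859. Sivia, D.S. & Skilling, J.
#'   (2006) Data Analysis: A Bayesian Tutorial. OUP.
#' @export
nested_sampling <- function(loglike, priors, settings = sampler_settings()) {
  stopifnot(inherits(priors, "prior_set"),
            inherits(settings, "sampler_settings"))
  set.seed(settings$seed)
  d <- length(priors)
  n <- settings$n_live
  tc <- .transform_coefs(priors)

  eval_ll <- function(th) {
    v <- loglike(th)
    if (is.nan(v)) stop("log-likelihood returned NaN at an in-prior point")
    v
  }

  U <- matrix(stats::runif(n * d), n, d)
  L <- numeric(n)
  TH <- matrix(0, n, d)
  for (i in seq_len(n)) {
    TH[i, ] <- .apply_transform(tc, U[i, ])
    L[i] <- eval_ll(TH[i, ])
  }
  n_calls <- n

  cap <- 4096L
  dead_th <- matrix(0, cap, d)
  dead_L <- numeric(cap)
  dead_logw <- numeric(cap)

  logZ <- -Inf
  log_shrink <- -1 / n                 # E[log X] shrinkage per iteration
  logw_unit <- log(1 - exp(log_shrink))  # width of shell k: X_{k-1}-X_k
  step <- 0.1
  it <- 0L

  repeat {
    it <- it + 1L
    if (it > cap) {
      cap <- cap * 2L
      dead_th <- rbind(dead_th, matrix(0, cap - nrow(dead_th), d))
      dead_L <- c(dead_L, numeric(cap - length(dead_L)))
      dead_logw <- c(dead_logw, numeric(cap - length(dead_logw)))
    }
    worst <- which.min(L)
    logL_w <- L[worst]
    log_X_prev <- (it - 1L) * log_shrink
    logw <- log_X_prev + logw_unit
    logZ <- logsumexp(logZ, logL_w + logw)
    dead_th[it, ] <- TH[worst, ]
    dead_L[it] <- logL_w
    dead_logw[it] <- logw

    log_X <- it * log_shrink
    remaining <- max(L) + log_X
    done <- (is.finite(logZ) &&
             remaining - logZ < log(settings$stop_tolerance)) ||
            it >= settings$max_iterations
    if (done) break

    # replacement: constrained Metropolis walk from a random survivor
    from <- if (n > 1L) {
      idx <- sample.int(n, 1L)
      if (idx == worst) idx <- if (idx == n) 1L else idx + 1L
      idx
    } else worst
    u <- U[from, ]
    th <- TH[from, ]
    Lc <- L[from]
    n_acc <- 0L
    n_rej <- 0L
    for (m in seq_len(settings$mcmc_steps)) {
      u2 <- u + step * stats::rnorm(d)
      # reflect into [0, 1]
      u2 <- u2 %% 2
      u2 <- ifelse(u2 > 1, 2 - u2, u2)
      th2 <- .apply_transform(tc, u2)
      L2 <- eval_ll(th2)
      n_calls <- n_calls + 1L
      if (L2 > logL_w) {
        u <- u2; th <- th2; Lc <- L2; n_acc <- n_acc + 1L
      } else {
        n_rej <- n_rej + 1L
      }
    }
    if (n_acc > n_rej) step <- step * exp(1 / max(n_acc, 1L))
    else step <- step / exp(1 / max(n_rej, 1L))
    step <- min(max(step, 1e-6), 1)
    U[worst, ] <- u
    TH[worst, ] <- th
    L[worst] <- Lc
  }

  # fold the surviving live points into the evidence and the sample set
  log_X <- it * log_shrink
  live_logw <- rep(log_X - log(n), n)
  for (i in seq_len(n)) logZ <- logsumexp(logZ, L[i] + live_logw[i])

  samples <- rbind(dead_th[seq_len(it), , drop = FALSE], TH)
  logL_all <- c(dead_L[seq_len(it)], L)
  logw_all <- c(dead_logw[seq_len(it)], live_logw)
  colnames(samples) <- names(priors)

  log_post <- logL_all + logw_all - logZ
  wts <- exp(log_post - max(log_post))
  wts <- wts / sum(wts)

  means <- colSums(samples * wts)
  vars <- colSums(samples^2 * wts) - means^2
  sds <- sqrt(pmax(vars, 0))
  H_info <- sum(wts * (logL_all - logZ), na.rm = TRUE)
  map_idx <- which.max(logL_all)

  structure(
    list(parameter_names = names(priors),
         mean = stats::setNames(means, names(priors)),
         sd = stats::setNames(sds, names(priors)),
         samples = samples, weights = wts, logL = logL_all,
         log_evidence = logZ,
         log_evidence_err = sqrt(max(H_info, 0) / n),
         map_estimate = stats::setNames(samples[map_idx, ], names(priors)),
         map_loglike = logL_all[map_idx],
         n_iterations = it, n_calls = n_calls,
         settings = settings),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("Posterior summary (", x$n_iterations, "iterations,",
      x$n_calls, "likelihood calls )\n")
  tab <- data.frame(mean = x$mean, sd = x$sd)
  print(signif(tab, 4))
  if (!is.null(x$log_evidence)) {
    cat(sprintf("log evidence: %.3f +/- %.3f\n",
                x$log_evidence, x$log_evidence_err))
  }
  invisible(x)
}

#' Posterior quantiles from weighted samples
#'
#' @param summary A `posterior_summary`.
#' @param parameter Parameter name.
#' @param probs Quantile probabilities.
#' @return Named numeric vector of quantiles.
#' @export
posterior_quantile <- function(summary, parameter, probs = c(0.025, 0.975)) {
  v <- summary$samples[, parameter]
  o <- order(v)
  cw <- cumsum(summary$weights[o])
  stats::setNames(vapply(probs, function(p) v[o][which(cw >= p)[1L]],
                         numeric(1)),
                  paste0(probs * 100, "%"))
}
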