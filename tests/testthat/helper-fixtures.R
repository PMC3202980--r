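# Shared fixtures: small arrays, quick sampler settings, generating truths.

quick_settings <- function(seed = 1L, n_live = 60L) {
  sampler_settings(n_live = n_live, mcmc_steps = 20L, seed = seed)
}

# two-receptor, two-ligand array with complementary specificities
test_array_2x2 <- function(sigma = 0.02) {
  array_params(c("Ra", "Rb"), c("A", "B"),
               dG = rbind(c(-9.0, -7.5), c(-7.8, -9.2)),
               eff = rbind(c(0.90, 0.15), c(0.30, 0.85)),
               bg = c(0.05, 0.04), sigma = rep(sigma, 2))
}

calib_truth <- function() list(dG = -8, eff = 0.8, bg = 0.05, sigma = 0.02)

ref_mu0 <- function(conc = 1e-3, const = model_constants()) {
  const$kT * log(conc)
}

# random single-curve parameters inside the calibration prior box
random_curve_theta <- function() {
  list(dG = stats::runif(1, -12, -5), eff = stats::runif(1, 0.2, 1),
       bg = stats::runif(1, 0, 0.2), sigma = stats::runif(1, 0.01, 0.1))
}

fd_hessian_oracle <- function(params, comp, mu0, s, replicates,
                              h = 1e-6) {
  # independent oracle: outer products of central finite differences of
  # the per-point intensities, never touching the analytic gradient code
  const <- model_constants()
  free <- setdiff(params$ligand_ids, comp$reference_ligand)
  theta0 <- c(comp$x[free], mu0)
  d <- length(theta0)
  H <- matrix(0, d, d)
  for (r in params$receptor_ids) {
    f <- function(th) {
      x <- comp$x
      x[free] <- th[seq_along(free)]
      cm <- mixture_composition(params$ligand_ids, x,
                                comp$reference_ligand)
      series_intensity(params, r, cm, s, mu0 = th[[d]])
    }
    J <- vapply(seq_len(d), function(k) {
      tp <- theta0; tm <- theta0
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (f(tp) - f(tm)) / (2 * h)
    }, numeric(s$n_points))
    H <- H + (replicates / params$sigma[[r]]^2) * crossprod(J)
  }
  H
}
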