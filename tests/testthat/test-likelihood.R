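test_that("single-curve likelihood matches its closed forms", {
  truth <- calib_truth()
  s <- default_series()
  curve <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                      sigma = 0, series = s,
                                      replicates = 4L, seed = 1L)
  M <- nrow(curve$records)
  expect_identical(M, 36L)
  th <- c(truth, list(sigma = NULL))
  # zero residuals: only the normalization term survives
  ll <- log_likelihood_single(curve, list(dG = truth$dG, eff = truth$eff,
                                          bg = truth$bg, sigma = 0.02))
  expect_equal(ll, -M * log(0.02 * sqrt(2 * pi)))
  # doubling sigma at zero residuals costs M ln 2
  ll2 <- log_likelihood_single(curve, list(dG = truth$dG, eff = truth$eff,
                                           bg = truth$bg, sigma = 0.04))
  expect_equal(ll - ll2, M * log(2))
  expect_error(log_likelihood_single(curve, list(dG = -8, eff = 1, bg = 0,
                                                 sigma = -1)), "sigma")
})

test_that("single-curve likelihood equals a per-point summation oracle", {
  set.seed(11)
  for (i in 1:5) {
    tr <- random_curve_theta()
    s <- default_series(n_points = 6L)
    curve <- generate_calibration_curve(tr$dG, tr$eff, tr$bg, tr$sigma, s,
                                        replicates = 3L, seed = 100 + i)
    th <- random_curve_theta()
    # independent oracle: explicit loop over records with dnorm
    mu <- series_mu(s)
    oracle <- 0
    for (k in seq_len(nrow(curve$records))) {
      m <- curve$records$point_index[[k]]
      I_k <- th$bg + th$eff / (1 + exp((th$dG - mu[[m]]) / 0.6))
      oracle <- oracle + dnorm(curve$records$intensity[[k]], I_k,
                               th$sigma, log = TRUE)
    }
    expect_equal(log_likelihood_single(curve, th), oracle,
                 tolerance = 1e-10)
  }
})

test_that("array likelihood reduces, is label-symmetric, and matches the
           direct oracle", {
  const <- model_constants()
  params <- test_array_2x2()
  mu0 <- ref_mu0()
  s <- default_series()
  # reduction: one receptor, one ligand present
  comp1 <- mixture_composition(c("A", "B"), c(1, 0), "A")
  ds1 <- generate_mixture_dataset(params, comp1, mu0, s, replicates = 2L,
                                  seed = 5L)
  one <- subset_dataset(ds1, receptors = "Ra")
  ll_arr <- log_likelihood_array(one, params,
                                 list(x = c(A = 1, B = 0), mu0 = mu0,
                                      sigma = c(Ra = 0.02)))
  ll_single <- log_likelihood_single(
    one, list(dG = params$dG["Ra", "A"], eff = params$eff["Ra", "A"],
              bg = params$bg[["Ra"]], sigma = 0.02, mu0 = mu0))
  expect_equal(ll_arr, ll_single, tolerance = 1e-12)

  # consistent ligand relabelling leaves the likelihood unchanged
  comp <- mixture_composition(c("A", "B"), c(1, 2.5), "A")
  ds <- generate_mixture_dataset(params, comp, mu0, s, replicates = 2L,
                                 seed = 6L)
  params_swap <- array_params(params$receptor_ids, c("B", "A"),
                              params$dG[, c(2, 1)], params$eff[, c(2, 1)],
                              params$bg, params$sigma)
  theta <- list(x = c(A = 1, B = 2.5), mu0 = mu0,
                sigma = c(Ra = 0.03, Rb = 0.025))
  expect_equal(log_likelihood_array(ds, params, theta),
               log_likelihood_array(ds, params_swap, theta))

  # two-receptor case against an explicit summation oracle
  oracle <- 0
  for (r in params$receptor_ids) {
    rec <- ds$records[ds$records$receptor == r, ]
    I_m <- series_intensity(params, r, comp, s, mu0 = mu0)
    oracle <- oracle + sum(dnorm(rec$intensity, I_m[rec$point_index],
                                 theta$sigma[[r]], log = TRUE))
  }
  expect_equal(log_likelihood_array(ds, params, theta), oracle,
               tolerance = 1e-10)

  expect_error(
    log_likelihood_array(ds, array_params("Rx", c("A", "B"),
                                          matrix(c(-8, -8), 1),
                                          matrix(c(1, 1), 1), 0, 0.02),
                         theta),
    "missing from params")
})
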