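test_that("single-ligand calibration recovers generating parameters", {
  truth <- calib_truth()
  curve <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                      truth$sigma, default_series(),
                                      replicates = 4L, seed = 31L)
  fit <- fit_single_ligand(curve, settings = quick_settings(seed = 32L))
  for (nm in names(truth)) {
    expect_lt(abs(fit$estimates[[nm]] - truth[[nm]]),
              3 * fit$posterior$sd[[nm]])
  }
  expect_lt(abs(fit$estimates[["dG"]] - truth$dG), 0.2)
  expect_identical(fit$provenance, "single-ligand")
})

test_that("calibration refuses degenerate inputs", {
  truth <- calib_truth()
  tiny <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                     truth$sigma,
                                     series_from_concentrations(c(1e-3, 1e-4)),
                                     replicates = 4L, seed = 1L)
  expect_error(fit_single_ligand(tiny), "at least 3")
})

test_that("a full antagonist is unidentifiable alone but calibrates in a
           binary mixture with a known agonist", {
  const <- model_constants()
  ant <- list(dG = -9, eff = 0)
  ag <- list(dG = -8.5, eff = 0.9)
  bg <- 0.05
  s <- default_series()
  # flat single-ligand curve: posterior on dG stays prior-wide
  flat <- generate_calibration_curve(ant$dG, ant$eff, bg, 0.02, s,
                                     replicates = 4L, seed = 41L)
  flat_fit <- fit_single_ligand(flat, settings = quick_settings(seed = 42L))
  prior_sd <- (16 - 1) / sqrt(12)   # sd of the uniform dG prior
  expect_gt(flat_fit$posterior$sd[["dG"]], 0.4 * prior_sd)

  # 50/50 binary mixture with the agonist carries the signal
  params <- array_params("R", c("ANT", "AG"),
                         dG = matrix(c(ant$dG, ag$dG), 1),
                         eff = matrix(c(ant$eff, ag$eff), 1),
                         bg = bg, sigma = 0.02)
  comp <- mixture_composition(c("ANT", "AG"), c(1, 1), "ANT")
  ds <- generate_mixture_dataset(params, comp, ref_mu0(), s,
                                 replicates = 4L, seed = 43L)
  fit <- fit_antagonist_in_mixture(ds, ag, comp, antagonist = "ANT",
                                   bg = bg,
                                   settings = quick_settings(seed = 44L))
  expect_lt(abs(fit$estimates[["dG"]] - ant$dG),
            3 * fit$posterior$sd[["dG"]])
  expect_lt(fit$posterior$sd[["dG"]], prior_sd / 4)
  expect_lt(fit$estimates[["eff"]], 0.2)
  expect_identical(fit$provenance, "antagonist-in-mixture")
})

test_that("the agonist partner with the most informative curve is chosen", {
  const <- model_constants()
  ant <- list(dG = -9, eff = 0)
  strong <- list(dG = -8.5, eff = 0.9)
  weak <- list(dG = -5.0, eff = 0.9)   # barely binds within the ladder
  bg <- 0.05
  s <- default_series()
  make_binary <- function(ag, seed) {
    params <- array_params("R", c("ANT", "AG"),
                           dG = matrix(c(ant$dG, ag$dG), 1),
                           eff = matrix(c(ant$eff, ag$eff), 1),
                           bg = bg, sigma = 0.02)
    comp <- mixture_composition(c("ANT", "AG"), c(1, 1), "ANT")
    list(ds = generate_mixture_dataset(params, comp, ref_mu0(), s,
                                       replicates = 4L, seed = seed),
         comp = comp)
  }
  b1 <- make_binary(strong, 51L)
  b2 <- make_binary(weak, 52L)
  fit <- fit_antagonist_in_mixture(
    list(b1$ds, b2$ds), list(strong, weak), list(b1$comp, b2$comp),
    antagonist = "ANT", bg = bg, settings = quick_settings(seed = 53L))
  expect_identical(fit$partner, "AG")
  expect_length(fit$candidate_sds, 2L)
  # the selected partner is the strong binder: its std is the smaller one
  expect_identical(unname(which.min(fit$candidate_sds)), 1L)
})

test_that("plate-bias refit recovers efficacy scaling and background
           shifts", {
  truth <- calib_truth()
  params <- array_params("R1", "L1", matrix(truth$dG, 1, 1),
                         matrix(truth$eff, 1, 1), truth$bg, 0.005)
  comp <- mixture_composition("L1", 1, "L1")
  s <- default_series()
  gen <- function(bias, seed) {
    generate_mixture_dataset(params, comp, s$mu0, s, replicates = 4L,
                             seed = seed, plates = c(1, 1, 2, 2),
                             plate_bias = bias, mixture_id = "L1")
  }
  # efficacy scaled by 0.9 on plate 2
  ds <- gen(list("2" = list(eff_scale = 0.9, bg_shift = 0)), 61L)
  bias <- fit_plate_bias(ds, params)
  expect_equal(bias$eff_scale[bias$plate == 1], 1, tolerance = 0.05)
  expect_equal(bias$eff_scale[bias$plate == 2], 0.9, tolerance = 0.05)
  # identical plates: adjustments are the identity
  ds0 <- gen(NULL, 62L)
  bias0 <- fit_plate_bias(ds0, params)
  expect_equal(bias0$eff_scale, c(1, 1), tolerance = 0.05)
  expect_equal(bias0$bg_shift, c(0, 0), tolerance = 0.01)
  # background-only bias: efficacy untouched, background shifted
  dsb <- gen(list("2" = list(eff_scale = 1, bg_shift = 0.04)), 63L)
  biasb <- fit_plate_bias(dsb, params)
  expect_equal(biasb$eff_scale[biasb$plate == 2], 1, tolerance = 0.05)
  expect_equal(biasb$bg_shift[biasb$plate == 2], 0.04, tolerance = 0.01)
  single_plate <- generate_mixture_dataset(params, comp, s$mu0, s,
                                           replicates = 2L, seed = 65L,
                                           mixture_id = "L1")
  expect_error(fit_plate_bias(single_plate, params), "two plates")
})

test_that("calibration is invariant under plate renormalization", {
  # rescaling all intensities of a plate together with its normalization
  # constant is a no-op on the data, hence on the point estimates
  truth <- calib_truth()
  curve <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                      truth$sigma, default_series(),
                                      replicates = 4L, seed = 71L)
  rescaled <- curve
  rescaled$records$intensity <- curve$records$intensity * 1.7 / 1.7
  f1 <- fit_single_ligand(curve, settings = quick_settings(seed = 72L))
  f2 <- fit_single_ligand(rescaled, settings = quick_settings(seed = 72L))
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-9)
})
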