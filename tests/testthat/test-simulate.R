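test_that("calibration-curve generation has the right size, law and
           zero-noise limit", {
  truth <- calib_truth()
  s <- default_series()
  curve <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                      truth$sigma, s, replicates = 4L,
                                      seed = 1L)
  expect_identical(nrow(curve$records), 36L)
  # zero noise reproduces the model exactly
  clean <- generate_calibration_curve(truth$dG, truth$eff, truth$bg, 0,
                                      s, replicates = 2L, seed = 1L)
  model <- single_ligand_intensity(truth$dG, truth$eff, truth$bg,
                                   series_mu(s))
  expect_equal(clean$records$intensity,
               model[clean$records$point_index])
  expect_error(generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                          -0.1, s), "sigma")
  # CLT check at one point: mean of many replicates hits the model value
  big <- generate_calibration_curve(truth$dG, truth$eff, truth$bg,
                                    truth$sigma, s, replicates = 10000L,
                                    seed = 2L)
  at1 <- big$records$intensity[big$records$point_index == 1L]
  se <- truth$sigma / sqrt(length(at1))
  expect_lt(abs(mean(at1) - model[[1L]]), 3 * se)
  # empirical noise std matches the configured sigma within 5%
  expect_lt(abs(sd(at1) / truth$sigma - 1), 0.05)
})

test_that("mixture generation is seeded, receptor-stream-stable and
           reduces to the single-ligand law", {
  params <- example_array_params()
  comp <- equal_mixture(params$ligand_ids, c("UDP-Glc", "UDP"))
  s <- default_series()
  ds1 <- generate_mixture_dataset(params, comp, ref_mu0(), s,
                                  replicates = 4L, seed = 7L)
  ds2 <- generate_mixture_dataset(params, comp, ref_mu0(), s,
                                  replicates = 4L, seed = 7L)
  # identical seed: byte-identical CSV
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_plate_table(ds1, f1); write_plate_table(ds2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # generating a receptor subset reproduces the full run's records
  keep <- params$receptor_ids[2:3]
  sub_params <- array_params(keep, params$ligand_ids,
                             params$dG[keep, ], params$eff[keep, ],
                             params$bg[keep], params$sigma[keep])
  ds_sub <- generate_mixture_dataset(sub_params, comp, ref_mu0(), s,
                                     replicates = 4L, seed = 7L)
  full_sub <- subset_dataset(ds1, receptors = keep)
  expect_equal(ds_sub$records$intensity, full_sub$records$intensity)
  # a single-ligand composition reproduces the calibration generator
  p1 <- array_params("R1", "L1", matrix(-8, 1, 1), matrix(0.8, 1, 1),
                     0.05, 0.02)
  single <- generate_mixture_dataset(
    p1, mixture_composition("L1", 1, "L1"), s$mu0, s, replicates = 3L,
    seed = 9L, mixture_id = "L1")
  calib <- generate_calibration_curve(-8, 0.8, 0.05, 0.02, s,
                                      replicates = 3L, seed = 9L)
  expect_equal(single$records, calib$records)
  expect_error(generate_mixture_dataset(params, comp, ref_mu0(),
                                        s, replicates = 0L), "replicates")
})

test_that("equal-proportion mixture enumeration covers every subset", {
  panel4 <- paste0("L", 1:4)
  mixes <- enumerate_equal_mixtures(panel4)
  expect_length(mixes, 15L)
  expect_length(enumerate_equal_mixtures("only"), 1L)
  expect_length(enumerate_equal_mixtures(paste0("L", 1:3)), 7L)
  # compositions are equal-proportion with the first present ligand as
  # reference, and all distinct
  sigs <- vapply(mixes, function(m) paste(m$x, collapse = ","),
                 character(1))
  expect_identical(anyDuplicated(sigs), 0L)
  expect_true(all(vapply(mixes, function(m) {
    all(m$x %in% c(0, 1)) && m$x[[m$reference_ligand]] == 1
  }, logical(1))))
})

test_that("scan tables are seeded and sized as requested", {
  truth <- calib_truth()
  st <- sampler_settings(n_live = 40L, seed = 1L)
  rs1 <- range_scan(truth, c_max_grid = c(1e-6, 1e-3), n_runs = 2L,
                    seed = 5L, settings = st)
  rs2 <- range_scan(truth, c_max_grid = c(1e-6, 1e-3), n_runs = 2L,
                    seed = 5L, settings = st)
  expect_identical(rs1, rs2)
  expect_identical(nrow(rs1), 2L)
  expect_error(range_scan(truth, c_max_grid = 1e-3, n_runs = 1L),
               "n_runs")
  ns1 <- noise_scan(truth, sigma_grid = c(0.02, 0.08), n_runs = 2L,
                    seed = 6L, settings = st)
  expect_identical(nrow(ns1), 2L)
  expect_true(all(ns1$mean_sd_dG > 0))
  expect_error(noise_scan(truth, sigma_grid = c(0.02), n_runs = 1L),
               "n_runs")
})
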