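test_that("a noise-free binary mixture is decoded to truth with absent
           ligands at the prior floor", {
  const <- model_constants()
  params <- example_array_params()
  mu0 <- ref_mu0(1e-3)
  comp <- equal_mixture(params$ligand_ids, c("UDP-Glc", "UDP-Gal"))
  noisefree <- array_params(params$receptor_ids, params$ligand_ids,
                            params$dG, params$eff, params$bg,
                            rep(1e-4, 4))
  ds <- generate_mixture_dataset(noisefree, comp, mu0, default_series(),
                                 replicates = 4L, seed = 81L)
  # the essentially noise-free likelihood peak is extreme; give the
  # sampler enough live points and walk length to reach it
  res <- decode_mixture(ds, params, reference_ligand = "UDP-Glc",
                        settings = sampler_settings(n_live = 150L,
                                                    mcmc_steps = 40L,
                                                    seed = 82L))
  truth_conc <- absolute_concentrations(comp, mu0)
  for (lig in c("UDP-Glc", "UDP-Gal")) {
    expect_lt(abs(res$conc_mean[[lig]] - truth_conc[[lig]]),
              2 * res$conc_sd[[lig]] + 1e-6)
  }
  for (lig in c("UDP-GlcNAc", "UDP")) {
    expect_lt(res$conc_mean[[lig]] / res$total_mean, 0.05)
    expect_true(res$absent[[lig]])
  }
  expect_false(res$absent[["UDP-Gal"]])
  expect_lt(abs(res$total_mean - 1e-3), 3 * res$total_sd + 5e-5)
  # re-referencing onto an absent ligand is refused
  expect_error(rereference(res, "UDP"), "absent")
})

test_that("decoding validates its inputs", {
  params <- test_array_2x2()
  comp <- equal_mixture(c("A", "B"))
  ds <- generate_mixture_dataset(params, comp, ref_mu0(), default_series(),
                                 replicates = 2L, seed = 1L)
  expect_error(decode_mixture(ds, params, receptor_subset = "Rz",
                              reference_ligand = "A"),
               "lacking calibration")
  expect_error(decode_mixture(ds, params, reference_ligand = "Q"),
               "unknown reference")
  expect_error(decode_mixture(ds, params, receptor_subset = character(0),
                              reference_ligand = "A"), "empty")
})

test_that("re-referencing transforms ratios and preserves absolute
           concentrations", {
  params <- test_array_2x2(sigma = 0.01)
  comp <- mixture_composition(c("A", "B"), c(1, 2), "A")
  ds <- generate_mixture_dataset(params, comp, ref_mu0(), default_series(),
                                 replicates = 4L, seed = 91L)
  res <- decode_mixture(ds, params, reference_ligand = "A",
                        settings = quick_settings(seed = 92L))
  # deterministic point transform of the sampled ratios
  rr <- rereference(res, "B")
  expect_equal(unname(rr$x_mean[["B"]]), 1)
  expect_equal(unname(rr$x_sd[["B"]]), 0)
  manual <- colSums((res$x_samples / res$x_samples[, "B"]) * res$weights)
  expect_equal(rr$x_mean, manual)
  # absolute concentrations are untouched by the reparametrization
  expect_identical(rr$conc_mean, res$conc_mean)
  # re-referencing onto the current reference is the identity
  same <- rereference(res, "A")
  expect_equal(same$x_mean, res$x_mean)
  # an independent decode referenced on B agrees on concentrations
  res_b <- decode_mixture(ds, params, reference_ligand = "B",
                          settings = quick_settings(seed = 93L))
  for (lig in c("A", "B")) {
    expect_lt(abs(res_b$conc_mean[[lig]] - res$conc_mean[[lig]]),
              3 * sqrt(res_b$conc_sd[[lig]]^2 + res$conc_sd[[lig]]^2))
  }
})

test_that("more receptors shrink decoding uncertainty", {
  params <- example_array_params()
  comp <- equal_mixture(params$ligand_ids, c("UDP-Glc", "UDP-Gal"))
  ds <- generate_mixture_dataset(params, comp, ref_mu0(), default_series(),
                                 replicates = 4L, seed = 97L)
  r1 <- decode_mixture(ds, params, receptor_subset = "H-20",
                       reference_ligand = "UDP-Glc",
                       settings = quick_settings(seed = 98L))
  r4 <- decode_mixture(ds, params, reference_ligand = "UDP-Glc",
                       settings = quick_settings(seed = 98L))
  expect_lt(r4$x_sd[["UDP-Gal"]], r1$x_sd[["UDP-Gal"]])
  expect_lt(r4$total_sd, r1$total_sd)
})

test_that("unequal binary ratios rank monotonically with the truth", {
  params <- test_array_2x2(sigma = 0.01)
  ratios <- c(0.25, 1, 4)
  est <- vapply(seq_along(ratios), function(i) {
    comp <- mixture_composition(c("A", "B"), c(1, ratios[[i]]), "A")
    ds <- generate_mixture_dataset(params, comp, ref_mu0(),
                                   default_series(), replicates = 4L,
                                   seed = 100L + i)
    res <- decode_mixture(ds, params, reference_ligand = "A",
                          settings = quick_settings(seed = 110L + i))
    res$x_mean[["B"]]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
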