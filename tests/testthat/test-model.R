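test_that("single-ligand response hits its analytic landmarks", {
  # half occupancy at mu = dG
  expect_equal(single_ligand_intensity(-6, 1, 0, mu = -6), 0.5)
  # zero-occupancy limit returns the background
  expect_equal(single_ligand_intensity(-6, 0.8, 0.1, mu = -60), 0.1,
               tolerance = 1e-10)
  # w = 3 => p = 3/4 => 0.1 + 0.8 * 0.75
  expect_equal(single_ligand_intensity(-6, 0.8, 0.1, mu = -6 + 0.6 * log(3)),
               0.7)
  # absent-ligand sentinel
  expect_equal(single_ligand_intensity(-6, 0.8, 0.1, mu = -Inf), 0.1)
  expect_error(single_ligand_intensity(NA, 1, 0, -6), "non-finite")
  expect_error(single_ligand_intensity(-6, 1.2, 0, -6), "eff")
})

test_that("competitive occupancies normalize and reduce correctly", {
  # two equal ligands at mu = dG: Z = 3
  occ <- mixture_occupancies(c(-6, -6), c(-6, -6))
  expect_equal(occ$p, c(1, 1) / 3)
  expect_equal(occ$unbound, 1 / 3)
  # everything absent
  occ0 <- mixture_occupancies(c(-6, -8), c(-Inf, -Inf))
  expect_equal(occ0$p, c(0, 0))
  expect_equal(occ0$unbound, 1)
  # one ligand present reduces to the two-state form
  occ1 <- mixture_occupancies(c(-7, -9), c(-6.2, -Inf))
  w <- exp((-6.2 + 7) / 0.6)
  expect_equal(occ1$p[[1]], w / (1 + w))
  expect_error(mixture_occupancies(c(-6, -6), -6), "length")
  # normalization property over random draws
  set.seed(42)
  for (i in 1:200) {
    L <- sample(2:6, 1)
    occ <- mixture_occupancies(runif(L, -12, -4), runif(L, -10, -2))
    expect_lt(abs(sum(occ$p) + occ$unbound - 1), 1e-12)
  }
})

test_that("mixture response reduces, saturates and respects ligand labels", {
  params <- test_array_2x2()
  # agonist at 1/3 occupancy, antagonist contributes nothing
  p2 <- array_params("R", c("ag", "ant"), matrix(c(-6, -6), 1),
                     matrix(c(1, 0), 1), bg = 0, sigma = 0.02)
  expect_equal(mixture_intensity(p2, "R", c(-6, -6)), 1 / 3)
  # all ligands absent: background only
  expect_equal(mixture_intensity(params, "Ra", c(-Inf, -Inf)),
               params$bg[["Ra"]])
  expect_error(mixture_intensity(params, "nope", c(-6, -6)), "unknown")
  # single-ligand reduction to machine precision
  set.seed(7)
  for (i in 1:100) {
    th <- random_curve_theta()
    mu <- runif(1, -10, -3)
    p1 <- array_params("R", c("L1", "L2"),
                       matrix(c(th$dG, runif(1, -12, -5)), 1),
                       matrix(c(th$eff, runif(1)), 1),
                       bg = th$bg, sigma = 0.02)
    expect_equal(mixture_intensity(p1, "R", c(mu, -Inf)),
                 single_ligand_intensity(th$dG, th$eff, th$bg, mu))
  }
  # strict monotonicity and saturation for a single agonist
  mu_grid <- seq(-14, 2, length.out = 60)
  I <- single_ligand_intensity(-8, 0.7, 0.05, mu_grid)
  expect_true(all(diff(I) > 0))
  expect_lt(max(I), 0.05 + 0.7 + 1e-12)
  expect_equal(single_ligand_intensity(-8, 0.7, 0.05, 20), 0.75,
               tolerance = 1e-10)
  # permuting ligand labels together with parameter columns changes nothing
  const <- model_constants()
  params4 <- example_array_params()
  comp <- mixture_composition(params4$ligand_ids, c(1, 0.5, 2, 0),
                              "UDP-Glc")
  mu <- chemical_potentials(comp, ref_mu0())
  perm <- c(3, 1, 4, 2)
  params_p <- array_params(params4$receptor_ids,
                           params4$ligand_ids[perm],
                           params4$dG[, perm], params4$eff[, perm],
                           params4$bg, params4$sigma)
  for (r in params4$receptor_ids) {
    expect_equal(mixture_intensity(params_p, r, mu[perm]),
                 mixture_intensity(params4, r, mu))
  }
})

test_that("chemical potentials split the total by relative concentration", {
  const <- model_constants()
  ligs <- paste0("L", 1:4)
  comp <- mixture_composition(ligs, c(1, 1, 1, 1), "L1")
  mu <- chemical_potentials(comp, mu_from_conc(1e-3))
  expect_equal(unname(conc_from_mu(mu)), rep(2.5e-4, 4))
  # single-component mixture: mu_1 = mu_total, rest absent
  comp1 <- mixture_composition(ligs, c(1, 0, 0, 0), "L1")
  mu1 <- chemical_potentials(comp1, -5)
  expect_equal(mu1[["L1"]], -5)
  expect_equal(unname(mu1[2:4]), rep(-Inf, 3))
  # proportional split: x = (1, 3), total 4e-3 M
  compb <- mixture_composition(c("a", "b"), c(1, 3), "a")
  mub <- chemical_potentials(compb, mu_from_conc(4e-3))
  expect_equal(unname(conc_from_mu(mub)), c(1e-3, 3e-3))
  # implied concentrations always recover the total
  expect_equal(sum(conc_from_mu(mub)), 4e-3)
  expect_error(chemical_potentials(
    mixture_composition("a", 1, "a"), Inf), "finite")
})

test_that("absolute concentrations follow from mu0 and are
           reference-invariant", {
  mu0 <- mu_from_conc(1e-3)
  comp <- mixture_composition(c("a", "b"), c(1, 1), "a")
  expect_equal(unname(absolute_concentrations(comp, mu0)), c(5e-4, 5e-4))
  comp1 <- mixture_composition(c("a", "b"), c(1, 0), "a")
  expect_equal(unname(absolute_concentrations(comp1, mu0)), c(1e-3, 0))
  expect_equal(sum(absolute_concentrations(comp, mu0)), 1e-3)
  # re-referencing the same ratios leaves concentrations unchanged
  compA <- mixture_composition(c("a", "b", "c"), c(1, 2, 4), "a")
  compB <- mixture_composition(c("a", "b", "c"), c(0.5, 1, 2), "b")
  expect_equal(absolute_concentrations(compA, mu0),
               absolute_concentrations(compB, mu0))
})

test_that("dilution series reconstruct their potentials", {
  s <- series_from_concentrations(c(1e-3, 1e-4, 1e-5))
  expect_equal(s$n_points, 3L)
  expect_equal(series_mu(s), mu_from_conc(c(1e-3, 1e-4, 1e-5)))
  # monotone ladder when all increments share a sign
  expect_true(all(diff(series_mu(s)) < 0))
  s_unknown <- dilution_series(s$delta_mu)
  expect_error(series_mu(s_unknown), "mu0")
  expect_equal(series_mu(s_unknown, mu0 = 0),
               series_mu(s) - series_mu(s)[[1]])
})
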