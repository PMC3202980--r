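# arraysense

Quantitative mixture decoding and information-based design for
**cross-specific receptor arrays** — small sensor panels (engineered
GPCR reporter strains, olfaction-style arrays) in which every receptor
responds to every ligand with its own affinity and efficacy, and
mixtures produce non-linear, competitive response patterns.

`arraysense` is for people who have (or plan to build) such a panel and
want to go beyond fingerprinting: to read out the **absolute
concentration of every component** of an unknown mixture from
dilution-series fluorescence data, and to know — before building
anything — **how many components an array of a given size can resolve
and what receptor properties make it best at the job**.

## The model and the two engines

Each receptor `j` responds to a mixture through competitive binding:

    I_j = bg_j + sum_i e_ji * p_ji,     p_ji = w_ji / (1 + sum_k w_jk),
    w_ji = exp((mu_i - dG_ji)/kT),      mu_i = mu_tot + kT*ln(x_i / sum_k x_k)

with binding free energies `dG_ji` (kcal/mol), efficacies `e_ji` in
[0, 1] (1 = full agonist, 0 = full antagonist: binds, silences, and
competitively displaces agonists), relative concentrations `x_i` and a
total chemical potential `mu_tot = kT*ln(total/1 M)`.

1. **Bayesian engine** — a from-scratch nested sampler (with evidence)
   plus Metropolis refinement. It calibrates `(dG, eff, bg, sigma)` per
   receptor–ligand pair from single-ligand curves (antagonists via
   binary mixtures with a known agonist), then decodes unknown mixtures:
   posterior over all relative concentrations, the total at the
   reference point, and per-receptor noise — hence absolute
   concentrations with error bars, from any receptor subset.
2. **Hessian (Fisher-information) engine** — closed-form low-noise
   information matrix for the concentration parameters; D-optimal
   design of `(dG, eff)` by determinant maximization; symmetry-aware
   enumeration of equivalent optima; array diagnostics; and capacity
   scans showing that an optimally designed array resolves **twice as
   many ligands as it has receptors** when antagonists are allowed, and
   only as many as it has receptors when every ligand must be an
   agonist.

## Worked example

Decode a 50/50 binary mixture (total 1 mM) presented to the built-in
synthetic four-receptor UDP-sugar panel:

```r
library(arraysense)
params <- example_array_params()           # synthetic 4R x 4L panel
comp   <- equal_mixture(params$ligand_ids, c("UDP-Glc", "UDP-Gal"))
ds  <- generate_mixture_dataset(params, comp, mu0 = mu_from_conc(1e-3),
                                series = default_series(), replicates = 4,
                                seed = 3)
res <- decode_mixture(ds, params, reference_ligand = "UDP-Glc",
                      settings = sampler_settings(n_live = 100, seed = 7))
print(res)
```

```
Mixture decode (reference: UDP-Glc ; receptors: 2211, H-20, K-3, L-3 )
              x_mean      x_sd    conc_M   conc_sd absent
UDP-Glc    1.0000000 0.0000000 5.143e-04 2.049e-05  FALSE
UDP-Gal    0.9737000 0.0492100 5.000e-04 1.654e-05  FALSE
UDP-GlcNAc 0.0007985 0.0007623 4.107e-07 3.933e-07   TRUE
UDP        0.0015510 0.0015930 7.995e-07 8.234e-07   TRUE
total: 0.00102 +/- 2.72e-05 M;  log evidence: 322.47
```

Read: both present ligands are recovered at ~5e-4 M (truth 5e-4 M each;
the ratio estimate 0.97 ± 0.05 brackets the true 1), the two ligands
that were *not* in the mixture are driven to the prior floor and called
absent, and the inferred total (1.02e-3 ± 2.7e-5 M) matches the true
1 mM. The log evidence allows model-level comparisons across runs.

The companion design engine answers the a-priori question:

```r
res <- optimize_design(design_problem(1, 2))   # 1 receptor, 2 ligands
round(res$eff, 2)                              # -> one 1, one 0
```

the optimal single receptor for a binary mixture makes one ligand a
full agonist and the other a full antagonist — inhibitory responses are
what make simultaneous recovery of composition *and* total possible.

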