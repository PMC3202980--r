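---
title: "Decoding ligand mixtures with cross-specific receptor arrays: model, inference and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding ligand mixtures with cross-specific receptor arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arraysense)
```

## The problem

A cross-specific sensor array is a small panel of receptors with
overlapping, non-orthogonal selectivities — the architecture of
olfaction, and of engineered GPCR reporter panels. A single analyte
already elicits a pattern across the whole array; a mixture elicits a
*non-linear* superposition of patterns, because ligands compete for the
same binding sites and some of them (antagonists) occupy receptors
without producing signal. `arraysense` treats this non-linearity as an
asset rather than an obstacle: a physical model of competitive binding
links the observed dilution-series response of each receptor to the
absolute concentration of every component, and Bayesian inference
inverts that link.

## The physical model

For one receptor and one ligand, the normalized reporter intensity is

$$ I(\mu) \;=\; bg \;+\; e\,\frac{w}{1+w}, \qquad
   w = e^{(\mu-\Delta G)/kT}, $$

where $\Delta G$ is the binding free energy (kcal/mol, negative =
favorable), $e \in [0,1]$ the efficacy (1 = full agonist, 0 = full
antagonist), $bg$ a small background, and $\mu = kT\ln(c/1\,\mathrm{M})$
the chemical potential of the ligand at molar concentration $c$. The
receptor is half-occupied where $\mu = \Delta G$.

For a mixture binding competitively to receptor $j$, the grand-canonical
occupancies are $p_{ji} = w_{ji}/Z_j$ with
$Z_j = 1 + \sum_i w_{ji}$, and the response is the efficacy-weighted sum

$$ I_j \;=\; bg_j + \sum_i e_{ji}\, p_{ji}. $$

With exactly one ligand present this reduces bit-exactly to the
single-ligand form — a property the test suite checks on a thousand
random draws. Mixtures are parametrized by *relative* concentrations
$x_i$ (each ligand's concentration over that of an arbitrary reference
ligand, so $x_{\mathrm{ref}} = 1$) plus the total chemical potential:
$\mu_i = \mu_{tot} + kT\ln(x_i/\sum_k x_k)$. A dilution series changes
$\mu_{tot}$ by exactly known increments, so a single unknown scalar
$\mu_0$ — the total potential at the reference point — fixes the whole
ladder, and decoding $\{x_i\}$ and $\mu_0$ yields the absolute
concentration of every component.

Absent ligands are represented by an exact chemical-potential sentinel
($\mu = -\infty$) rather than a small $\epsilon$, so true zeros are
representable in compositions and the partition function degrades
gracefully.

### Choices the model fixes

* `kT = 0.6` kcal/mol by default (about 302 K, the incubation
  temperature of the yeast reporter strains this model grew out of);
  configurable through `model_constants()`.
* Chemical potential is referenced to 1 M. Only relative potentials
  matter for fitting; the 1 M convention only fixes the units in which
  absolute concentrations are reported.
* No constraint $bg + \sum e \le 1$ is imposed: plate normalization
  makes intensities approximately bounded by 1 but the model does not
  require it.

## Inference

Measurements are modelled as Gaussian around the model response with a
per-receptor noise scale $\sigma_j$, giving the usual sum-of-squares
log-likelihood over every point and replicate. Posteriors are explored
by **nested sampling**, which integrates the likelihood over the prior
and therefore returns the Bayesian evidence alongside weighted posterior
samples. The implementation is the classic scheme: `n_live` points
(default 100) drawn from the prior; at each step the worst point is
swapped out under a hard likelihood constraint via a short Metropolis
walk in the unit cube (20 steps, step size adapted toward ~50%
acceptance, started from a random surviving point); termination when
the maximum possible remaining evidence contribution falls below `1e-4`
of the accumulated evidence. The estimator error on $\log Z$ is
$\sqrt{H/n_{live}}$ with $H$ the information. A Metropolis refinement
pass (`metropolis_refine()`, default 50000 samples started from the
likelihood maximum) reproduces the histogram-style posterior summaries
of the original protocol; by default, summaries come from the
nested-sampling weights, which are stabler at equal cost.

Priors follow the parameter's symmetry: uniform (translation-invariant)
for location-like parameters — $\Delta G$ on $[-16,-1]$ kcal/mol,
efficacies on $[0,1]$, backgrounds on $[0,0.5]$, $\mu_0$ over $kT\ln$ of
$[10^{-9},10^{-1}]$ M — and Jeffreys (scale-invariant, $\propto
1/\theta$) for positive scale parameters — $\sigma$ on
$[5\times10^{-3}, 0.5]$ and concentration ratios on $[10^{-4},10^{4}]$.
The ratio prior spans eight decades so that effectively absent ligands
can settle near the floor; ratios are therefore sampled on the log
scale (the Jeffreys transform is log-uniform in the unit cube) and
reported on the linear scale from the weighted samples.

### Calibration

Calibration curves are prepared by the experimenter, so their total
concentrations are treated as exactly known and only `(dG, eff, bg,
sigma)` are inferred per receptor-ligand pair (`fit_single_ligand()`).
Point estimates are posterior means: they are stabler under sampling
noise than the maximum-likelihood point, which remains available via
`metropolis_refine()`. A full antagonist produces a flat single-ligand
curve — no signal, no information — so its parameters are calibrated
from a binary mixture with an already-calibrated agonist, fixed at its
known composition, through the suppression of the agonist signal
(`fit_antagonist_in_mixture()`); when several candidate partners exist,
the one minimizing the posterior standard deviation of the antagonist's
$\Delta G$ is kept. Plate-to-plate systematics are refit as a per-plate
multiplicative efficacy scale and additive background shift
(`fit_plate_bias()`); with occupancies pinned by the calibrated
$\Delta G$, that model is linear, so the Gaussian-likelihood maximum is
obtained in closed form by least squares instead of sampling.

### Decoding

`decode_mixture()` always fits the full ligand panel — even when fewer
ligands are actually present — inferring $(x_{i\neq\mathrm{ref}},
\mu_0, \sigma_r)$ from any receptor subset. A ligand is *called* absent
when its posterior mean concentration is below 5% of the total and its
95% interval reaches the ratio-prior floor; the 5% figure is this
package's operational choice, as no numeric criterion is standard.
Re-referencing (`rereference()`) divides the sampled ratios by the new
reference's ratio; absolute concentrations are invariant under this
reparametrization, which the tests verify both exactly (point
transform) and statistically (independent decodes under two
references).

## Uncertainty forecasting and design

In the low-noise limit the Hessian of the negative log-likelihood at
truth collapses to the Fisher form

$$ H_{kl} = \sum_r \frac{1}{\sigma_r^2} \sum_m
   \partial_{\theta_k} I_r(\mu_m)\, \partial_{\theta_l} I_r(\mu_m),
   \qquad \theta = (x_{i\neq\mathrm{ref}},\ \mu_0), $$

with the response derivatives available in closed form from the
competitive-binding model (`concentration_hessian()`; the analytic
gradient is validated against a finite-difference oracle to $10^{-4}$
relative error). Forecast uncertainties are
$\delta\theta_k = \sqrt{(H^{-1})_{kk}}$; a numerically singular $H$
(reciprocal condition number below $10^{-15}$) reports $\delta=\infty$,
the correct statement that some parameter combination is unconstrained
by the array. The parametrization is deliberately linear in $x$ — the
determinant is parametrization-dependent, and this matches reporting
$\delta$ directly on relative and total concentrations.

`optimize_design()` performs D-optimal design: it maximizes
$\det H$ over the binding free energies and (optionally) efficacies of
every receptor-ligand pair, using nested sampling over the box as a
global search followed by a local box-constrained polish. The landscape
has exactly symmetric optima (relabelling receptors, or exchanging
ligand labels together with their concentrations), which
`enumerate_optima()` clusters by agonist/antagonist pattern modulo
receptor permutation.

Two robust findings reproduced by the test suite:

* For one receptor reading a binary mixture, the optimum always pairs
  one full agonist with one full antagonist (two label-swapped optima
  of equal determinant). With both efficacies pinned to 1 the response
  depends on $x$ and $\mu_0$ only through a single effective
  concentration, the information matrix is rank-deficient, and no
  choice of binding energies can pin both parameters — antagonism is
  *necessary* for joint recovery of composition and total.
* `capacity_scan()` grows the ligand panel until optimal design can no
  longer force every forecast uncertainty below the discrimination
  threshold. With free efficacies the capacity is twice the number of
  receptors; with all-agonist arrays it equals the number of receptors.

The discrimination threshold defaults to $\delta x < 0.3\,x_{true}$ and
$\delta\mu_0 < kT\ln 2$ (a twofold uncertainty in total concentration);
the cutoff is configurable, and this default — a 30%/twofold criterion —
was fixed once as the weakest level that still separates the capacity
regimes cleanly. Design evaluations use the default measurement model:
a 9-point dilution ladder log-spaced over $10^{-9}$–$10^{-3}$ M (the
reference point at 1 mM total), 4 replicates, $\sigma = 0.02$ for every
receptor, equal-proportion compositions, and $bg = 0$.

`diagnose_array()` applies the same machinery to a *calibrated* array:
per-mixture determinants and uncertainty forecasts, plus constrained
re-optimizations (efficacies only, then everything) that show which
physical relaxation would most improve the hardware.
`robustness_scan()` quantifies how much of the per-composition optimal
determinant a fixed design retains as the composition sweeps a range —
designed arrays remain near-optimal over roughly tenfold composition
changes, so one design serves a family of mixtures.

## Synthetic data

All datasets used in tests and in the acceptance script are generated
by the package itself (`generate_calibration_curve()`,
`generate_mixture_dataset()`): exact model responses along the ladder
plus iid Gaussian noise, with optional per-plate efficacy scaling and
background shifts emulating plate bias. Noise streams are keyed by
(seed, receptor, plate), so generating a receptor subset reproduces the
full run's records for those receptors exactly. The generator's default
conditions are the study conditions throughout: 9-point million-fold
ladder, 4 replicates ($9\times4 = 36$ points per curve),
$\sigma = 0.02$; the low-noise correspondence suite uses
$\sigma = 0.005$, several-fold below the experimental scale. The
built-in `example_array_params()` is a synthetic stand-in for a
calibrated four-receptor UDP-sugar panel — plausible overlapping
affinities, UDP as a near-universal antagonist — not measured values.

What the generator deliberately does *not* emulate: raw (un-normalized)
fluorescence counts, plate-reader optics, growth effects, receptor
expression variability, multiple binding sites, or binding kinetics.
Passing tests therefore demonstrate correctness of the inference and
design machinery under the stated noise model, not robustness to every
systematic a real plate reader can produce; plate bias is the one
systematic explicitly modelled.

## Numerical choices and problem sizes

* Nested-sampling live points are scaled to the job: 100 by default,
  60 for the many repeated fits in the coverage and trend studies, 150
  with longer walks (40 steps) for essentially noise-free posteriors,
  whose likelihood peaks are extreme; 200 for the evidence oracle and
  the default global design search.
* The coverage study runs 50 calibration replicates (four parameters
  each) plus 12 two-receptor binary-mixture decodes and pools all
  parameters; the correspondence study decodes all 15 equal-proportion
  mixtures of the four-ligand panel once each.
* Capacity is established at one and two receptors (panels up to five
  ligands), each design cell given two independent optimization starts.
* `optim`'s box-constrained quasi-Newton polish runs on a floored
  objective (degenerate determinants mapped to a large negative value)
  with a Nelder–Mead fallback, since the determinant landscape has
  razor edges where a ligand decouples.
* Ties and degeneracies: a ligand with $x_{true} = 0$ is judged against
  the reference scale in threshold checks (its absolute uncertainty
  compared to the reference ligand's unit ratio); occupancy derivatives
  at $x_i = 0$ are computed from the finite ratio $p_i/x_i$ rather than
  the indeterminate quotient.

## Known limitations

* Nested sampling on near-noise-free data converges slowly along the
  likelihood ridge; under-provisioned settings bias posterior summaries
  toward the prior. The defaults above were chosen to avoid this in the
  shipped studies, but very low $\sigma$ with many parameters warrants
  more live points.
* The Hessian forecast is a quadratic approximation at truth; for
  barely-identified parameters (uncertainty comparable to the prior
  width) the sampled posterior is the authority, and the two are only
  expected to *rank* uncertainties consistently.
* `enumerate_optima()` canonicalizes patterns by binarizing efficacies
  at 0.5; designs with genuinely intermediate efficacies would cluster
  coarsely. It is restricted to small problems (≤3 receptors, ≤4
  ligands) where exhaustive multi-start search is meaningful.
* Calibration assumes known totals; decoding assumes calibrated
  parameters are exact (their posterior width is not propagated into
  the mixture posterior).
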