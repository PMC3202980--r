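#' Per-parameter prior specification
#'
#' Two prior families are supported, matching the symmetry of the
#' parameter: `uniform` (invariant under translations — location-like
#' parameters such as binding free energies, efficacies, backgrounds and
#' chemical potentials) and `jeffreys` (invariant under rescaling,
#' density \eqn{\propto 1/\theta} — positive scale parameters such as the
#' noise \eqn{\sigma} and concentration ratios \eqn{x}).
#'
#' @param name Parameter name.
#' @param kind `"uniform"` or `"jeffreys"`.
#' @param lo,hi Bounds in the parameter's units; `lo < hi`, and `lo > 0`
#'   for a Jeffreys prior.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(name, kind = c("uniform", "jeffreys"), lo, hi) {
  kind <- match.arg(kind)
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi) {
    stop("invalid prior bounds for `", name, "`: need lo < hi")
  }
  if (kind == "jeffreys" && lo <= 0) {
    stop("Jeffreys prior for `", name, "` requires lo > 0")
  }
  structure(list(name = name, kind = kind, lo = lo, hi = hi),
            class = "prior_spec")
}

#' Collect prior specifications into a prior set
#'
#' @param ... [prior_spec()] objects (or a single list of them).
#' @return An object of class `prior_set`.
#' @export
prior_set <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "prior_spec")) {
    specs <- specs[[1L]]
  }
  stopifnot(all(vapply(specs, inherits, logical(1), "prior_spec")))
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs))) stop("duplicate parameter names in prior set")
  structure(specs, class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  for (p in x) {
    cat(sprintf("%-12s %-9s [%g, %g]\n", p$name, p$kind, p$lo, p$hi))
  }
  invisible(x)
}

#' Map unit-cube coordinates to parameter values
#'
#' Nested sampling explores the unit hypercube; this applies the inverse
#' CDF of each prior. Uniform priors map linearly; Jeffreys priors map
#' log-uniformly, so unit-cube steps are steps in \eqn{\log\theta}.
#'
#' @param priors A [prior_set()].
#' @param u Numeric vector in `[0, 1]^d` (or a matrix with `d` columns).
#' @return Parameter vector (or matrix) in natural units.
#' @export
prior_transform <- function(priors, u) {
  f <- function(uv) {
    vapply(seq_along(priors), function(k) {
      p <- priors[[k]]
      if (p$kind == "uniform") p$lo + uv[k] * (p$hi - p$lo)
      else p$lo * (p$hi / p$lo)^uv[k]
    }, numeric(1))
  }
  if (is.matrix(u)) {
    out <- apply(u, 1L, f)
    out <- if (length(priors) == 1L) matrix(out, ncol = 1L) else t(out)
    colnames(out) <- names(priors)
    out
  } else {
    stats::setNames(f(u), names(priors))
  }
}

#' Log prior density at a parameter vector
#'
#' @param priors A [prior_set()].
#' @param theta Parameter vector in natural units.
#' @return Log density (`-Inf` outside the bounds).
#' @export
prior_log_density <- function(priors, theta) {
  total <- 0
  for (k in seq_along(priors)) {
    p <- priors[[k]]
    v <- theta[[k]]
    if (v < p$lo || v > p$hi) return(-Inf)
    total <- total + if (p$kind == "uniform") -log(p$hi - p$lo)
                     else -log(v) - log(log(p$hi / p$lo))
  }
  total
}

#' Default priors for single-curve calibration
#'
#' Binding free energy uniform on \[-16, -1\] kcal/mol, efficacy uniform
#' on \[0, 1\], background uniform on \[0, 0.5\], noise Jeffreys on
#' \[5e-3, 0.5\] — wide enough to cover the experimental dynamic range of
#' the reporter assays with margin.
#'
#' @return A [prior_set()] over `(dG, eff, bg, sigma)`.
#' @export
calibration_priors <- function() {
  prior_set(
    prior_spec("dG", "uniform", -16, -1),
    prior_spec("eff", "uniform", 0, 1),
    prior_spec("bg", "uniform", 0, 0.5),
    prior_spec("sigma", "jeffreys", 5e-3, 0.5))
}

#' Default priors for mixture decoding
#'
#' Concentration ratios get Jeffreys priors on \[1e-4, 1e4\] (eight
#' decades, so effectively absent ligands can be represented near the
#' floor), the reference-point total chemical potential a uniform prior
#' over `kT ln` of \[1e-9, 1e-1\] M (a million-fold dilution range with
#' margin), and each receptor's noise a Jeffreys prior on \[5e-3, 0.5\].
#'
#' @param ligand_ids Full ligand panel.
#' @param reference_ligand Reference ligand (excluded: its ratio is 1).
#' @param receptor_ids Receptors whose noise scales are fitted.
#' @param const A [model_constants()] object.
#' @return A [prior_set()] over `(x_<lig>..., mu0, sigma_<rec>...)`.
#' @export
decode_priors <- function(ligand_ids, reference_ligand, receptor_ids,
                          const = model_constants()) {
  specs <- list()
  for (lig in setdiff(ligand_ids, reference_ligand)) {
    specs[[length(specs) + 1L]] <-
      prior_spec(paste0("x_", lig), "jeffreys", 1e-4, 1e4)
  }
  specs[[length(specs) + 1L]] <-
    prior_spec("mu0", "uniform", const$kT * log(1e-9), const$kT * log(1e-1))
  for (r in receptor_ids) {
    specs[[length(specs) + 1L]] <-
      prior_spec(paste0("sigma_", r), "jeffreys", 5e-3, 0.5)
  }
  prior_set(specs)
}
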