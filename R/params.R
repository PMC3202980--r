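#' Calibrated physical description of a receptor array
#'
#' Bundles everything the response model needs about an array: binding free
#' energies \eqn{\Delta G_{ji}} (kcal/mol; more negative = stronger
#' binding), efficacies \eqn{e_{ji}} in \[0, 1\] (1 = full agonist, 0 =
#' full antagonist that occupies the binding site without activating the
#' reporter), per-receptor background intensities and Gaussian noise
#' scales, both in normalized fluorescence units.
#'
#' @param receptor_ids Character vector of receptor labels.
#' @param ligand_ids Character vector of ligand labels.
#' @param dG Numeric matrix `[receptor x ligand]` of binding free energies
#'   (kcal/mol).
#' @param eff Numeric matrix `[receptor x ligand]` of efficacies in \[0, 1\].
#' @param bg Numeric vector `[receptor]` of background intensities, `>= 0`.
#' @param sigma Numeric vector `[receptor]` of noise scales, `> 0`.
#' @return An object of class `array_params`.
#' @seealso [example_array_params()], [write_array_params()]
#' @export
array_params <- function(receptor_ids, ligand_ids, dG, eff, bg, sigma) {
  receptor_ids <- as.character(receptor_ids)
  ligand_ids <- as.character(ligand_ids)
  nr <- length(receptor_ids)
  nl <- length(ligand_ids)
  dG <- as.matrix(dG)
  eff <- as.matrix(eff)
  if (anyDuplicated(receptor_ids) || anyDuplicated(ligand_ids)) {
    stop("receptor and ligand labels must be unique")
  }
  if (!all(dim(dG) == c(nr, nl)) || !all(dim(eff) == c(nr, nl))) {
    stop("`dG` and `eff` must be [receptor x ligand] matrices matching the id lists")
  }
  if (length(bg) != nr || length(sigma) != nr) {
    stop("`bg` and `sigma` must have one entry per receptor")
  }
  if (!all(is.finite(dG)) || !all(is.finite(eff))) {
    stop("`dG` and `eff` must be finite")
  }
  if (any(eff < 0 | eff > 1)) stop("efficacies must lie in [0, 1]")
  if (any(bg < 0)) stop("background intensities must be >= 0")
  if (any(sigma <= 0)) stop("noise scales must be > 0")
  dimnames(dG) <- dimnames(eff) <- list(receptor_ids, ligand_ids)
  structure(
    list(receptor_ids = receptor_ids, ligand_ids = ligand_ids,
         dG = dG, eff = eff,
         bg = stats::setNames(as.numeric(bg), receptor_ids),
         sigma = stats::setNames(as.numeric(sigma), receptor_ids)),
    class = "array_params")
}

#' @export
print.array_params <- function(x, ...) {
  cat("Receptor array:", length(x$receptor_ids), "receptors x",
      length(x$ligand_ids), "ligands\n")
  cat("Binding free energies (kcal/mol):\n")
  print(round(x$dG, 3))
  cat("Efficacies:\n")
  print(round(x$eff, 3))
  cat("Background:", paste(signif(x$bg, 3), collapse = " "),
      "  sigma:", paste(signif(x$sigma, 3), collapse = " "), "\n")
  invisible(x)
}

#' Synthetic example array emulating a four-receptor GPCR panel
#'
#' A synthetic stand-in for a calibrated four-receptor array with
#' overlapping specificities for four UDP-sugar ligands. The fourth ligand
#' (UDP) is a near-full antagonist of every receptor, mirroring the
#' qualitative behaviour of the engineered UDP-glucose receptor panel this
#' package models. The numbers are invented but physically plausible; they
#' are not measurements.
#'
#' @return An [array_params()] object.
#' @export
example_array_params <- function() {
  receptors <- c("H-20", "K-3", "L-3", "2211")
  ligands <- c("UDP-Glc", "UDP-Gal", "UDP-GlcNAc", "UDP")
  dG <- rbind(
    c(-9.5, -8.0, -7.0, -8.5),
    c(-8.0, -9.2, -7.5, -8.8),
    c(-7.2, -7.8, -9.0, -8.2),
    c(-8.6, -8.4, -8.8, -9.0))
  eff <- rbind(
    c(0.95, 0.55, 0.25, 0.05),
    c(0.50, 0.90, 0.35, 0.02),
    c(0.30, 0.45, 0.85, 0.08),
    c(0.70, 0.60, 0.50, 0.04))
  array_params(receptors, ligands, dG, eff,
               bg = c(0.05, 0.04, 0.06, 0.05),
               sigma = rep(0.02, 4))
}

#' Write / read array parameters as JSON
#'
#' @param params An [array_params()] object.
#' @param path File path.
#' @return `write_array_params()` returns `path` invisibly;
#'   `read_array_params()` returns an [array_params()] object.
#' @export
write_array_params <- function(params, path) {
  stopifnot(inherits(params, "array_params"))
  obj <- list(
    receptor_ids = params$receptor_ids,
    ligand_ids = params$ligand_ids,
    dG = unname(params$dG),
    eff = unname(params$eff),
    bg = unname(params$bg),
    sigma = unname(params$sigma))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_array_params
#' @export
read_array_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  array_params(obj$receptor_ids, obj$ligand_ids,
               obj$dG, obj$eff, obj$bg, obj$sigma)
}

#' Mixture composition in relative-concentration form
#'
#' A mixture is described by relative concentrations \eqn{x_i}: each
#' ligand's concentration divided by that of a designated reference
#' ligand, so `x[reference_ligand] == 1` by construction. Together with
#' the total concentration (equivalently the total chemical potential) the
#' relative concentrations determine all absolute concentrations. The
#' choice of reference is arbitrary; see [rereference()].
#'
#' @param ligand_ids Character vector of ligand labels.
#' @param x Numeric vector of relative concentrations, `>= 0`; the entry
#'   for `reference_ligand` must equal 1.
#' @param reference_ligand Label of the reference ligand.
#' @param total_concentration Optional total molar concentration, `> 0`.
#' @return An object of class `mixture_composition`.
#' @export
mixture_composition <- function(ligand_ids, x, reference_ligand,
                                total_concentration = NULL) {
  ligand_ids <- as.character(ligand_ids)
  x <- as.numeric(x)
  if (length(x) != length(ligand_ids)) {
    stop("`x` must have one entry per ligand")
  }
  if (!reference_ligand %in% ligand_ids) {
    stop("`reference_ligand` not among `ligand_ids`")
  }
  if (any(x < 0) || any(!is.finite(x))) stop("`x` must be finite and >= 0")
  names(x) <- ligand_ids
  if (x[reference_ligand] != 1) {
    stop("the reference ligand must have relative concentration exactly 1")
  }
  if (!is.null(total_concentration)) {
    stopifnot(is.numeric(total_concentration), total_concentration > 0)
  }
  structure(list(ligand_ids = ligand_ids, x = x,
                 reference_ligand = reference_ligand,
                 total_concentration = total_concentration),
            class = "mixture_composition")
}

#' Equal-proportion mixture over a set of present ligands
#'
#' @param ligand_ids Full ligand panel.
#' @param present Labels of the ligands present (equal proportions);
#'   others get `x = 0`.
#' @param total_concentration Optional total molar concentration.
#' @return A [mixture_composition()] with the first present ligand as
#'   reference.
#' @export
equal_mixture <- function(ligand_ids, present = ligand_ids,
                          total_concentration = NULL) {
  stopifnot(length(present) >= 1L, all(present %in% ligand_ids))
  x <- as.numeric(ligand_ids %in% present)
  mixture_composition(ligand_ids, x, reference_ligand = present[[1L]],
                      total_concentration = total_concentration)
}

#' @export
print.mixture_composition <- function(x, ...) {
  cat("Mixture (reference:", x$reference_ligand, ")\n")
  print(x$x)
  if (!is.null(x$total_concentration)) {
    cat("Total concentration:", x$total_concentration, "M\n")
  }
  invisible(x)
}
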