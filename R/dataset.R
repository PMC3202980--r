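#' Normalized fluorescence measurements with their dilution ladders
#'
#' A `response_dataset` couples a table of per-record measurements with
#' the [dilution_series()] of every receptor. Records carry: `receptor`,
#' `mixture_id` (a free label: a ligand name for calibration curves, any
#' identifier for mixtures), `point_index` (1-based position in the
#' receptor's series, 1 = reference point), `replicate`, `plate` and
#' `intensity` (normalized fluorescence). `log10_total_conc` is present
#' when absolute total concentrations are known (calibration and synthetic
#' data); it is `NA` for a genuinely unknown mixture.
#'
#' @param records A data.frame with the columns above.
#' @param series A named list of [dilution_series()], one per receptor
#'   appearing in `records`. Per-receptor ladders may differ in range and
#'   length.
#' @return An object of class `response_dataset`.
#' @export
response_dataset <- function(records, series) {
  required <- c("receptor", "mixture_id", "point_index", "replicate",
                "plate", "intensity")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"log10_total_conc" %in% names(records)) {
    records$log10_total_conc <- NA_real_
  }
  records$receptor <- as.character(records$receptor)
  records$mixture_id <- as.character(records$mixture_id)
  records$point_index <- as.integer(records$point_index)
  if (any(!is.finite(records$intensity))) {
    bad <- which(!is.finite(records$intensity))
    stop("non-finite intensity at record row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  recs <- unique(records$receptor)
  if (!all(recs %in% names(series))) {
    stop("no dilution series supplied for receptor(s): ",
         paste(setdiff(recs, names(series)), collapse = ", "))
  }
  for (r in recs) {
    s <- series[[r]]
    stopifnot(inherits(s, "dilution_series"))
    idx <- records$point_index[records$receptor == r]
    if (any(idx < 1L | idx > s$n_points)) {
      stop("point_index out of range for receptor ", r)
    }
  }
  structure(list(records = records[, c(required[1:5], "log10_total_conc",
                                       "intensity")],
                 series = series),
            class = "response_dataset")
}

#' @export
print.response_dataset <- function(x, ...) {
  cat("Response dataset:", nrow(x$records), "records,",
      length(unique(x$records$receptor)), "receptor(s),",
      length(unique(x$records$mixture_id)), "mixture id(s)\n")
  invisible(x)
}

#' Restrict a dataset to a subset of receptors and/or mixtures
#'
#' @param data A [response_dataset()].
#' @param receptors,mixtures Labels to keep (default: all).
#' @return A [response_dataset()].
#' @export
subset_dataset <- function(data, receptors = NULL, mixtures = NULL) {
  rec <- data$records
  if (!is.null(receptors)) rec <- rec[rec$receptor %in% receptors, ]
  if (!is.null(mixtures)) rec <- rec[rec$mixture_id %in% mixtures, ]
  if (nrow(rec) == 0L) stop("subset selects no records")
  response_dataset(rec, data$series[unique(rec$receptor)])
}
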