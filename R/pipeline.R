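#' Run the full constituent-enhancer fingerprint pipeline
#'
#' From a raw CE-by-sample count matrix to cancer-specific fingerprint SEs:
#' replicate aggregation, median-of-ratios normalization, zero imputation,
#' the SE-contribution filter, log2 transform, global mixture priors, per-CE
#' two-component EM state calls, prevalence profiles, prevalence-threshold
#' selection by variation of information, cell- and cancer-specific CE
#' calls, and the per-SE fingerprint summary.
#'
#' Normalization and the global priors use all CE rows (the genome-wide
#' enhancer set supplied); the per-CE models are restricted to CEs passing
#' the contribution filter.
#'
#' @param counts CE x sample raw count matrix (rownames = CE ids).
#' @param sheet sample sheet (see [read_sample_sheet()]).
#' @param map CE-to-SE assignment from [assign_ce_to_se()] covering every
#'   counts row.
#' @param threshold `"auto"` (variation-of-information selection) or a fixed
#'   prevalence threshold.
#' @param contribution_threshold SE-contribution filter cutoff.
#' @param se_regions,ce_regions optional unified `GRanges`; when both are
#'   supplied a [build_fingerprint_db()] database is attached to the result.
#' @param genes optional gene table for the database.
#' @param grid,smooth_window threshold-scan controls (see
#'   [select_threshold()]).
#' @param tol,max_iter EM controls (see [em_fit()]).
#' @return list with every stage: `aggregated`, `normalized`, `imputed`,
#'   `log2`, `contribution` (filter output), `priors`, `fits`, `states`,
#'   `classes`, `profiles`, `scan` (`NULL` for fixed thresholds),
#'   `threshold`, `cell_calls`, `cancer_calls`, `se_summary`, `db`.
#' @export
run_fingerprint_pipeline <- function(counts, sheet, map,
                                     threshold = "auto",
                                     contribution_threshold = 0.03,
                                     se_regions = NULL, ce_regions = NULL,
                                     genes = NULL,
                                     grid = seq(0, 0.5, by = 0.01),
                                     smooth_window = 11,
                                     tol = 1e-8, max_iter = 1000) {
  sheet <- validate_sample_sheet(sheet)
  raw <- activity_matrix(counts, stage = "raw")
  aggregated <- aggregate_replicates(raw, sheet)
  normalized <- rle_normalize(aggregated)
  imputed <- impute_zeros(normalized)
  contribution <- se_contribution_filter(imputed, map,
                                         threshold = contribution_threshold)
  lg <- log2_transform(imputed)
  priors <- fit_global_priors(lg, tol = tol, max_iter = max_iter)

  keep <- rownames(lg$values) %in% contribution$retained
  lg_sel <- activity_matrix(lg$values[keep, , drop = FALSE], stage = "log2",
                            zero_mask = lg$zero_mask[keep, , drop = FALSE],
                            size_factors = lg$size_factors)
  fit <- fit_ce_states(lg_sel, priors, tol = tol, max_iter = max_iter)
  states <- fit$states
  classes <- classify_ce(states)
  profiles <- compute_prevalence(states)

  true_labels <- sheet$cancer_type[!duplicated(sheet$cell_line)]
  names(true_labels) <- sheet$cell_line[!duplicated(sheet$cell_line)]
  true_labels <- true_labels[colnames(states)]

  scan <- NULL
  if (identical(threshold, "auto")) {
    scan <- select_threshold(profiles, lg_sel, true_labels,
                             grid = grid, smooth_window = smooth_window)
    threshold <- scan$threshold
  }
  cell_calls <- call_cell_specific(profiles, states, threshold)
  cancer_calls <- call_cancer_specific(cell_calls, sheet)
  se_summary <- summarize_cancer_specific_se(cancer_calls, map)

  db <- NULL
  if (!is.null(se_regions) && !is.null(ce_regions)) {
    db <- build_fingerprint_db(
      se_regions = se_regions, ce_regions = ce_regions, map = map,
      states = states, cell_calls = cell_calls,
      cancer_calls = cancer_calls, se_summary = se_summary, sheet = sheet,
      genes = genes,
      params = list(threshold = threshold,
                    contribution_threshold = contribution_threshold,
                    tol = tol, max_iter = max_iter))
  }
  list(aggregated = aggregated, normalized = normalized, imputed = imputed,
       log2 = lg, contribution = contribution, priors = priors,
       fits = fit$fits, states = states, classes = classes,
       profiles = profiles, scan = scan, threshold = threshold,
       cell_calls = cell_calls, cancer_calls = cancer_calls,
       se_summary = se_summary, db = db)
}
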