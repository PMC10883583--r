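#' Enhancer activity matrix container
#'
#' A light container for the regions-by-columns activity matrix as it moves
#' through the pipeline stages `raw` (per-sample counts), `aggregated`
#' (summed replicates, one column per cell line), `normalized`
#' (median-of-ratios size factors applied), `imputed` (zeros replaced) and
#' `log2`.
#'
#' @param values numeric matrix, region ids as rownames, sample/cell-line ids
#'   as colnames; non-negative.
#' @param stage pipeline stage.
#' @param zero_mask logical matrix marking pre-imputation zeros (recorded at
#'   the normalized stage and carried forward).
#' @param size_factors positive per-column scalars (normalized stage onward).
#' @return an `ActivityMatrix` object.
#' @export
activity_matrix <- function(values, stage = c("raw", "aggregated",
                                              "normalized", "imputed", "log2"),
                            zero_mask = NULL, size_factors = NULL) {
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have region rownames and column names")
  if (stage != "log2" && any(values < 0))
    stop("activity values must be non-negative")
  if (stage == "imputed" && any(values <= 0))
    stop("imputed values must be strictly positive")
  if (!is.null(zero_mask) && !identical(dim(zero_mask), dim(values)))
    stop("zero_mask must match the matrix dimensions")
  if (!is.null(size_factors)) {
    if (length(size_factors) != ncol(values) || any(size_factors <= 0))
      stop("size_factors must be positive, one per column")
    names(size_factors) <- colnames(values)
  }
  structure(list(values = values, stage = stage, zero_mask = zero_mask,
                 size_factors = size_factors),
            class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix [%s]: %d regions x %d columns\n",
              x$stage, nrow(x$values), ncol(x$values)))
  if (!is.null(x$size_factors))
    cat("  size factors: ",
        paste(sprintf("%.3g", utils::head(x$size_factors, 5)), collapse = ", "),
        if (length(x$size_factors) > 5) ", ..." else "", "\n", sep = "")
  if (!is.null(x$zero_mask))
    cat(sprintf("  pre-imputation zeros: %d\n", sum(x$zero_mask)))
  invisible(x)
}

#' Summarize per-base coverage tracks over unified regions
#'
#' Entry (r, s) is the total coverage (sum of per-base depth) of sample s's
#' track within region r — the bedGraph equivalent of counting reads at the
#' unified enhancer regions. A region on a chromosome absent from a track
#' scores 0 with a warning.
#'
#' @param regions unified `GRanges` with `region_id` metadata (or ids derived
#'   from coordinates).
#' @param tracks named list of coverage `GRanges` (e.g. from
#'   [read_bedgraph()]), one per sample, each with a numeric `score`.
#' @return raw-stage [activity_matrix()].
#' @export
summarize_coverage <- function(regions, tracks) {
  regions <- .validate_regions(regions)
  if (is.null(names(tracks)) || any(names(tracks) == ""))
    stop("'tracks' must be a named list (one coverage track per sample)")
  ids <- .region_ids(regions, "region")
  vals <- vapply(names(tracks), function(s) {
    tr <- tracks[[s]]
    out <- numeric(length(regions))
    if (length(tr) == 0L) return(out)
    missing_chr <- setdiff(unique(as.character(GenomicRanges::seqnames(regions))),
                           unique(as.character(GenomicRanges::seqnames(tr))))
    if (length(missing_chr))
      warning(sprintf("track '%s' lacks chromosomes: %s (regions scored 0)",
                      s, paste(missing_chr, collapse = ", ")))
    ## seqlevel-mismatch warnings are redundant with the explicit one above
    hits <- suppressWarnings(GenomicRanges::findOverlaps(regions, tr))
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); j <- S4Vectors::subjectHits(hits)
      ov <- BiocGenerics::width(IRanges::pintersect(
        GenomicRanges::ranges(regions)[q], GenomicRanges::ranges(tr)[j]))
      contrib <- as.numeric(ov) * tr$score[j]
      agg <- tapply(contrib, q, sum)
      out[as.integer(names(agg))] <- as.numeric(agg)
    }
    out
  }, numeric(length(regions)))
  vals <- matrix(vals, nrow = length(regions),
                 dimnames = list(ids, names(tracks)))
  activity_matrix(vals, stage = "raw")
}

#' Aggregate replicate samples into cell-line columns
#'
#' @param m raw-stage [activity_matrix()] with one column per sample.
#' @param sheet sample sheet (see [read_sample_sheet()]); every matrix column
#'   must appear in `sheet$sample_id`.
#' @param fun `"sum"` (default; preserves count semantics for the
#'   median-of-ratios normalization) or `"mean"`.
#' @return aggregated-stage [activity_matrix()], one column per cell line, in
#'   sheet order of first appearance.
#' @export
aggregate_replicates <- function(m, sheet, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  stopifnot(inherits(m, "ActivityMatrix"))
  sheet <- validate_sample_sheet(sheet)
  missing <- setdiff(colnames(m$values), sheet$sample_id)
  if (length(missing))
    stop("matrix columns absent from sample sheet: ",
         paste(missing, collapse = ", "))
  cl_of <- stats::setNames(sheet$cell_line, sheet$sample_id)
  cls <- unique(cl_of[colnames(m$values)])
  agg <- vapply(cls, function(cl) {
    cols <- colnames(m$values)[cl_of[colnames(m$values)] == cl]
    v <- rowSums(m$values[, cols, drop = FALSE])
    if (fun == "mean") v <- v / length(cols)
    v
  }, numeric(nrow(m$values)))
  agg <- matrix(agg, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), cls))
  activity_matrix(agg, stage = "aggregated")
}

#' Median-of-ratios (RLE) size factors
#'
#' Re-implementation of relative-log-expression normalization: the size
#' factor of column j is the median, over regions whose values are positive
#' in every column, of the ratio of the region's value in column j to the
#' region's geometric mean across columns. Every value is then divided by its
#' column's size factor; rows containing zeros are excluded from the
#' median/geometric-mean computation but are still normalized.
#'
#' The zero mask (pre-imputation zeros) is recorded on the result for
#' downstream exclusion from global prior fits.
#'
#' @param m aggregated-stage (or raw-stage) [activity_matrix()].
#' @return normalized-stage [activity_matrix()] with `size_factors` and
#'   `zero_mask` populated.
#' @export
rle_normalize <- function(m) {
  stopifnot(inherits(m, "ActivityMatrix"))
  v <- m$values
  if (ncol(v) < 1L) stop("matrix has no columns")
  log_geo <- rowMeans(log(v))
  ok <- is.finite(log_geo)
  if (!any(ok))
    stop("cannot compute size factors: no region has positive values in all columns")
  sf <- apply(v, 2, function(col) exp(stats::median(log(col[ok]) - log_geo[ok])))
  norm <- sweep(v, 2, sf, "/")
  activity_matrix(norm, stage = "normalized", zero_mask = norm == 0,
                  size_factors = sf)
}

#' Replace zeros with half the column-wise minimum positive value
#'
#' For each column (cell line), every zero becomes 0.5 x the minimum positive
#' value of that column; non-zero values are untouched. The pre-imputation
#' zero mask is preserved for downstream exclusion from global prior fits.
#'
#' @param m normalized-stage [activity_matrix()].
#' @return imputed-stage [activity_matrix()].
#' @export
impute_zeros <- function(m) {
  stopifnot(inherits(m, "ActivityMatrix"))
  v <- m$values
  mask <- if (is.null(m$zero_mask)) v == 0 else m$zero_mask
  for (j in seq_len(ncol(v))) {
    zi <- v[, j] == 0
    if (!any(zi)) next
    pos <- v[, j][!zi]
    if (length(pos) == 0L)
      stop("column '", colnames(v)[j],
           "' is entirely zero; no minimum positive value exists")
    v[zi, j] <- 0.5 * min(pos)
  }
  activity_matrix(v, stage = "imputed", zero_mask = mask,
                  size_factors = m$size_factors)
}

#' log2-transform an imputed activity matrix
#'
#' Applied after imputation so all values are positive; no pseudocount.
#'
#' @param m imputed-stage [activity_matrix()] (or any all-positive matrix).
#' @return log2-stage [activity_matrix()].
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "ActivityMatrix"))
  if (any(m$values <= 0))
    stop("log2 transform requires strictly positive values; impute first")
  out <- activity_matrix(log2(m$values), stage = "log2",
                         zero_mask = m$zero_mask,
                         size_factors = m$size_factors)
  out
}

#' Filter constituent enhancers by contribution to SE activity
#'
#' A CE passes in a cell line when its activity exceeds `threshold` (default
#' 3%) of the total activity of its parent SE (the sum over the SE's member
#' CEs) in that cell line. A CE is retained in the candidate list if it
#' passes in at least one cell line. An SE total of 0 in a cell line fails
#' all of its CEs there.
#'
#' @param ce_matrix [activity_matrix()] with CE rows (any positive stage).
#' @param map CE-to-SE assignment from [assign_ce_to_se()]; every CE row must
#'   be mapped.
#' @param threshold contribution fraction, strict `>` comparison.
#' @return list with `mask` (logical CE x cell-line matrix), `retained`
#'   (character vector of CE ids passing anywhere), and `contribution`
#'   (the ratio matrix).
#' @export
se_contribution_filter <- function(ce_matrix, map, threshold = 0.03) {
  stopifnot(inherits(ce_matrix, "ActivityMatrix"))
  if (ce_matrix$stage == "log2")
    stop("contribution filter operates on linear-scale activities")
  v <- ce_matrix$values
  se_of <- stats::setNames(map$se_id, map$ce_id)
  missing <- setdiff(rownames(v), map$ce_id)
  if (length(missing))
    stop("CE rows absent from CE-to-SE map: ", paste(missing, collapse = ", "))
  se <- se_of[rownames(v)]
  if (anyNA(se))
    stop("every CE row must be assigned to an SE before filtering")
  totals <- rowsum(v, group = se)                  # SE x cell line
  denom <- totals[se, , drop = FALSE]
  contribution <- v / denom
  contribution[denom == 0] <- 0
  mask <- contribution > threshold
  dimnames(mask) <- dimnames(v)
  list(mask = mask,
       retained = rownames(v)[rowSums(mask) > 0],
       contribution = contribution)
}

#' Per-kilobase enhancer activity
#'
#' Normalizes a total signal over a region by region width: signal / width x
#' 1000. Used to compare enhancer strength across regions of different size
#' (e.g. STARR-seq or nascent-RNA coverage at CEs).
#'
#' @param signal non-negative total signal(s).
#' @param width region width(s) in bp, positive.
#' @return per-kilobase activity.
#' @export
activity_per_kb <- function(signal, width) {
  if (any(width <= 0)) stop("width must be positive")
  if (any(signal < 0)) stop("signal must be non-negative")
  signal / width * 1000
}
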