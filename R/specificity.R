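#' Active/inactive prevalence per constituent enhancer
#'
#' Active prevalence is the fraction of cell lines in which the CE is called
#' active; inactive prevalence is its complement.
#'
#' @param states logical state matrix (CE x cell lines, TRUE = active).
#' @return data.frame with `ce_id`, `n_active`, `active_prevalence`,
#'   `inactive_prevalence`.
#' @export
compute_prevalence <- function(states) {
  if (anyNA(states)) stop("state matrix must be complete")
  n_active <- rowSums(states)
  data.frame(ce_id = rownames(states),
             n_active = as.integer(n_active),
             active_prevalence = n_active / ncol(states),
             inactive_prevalence = 1 - n_active / ncol(states),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Variation of information between two partitions
#'
#' The information-theoretic metric distance VI(A, B) = H(A) + H(B) -
#' 2 I(A; B), computed from the contingency table of the two labelings in
#' natural-log units. VI is 0 iff the partitions are identical up to label
#' renaming, symmetric, and satisfies the triangle inequality.
#'
#' @param labels_a,labels_b cluster labelings of the same items (equal
#'   length; any atomic type).
#' @return non-negative VI distance in nats.
#' @export
variation_of_information <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("partitions must label the same item set")
  n <- length(labels_a)
  if (n == 0L) stop("empty partitions")
  tab <- table(labels_a, labels_b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- sum(tab * log(tab / outer(pa, pb)), na.rm = TRUE)
  max(0, ent(pa) + ent(pb) - 2 * mi)
}

#' Hierarchical clustering of cell lines on selected CE activities
#'
#' Agglomerative clustering of the cell-line columns on Euclidean distance
#' between log2 activity profiles, Ward linkage, tree cut into `k` groups.
#' Deterministic for fixed input.
#'
#' @param m log2 activity matrix (CE rows x cell-line columns) or a log2
#'   [activity_matrix()]; must have at least one row.
#' @param k number of clusters (typically the number of distinct cancer
#'   types present).
#' @param dist_method,linkage distance and linkage passed to [stats::dist()]
#'   and [stats::hclust()].
#' @return integer cluster membership named by cell line.
#' @export
cluster_cells <- function(m, k, dist_method = "euclidean",
                          linkage = "ward.D2") {
  v <- if (inherits(m, "ActivityMatrix")) m$values else m
  if (!is.matrix(v) || nrow(v) == 0L)
    stop("need at least one selected CE to cluster on")
  k <- max(1L, min(as.integer(k), ncol(v)))
  hc <- stats::hclust(stats::dist(t(v), method = dist_method),
                      method = linkage)
  stats::cutree(hc, k = k)
}

#' Prevalence-threshold selection by variation of information
#'
#' Scans candidate prevalence cutoffs (0 to 0.5, step 0.01 by default). At
#' each cutoff the CEs with active prevalence strictly below it are selected,
#' the cell lines are clustered on those CEs' log2 activities
#' ([cluster_cells()], k = number of distinct cancer types), and the
#' clustering is compared with the true cancer-type labels by
#' [variation_of_information()]. Cutoffs selecting zero CEs score the VI of
#' the single-cluster partition (maximal uninformativeness).
#'
#' Both axes of the (cutoff, VI) curve are min-max scaled to `[0, 1]`, the VI
#' curve is smoothed with a local quadratic (Savitzky-Golay) filter over
#' `smooth_window` grid points, and the selected threshold is the largest
#' cutoff at which the smoothed scaled slope is still at or below -1 — the
#' inflection point balancing clustering quality against CE specificity. If
#' the slope never reaches -1 the fallback picks the cutoff minimizing
#' (scaled VI + scaled cutoff), the point closest to the ideal corner, with
#' a warning.
#'
#' @param profiles prevalence table from [compute_prevalence()].
#' @param m log2 [activity_matrix()] (or matrix) over the same CEs.
#' @param true_labels cancer-type label per cell-line column of `m`.
#' @param grid increasing cutoff grid.
#' @param smooth_window odd number of grid points for the local quadratic
#'   smoother.
#' @param k clusters to cut; defaults to the number of distinct true labels.
#' @param ... passed to [cluster_cells()].
#' @return a `ThresholdScan` list: `scan` (data.frame cutoff / n_selected /
#'   vi / vi_scaled_smooth / slope), `threshold`, `method`
#'   (`"slope"` or `"corner-fallback"`).
#' @export
select_threshold <- function(profiles, m, true_labels,
                             grid = seq(0, 0.5, by = 0.01),
                             smooth_window = 11,
                             k = length(unique(true_labels)), ...) {
  v <- if (inherits(m, "ActivityMatrix")) m$values else m
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  if (length(true_labels) != ncol(v))
    stop("true_labels must match the matrix columns")
  missing <- setdiff(profiles$ce_id, rownames(v))
  if (length(missing)) stop("profiles reference CEs absent from the matrix")
  single <- rep(1L, ncol(v))
  res <- lapply(grid, function(cutoff) {
    sel <- profiles$ce_id[profiles$active_prevalence < cutoff]
    part <- if (length(sel) == 0L) single
            else cluster_cells(v[sel, , drop = FALSE], k = k, ...)
    data.frame(cutoff = cutoff, n_selected = length(sel),
               vi = variation_of_information(part, true_labels))
  })
  scan <- do.call(rbind, res)
  sel <- .threshold_from_curve(scan$cutoff, scan$vi, smooth_window)
  scan$vi_scaled_smooth <- sel$smooth
  scan$slope <- sel$slope
  structure(list(scan = scan, threshold = sel$threshold,
                 method = sel$method),
            class = "ThresholdScan")
}

## min-max scale both axes, smooth VI with a local quadratic, and apply the
## slope = -1 inflection rule (fallback: closest-to-corner)
.threshold_from_curve <- function(cutoff, vi, smooth_window) {
  x <- (cutoff - min(cutoff)) / diff(range(cutoff))
  vi_range <- diff(range(vi))
  if (vi_range > 0) {
    y <- (vi - min(vi)) / vi_range
    ys <- .sg_smooth(y, smooth_window)
    slope <- .gradient(ys, x)
  } else {
    ys <- rep(0, length(x))
    slope <- rep(0, length(x))
  }
  at <- which(slope <= -1 + 1e-8)
  if (length(at)) {
    list(threshold = cutoff[max(at)], method = "slope",
         smooth = ys, slope = slope)
  } else {
    warning("smoothed VI slope never reached -1; using closest-to-corner fallback")
    list(threshold = cutoff[which.min(ys + x)], method = "corner-fallback",
         smooth = ys, slope = slope)
  }
}

.sg_smooth <- function(y, window) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window >= length(y)) return(y)
  as.numeric(signal::sgolayfilt(y, p = 2, n = window))
}

.gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    g[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  g
}

#' @export
print.ThresholdScan <- function(x, ...) {
  cat(sprintf("ThresholdScan: %d cutoffs, selected threshold %.2f (%s)\n",
              nrow(x$scan), x$threshold, x$method))
  invisible(x)
}

#' Cell-specific CE calls at a prevalence threshold
#'
#' A CE is specific-active when its active prevalence is strictly below the
#' threshold (and positive: the rare active cell lines are the call's cells);
#' specific-inactive mirrors the rule on inactive prevalence. The same
#' threshold is used for both modes.
#'
#' @param profiles prevalence table from [compute_prevalence()].
#' @param states logical state matrix (CE x cell lines).
#' @param threshold prevalence threshold (strict `<`).
#' @return data.frame with `ce_id`, `mode` (`specific_active` /
#'   `specific_inactive`), `prevalence`, and `cells` (comma-separated
#'   minority cell lines).
#' @export
call_cell_specific <- function(profiles, states, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  rows <- list()
  for (mode in c("specific_active", "specific_inactive")) {
    prev <- if (mode == "specific_active") profiles$active_prevalence
            else profiles$inactive_prevalence
    hit <- prev < threshold & prev > 0
    if (!any(hit)) next
    ids <- profiles$ce_id[hit]
    cells <- vapply(ids, function(ce) {
      s <- states[ce, ]
      paste(colnames(states)[if (mode == "specific_active") s else !s],
            collapse = ",")
    }, character(1))
    rows[[mode]] <- data.frame(ce_id = ids, mode = mode,
                               prevalence = prev[hit], cells = unname(cells),
                               stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(ce_id = character(0), mode = character(0),
                      prevalence = numeric(0), cells = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Promote cell-specific CEs to cancer-specific CEs
#'
#' A cancer type is attached to a call when at least two of its cell lines
#' carry the call's minority state, or when the cancer has exactly one cell
#' line in the panel and that line carries the state. Calls with no attached
#' cancer are dropped from the cancer-specific table (they remain
#' cell-specific).
#'
#' @param calls cell-specific call table from [call_cell_specific()].
#' @param sheet sample sheet (cell_line -> cancer_type mapping).
#' @return data.frame with `ce_id`, `mode`, `cancer_type`, `n_cells`,
#'   `cells` (the call's cell lines of that cancer).
#' @export
call_cancer_specific <- function(calls, sheet) {
  sheet <- validate_sample_sheet(sheet)
  panel <- unique(sheet[c("cell_line", "cancer_type")])
  panel_size <- table(panel$cancer_type)
  cancer_of <- stats::setNames(panel$cancer_type, panel$cell_line)
  rows <- list()
  for (i in seq_len(nrow(calls))) {
    cells <- strsplit(calls$cells[i], ",", fixed = TRUE)[[1]]
    unknown <- setdiff(cells, names(cancer_of))
    if (length(unknown))
      stop("cell lines absent from sample sheet: ",
           paste(unknown, collapse = ", "))
    hits <- table(cancer_of[cells])
    ok <- names(hits)[hits >= 2L |
                        (hits == 1L & panel_size[names(hits)] == 1L)]
    for (cancer in ok) {
      cc <- cells[cancer_of[cells] == cancer]
      rows[[length(rows) + 1L]] <- data.frame(
        ce_id = calls$ce_id[i], mode = calls$mode[i], cancer_type = cancer,
        n_cells = length(cc), cells = paste(sort(cc), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(ce_id = character(0), mode = character(0),
                      cancer_type = character(0), n_cells = integer(0),
                      cells = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize cancer-specific SEs from their CE calls
#'
#' Each SE containing at least one cancer-specific CE is a fingerprint SE.
#' The per-(SE, cancer) table lists the SE's specific-active and
#' specific-inactive CEs for that cancer (an SE may be specific to several
#' cancers and is listed once per cancer). Each SE also gets an overall
#' category: `both` (holds specific-active and specific-inactive CEs),
#' `active_only`, `inactive_only`, or `none`.
#'
#' @param cancer_ces cancer-specific CE table from [call_cancer_specific()].
#' @param map CE-to-SE assignment from [assign_ce_to_se()]; CEs without an
#'   SE assignment are excluded with a warning.
#' @return list with `per_cancer` (data.frame se_id / cancer_type / mode /
#'   n_ces / ce_ids) and `category` (data.frame se_id / category covering
#'   every SE in `map`).
#' @export
summarize_cancer_specific_se <- function(cancer_ces, map) {
  se_of <- stats::setNames(map$se_id, map$ce_id)
  all_ses <- sort(unique(stats::na.omit(map$se_id)))
  ces <- cancer_ces
  if (nrow(ces)) {
    unmapped <- is.na(se_of[ces$ce_id])
    if (any(unmapped)) {
      warning("dropping cancer-specific CEs without an SE assignment: ",
              paste(unique(ces$ce_id[unmapped]), collapse = ", "))
      ces <- ces[!unmapped, , drop = FALSE]
    }
  }
  if (nrow(ces)) {
    ces$se_id <- unname(se_of[ces$ce_id])
    key <- interaction(ces$se_id, ces$cancer_type, ces$mode, drop = TRUE)
    per_cancer <- do.call(rbind, lapply(split(ces, key), function(g)
      data.frame(se_id = g$se_id[1], cancer_type = g$cancer_type[1],
                 mode = g$mode[1], n_ces = length(unique(g$ce_id)),
                 ce_ids = paste(sort(unique(g$ce_id)), collapse = ","),
                 stringsAsFactors = FALSE)))
    per_cancer <- per_cancer[order(per_cancer$se_id, per_cancer$cancer_type,
                                   per_cancer$mode), , drop = FALSE]
    rownames(per_cancer) <- NULL
  } else {
    per_cancer <- data.frame(se_id = character(0), cancer_type = character(0),
                             mode = character(0), n_ces = integer(0),
                             ce_ids = character(0), stringsAsFactors = FALSE)
  }
  has_active <- all_ses %in% per_cancer$se_id[per_cancer$mode == "specific_active"]
  has_inactive <- all_ses %in% per_cancer$se_id[per_cancer$mode == "specific_inactive"]
  category <- rep("none", length(all_ses))
  category[has_active & !has_inactive] <- "active_only"
  category[!has_active & has_inactive] <- "inactive_only"
  category[has_active & has_inactive] <- "both"
  list(per_cancer = per_cancer,
       category = data.frame(se_id = all_ses, category = category,
                             stringsAsFactors = FALSE))
}
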