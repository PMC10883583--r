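#' Build a fingerprint database from pipeline outputs
#'
#' Bundles the unified regions, CE-to-SE map, state matrix, specificity
#' calls, SE summary and sample sheet into one integrity-checked object
#' supporting the four query modes (cancer type, cell line, gene, location)
#' and round-trippable serialization.
#'
#' @param se_regions,ce_regions unified `GRanges` from [merge_regions()].
#' @param map CE-to-SE assignment from [assign_ce_to_se()].
#' @param states logical state matrix (CE x cell lines).
#' @param cell_calls cell-specific call table from [call_cell_specific()].
#' @param cancer_calls cancer-specific CE table from [call_cancer_specific()].
#' @param se_summary SE summary from [summarize_cancer_specific_se()].
#' @param sheet sample sheet.
#' @param genes optional gene/TSS table: data.frame with `gene`, `chrom`,
#'   `tss` (1-based position) and optionally `strand`, `start`, `end`.
#' @param params named list of provenance metadata (thresholds, cutoffs,
#'   seeds, versions) stored verbatim.
#' @return a `FingerprintDB` object.
#' @export
build_fingerprint_db <- function(se_regions, ce_regions, map, states,
                                 cell_calls, cancer_calls, se_summary,
                                 sheet, genes = NULL, params = list()) {
  sheet <- validate_sample_sheet(sheet)
  ce_ids <- .region_ids(ce_regions, "ce")
  se_ids <- .region_ids(se_regions, "se")
  bad <- setdiff(map$ce_id, ce_ids)
  if (length(bad)) stop("map references unknown CEs: ", paste(bad, collapse = ", "))
  bad <- setdiff(stats::na.omit(map$se_id), se_ids)
  if (length(bad)) stop("map references unknown SEs: ", paste(bad, collapse = ", "))
  for (tab in list(cell_calls, cancer_calls)) {
    bad <- setdiff(tab$ce_id, ce_ids)
    if (length(bad))
      stop("calls reference unknown CEs: ", paste(bad, collapse = ", "))
  }
  bad <- setdiff(cancer_calls$ce_id, map$ce_id[!is.na(map$se_id)])
  if (length(bad))
    stop("cancer-specific CEs lack an SE assignment: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(rownames(states), ce_ids)
  if (length(bad))
    stop("state matrix references unknown CEs: ", paste(bad, collapse = ", "))
  if (!is.null(genes)) {
    req <- c("gene", "chrom", "tss")
    if (!all(req %in% names(genes)))
      stop("gene table needs columns: ", paste(req, collapse = ", "))
  }
  structure(list(
    se_regions = se_regions, ce_regions = ce_regions, map = map,
    states = states, cell_calls = cell_calls, cancer_calls = cancer_calls,
    se_summary = se_summary, sheet = sheet, genes = genes,
    params = params), class = "FingerprintDB")
}

#' @export
print.FingerprintDB <- function(x, ...) {
  cat(sprintf(paste0("FingerprintDB: %d SEs, %d CEs, %d cell lines / %d cancers\n",
                     "  %d cell-specific CE calls, %d cancer-specific CE calls, %d fingerprint SEs\n"),
              length(x$se_regions), length(x$ce_regions),
              length(unique(x$sheet$cell_line)),
              length(unique(x$sheet$cancer_type)),
              nrow(x$cell_calls), nrow(x$cancer_calls),
              sum(x$se_summary$category$category != "none")))
  invisible(x)
}

.regions_to_df <- function(gr) {
  mc <- S4Vectors::mcols(gr)
  data.frame(
    region_id = as.character(mc$region_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    region_class = as.character(mc$region_class),
    n_members = if (is.null(mc$n_members)) rep(1L, length(gr)) else mc$n_members,
    members = if (is.null(mc$members)) rep(".", length(gr))
              else vapply(mc$members, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
}

.df_to_regions <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    region_id = df$region_id, region_class = df$region_class,
    n_members = as.integer(df$n_members),
    members = IRanges::CharacterList(strsplit(df$members, ";", fixed = TRUE)))
  gr
}

#' Save / load a fingerprint database
#'
#' The database is stored as a plain JSON + TSV bundle (one directory) with
#' deterministic field ordering, so identical inputs serialize
#' byte-identically and the bundle diffs cleanly.
#'
#' @param db `FingerprintDB`.
#' @param dir bundle directory (created if needed).
#' @return `save_fingerprint_db()` returns `dir` invisibly;
#'   `load_fingerprint_db()` returns the reconstructed `FingerprintDB`.
#' @export
save_fingerprint_db <- function(db, dir) {
  stopifnot(inherits(db, "FingerprintDB"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(.regions_to_df(db$se_regions), "se_regions.tsv")
  wt(.regions_to_df(db$ce_regions), "ce_regions.tsv")
  wt(db$map, "ce_se_map.tsv")
  states <- data.frame(ce_id = rownames(db$states),
                       db$states * 1L, check.names = FALSE)
  wt(states, "states.tsv")
  wt(db$cell_calls, "cell_calls.tsv")
  wt(db$cancer_calls, "cancer_calls.tsv")
  wt(db$se_summary$per_cancer, "se_summary_per_cancer.tsv")
  wt(db$se_summary$category, "se_summary_category.tsv")
  wt(db$sheet, "sample_sheet.tsv")
  if (!is.null(db$genes)) wt(db$genes, "genes.tsv")
  meta <- list(format = "SEfingerprint-db", version = 1L,
               has_genes = !is.null(db$genes), params = db$params)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_fingerprint_db
#' @export
load_fingerprint_db <- function(dir) {
  rt <- function(f, cls = NA) utils::read.table(
    file.path(dir, f), header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = cls)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "SEfingerprint-db"))
    stop("not a fingerprint database bundle: ", dir)
  states_df <- rt("states.tsv")
  states <- as.matrix(states_df[, -1, drop = FALSE]) == 1L
  rownames(states) <- states_df$ce_id
  cell_calls <- rt("cell_calls.tsv",
                   c(ce_id = "character", mode = "character",
                     prevalence = "numeric", cells = "character"))
  cancer_calls <- rt("cancer_calls.tsv",
                     c(ce_id = "character", mode = "character",
                       cancer_type = "character", n_cells = "integer",
                       cells = "character"))
  build_fingerprint_db(
    se_regions = .df_to_regions(rt("se_regions.tsv")),
    ce_regions = .df_to_regions(rt("ce_regions.tsv")),
    map = rt("ce_se_map.tsv"),
    states = states,
    cell_calls = cell_calls,
    cancer_calls = cancer_calls,
    se_summary = list(per_cancer = rt("se_summary_per_cancer.tsv"),
                      category = rt("se_summary_category.tsv")),
    sheet = rt("sample_sheet.tsv"),
    genes = if (isTRUE(meta$has_genes)) rt("genes.tsv") else NULL,
    params = meta$params)
}

#' Query the fingerprint database
#'
#' Four query modes:
#' \describe{
#'   \item{cancer}{all (SE, mode) records attached to the cancer type, with
#'     their contributing cancer-specific CEs.}
#'   \item{cell}{all cell-specific CE calls whose minority cell set contains
#'     the cell line, with their parent SEs.}
#'   \item{gene}{SEs near the gene: within `window` bp of its TSS or
#'     overlapping the gene body (when `start`/`end` are present in the gene
#'     table).}
#'   \item{location}{SEs intersecting the interval `"chrom:start-end"`
#'     (1-based, inclusive), with their per-cancer CE statuses.}
#' }
#' Unknown cancer/cell/gene keys return an empty result with a warning;
#' malformed locations are an error.
#'
#' @param db `FingerprintDB`.
#' @param mode query mode.
#' @param key query key (cancer type, cell line, gene symbol, or location
#'   string).
#' @param window gene-mode proximity window around the TSS, bp.
#' @return data.frame of matching records (shape depends on mode).
#' @export
query_fingerprint <- function(db, mode = c("cancer", "cell", "gene",
                                           "location"),
                              key, window = 50000) {
  stopifnot(inherits(db, "FingerprintDB"))
  mode <- match.arg(mode)
  switch(mode,
    cancer = {
      if (!key %in% db$sheet$cancer_type)
        warning("unknown cancer type: ", key)
      out <- db$se_summary$per_cancer
      out[out$cancer_type == key, , drop = FALSE]
    },
    cell = {
      if (!key %in% db$sheet$cell_line)
        warning("unknown cell line: ", key)
      calls <- db$cell_calls
      hit <- vapply(strsplit(calls$cells, ",", fixed = TRUE),
                    function(cc) key %in% cc, logical(1))
      out <- calls[hit, , drop = FALSE]
      se_of <- stats::setNames(db$map$se_id, db$map$ce_id)
      out$se_id <- unname(se_of[out$ce_id])
      rownames(out) <- NULL
      out
    },
    gene = {
      if (is.null(db$genes))
        stop("gene queries require a gene table in the database")
      g <- db$genes[db$genes$gene == key, , drop = FALSE]
      if (nrow(g) == 0L) {
        warning("unknown gene: ", key)
        return(.se_records(db, character(0)))
      }
      tss_win <- GenomicRanges::GRanges(
        g$chrom, IRanges::IRanges(pmax(1L, g$tss - window), g$tss + window))
      q <- tss_win
      if (all(c("start", "end") %in% names(g)) && !anyNA(g$start) &&
          !anyNA(g$end))
        q <- c(q, GenomicRanges::GRanges(g$chrom,
                                         IRanges::IRanges(g$start, g$end)))
      hits <- suppressWarnings(GenomicRanges::findOverlaps(db$se_regions, q))
      .se_records(db, .region_ids(db$se_regions, "se")[
        unique(S4Vectors::queryHits(hits))])
    },
    location = {
      loc <- .parse_location(key)
      # a chromosome outside the database is simply an empty result
      hits <- suppressWarnings(GenomicRanges::findOverlaps(db$se_regions, loc))
      .se_records(db, .region_ids(db$se_regions, "se")[
        unique(S4Vectors::queryHits(hits))])
    })
}

.parse_location <- function(key) {
  m <- regmatches(key, regexec("^([^:]+):([0-9]+)-([0-9]+)$", key))[[1]]
  if (length(m) != 4L)
    stop("malformed location (expected \"chrom:start-end\"): ", key)
  start <- as.numeric(m[3]); end <- as.numeric(m[4])
  if (start > end) stop("malformed location: start > end in ", key)
  GenomicRanges::GRanges(m[2], IRanges::IRanges(start, end))
}

.se_records <- function(db, se_ids) {
  out <- db$se_summary$per_cancer
  out <- out[out$se_id %in% se_ids, , drop = FALSE]
  found <- setdiff(se_ids, out$se_id)
  if (length(found)) {
    cat_of <- stats::setNames(db$se_summary$category$category,
                              db$se_summary$category$se_id)
    out <- rbind(out, data.frame(
      se_id = found, cancer_type = NA_character_, mode = NA_character_,
      n_ces = 0L, ce_ids = "", stringsAsFactors = FALSE))
  }
  out <- out[order(out$se_id, out$cancer_type, out$mode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export the fingerprint database to standard formats
#'
#' `se_bed` / `ce_bed` write the unified regions as BED6 (name = region id,
#' score 0, strand `"."`); `calls_json` writes the cancer-specific calls as
#' a JSON document keyed by cancer type with stable field ordering.
#'
#' @param db `FingerprintDB`.
#' @param what export target.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
export_fingerprint <- function(db, what = c("se_bed", "ce_bed", "calls_json"),
                               file) {
  stopifnot(inherits(db, "FingerprintDB"))
  what <- match.arg(what)
  switch(what,
    se_bed = write_region_bed(db$se_regions, file),
    ce_bed = write_region_bed(db$ce_regions, file),
    calls_json = {
      calls <- db$cancer_calls
      by_cancer <- lapply(split(calls, calls$cancer_type), function(g) {
        g <- g[order(g$ce_id, g$mode), , drop = FALSE]
        se_of <- stats::setNames(db$map$se_id, db$map$ce_id)
        lapply(seq_len(nrow(g)), function(i) list(
          ce_id = g$ce_id[i], se_id = unname(se_of[g$ce_id[i]]),
          mode = g$mode[i], cells = strsplit(g$cells[i], ",", fixed = TRUE)[[1]]))
      })
      jsonlite::write_json(by_cancer, file, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      invisible(file)
    })
}
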