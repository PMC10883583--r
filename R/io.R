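#' Read per-sample SE/CE regions from a BED file
#'
#' @param file BED3/BED6 path.
#' @param sample_id sample identifier attached to every region.
#' @param region_class one of `"SE"`, `"CE"`, `"enhancer"`, `"promoter"`,
#'   `"blacklist"`.
#' @return `GRanges` with `sample_id` and `region_class` metadata columns.
#' @export
read_region_bed <- function(file, sample_id = NA_character_,
                            region_class = c("SE", "CE", "enhancer",
                                             "promoter", "blacklist")) {
  region_class <- match.arg(region_class)
  gr <- rtracklayer::import(file, format = "BED")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample_id = rep(sample_id, length(gr)),
    region_class = rep(region_class, length(gr)))
  gr
}

#' Write regions to BED
#'
#' Unified regions are written as BED6 with the name field encoding
#' `region_id` and member count (`<region_id>|n=<members>`), score 0 and
#' strand `"."`.
#'
#' @param gr `GRanges`; `region_id`/`n_members` metadata used when present.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_region_bed <- function(gr, file) {
  mc <- S4Vectors::mcols(gr)
  name <- if (!is.null(mc$region_id)) {
    if (!is.null(mc$n_members))
      paste0(mc$region_id, "|n=", mc$n_members)
    else as.character(mc$region_id)
  } else .region_ids(gr, "region")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # BED is 0-based half-open
    end = BiocGenerics::end(gr),
    name = name, score = 0L, strand = ".",
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a bedGraph coverage track
#'
#' @param file bedGraph path.
#' @return `GRanges` with a numeric `score` column (per-base depth).
#' @export
read_bedgraph <- function(file) {
  rtracklayer::import(file, format = "bedGraph")
}

#' Read and validate a sample sheet
#'
#' Three tab-separated columns: `sample_id`, `cell_line`, `cancer_type`.
#' Replicate structure is implied by multiple samples per cell line.
#'
#' @param file TSV path, or a data.frame with the three columns.
#' @return validated data.frame.
#' @export
read_sample_sheet <- function(file) {
  sheet <- if (is.data.frame(file)) file
           else utils::read.table(file, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  validate_sample_sheet(sheet)
}

#' @rdname read_sample_sheet
#' @param sheet data.frame to validate.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "cell_line", "cancer_type")
  if (!all(req %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  sheet <- as.data.frame(sheet)[req]
  if (anyDuplicated(sheet$sample_id))
    stop("sample ids must be unique")
  n_types <- tapply(sheet$cancer_type, sheet$cell_line,
                    function(x) length(unique(x)))
  if (any(n_types > 1L))
    stop("each cell line must map to exactly one cancer type: ",
         paste(names(n_types)[n_types > 1L], collapse = ", "))
  sheet
}

#' Activity matrix TSV I/O
#'
#' Matrices are stored with region ids as the first column (`region_id`) and
#' one column per sample or cell line.
#'
#' @param file TSV path.
#' @return for the reader, a numeric matrix with region-id rownames.
#' @export
read_counts_tsv <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_counts_tsv
#' @param m matrix with rownames (region ids) and colnames.
#' @export
write_counts_tsv <- function(m, file) {
  df <- data.frame(region_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
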