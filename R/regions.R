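#' Fractional overlap between genomic regions
#'
#' Computes the width of the intersection of two regions relative to a
#' reference width. With `denom = "smaller"` (the default) the reference is
#' the width of the smaller region, so the fraction is the maximum of the two
#' per-region overlap fractions; `"either"` is the same rule stated the other
#' way around (a pair passes a cutoff if either region is covered to that
#' fraction) and is kept as an alias. `"reciprocal"` uses the larger region's
#' width, i.e. both regions must be covered to the cutoff fraction.
#'
#' Regions on different chromosomes have overlap 0 by definition.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled); widths must
#'   be positive.
#' @param denom reference width: `"smaller"`, `"either"` (alias), or
#'   `"reciprocal"`.
#' @return numeric vector of fractions in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b, denom = c("smaller", "either", "reciprocal")) {
  denom <- match.arg(denom)
  a <- .validate_regions(a)
  b <- .validate_regions(b)
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("'a' and 'b' must have equal length (or one of length 1)")
  }
  inter <- pmax(0L, pmin(BiocGenerics::end(a), BiocGenerics::end(b)) -
                  pmax(BiocGenerics::start(a), BiocGenerics::start(b)) + 1L)
  inter[as.character(GenomicRanges::seqnames(a)) !=
          as.character(GenomicRanges::seqnames(b))] <- 0L
  ref <- switch(denom,
    smaller = ,
    either = pmin(BiocGenerics::width(a), BiocGenerics::width(b)),
    reciprocal = pmax(BiocGenerics::width(a), BiocGenerics::width(b)))
  as.numeric(inter) / as.numeric(ref)
}

.validate_regions <- function(gr) {
  if (!methods::is(gr, "GRanges"))
    stop("regions must be a GRanges object")
  if (length(gr) && any(BiocGenerics::width(gr) < 1L))
    stop("invalid region: width must be positive (start <= end)")
  gr
}

#' Merge regions across samples into a unified candidate list
#'
#' Builds the unified cross-sample SE (or CE) candidate list: any two input
#' regions whose [overlap_fraction()] is at least `min_overlap` belong to the
#' same unified region, and the relation is closed transitively (chains of
#' pairwise-overlapping regions merge), so the output is a partition of the
#' input. Each unified region spans the union of its members. The result is
#' deterministic and independent of input order.
#'
#' @param regions `GRanges`, optionally with metadata columns `sample_id` and
#'   `region_class`; all regions should share one `region_class`.
#' @param min_overlap minimum fractional overlap in `[0, 1]` required to merge
#'   a pair (0.25 merges regions sharing at least 25% of the smaller width).
#' @param denom reference width passed to [overlap_fraction()].
#' @return `GRanges` sorted by (chrom, start) with metadata columns
#'   `region_id`, `region_class`, `n_members`, and `members` (a
#'   `CharacterList` of `"sample|chrom:start-end"` provenance strings).
#' @export
merge_regions <- function(regions, min_overlap = 0.25,
                          denom = c("smaller", "either", "reciprocal")) {
  denom <- match.arg(denom)
  stopifnot(min_overlap >= 0, min_overlap <= 1)
  regions <- .validate_regions(regions)
  n <- length(regions)
  region_class <- .region_class(regions)
  if (n == 0L) return(.unified_granges(regions, integer(0), region_class))

  hits <- GenomicRanges::findOverlaps(regions, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(hits)) {
    frac <- overlap_fraction(regions[S4Vectors::queryHits(hits)],
                             regions[S4Vectors::subjectHits(hits)],
                             denom = denom)
    hits <- hits[frac >= min_overlap]
  }
  comp <- .union_find(n, S4Vectors::queryHits(hits), S4Vectors::subjectHits(hits))
  .unified_granges(regions, comp, region_class)
}

.region_class <- function(regions) {
  rc <- S4Vectors::mcols(regions)$region_class
  if (is.null(rc)) return(NA_character_)
  u <- unique(as.character(rc))
  if (length(u) > 1L)
    stop("all regions passed to merge_regions() must share one region_class")
  if (length(u)) u else NA_character_
}

## iterative weighted union-find with path halving
.union_find <- function(n, from, to) {
  parent <- seq_len(n)
  rank <- integer(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (k in seq_along(from)) {
    ra <- find(from[k]); rb <- find(to[k])
    if (ra == rb) next
    if (rank[ra] < rank[rb]) { tmp <- ra; ra <- rb; rb <- tmp }
    parent[rb] <- ra
    if (rank[ra] == rank[rb]) rank[ra] <- rank[ra] + 1L
  }
  vapply(seq_len(n), find, integer(1))
}

.unified_granges <- function(regions, comp, region_class) {
  if (length(regions) == 0L) {
    out <- GenomicRanges::GRanges()
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(
      region_id = character(0), region_class = character(0),
      n_members = integer(0), members = IRanges::CharacterList())
    return(out)
  }
  sid <- S4Vectors::mcols(regions)$sample_id
  if (is.null(sid)) sid <- rep(NA_character_, length(regions))
  idx <- split(seq_along(regions), comp)
  spans <- lapply(idx, function(i) {
    r <- regions[i]
    GenomicRanges::GRanges(
      GenomicRanges::seqnames(r)[1],
      IRanges::IRanges(min(BiocGenerics::start(r)), max(BiocGenerics::end(r))))
  })
  out <- suppressWarnings(do.call(c, unname(spans)))
  members <- IRanges::CharacterList(lapply(idx, function(i) {
    sort(paste0(ifelse(is.na(sid[i]), "", sid[i]), "|",
                as.character(GenomicRanges::seqnames(regions[i])), ":",
                BiocGenerics::start(regions[i]), "-",
                BiocGenerics::end(regions[i])))
  }))
  n_members <- lengths(idx)
  ord <- order(as.character(GenomicRanges::seqnames(out)),
               BiocGenerics::start(out), BiocGenerics::end(out))
  out <- out[ord]
  S4Vectors::mcols(out) <- S4Vectors::DataFrame(
    region_id = paste0(
      if (is.na(region_class)) "region" else tolower(region_class), "_",
      as.character(GenomicRanges::seqnames(out)), ":",
      BiocGenerics::start(out), "-", BiocGenerics::end(out)),
    region_class = rep(region_class, length(out)),
    n_members = unname(n_members[ord]),
    members = unname(members[ord]))
  out
}

#' Promoter windows around transcription start sites
#'
#' Expands each TSS into the exclusion window used when selecting enhancer
#' peaks: 3 kb upstream to 1 kb downstream of the TSS, oriented by strand.
#'
#' @param tss `GRanges` of TSS positions (width-1 anchors are taken at the
#'   strand-aware start of each range); unstranded ranges are treated as `+`.
#' @param upstream,downstream window extents in bp.
#' @return `GRanges` of promoter windows.
#' @export
promoter_windows <- function(tss, upstream = 3000, downstream = 1000) {
  tss <- .validate_regions(tss)
  strand <- as.character(BiocGenerics::strand(tss))
  strand[strand == "*"] <- "+"
  BiocGenerics::strand(tss) <- strand
  anchors <- GenomicRanges::resize(tss, width = 1L, fix = "start")
  GenomicRanges::promoters(anchors, upstream = upstream,
                           downstream = downstream)
}

#' Remove peaks overlapping promoters or blacklist regions
#'
#' Retains only peaks with zero base-pair intersection with any promoter
#' window or blacklist region. Abutting regions (no shared base) are kept.
#'
#' @param peaks,promoters,blacklist `GRanges`.
#' @return the retained subset of `peaks`.
#' @export
filter_excluded <- function(peaks, promoters = GenomicRanges::GRanges(),
                            blacklist = GenomicRanges::GRanges()) {
  peaks <- .validate_regions(peaks)
  excl <- c(GenomicRanges::granges(promoters), GenomicRanges::granges(blacklist))
  if (length(excl) == 0L) return(peaks)
  keep <- GenomicRanges::countOverlaps(peaks, excl, minoverlap = 1L) == 0L
  peaks[keep]
}

#' Assign constituent enhancers to their parent super-enhancers
#'
#' Each unified CE is assigned to the unified SE with which it shares the most
#' bases. Ties go to the SE with the smaller start coordinate. CEs
#' intersecting no SE are flagged as unassigned (`se_id = NA`).
#'
#' @param ces,ses unified `GRanges` as returned by [merge_regions()] (a
#'   `region_id` metadata column is used when present, otherwise ids are
#'   derived from coordinates).
#' @return data.frame with columns `ce_id`, `se_id`, `overlap_bp`, `assigned`.
#' @export
assign_ce_to_se <- function(ces, ses) {
  ces <- .validate_regions(ces)
  ses <- .validate_regions(ses)
  ce_id <- .region_ids(ces, "ce")
  se_id <- .region_ids(ses, "se")
  if (anyDuplicated(ce_id)) stop("duplicated CE region ids")
  if (anyDuplicated(se_id)) stop("duplicated SE region ids")
  res <- data.frame(ce_id = ce_id, se_id = NA_character_,
                    overlap_bp = 0L, assigned = FALSE,
                    stringsAsFactors = FALSE)
  if (length(ces) == 0L || length(ses) == 0L) return(res)
  hits <- GenomicRanges::findOverlaps(ces, ses)
  if (length(hits) == 0L) return(res)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- BiocGenerics::width(IRanges::pintersect(
    GenomicRanges::ranges(ces)[q], GenomicRanges::ranges(ses)[s]))
  ## max intersection per CE; ties broken by smaller SE start
  ord <- order(q, -ov, BiocGenerics::start(ses)[s])
  first <- !duplicated(q[ord])
  qi <- q[ord][first]
  res$se_id[qi] <- se_id[s[ord][first]]
  res$overlap_bp[qi] <- ov[ord][first]
  res$assigned[qi] <- TRUE
  res
}

.region_ids <- function(gr, prefix) {
  id <- S4Vectors::mcols(gr)$region_id
  if (is.null(id))
    id <- paste0(prefix, "_", as.character(GenomicRanges::seqnames(gr)), ":",
                 BiocGenerics::start(gr), "-", BiocGenerics::end(gr))
  as.character(id)
}
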