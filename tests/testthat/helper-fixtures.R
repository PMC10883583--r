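## Construct a GRanges from BED-style 0-based half-open coordinates, so
## interval examples read as [start, end).
gr0 <- function(start, end, chrom = "chr1", sample_id = NA_character_,
                region_class = "SE") {
  GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start + 1L, end),
    sample_id = rep_len(sample_id, length(start)),
    region_class = rep_len(region_class, length(start)))
}

## Random interval instance for merge property tests.
random_regions <- function(n, n_chrom = 2, span = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  start <- sample.int(span, n, replace = TRUE)
  width <- sample(20:400, n, replace = TRUE)
  GenomicRanges::GRanges(
    paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
    IRanges::IRanges(start, start + width - 1L),
    sample_id = paste0("s", seq_len(n)), region_class = "SE")
}

## Brute-force O(n^2) merge oracle: pairwise fractional overlaps, then
## connected components by union-find over the full pair list.
oracle_merge_components <- function(gr, min_overlap, denom = "smaller") {
  n <- length(gr)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  chrom <- as.character(GenomicRanges::seqnames(gr))
  s <- BiocGenerics::start(gr); e <- BiocGenerics::end(gr)
  w <- BiocGenerics::width(gr)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || chrom[i] != chrom[j]) next
    inter <- max(0, min(e[i], e[j]) - max(s[i], s[j]) + 1)
    ref <- if (denom == "reciprocal") max(w[i], w[j]) else min(w[i], w[j])
    if (inter / ref >= min_overlap) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  match(comp, unique(comp))
}

## Canonical signature of a merge result: component spans plus member counts.
merge_signature <- function(unified) {
  paste(as.character(GenomicRanges::seqnames(unified)),
        BiocGenerics::start(unified), BiocGenerics::end(unified),
        unified$n_members, sep = ":")
}

## Literal median-of-ratios oracle. The median of the ratios is taken on the
## log scale (for an even row count the two central ratios interpolate
## geometrically), the standard RLE convention.
oracle_rle <- function(m) {
  geo <- apply(m, 1, function(r) prod(r)^(1 / length(r)))
  ok <- apply(m, 1, function(r) all(r > 0))
  sf <- apply(m, 2, function(col) exp(stats::median(log(col[ok] / geo[ok]))))
  list(size_factors = sf, normalized = sweep(m, 2, sf, "/"))
}

## Direct entropy/contingency VI oracle.
oracle_vi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  ha <- 0; hb <- 0; mi <- 0
  for (ca in ua) {
    pa <- sum(a == ca) / n
    ha <- ha - pa * log(pa)
  }
  for (cb in ub) {
    pb <- sum(b == cb) / n
    hb <- hb - pb * log(pb)
  }
  for (ca in ua) for (cb in ub) {
    pab <- sum(a == ca & b == cb) / n
    if (pab > 0)
      mi <- mi + pab * log(pab / (sum(a == ca) / n * sum(b == cb) / n))
  }
  ha + hb - 2 * mi
}

## A minimal MixtureFit-shaped object for posterior/assignment tests.
fake_fit <- function(mu = c(3, 9), sigma = c(1, 1), pi = c(0.5, 0.5),
                     posterior = NULL, fit_class = "mixed", values = NULL) {
  structure(list(
    ce_id = "ce_test",
    mu = c(inactive = mu[1], active = mu[2]),
    sigma = c(inactive = sigma[1], active = sigma[2]),
    pi = c(inactive = pi[1], active = pi[2]),
    posterior_active = posterior,
    loglik_trace = numeric(0), n_iter = 0L, converged = TRUE,
    fit_class = fit_class, values = values), class = "MixtureFit")
}

## Small simulated dataset + pipeline run shared by db/pipeline tests.
tiny_pipeline <- function(seed = 5) {
  cfg <- simulation_config(n_cancers = 3, cells_per_cancer = 2,
                           n_ses = 15, ces_per_se_mean = 3, seed = seed)
  sim <- simulate_fingerprint_dataset(cfg)
  map <- data.frame(ce_id = sim$truth$spec$ce_id,
                    se_id = sim$truth$spec$se_id,
                    overlap_bp = NA_integer_, assigned = TRUE,
                    stringsAsFactors = FALSE)
  res <- run_fingerprint_pipeline(sim$counts, sim$sheet, map,
                                  threshold = 0.4,
                                  se_regions = sim$regions$truth_se,
                                  ce_regions = sim$regions$truth_ce)
  list(cfg = cfg, sim = sim, map = map, res = res)
}
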