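#' Simulation configuration for a synthetic cancer cell-line panel
#'
#' Defines the study conditions the generator emulates: a multi-cancer panel
#' of cell lines with replicated H3K27Ac-like activity at constituent
#' enhancers nested inside super-enhancers, bimodal log2-scale activities,
#' planted cancer-specific CEs, variable sequencing depth and excess zeros.
#'
#' Defaults describe a 10-cancer x 3-cell-line x 2-replicate panel with 200
#' SEs of ~5 CEs each; log2 activity components N(9, 1) (active) and
#' N(3, 1) (inactive); 30% of CEs planted specific-active and 10%
#' specific-inactive at a target prevalence of ~0.15; 1% each uniformly
#' active/inactive; replicate noise SD 0.25 (log2); lognormal per-sample
#' depth factors (sdlog 0.3); 5% dropout among inactive occurrences.
#'
#' @param n_cancers,cells_per_cancer,replicates_per_cell panel structure.
#' @param n_ses number of super-enhancers.
#' @param ces_per_se_mean mean CEs per SE (1 + Poisson(mean - 1)).
#' @param mu_active,mu_inactive,sd_active,sd_inactive log2 activity
#'   components.
#' @param fraction_specific_active,fraction_specific_inactive fractions of
#'   CEs planted as cancer-specific (active / inactive mode).
#' @param fraction_all_active,fraction_all_inactive fractions of uniformly
#'   active / inactive CEs.
#' @param planted_specific_prevalence target minority-state prevalence of
#'   planted specific CEs (own cancer's cells plus Poisson extras).
#' @param background_active_rate per-cell-line activity probability of
#'   non-planted (mixed background) CEs.
#' @param replicate_sd log2-scale replicate noise SD.
#' @param depth_sdlog lognormal sdlog of per-sample depth factors (0 gives
#'   unit depths).
#' @param zero_rate dropout probability for inactive CE occurrences (the
#'   occurrence is zeroed in all replicates of the cell line).
#' @param jitter_frac per-sample region boundary jitter, as a fraction of
#'   region width (SD of the Gaussian jitter).
#' @param seed integer RNG seed recorded in the output.
#' @return a `SimulationConfig` list.
#' @export
simulation_config <- function(n_cancers = 10, cells_per_cancer = 3,
                              replicates_per_cell = 2, n_ses = 200,
                              ces_per_se_mean = 5,
                              mu_active = 9, mu_inactive = 3,
                              sd_active = 1, sd_inactive = 1,
                              fraction_specific_active = 0.3,
                              fraction_specific_inactive = 0.1,
                              fraction_all_active = 0.01,
                              fraction_all_inactive = 0.01,
                              planted_specific_prevalence = 0.15,
                              background_active_rate = 0.5,
                              replicate_sd = 0.25,
                              depth_sdlog = 0.3,
                              zero_rate = 0.05,
                              jitter_frac = 0.05,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$mu_active > cfg$mu_inactive,
            cfg$sd_active > 0, cfg$sd_inactive > 0,
            cfg$n_cancers >= 1, cfg$cells_per_cancer >= 1,
            cfg$replicates_per_cell >= 1, cfg$n_ses >= 1,
            cfg$zero_rate >= 0, cfg$zero_rate <= 1,
            cfg$planted_specific_prevalence >= 0,
            cfg$planted_specific_prevalence <= 1,
            cfg$fraction_specific_active + cfg$fraction_specific_inactive +
              cfg$fraction_all_active + cfg$fraction_all_inactive <= 1)
  structure(cfg, class = "SimulationConfig")
}

## evaluate code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate SE/CE region structure with per-sample boundary jitter
#'
#' Lays out non-overlapping SEs along synthetic chromosomes, nests CEs
#' inside them (widths 800-3000 bp, gaps 500-2000 bp), and derives
#' per-sample observed regions by jittering each true boundary with Gaussian
#' noise of SD `jitter_frac` x width, so fractional-overlap merging is
#' exercised. Deterministic given `(cfg, cfg$seed)`.
#'
#' @param cfg [simulation_config()].
#' @return list with `truth_se` and `truth_ce` (`GRanges` with `region_id`,
#'   and `se_id` on CEs) and `samples` (per-sample list of `se` / `ce`
#'   `GRanges` with `sample_id`, `region_class`).
#' @export
simulate_regions <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  .with_seed(cfg$seed, {
    per_chrom <- 50L
    n_chrom <- ceiling(cfg$n_ses / per_chrom)
    se_rows <- vector("list", cfg$n_ses)
    ce_rows <- vector("list", cfg$n_ses)
    for (i in seq_len(cfg$n_ses)) {
      chrom <- paste0("chr", (i - 1L) %/% per_chrom + 1L)
      slot <- (i - 1L) %% per_chrom
      base <- 1e5 + slot * 2e5   # 200 kb spacing: no cross-SE merging
      k <- 1L + stats::rpois(1, max(0, cfg$ces_per_se_mean - 1))
      widths <- round(stats::runif(k, 800, 3000))
      gaps <- if (k > 1) round(stats::runif(k - 1, 500, 2000)) else integer(0)
      starts <- base + cumsum(c(0, widths[-k] + gaps))
      ends <- starts + widths - 1
      ce_rows[[i]] <- data.frame(chrom = chrom, start = starts, end = ends,
                                 se = i)
      se_rows[[i]] <- data.frame(chrom = chrom, start = starts[1],
                                 end = ends[k])
    }
    se_df <- do.call(rbind, se_rows)
    ce_df <- do.call(rbind, ce_rows)
    se_ids <- sprintf("se_%04d", seq_len(nrow(se_df)))
    ce_ids <- sprintf("ce_%05d", seq_len(nrow(ce_df)))
    truth_se <- GenomicRanges::GRanges(se_df$chrom,
                                       IRanges::IRanges(se_df$start, se_df$end),
                                       region_id = se_ids, region_class = "SE")
    truth_ce <- GenomicRanges::GRanges(ce_df$chrom,
                                       IRanges::IRanges(ce_df$start, ce_df$end),
                                       region_id = ce_ids, region_class = "CE",
                                       se_id = se_ids[ce_df$se])
    sheet <- .panel_sheet(cfg)
    samples <- lapply(sheet$sample_id, function(s) {
      jit <- function(gr, class) {
        w <- BiocGenerics::width(gr)
        ds <- round(stats::rnorm(length(gr), 0, cfg$jitter_frac * w))
        de <- round(stats::rnorm(length(gr), 0, cfg$jitter_frac * w))
        start <- BiocGenerics::start(gr) + ds
        end <- BiocGenerics::end(gr) + de
        end <- pmax(end, start + 99L)   # keep widths sane
        GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                               IRanges::IRanges(pmax(1L, start), end),
                               sample_id = s, region_class = class)
      }
      list(se = jit(truth_se, "SE"), ce = jit(truth_ce, "CE"))
    })
    names(samples) <- sheet$sample_id
    list(truth_se = truth_se, truth_ce = truth_ce, samples = samples)
  })
}

.panel_sheet <- function(cfg) {
  cancers <- sprintf("cancer%02d", seq_len(cfg$n_cancers))
  cells <- as.vector(t(outer(cancers, seq_len(cfg$cells_per_cancer),
                             function(a, b) paste0(a, "_cell", b))))
  sheet <- do.call(rbind, lapply(seq_along(cells), function(i) data.frame(
    sample_id = paste0(cells[i], "_rep", seq_len(cfg$replicates_per_cell)),
    cell_line = cells[i],
    cancer_type = rep(cancers, each = cfg$cells_per_cancer)[i],
    stringsAsFactors = FALSE)))
  rownames(sheet) <- NULL
  sheet
}

#' Simulate replicate-level activity counts with ground truth
#'
#' Draws per-(CE, cell line) log2 activities from the active or inactive
#' component according to a planted truth (cancer-specific CEs active — or
#' inactive — in their cancer's cell lines plus a few random extras at the
#' target prevalence; mixed background CEs active per cell line at the
#' background rate; small uniformly active/inactive classes), adds replicate
#' noise, exponentiates, applies per-sample depth factors, rounds to counts,
#' and zeroes inactive occurrences at the dropout rate. Deterministic given
#' `(cfg, cfg$seed)`; uses an RNG stream separate from [simulate_regions()]
#' (seed + 1) so the two compose into one reproducible dataset.
#'
#' @param cfg [simulation_config()].
#' @param regions output of [simulate_regions()] (defaults to regenerating
#'   it from `cfg`); supplies CE ids and the CE-to-SE structure.
#' @return list with `counts` (CE x sample matrix), `sheet`, and `truth`
#'   (list: `states` logical CE x cell-line matrix, `spec` per-CE label
#'   table, `depth_factors`, `seed`).
#' @export
simulate_activity <- function(cfg, regions = simulate_regions(cfg)) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  ce_ids <- regions$truth_ce$region_id
  n_ce <- length(ce_ids)
  sheet <- .panel_sheet(cfg)
  cells <- unique(sheet$cell_line)
  cancers_of <- stats::setNames(
    sheet$cancer_type[!duplicated(sheet$cell_line)], cells)
  n_cells <- length(cells)
  .with_seed(cfg$seed + 1L, {
    ## planted CE labels
    n_sa <- round(cfg$fraction_specific_active * n_ce)
    n_si <- round(cfg$fraction_specific_inactive * n_ce)
    n_aa <- round(cfg$fraction_all_active * n_ce)
    n_ai <- round(cfg$fraction_all_inactive * n_ce)
    label <- rep("background", n_ce)
    pick <- sample.int(n_ce, n_sa + n_si + n_aa + n_ai)
    label[pick] <- rep(c("specific_active", "specific_inactive",
                         "all_active", "all_inactive"),
                       times = c(n_sa, n_si, n_aa, n_ai))
    cancers <- unique(sheet$cancer_type)
    planted_cancer <- rep(NA_character_, n_ce)
    is_spec <- label %in% c("specific_active", "specific_inactive")
    planted_cancer[is_spec] <- rep_len(cancers, sum(is_spec))

    ## true states; planted minority size matches the target prevalence
    ## (floor/ceiling randomization), own cancer's cells always included
    states <- matrix(NA, n_ce, n_cells, dimnames = list(ce_ids, cells))
    target <- cfg$planted_specific_prevalence * n_cells
    for (i in seq_len(n_ce)) {
      states[i, ] <- switch(label[i],
        all_active = rep(TRUE, n_cells),
        all_inactive = rep(FALSE, n_cells),
        background = stats::runif(n_cells) < cfg$background_active_rate,
        {
          own <- cancers_of[cells] == planted_cancer[i]
          minority <- own
          pool <- which(!own)
          m <- floor(target) + stats::rbinom(1, 1, target - floor(target))
          n_extra <- min(max(0, m - sum(own)), length(pool))
          if (n_extra > 0) {
            ## sporadic extras in distinct other cancers, so the planted
            ## cancer is the only coherent (>= 2 cell line) signal
            other <- sample(unique(cancers_of[cells][pool]))
            extra_cancers <- utils::head(other, n_extra)
            extras <- vapply(extra_cancers, function(ca)
              sample(pool[cancers_of[cells][pool] == ca], 1), integer(1))
            minority[extras] <- TRUE
          }
          if (label[i] == "specific_active") minority else !minority
        })
    }

    ## log2 activity per (CE, cell line), then replicate counts
    mu <- ifelse(states, cfg$mu_active, cfg$mu_inactive)
    sd <- ifelse(states, cfg$sd_active, cfg$sd_inactive)
    x <- matrix(stats::rnorm(n_ce * n_cells, mu, sd), n_ce, n_cells,
                dimnames = list(ce_ids, cells))
    depth <- stats::setNames(
      if (cfg$depth_sdlog > 0)
        stats::rlnorm(nrow(sheet), 0, cfg$depth_sdlog)
      else rep(1, nrow(sheet)),
      sheet$sample_id)
    dropout <- !states & matrix(stats::runif(n_ce * n_cells) < cfg$zero_rate,
                                n_ce, n_cells)
    counts <- matrix(0, n_ce, nrow(sheet),
                     dimnames = list(ce_ids, sheet$sample_id))
    for (s in seq_len(nrow(sheet))) {
      cl <- sheet$cell_line[s]
      noise <- stats::rnorm(n_ce, 0, cfg$replicate_sd)
      counts[, s] <- round(2^(x[, cl] + noise) * depth[s])
      counts[dropout[, cl], s] <- 0
    }
    spec <- data.frame(ce_id = ce_ids, label = label,
                       cancer_type = planted_cancer,
                       se_id = regions$truth_ce$se_id,
                       stringsAsFactors = FALSE)
    list(counts = counts, sheet = sheet,
         truth = list(states = states, spec = spec, depth_factors = depth,
                      seed = cfg$seed))
  })
}

#' Simulate a complete fingerprint dataset
#'
#' Composes [simulate_regions()] and [simulate_activity()] into one dataset
#' with region files, counts, sample sheet and ground truth.
#'
#' @param cfg [simulation_config()].
#' @return list with `regions`, `counts`, `sheet`, `truth`.
#' @export
simulate_fingerprint_dataset <- function(cfg = simulation_config()) {
  regions <- simulate_regions(cfg)
  act <- simulate_activity(cfg, regions)
  list(regions = regions, counts = act$counts, sheet = act$sheet,
       truth = act$truth)
}

#' Write a simulated dataset to plain-text files
#'
#' Emits per-sample SE/CE BED files, the counts TSV, the sample sheet TSV
#' and the ground-truth tables into a directory.
#'
#' @param sim output of [simulate_fingerprint_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(sim$regions$samples)) {
    write_region_bed(sim$regions$samples[[s]]$se,
                     file.path(dir, paste0(s, ".se.bed")))
    write_region_bed(sim$regions$samples[[s]]$ce,
                     file.path(dir, paste0(s, ".ce.bed")))
  }
  write_counts_tsv(sim$counts, file.path(dir, "counts.tsv"))
  utils::write.table(sim$sheet, file.path(dir, "sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$spec, file.path(dir, "truth_spec.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  states <- data.frame(ce_id = rownames(sim$truth$states),
                       sim$truth$states * 1L, check.names = FALSE)
  utils::write.table(states, file.path(dir, "truth_states.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
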