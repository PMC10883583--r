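test_that("compute_prevalence is the active fraction with complement", {
  states <- rbind(a = c(rep(TRUE, 12), rep(FALSE, 48)),
                  b = rep(TRUE, 60),
                  c = rep(FALSE, 60))
  colnames(states) <- sprintf("cl%02d", 1:60)
  p <- compute_prevalence(states)
  expect_equal(p$active_prevalence, c(0.2, 1, 0))
  expect_equal(p$active_prevalence + p$inactive_prevalence, rep(1, 3))
})

test_that("variation_of_information matches hand-computed and oracle values", {
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 1, 2, 2)), 0)
  # relabeled identical partition is still distance 0
  expect_equal(variation_of_information(c(1, 1, 2, 2), c("b", "b", "a", "a")), 0)
  # {ab|cd} vs {ac|bd}: H(A)=H(B)=ln 2, I=0 -> VI = 2 ln 2
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(1, 2, 1, 2)),
               2 * log(2))
  # against a single cluster, VI = H(A)
  a <- c(1, 1, 2, 2, 3, 3)
  expect_equal(variation_of_information(a, rep(1, 6)),
               -sum(rep(1 / 3, 3) * log(1 / 3)))
  expect_error(variation_of_information(1:3, 1:4), "same item set")
})

test_that("VI agrees with the entropy oracle, is symmetric, and is a metric", {
  set.seed(413)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    a <- sample.int(4, n, replace = TRUE)
    b <- sample.int(3, n, replace = TRUE)
    expect_equal(variation_of_information(a, b), oracle_vi(a, b),
                 tolerance = 1e-12)
    expect_equal(variation_of_information(a, b),
                 variation_of_information(b, a))
    # triangle inequality on a random triple
    c3 <- sample.int(3, n, replace = TRUE)
    expect_lte(variation_of_information(a, b),
               variation_of_information(a, c3) +
                 variation_of_information(c3, b) + 1e-12)
  }
})

test_that("VI agrees with the igraph reference implementation", {
  skip_if_not_installed("igraph")
  set.seed(414)
  for (rep in 1:10) {
    n <- sample(10:60, 1)
    a <- sample.int(5, n, replace = TRUE)
    b <- sample.int(4, n, replace = TRUE)
    expect_equal(variation_of_information(a, b),
                 igraph::compare(a, b, method = "vi"), tolerance = 1e-12)
  }
})

test_that("cluster_cells recovers planted blocks and handles edge k", {
  set.seed(415)
  block <- rep(c(1, 2), each = 10)
  v <- matrix(rnorm(40 * 20, mean = rep(ifelse(block == 1, 0, 6), each = 40)),
              40, 20, dimnames = list(paste0("ce", 1:40), paste0("cl", 1:20)))
  part <- cluster_cells(v, k = 2)
  expect_equal(variation_of_information(part, block), 0)
  expect_true(all(cluster_cells(v, k = 1) == 1))
  expect_equal(length(unique(cluster_cells(v, k = 20))), 20)
  expect_error(cluster_cells(v[0, , drop = FALSE], k = 2), "at least one")
})

test_that("the slope = -1 rule picks the largest qualifying cutoff", {
  grid <- seq(0, 0.5, by = 0.01)
  # scaled curve linear with slope exactly -1 everywhere -> largest grid point
  lin <- SEfingerprint:::.threshold_from_curve(grid, rev(grid), 11)
  expect_equal(lin$threshold, 0.5)
  expect_equal(lin$method, "slope")
  # flat curve: slope never reaches -1 -> corner fallback at the first cutoff
  expect_warning(
    flat <- SEfingerprint:::.threshold_from_curve(grid, rep(2, 51), 11),
    "fallback")
  expect_equal(flat$method, "corner-fallback")
  # a step curve: the qualifying region ends just past the smoothed drop
  vi <- c(rep(1, 20), rep(0, 31))
  step <- SEfingerprint:::.threshold_from_curve(grid, vi, 11)
  expect_equal(step$method, "slope")
  expect_gt(step$threshold, 0.19)
  expect_lt(step$threshold, 0.32)
})

test_that("select_threshold separates planted specific CEs from background", {
  set.seed(416)
  n_cancer <- 6; per <- 3
  cells <- paste0("c", 1:(n_cancer * per))
  labels <- rep(paste0("K", 1:n_cancer), each = per)
  n_bg <- 120; n_sp <- 60
  # planted: active only in one cancer's three cells plus one random extra
  sp_states <- t(vapply(seq_len(n_sp), function(i) {
    own <- labels == paste0("K", (i - 1) %% n_cancer + 1)
    own[sample(which(!own), 1)] <- TRUE
    own
  }, logical(length(cells))))
  bg_states <- matrix(runif(n_bg * length(cells)) < 0.5, n_bg)
  states <- rbind(sp_states, bg_states)
  rownames(states) <- sprintf("ce%03d", seq_len(nrow(states)))
  colnames(states) <- cells
  v <- matrix(rnorm(length(states), ifelse(states, 9, 3), 1),
              nrow(states), ncol(states), dimnames = dimnames(states))
  profiles <- compute_prevalence(states)
  scan <- select_threshold(profiles, v, labels)
  expect_s3_class(scan, "ThresholdScan")
  expect_equal(nrow(scan$scan), 51)
  expect_true(all(scan$scan$vi >= 0))
  expect_true(scan$threshold > 4 / 18 & scan$threshold < 0.5)
  # selected CEs at the threshold recover the planted set well
  sel <- profiles$ce_id[profiles$active_prevalence < scan$threshold]
  tp <- sum(sel %in% rownames(states)[1:n_sp])
  f1 <- 2 * tp / (length(sel) + n_sp)
  expect_gte(f1, 0.9)
})

test_that("call_cell_specific applies the strict prevalence rule", {
  states <- rbind(a = c(rep(TRUE, 12), rep(FALSE, 48)),
                  b = c(rep(TRUE, 13), rep(FALSE, 47)),  # prevalence 0.2167
                  c = c(rep(FALSE, 3), rep(TRUE, 57)),   # inactive prev 0.05
                  d = rep(FALSE, 60))
  colnames(states) <- sprintf("cl%02d", 1:60)
  p <- compute_prevalence(states)
  calls <- call_cell_specific(p, states, threshold = 0.21)
  # 0.2 < 0.21 called with its 12 active cells
  a_call <- calls[calls$ce_id == "a", ]
  expect_equal(a_call$mode, "specific_active")
  expect_equal(strsplit(a_call$cells, ",")[[1]], sprintf("cl%02d", 1:12))
  # 0.2167 not called (strict <)
  expect_false("b" %in% calls$ce_id)
  # inactive mirror: cells are the inactive minority
  c_call <- calls[calls$ce_id == "c", ]
  expect_equal(c_call$mode, "specific_inactive")
  expect_equal(strsplit(c_call$cells, ",")[[1]], sprintf("cl%02d", 1:3))
  # prevalence 0 never yields a call (no minority cells exist)
  expect_false("d" %in% calls$ce_id)
  # active and inactive calls are disjoint for thresholds <= 0.5
  expect_false(any(duplicated(calls$ce_id)))
  # exact-threshold prevalence is excluded
  calls2 <- call_cell_specific(p, states, threshold = 0.2)
  expect_false("a" %in% calls2$ce_id)
})

test_that("raising the threshold never removes a call", {
  set.seed(417)
  states <- matrix(runif(50 * 20) < runif(50, 0, 0.6), 50, 20,
                   dimnames = list(sprintf("ce%02d", 1:50),
                                   sprintf("cl%02d", 1:20)))
  p <- compute_prevalence(states)
  prev_ids <- character(0)
  for (thr in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
    ids <- call_cell_specific(p, states, thr)
    ids <- paste(ids$ce_id, ids$mode)
    expect_true(all(prev_ids %in% ids))
    prev_ids <- ids
  }
})

test_that("call_cancer_specific enforces the two-cell-line rule", {
  sheet <- data.frame(
    sample_id = paste0("s", 1:8),
    cell_line = c("A", "B", "C", "D", "E", "F", "G", "H"),
    cancer_type = c("X", "X", "X", "Y", "Z", "Z", "Z", "W"))
  calls <- data.frame(
    ce_id = c("ce1", "ce2", "ce3"),
    mode = "specific_active",
    prevalence = 0.1,
    cells = c("A,B,E",   # two X lines -> X attached; one Z line -> not
              "D",       # Y has a single line in the panel -> attached
              "A"),      # one of three X lines -> dropped entirely
    stringsAsFactors = FALSE)
  out <- call_cancer_specific(calls, sheet)
  expect_equal(out$cancer_type[out$ce_id == "ce1"], "X")
  expect_equal(out$cells[out$ce_id == "ce1"], "A,B")
  expect_equal(out$cancer_type[out$ce_id == "ce2"], "Y")
  expect_false("ce3" %in% out$ce_id)
  # a call can attach to several cancers
  multi <- data.frame(ce_id = "ce4", mode = "specific_inactive",
                      prevalence = 0.1, cells = "A,B,E,F")
  out2 <- call_cancer_specific(multi, sheet)
  expect_setequal(out2$cancer_type, c("X", "Z"))
})

test_that("summarize_cancer_specific_se categorizes fingerprint SEs", {
  map <- data.frame(ce_id = paste0("ce", 1:6),
                    se_id = c("se1", "se1", "se2", "se2", "se3", NA),
                    assigned = c(rep(TRUE, 5), FALSE))
  cancer_ces <- data.frame(
    ce_id = c("ce1", "ce2", "ce3", "ce4", "ce6"),
    mode = c("specific_active", "specific_inactive",
             "specific_active", "specific_active", "specific_active"),
    cancer_type = c("X", "Y", "X", "X", "X"),
    n_cells = 2, cells = "A,B", stringsAsFactors = FALSE)
  expect_warning(out <- summarize_cancer_specific_se(cancer_ces, map),
                 "without an SE")
  cat1 <- out$category
  expect_equal(cat1$category[cat1$se_id == "se1"], "both")
  expect_equal(cat1$category[cat1$se_id == "se2"], "active_only")
  expect_equal(cat1$category[cat1$se_id == "se3"], "none")
  # se1 listed under both cancers
  se1 <- out$per_cancer[out$per_cancer$se_id == "se1", ]
  expect_setequal(se1$cancer_type, c("X", "Y"))
  # two active CEs of the same cancer in one SE are one record with n_ces = 2
  se2 <- out$per_cancer[out$per_cancer$se_id == "se2", ]
  expect_equal(nrow(se2), 1)
  expect_equal(se2$n_ces, 2L)
  expect_equal(se2$ce_ids, "ce3,ce4")
})
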