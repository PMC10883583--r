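test_that("summarize_coverage totals per-base depth within regions", {
  regions <- gr0(c(0, 20), c(10, 30), region_class = "CE")
  regions$region_id <- c("r1", "r2")
  flat3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000), score = 3)
  half2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5), score = 2)
  empty <- GenomicRanges::GRanges()
  m <- summarize_coverage(regions, list(s1 = flat3, s2 = half2))
  expect_equal(m$values["r1", "s1"], 30)
  expect_equal(m$values["r2", "s1"], 30)
  expect_equal(m$values["r1", "s2"], 10)
  expect_equal(m$values["r2", "s2"], 0)
  expect_warning(m0 <- summarize_coverage(regions, list(s3 = empty)), NA)
  expect_true(all(m0$values == 0))
  # region on a chromosome the track lacks scores 0 with a warning
  other <- GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 100), score = 5)
  expect_warning(m1 <- summarize_coverage(regions, list(s4 = other)),
                 "lacks chromosomes")
  expect_true(all(m1$values == 0))
})

test_that("aggregate_replicates sums replicate columns per cell line", {
  counts <- matrix(c(4, 1, 6, 2, 5, 0), nrow = 2,
                   dimnames = list(c("ce1", "ce2"), c("a_r1", "a_r2", "b_r1")))
  sheet <- data.frame(sample_id = c("a_r1", "a_r2", "b_r1"),
                      cell_line = c("a", "a", "b"),
                      cancer_type = c("x", "x", "y"))
  agg <- aggregate_replicates(activity_matrix(counts), sheet)
  expect_equal(agg$values["ce1", "a"], 10)
  expect_equal(agg$values["ce2", "a"], 3)
  # single-replicate cell line passes through unchanged
  expect_equal(agg$values[, "b"], c(ce1 = 5, ce2 = 0))
  # mean mode
  aggm <- aggregate_replicates(activity_matrix(counts), sheet, fun = "mean")
  expect_equal(aggm$values["ce1", "a"], 5)
  # unknown matrix column is rejected
  bad <- counts
  colnames(bad)[3] <- "zzz"
  expect_error(aggregate_replicates(activity_matrix(bad), sheet), "absent")
})

test_that("rle_normalize reproduces the hand-computed median-of-ratios example", {
  m <- matrix(c(2, 8, 4, 16), nrow = 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  norm <- rle_normalize(activity_matrix(m))
  expect_equal(unname(norm$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(norm$values),
               matrix(c(2, 8, 2, 8), 2) * sqrt(2))
  # identical columns: unit size factors, matrix unchanged
  m2 <- matrix(c(3, 7, 3, 7), nrow = 2,
               dimnames = list(c("r1", "r2"), c("c1", "c2")))
  norm2 <- rle_normalize(activity_matrix(m2))
  expect_equal(unname(norm2$size_factors), c(1, 1))
  expect_equal(norm2$values, m2)
})

test_that("rle_normalize matches the brute-force oracle and is scale-equivariant", {
  set.seed(403)
  for (rep in 1:30) {
    nr <- sample(5:20, 1); nc <- sample(2:6, 1)
    m <- matrix(rlnorm(nr * nc, 3, 1), nr, nc,
                dimnames = list(paste0("r", 1:nr), paste0("c", 1:nc)))
    # sprinkle zeros but keep at least two all-positive rows
    m[sample(length(m), floor(length(m) / 6))] <- 0
    m[1:2, ] <- abs(m[1:2, ]) + 1
    got <- rle_normalize(activity_matrix(m))
    want <- oracle_rle(m)
    expect_equal(unname(got$size_factors), unname(want$size_factors),
                 tolerance = 1e-10)
    expect_equal(got$values, want$normalized, tolerance = 1e-10)
    # depth equivariance: size factors absorb per-column scaling and the
    # normalized matrix is unchanged (scale vector of geometric mean 1;
    # an overall depth shift only rescales the common reference)
    scale <- rlnorm(nc, 0, 1)
    scale <- scale / exp(mean(log(scale)))
    got2 <- rle_normalize(activity_matrix(sweep(m, 2, scale, "*")))
    expect_equal(unname(got2$size_factors),
                 unname(got$size_factors * scale), tolerance = 1e-10)
    expect_equal(got2$values, got$values, tolerance = 1e-10)
    # a global depth change rescales everything by that constant
    gotc <- rle_normalize(activity_matrix(m * 3))
    expect_equal(gotc$values, got$values * 3, tolerance = 1e-10)
  }
  # no all-positive row -> size factors undefined
  bad <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(rle_normalize(activity_matrix(bad)), "size factors")
})

test_that("rle_normalize agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(404)
  m <- matrix(rpois(200, 40) + 1, 50, 4,
              dimnames = list(paste0("r", 1:50), paste0("c", 1:4)))
  got <- rle_normalize(activity_matrix(m))
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(got$size_factors), unname(ref), tolerance = 1e-8)
})

test_that("impute_zeros replaces zeros with half the column minimum positive", {
  m <- matrix(c(0, 4, 8, 5, 0, 0), 3,
              dimnames = list(paste0("r", 1:3), c("c1", "c2")))
  norm <- activity_matrix(m, stage = "normalized", zero_mask = m == 0)
  imp <- impute_zeros(norm)
  expect_equal(unname(imp$values[, "c1"]), c(2, 4, 8))
  # both zeros in one column get the same imputed value
  expect_equal(unname(imp$values[, "c2"]), c(5, 2.5, 2.5))
  # zero mask preserved
  expect_identical(imp$zero_mask, m == 0)
  # column without zeros is untouched
  m2 <- matrix(c(1, 2), 1, dimnames = list("r1", c("c1", "c2")))
  expect_equal(impute_zeros(activity_matrix(m2, stage = "normalized"))$values,
               m2)
  # imputed values sit strictly below the positive values, preserving order
  set.seed(405)
  m3 <- matrix(rlnorm(60), 12, 5,
               dimnames = list(paste0("r", 1:12), paste0("c", 1:5)))
  m3[sample(length(m3), 12)] <- 0
  m3[1, ] <- 1  # keep no column all-zero
  imp3 <- impute_zeros(activity_matrix(m3, stage = "normalized"))
  for (j in 1:5) {
    pos <- m3[, j][m3[, j] > 0]
    zi <- m3[, j] == 0
    if (any(zi)) expect_true(all(imp3$values[zi, j] < min(pos)))
    expect_equal(imp3$values[!zi, j], m3[!zi, j])
  }
  # entirely zero column has no minimum
  allz <- matrix(c(1, 2, 0, 0), 2, dimnames = list(c("r1", "r2"), c("c1", "c2")))
  expect_error(impute_zeros(activity_matrix(allz, stage = "normalized")),
               "entirely zero")
})

test_that("se_contribution_filter applies the 3% rule per cell line", {
  v <- matrix(c(5, 2, 93, 10, 0, 0), nrow = 3,
              dimnames = list(c("ceA", "ceB", "ceC"), c("cl1", "cl2")))
  map <- data.frame(ce_id = c("ceA", "ceB", "ceC"),
                    se_id = "se1", assigned = TRUE)
  out <- se_contribution_filter(activity_matrix(v), map, threshold = 0.03)
  # 5/100 = 0.05 > 0.03 passes; 2/100 = 0.02 fails
  expect_true(out$mask["ceA", "cl1"])
  expect_false(out$mask["ceB", "cl1"])
  expect_true(out$mask["ceC", "cl1"])
  # cl2: SE total 10, all from ceA -> ratio 1 passes, others have 0
  expect_true(out$mask["ceA", "cl2"])
  expect_false(out$mask["ceB", "cl2"])
  # retained if passing anywhere
  expect_setequal(out$retained, c("ceA", "ceC"))
  # contribution ratios sum to 1 within an SE and cell line with positive total
  expect_equal(sum(out$contribution[, "cl1"]), 1)
  expect_equal(sum(out$contribution[, "cl2"]), 1)
  # an SE totalling zero in a cell line fails all of its CEs there
  v0 <- matrix(c(1, 1, 0, 0), nrow = 2,
               dimnames = list(c("x", "y"), c("cl1", "cl2")))
  map0 <- data.frame(ce_id = c("x", "y"), se_id = "se9", assigned = TRUE)
  out0 <- se_contribution_filter(activity_matrix(v0), map0)
  expect_false(any(out0$mask[, "cl2"]))
  # single-CE SE always passes where active
  expect_true(out0$mask["x", "cl1"])
  # unmapped CE row is rejected
  expect_error(se_contribution_filter(activity_matrix(v),
                                      map[1:2, ], threshold = 0.03),
               "absent")
})

test_that("activity_per_kb scales signal by region width", {
  expect_equal(activity_per_kb(500, 250), 2000)
  expect_equal(activity_per_kb(0, 100), 0)
  expect_equal(activity_per_kb(1000, 1000), 1000)
  expect_equal(activity_per_kb(c(500, 1000), c(250, 1000)), c(2000, 1000))
  expect_error(activity_per_kb(10, 0), "width")
  expect_error(activity_per_kb(-1, 10), "signal")
})
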