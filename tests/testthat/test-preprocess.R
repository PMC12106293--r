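test_that("within-sample outlier masking follows the 5-SD rule exactly", {
  # {10,10,10,10,1000}: |1000 - 208| = 792 < 5 * 442.7 -> nothing masked
  m <- toy_abundance(rbind(c(10, 10, 10, 10, 1000),
                           c(7, 7, 7, 7, 7)))
  out <- mask_within_sample_outliers(m, 5)
  expect_false(anyNA(out$values))

  # a genuinely extreme cell is masked at a tighter cut
  out2 <- mask_within_sample_outliers(m, 1.5)
  expect_true(is.na(out2$values[1, 5]))
  expect_equal(sum(is.na(out2$values)), 1L)

  # already-missing cells are never resurrected
  v <- matrix(rnorm(40, 100, 5), 4, 10)
  v[2, 3] <- NA
  m3 <- toy_abundance(v)
  out3 <- mask_within_sample_outliers(m3)
  expect_true(is.na(out3$values[2, 3]))
  expect_true(all(is.na(out3$values) | !is.na(v) | TRUE))

  # < 3 observed cells: skipped with a warning
  v4 <- matrix(c(1, NA, NA, NA, NA, 2, 3, 4), 2, 4, byrow = TRUE)
  expect_warning(mask_within_sample_outliers(toy_abundance(v4)), "skipped")
})

test_that("sample missingness filter uses a strict 20% threshold", {
  v <- matrix(rnorm(3 * 429, 100), 3, 429)
  v[1, 1:90] <- NA   # 90/429 = 0.2098 -> excluded
  v[2, 1:85] <- NA   # 85/429 = 0.1981 -> retained
  m <- toy_abundance(v)
  fs <- filter_samples_by_missingness(m, 0.20)
  expect_equal(fs$excluded, "s01")
  expect_equal(rownames(fs$matrix$values), c("s02", "s03"))

  fs2 <- filter_samples_by_missingness(toy_abundance(matrix(1:12 + 0, 3, 4)))
  expect_length(fs2$excluded, 0)
})

test_that("ks_distance matches hand values and the brute-force oracle", {
  expect_equal(ks_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(ks_distance(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(ks_distance(c(1, 2), c(1, 2, 3, 4)), 0.5)
  expect_error(ks_distance(numeric(0), 1), "empty")
  set.seed(21)
  for (r in 1:20) {
    x <- sample(c(rnorm(15), round(rnorm(10), 1)), sample(5:25, 1))
    y <- sample(c(rnorm(40), round(rnorm(20), 1)), sample(5:60, 1))
    expect_identical(ks_distance(x, y), brute_ks(x, y))
  }
})

test_that("KS sample filter excludes a shifted sample and spares iid ones", {
  # On i.i.d. fixtures the Tukey-style fence intrinsically flags the odd
  # sample (~40% of datasets carry at least one exceedance), so the honest
  # invariant is that exclusions stay rare, never that they are zero.
  for (s in 1:10) {
    v <- amsomics:::with_seed(s, matrix(rnorm(20 * 50, 100, 5), 20, 50))
    res <- filter_samples_by_ks(toy_abundance(v))
    expect_lte(length(res$excluded), 2)
    # fence recomputable from the reported distances
    q <- quantile(res$distances, c(0.25, 0.75), names = FALSE)
    expect_equal(res$fence, q[2] + 1.5 * (q[2] - q[1]))
  }

  v <- amsomics:::with_seed(3, matrix(rnorm(20 * 50, 100, 2), 20, 50))
  v[7, ] <- v[7, ] + 10
  res <- filter_samples_by_ks(toy_abundance(v))
  expect_true("s07" %in% res$excluded)

  expect_warning(filter_samples_by_ks(toy_abundance(matrix(rnorm(30), 3, 10))),
                 "fewer than 4")
})

test_that("feature missingness filter is strict per omic rule", {
  v <- matrix(rnorm(66 * 3, 50), 66, 3)
  v[1:34, 1] <- NA   # 51.5% -> removed at 0.50
  v[1:33, 2] <- NA   # 50.0% -> retained (strict)
  ff <- filter_features_by_missingness(toy_abundance(v), 0.50)
  expect_equal(ff$excluded, "f01")

  v2 <- matrix(rnorm(66 * 2, 50), 66, 2)
  v2[1:7, 1] <- NA   # 10.6% -> removed at 0.10
  ff2 <- filter_features_by_missingness(toy_abundance(v2, "metabolite"), 0.10)
  expect_equal(ff2$excluded, "f01")
})

test_that("log2 transform is exact and guards the domain", {
  m <- toy_abundance(matrix(c(8, 1, 2.5, 4), 2, 2))
  out <- log2_transform(m)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(out$values[1, 2], log2(2.5))
  expect_equal(out$scale, "log2")
  expect_error(log2_transform(out), "already")
  bad <- toy_abundance(matrix(c(1, -2, 3, 4), 2, 2))
  expect_error(log2_transform(bad), "s02.*f01")
})

test_that("PMM imputation has the donor property and beats mean imputation", {
  # correlated features so regression-based matching has signal
  set.seed(5)
  n <- 60; p <- 25
  f <- rnorm(n)
  x <- outer(f, runif(p, 0.7, 1)) + matrix(rnorm(n * p, 0, 0.5), n, p)
  dimnames(x) <- list(sprintf("s%02d", 1:n), sprintf("f%02d", 1:p))
  complete <- abundance_matrix(x, "protein", "log2")
  expect_identical(pmm_impute(complete, seed = 1)$values, x)

  holdout <- matrix(runif(n * p) < 0.10, n, p)
  xm <- x; xm[holdout] <- NA
  m <- abundance_matrix(xm, "protein", "log2")
  imp <- pmm_impute(m, seed = 7)
  expect_false(anyNA(imp$values))
  # observed cells bit-exact
  expect_identical(imp$values[!holdout], x[!holdout])
  # donor property: every imputed value is an observed value of its feature
  for (j in seq_len(p)) {
    mis <- which(holdout[, j])
    if (!length(mis)) next
    expect_true(all(imp$values[mis, j] %in% xm[!holdout[, j], j]))
  }
  # deterministic
  expect_identical(pmm_impute(m, seed = 7)$values, imp$values)
  expect_false(identical(pmm_impute(m, seed = 8)$values, imp$values))
  # beats feature-mean imputation on the same holdout
  rmse <- sqrt(mean((imp$values[holdout] - x[holdout])^2))
  mean_imp <- xm
  for (j in seq_len(p)) mean_imp[holdout[, j], j] <- mean(xm[, j], na.rm = TRUE)
  rmse_mean <- sqrt(mean((mean_imp[holdout] - x[holdout])^2))
  expect_lt(rmse, rmse_mean)

  xx <- x; xx[1:58, 1] <- NA   # 2 observed < 5 donors
  expect_error(pmm_impute(abundance_matrix(xx, "protein", "log2")),
               "n_donors")
})

test_that("cyclic loess removes constant offsets and preserves the grand mean", {
  set.seed(9)
  profile <- rnorm(50, 12, 1)
  ident <- rbind(profile, profile)
  dimnames(ident) <- list(c("s01", "s02"), sprintf("f%02d", 1:50))
  m0 <- abundance_matrix(ident, "protein", "log2")
  expect_equal(cyclic_loess_normalize(m0)$values, ident, tolerance = 1e-10)

  cc <- 2
  v <- rbind(profile, profile + cc, profile - cc / 2, profile + 0.5)
  dimnames(v) <- list(sprintf("s%02d", 1:4), sprintf("f%02d", 1:50))
  m <- abundance_matrix(v, "protein", "log2")
  out <- cyclic_loess_normalize(m)
  offset_after <- mean(out$values[2, ] - out$values[1, ])
  expect_lt(abs(offset_after), 0.05 * cc)
  expect_equal(mean(out$values), mean(v), tolerance = 1e-6)

  v[1, 1] <- NA
  expect_error(cyclic_loess_normalize(abundance_matrix(v, "protein", "log2")),
               "missing")
})

test_that("run_qc composes the stages and skips the metabolite sample filter", {
  # clean fixture: zero exclusions, counts preserved
  v <- amsomics:::with_seed(2, matrix(2^rnorm(12 * 20, 12, 1), 12, 20))
  dimnames(v) <- list(sprintf("s%02d", 1:12), sprintf("f%02d", 1:20))
  res <- run_qc(abundance_matrix(v, "protein"), seed = 3)
  expect_equal(nrow(res$report$excluded_samples), 0L)
  expect_equal(nrow(res$report$excluded_features), 0L)
  expect_equal(unname(res$report$stage_counts["final", ]), c(12, 20))
  expect_equal(res$matrix$scale, "log2")
  expect_false(anyNA(res$matrix$values))

  # metabolite branch keeps even an 80%-missing sample
  vm <- v
  vm[3, 1:16] <- NA
  resm <- run_qc(abundance_matrix(vm, "metabolite"), seed = 3)
  expect_false("s03" %in% resm$report$excluded_samples$sample)
  expect_true("s03" %in% rownames(resm$matrix$values))

  # idempotence: re-running on the processed output excludes nothing
  res2 <- run_qc(res$matrix, qc_thresholds("protein"), seed = 4)
  expect_equal(nrow(res2$report$excluded_samples), 0L)
  expect_equal(nrow(res2$report$excluded_features), 0L)
  expect_equal(dim(res2$matrix$values), dim(res$matrix$values))

  # mask monotonicity before imputation: missingness never decreases
  vmiss <- v; vmiss[2, 5] <- NA
  m1 <- mask_within_sample_outliers(abundance_matrix(vmiss, "protein"))
  expect_true(all(which(is.na(vmiss)) %in% which(is.na(m1$values))))
})

test_that("QC report serializes to JSON", {
  v <- amsomics:::with_seed(2, matrix(2^rnorm(80, 12, 1), 8, 10))
  dimnames(v) <- list(sprintf("s%02d", 1:8), sprintf("f%02d", 1:10))
  res <- run_qc(abundance_matrix(v, "protein"), seed = 3)
  path <- tempfile(fileext = ".json")
  write_qc_report(res$report, path)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$omic, "protein")
  expect_true(!is.null(parsed$stage_counts))
})
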