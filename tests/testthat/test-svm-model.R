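blobs <- function(n = 20, sep = 6, seed = 1) {
  amsomics:::with_seed(seed, {
    x <- rbind(matrix(rnorm(n, 0), n / 2), matrix(rnorm(n, sep), n / 2))
    colnames(x) <- c("a", "b")
    list(x = x, y = rep(0:1, each = n / 2))
  })
}

test_that("radial SVM separates blobs and calibrates symmetrically", {
  b <- blobs(40)
  model <- train_radial_svm(b$x, b$y, seed = 3)
  expect_equal(predict(model, b$x, type = "class"), b$y)
  p <- predict(model, b$x, type = "prob")
  expect_true(all(p > 0 & p < 1))

  # label flip maps probabilities to ~ 1 - p
  model_f <- train_radial_svm(b$x, 1L - b$y, seed = 3)
  p_f <- predict(model_f, b$x, type = "prob")
  expect_lt(max(abs(p_f - (1 - p))), 0.05)

  expect_error(train_radial_svm(b$x, rep(1, 40)), "both classes")
})

test_that("SMO solution satisfies the KKT box and margin conditions", {
  b <- blobs(30, sep = 2, seed = 7)
  fit <- svm_fit(b$x, b$y, C = 1)
  expect_true(all(abs(fit$sv_coef) <= 1 + 1e-6))
  dv <- svm_decision(fit, b$x)
  yf <- ifelse(b$y == 1, 1, -1)
  # free support vectors sit on the margin
  free <- abs(fit$sv_coef) > 1e-6 & abs(fit$sv_coef) < 1 - 1e-6
  if (any(free)) {
    sv_rows <- match(data.frame(t(fit$sv_x[free, , drop = FALSE])),
                     data.frame(t(scale(b$x))))
  }
  # all training points respect y f(x) >= 1 - slack with slack >= 0 implied
  # by the box: non-SVs must satisfy y f(x) >= 1 - 1e-4
  svm_scaled <- sweep(sweep(b$x, 2, fit$center), 2, fit$scale, "/")
  is_sv <- rowSums(outer(seq_len(nrow(svm_scaled)), seq_len(nrow(fit$sv_x)),
                         Vectorize(function(i, j) {
                           all(abs(svm_scaled[i, ] - fit$sv_x[j, ]) < 1e-12)
                         }))) > 0
  expect_true(all(yf[!is_sv] * dv[!is_sv] >= 1 - 1e-4))
})

test_that("roc_auc matches hand values and the pair-counting oracle", {
  res <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(res$auc, 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1))$auc, 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")

  set.seed(13)
  for (r in 1:100) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y <- rep(0:1, length.out = n)
    scores <- round(rnorm(n), sample(0:2, 1))  # force some ties
    expect_equal(roc_auc(scores, y)$auc, pair_auc(scores, y),
                 tolerance = 1e-12)
  }
})

test_that("calibration curve bins behave", {
  set.seed(17)
  p <- runif(2000)
  y <- rbinom(2000, 1, p)
  cal <- calibration_curve(p, y)
  expect_lte(nrow(cal), 10)
  expect_lt(max(abs(cal$mean_pred - cal$obs_rate)), 0.1)
  one <- calibration_curve(rep(1, 5), rep(1, 5))
  expect_equal(nrow(one), 1L)
  expect_equal(one$obs_rate - one$mean_pred, 0)
  expect_error(calibration_curve(c(0.5, 1.2), c(0, 1)), "\\[0, 1\\]")
})

test_that("kernel SHAP is exact: additive closed form, local accuracy, null player", {
  set.seed(19)
  bg <- matrix(rnorm(50 * 3), 50, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  ex <- matrix(rnorm(4 * 3), 4, 3, dimnames = list(NULL, colnames(bg)))
  f_add <- function(X) X[, 1] + 2 * X[, 2]  # x3 is a null player
  sh <- kernel_shap(f_add, bg, ex)
  expect_equal(sh$base_value, mean(f_add(bg)))
  expect_equal(sh$shap[, "x1"], ex[, 1] - mean(bg[, 1]), tolerance = 1e-10)
  expect_equal(sh$shap[, "x2"], 2 * (ex[, 2] - mean(bg[, 2])),
               tolerance = 1e-10)
  expect_equal(sh$shap[, "x3"], rep(0, 4), tolerance = 1e-10)
  # local accuracy
  expect_lt(max(abs(sh$base_value + rowSums(sh$shap) - f_add(ex))), 1e-8)
})

test_that("kernel SHAP equals the direct Shapley sum for a nonlinear model", {
  set.seed(23)
  p <- 5
  bg <- matrix(rnorm(12 * p), 12, p, dimnames = list(NULL, paste0("x", 1:p)))
  ex <- rnorm(p); names(ex) <- colnames(bg)
  f <- function(X) sin(X[, 1]) * X[, 2] + X[, 3]^2 - 0.5 * X[, 4] * X[, 1]
  sh <- kernel_shap(f, bg, matrix(ex, 1, dimnames = list(NULL, names(ex))))
  phi_oracle <- direct_shapley(f, bg, ex)
  expect_equal(unname(sh$shap[1, ]), phi_oracle, tolerance = 1e-8)
  expect_error(kernel_shap(f, matrix(0, 2, 21), matrix(0, 1, 21)), "p > 20")
})

test_that("decision curve identities hold", {
  y <- rep(c(1, 0), each = 10)   # prevalence 0.5
  dca <- decision_curve(list(perfect = y), y,
                        thresholds = c(0.1, 0.2, 0.5, 0.75))
  tn <- dca[dca$model == "treat_none", ]
  expect_equal(tn$net_benefit, rep(0, 4))
  ta <- dca[dca$model == "treat_all", ]
  expect_equal(ta$net_benefit[ta$threshold == 0.2], 0.5 - 0.5 * 0.25,
               tolerance = 1e-12)
  expect_equal(ta$net_benefit,
               0.5 - 0.5 * ta$threshold / (1 - ta$threshold),
               tolerance = 1e-12)
  pf <- dca[dca$model == "perfect", ]
  expect_equal(pf$net_benefit, rep(0.5, 4), tolerance = 1e-12)
  # all curves bounded by prevalence
  expect_true(all(dca$net_benefit <= 0.5 + 1e-12))
})

test_that("univariate clinical ROC reports AUC and a usable threshold", {
  clin <- data.frame(sample_id = paste0("s", 1:20),
                     AMS = rep(0:1, each = 10),
                     PEF = c(rnorm(10, 500, 20), rnorm(10, 350, 20)))
  res <- univariate_clinical_roc(clin, "PEF")
  expect_equal(res$auc, 1)
  expect_equal(res$direction, "<=")
  expect_gt(res$threshold, max(clin$PEF[clin$AMS == 1]))
  expect_lt(res$threshold, min(clin$PEF[clin$AMS == 0]))
  # AUC invariant under a monotone transform
  clin$PEF <- exp(clin$PEF / 100)
  expect_equal(univariate_clinical_roc(clin, "PEF")$auc, 1)
  # null variable: AUC near 0.5
  set.seed(5)
  clin2 <- data.frame(sample_id = paste0("s", 1:500),
                      AMS = rbinom(500, 1, 0.5), HR = rnorm(500))
  expect_lt(abs(univariate_clinical_roc(clin2, "HR")$auc - 0.5), 0.1)
})

test_that("model serialization round-trips predictions bit-exactly", {
  b <- blobs(30, sep = 3, seed = 9)
  model <- train_radial_svm(b$x, b$y, seed = 2)
  path <- tempfile(fileext = ".json")
  write_svm_model(model, path)
  model2 <- read_svm_model(path)
  newx <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(predict(model, newx, type = "prob"),
                   predict(model2, newx, type = "prob"))
})

test_that("evaluate_submodels covers the types and the full model", {
  set.seed(33)
  n <- 40
  y <- rep(0:1, each = n / 2)
  x <- cbind(SBP = rnorm(n) + y, "protein:P1" = rnorm(n) + 1.2 * y,
             "metabolite:M1" = rnorm(n) + 1.2 * y)
  xv <- cbind(SBP = rnorm(20) + rep(0:1, each = 10),
              "protein:P1" = rnorm(20) + 1.2 * rep(0:1, each = 10),
              "metabolite:M1" = rnorm(20) + 1.2 * rep(0:1, each = 10))
  res <- evaluate_submodels(x, y, xv, rep(0:1, each = 10),
                            types = c("clinical", "protein", "metabolite"),
                            seed = 4)
  expect_setequal(setdiff(names(res), "dca"),
                  c("full", "clinical", "protein", "metabolite"))
  expect_equal(res$protein$features, "protein:P1")
  for (nm in setdiff(names(res), "dca")) {
    expect_true(res[[nm]]$train$auc >= 0 && res[[nm]]$train$auc <= 1)
  }
  expect_setequal(unique(res$dca$train$model),
                  c("full", "clinical", "protein", "metabolite",
                    "treat_all", "treat_none"))
})
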