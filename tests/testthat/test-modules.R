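make_integrated <- function(n = 20, p_prot = 6, p_met = 4, seed = 2) {
  amsomics:::with_seed(seed, {
    pv <- matrix(rnorm(n * p_prot, 12), n, p_prot,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 sprintf("P%02d", 1:p_prot)))
    mv <- matrix(rnorm(n * p_met, 10), n, p_met,
                 dimnames = list(sprintf("s%02d", 1:n),
                                 sprintf("MB%02d", 1:p_met)))
    list(p = abundance_matrix(pv, "protein", "log2"),
         m = abundance_matrix(mv, "metabolite", "log2"))
  })
}

test_that("concatenate_omics binds layers with omic-prefixed ids", {
  om <- make_integrated()
  ix <- concatenate_omics(om$p, om$m)
  expect_equal(dim(ix$values), c(20L, 10L))
  expect_equal(colnames(ix$values)[1], "protein:P01")
  expect_equal(colnames(ix$values)[7], "metabolite:MB01")
  expect_equal(ix$omic, rep(c("protein", "metabolite"), c(6, 4)))
  # stable order: proteins then metabolites, samples as in the protein layer
  expect_equal(rownames(ix$values), rownames(om$p$values))

  om2 <- make_integrated()
  rownames(om2$m$values) <- sprintf("t%02d", 1:20)
  expect_error(concatenate_omics(om2$p, om2$m), "no samples")
  om3 <- make_integrated()
  om3$p$values[1, 1] <- NA
  expect_error(concatenate_omics(om3$p, om3$m), "complete")
})

test_that("spearman_dissimilarity matches rank arithmetic", {
  x <- cbind(a = c(1, 2, 3), b = c(1, 3, 2), c = c(3, 2, 1))
  d <- spearman_dissimilarity(x)
  expect_equal(diag(d), rep(0, 3), ignore_attr = TRUE)
  expect_equal(d["a", "b"], 0.5)      # rho = 0.5
  expect_equal(d["a", "c"], 2)        # perfectly anti-monotone
  expect_true(isSymmetric(unname(d)))
  xc <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_error(spearman_dissimilarity(xc), "constant")
})

test_that("ward_cluster agrees with the naive O(n^3) oracle", {
  set.seed(31)
  for (r in 1:10) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 5), n)
    d <- as.matrix(dist(x))
    dimnames(d) <- list(paste0("o", 1:n), paste0("o", 1:n))
    hc <- ward_cluster(d)
    expect_true(all(diff(hc$height) >= -1e-10))
    coph <- as.matrix(cophenetic(hc))
    coph_oracle <- naive_ward_cophenetic(d)
    dimnames(coph_oracle) <- dimnames(d)
    expect_equal(coph, coph_oracle[rownames(coph), colnames(coph)],
                 tolerance = 1e-9)
  }
  # two well-separated blocks: the final merge height is strictly largest
  x <- rbind(matrix(rnorm(20, 0, .1), 10), matrix(rnorm(20, 5, .1), 10))
  d <- as.matrix(dist(x))
  dimnames(d) <- list(paste0("o", 1:20), paste0("o", 1:20))
  hc <- ward_cluster(d)
  expect_gt(hc$height[19], max(hc$height[1:18]) * 2)
  expect_error(ward_cluster(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("dynamic tree cut recovers planted blocks and rejects noise", {
  bm <- make_block_matrix(60, blocks = 6, block_size = 60, loading = 0.78,
                          seed = 41)
  d <- spearman_dissimilarity(bm$x)
  asg <- dynamic_tree_cut(ward_cluster(d), d, min_cluster_size = 45)
  expect_gte(adjusted_rand_index(asg, bm$member), 0.9)

  # single homogeneous block -> one module, nothing unassigned
  bm1 <- make_block_matrix(60, blocks = 1, block_size = 100, loading = 0.7,
                           seed = 42)
  d1 <- spearman_dissimilarity(bm1$x)
  asg1 <- dynamic_tree_cut(ward_cluster(d1), d1, min_cluster_size = 45)
  expect_equal(unname(asg1), rep(1L, 100))

  # pure noise -> mostly unassigned, across 5 seeds
  for (s in 1:5) {
    xn <- amsomics:::with_seed(100 + s,
                               matrix(rnorm(50 * 300), 50, 300))
    colnames(xn) <- sprintf("f%03d", 1:300)
    rownames(xn) <- sprintf("s%03d", 1:50)
    dn <- spearman_dissimilarity(xn)
    asgn <- dynamic_tree_cut(ward_cluster(dn), dn, min_cluster_size = 45)
    expect_gte(mean(asgn == 0), 0.8)
  }

  expect_error(dynamic_tree_cut(ward_cluster(d1), d1, min_cluster_size = 60),
               "min_cluster_size")
})

test_that("module eigengene is the leading PC with the sign convention", {
  # identical features: eigengene proportional to the shared z-profile
  z <- rnorm(15)
  x <- matrix(rep(z, 4), 15, 4) ; colnames(x) <- paste0("f", 1:4)
  rownames(x) <- paste0("s", 1:15)
  e <- module_eigengene(x, colnames(x))
  expect_equal(sqrt(sum(e^2)), 1, tolerance = 1e-9)
  expect_equal(abs(cor(e, z)), 1, tolerance = 1e-9)
  expect_gte(cor(e, scale(z)[, 1]), 0)

  # variance explained >= any single member profile (SVD optimality)
  set.seed(7)
  x2 <- matrix(rnorm(20 * 6), 20, 6) + rnorm(20)
  dimnames(x2) <- list(paste0("s", 1:20), paste0("f", 1:6))
  e2 <- module_eigengene(x2, colnames(x2))
  z2 <- scale(x2)
  var_expl <- function(v) sum(crossprod(z2, v / sqrt(sum(v^2)))^2)
  sv <- svd(t(z2))
  expect_equal(var_expl(e2), sv$d[1]^2, tolerance = 1e-8)
  for (j in 1:6) expect_lte(var_expl(z2[, j]) - 1e-8, var_expl(e2))

  # flipping every member flips the eigengene with it (sign rule follows
  # the member-averaged profile)
  e3 <- module_eigengene(-x2, colnames(x2))
  expect_equal(e3, -e2, tolerance = 1e-8)

  x2[, 2] <- 5
  expect_error(module_eigengene(x2, colnames(x2)), "constant")
})

test_that("merge_close_modules merges correlated modules only", {
  set.seed(13)
  n <- 40
  f1 <- rnorm(n); f2 <- rnorm(n)
  # modules 1 and 2 share a latent factor; module 3 is orthogonal
  x <- cbind(outer(f1, rep(1, 30)) + matrix(rnorm(n * 30, 0, .4), n),
             outer(f1, rep(1, 30)) + matrix(rnorm(n * 30, 0, .4), n),
             outer(f2, rep(1, 30)) + matrix(rnorm(n * 30, 0, .4), n))
  colnames(x) <- sprintf("f%03d", 1:90)
  rownames(x) <- sprintf("s%03d", 1:n)
  asg <- setNames(rep(1:3, each = 30), colnames(x))
  ms <- merge_close_modules(x, asg, cut_height = 0.4)
  expect_equal(nrow(ms$eigengenes), 2L)
  merged <- unname(ms$assignment[1] == ms$assignment[31])
  expect_true(merged)
  expect_false(unname(ms$assignment[1] == ms$assignment[61]))
  # partition preserved
  expect_setequal(names(ms$assignment), colnames(x))

  # orthogonal modules: unchanged
  asg2 <- setNames(rep(1:2, c(30, 30)), colnames(x)[c(1:30, 61:90)])
  ms2 <- merge_close_modules(x[, c(1:30, 61:90)], asg2, cut_height = 0.4)
  expect_equal(nrow(ms2$eigengenes), 2L)
})

test_that("module-trait association computes r, p and BH flags", {
  set.seed(17)
  n <- 30
  E <- rbind(M1 = rnorm(n), M2 = rnorm(n))
  colnames(E) <- sprintf("s%03d", 1:n)
  clin <- data.frame(sample_id = colnames(E),
                     AMS_degree = as.numeric(E["M1", ] > 0) +
                       (E["M1", ] > 1),
                     SBP = rnorm(n, 118, 8))
  # exact trait copy: r = 1, p ~ 0
  clin$PEF <- E["M2", ]
  res <- module_trait_association(E, clin,
                                  traits = c("AMS_degree", "SBP", "PEF"))
  row <- res$table[res$table$module == "M2" & res$table$trait == "PEF", ]
  expect_equal(row$r, 1, tolerance = 1e-12)
  expect_lt(row$p, 1e-20)
  expect_true(all(res$table$p_adj >= res$table$p - 1e-15, na.rm = TRUE))
  expect_true(all(res$table$p_adj <= 1, na.rm = TRUE))
  expect_true("M1" %in% res$ams_modules)

  # pairwise-complete handling and the < 4 pairs guard
  clin$SBP[1:27] <- NA
  res2 <- module_trait_association(E, clin,
                                   traits = c("AMS_degree", "SBP"))
  expect_true(is.na(res2$table$r[res2$table$trait == "SBP"][1]))
})

test_that("BH over the grid matches the step-up hand computation", {
  p <- c(0.01, 0.02, 0.04)
  expect_equal(amsomics:::adjust_p(p, "BH"), c(0.03, 0.03, 0.04))
  expect_equal(amsomics:::adjust_p(p, "BH"), bh_oracle(p))
})

test_that("independent eigengenes and traits stay mostly non-significant", {
  set.seed(23)
  frac <- replicate(200, {
    E <- matrix(rnorm(5 * 25), 5, 25,
                dimnames = list(paste0("M", 1:5), paste0("s", 1:25)))
    clin <- data.frame(sample_id = colnames(E),
                       AMS_degree = sample(0:2, 25, replace = TRUE),
                       SBP = rnorm(25), PEF = rnorm(25), HR = rnorm(25))
    res <- module_trait_association(E, clin,
                                    traits = c("AMS_degree", "SBP", "PEF",
                                               "HR"))
    mean(res$table$significant)
  })
  expect_lte(mean(frac), 0.05 + 0.02)
})
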