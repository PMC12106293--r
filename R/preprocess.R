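#' Quality-control thresholds
#'
#' Defaults follow the study design this package reimplements: within-sample
#' abundances more than 5 SDs from the sample mean are treated as missing;
#' samples missing more than 20% of proteins are excluded (proteins only);
#' samples whose abundance distribution sits above the Q3 + 1.5 IQR fence of
#' per-sample Kolmogorov-Smirnov distances are excluded; features missing in
#' more than 50% (proteins) or 10% (metabolites) of the remaining samples
#' are dropped. All comparisons are strict (">" as stated).
#'
#' @param omic "protein" or "metabolite"; sets the feature-missingness
#'   default and whether the sample-missingness filter applies.
#' @param outlier_sd within-sample outlier cut in SD units.
#' @param max_sample_missing_frac sample-level missingness cut (proteins).
#' @param max_feature_missing_frac feature-level missingness cut.
#' @param ks_fence_multiplier IQR multiplier of the KS exclusion fence.
#' @return a `QCThresholds` object.
#' @export
qc_thresholds <- function(omic = c("protein", "metabolite"),
                          outlier_sd = 5,
                          max_sample_missing_frac = 0.20,
                          max_feature_missing_frac = NULL,
                          ks_fence_multiplier = 1.5) {
  omic <- match.arg(omic)
  if (is.null(max_feature_missing_frac)) {
    max_feature_missing_frac <- if (omic == "protein") 0.50 else 0.10
  }
  stopifnot(outlier_sd > 0, ks_fence_multiplier > 0,
            max_sample_missing_frac > 0, max_sample_missing_frac <= 1,
            max_feature_missing_frac > 0, max_feature_missing_frac <= 1)
  structure(list(omic = omic, outlier_sd = outlier_sd,
                 max_sample_missing_frac = max_sample_missing_frac,
                 max_feature_missing_frac = max_feature_missing_frac,
                 ks_fence_multiplier = ks_fence_multiplier,
                 apply_sample_missing_filter = omic == "protein"),
            class = "QCThresholds")
}

#' Mask within-sample outlier abundances
#'
#' For each sample, cells deviating from that sample's mean by more than
#' `n_sd` sample SDs (mean and SD over the sample's non-missing cells,
#' including the candidate cell) are set missing. Samples with fewer than 3
#' observed cells are skipped with a warning (SD undefined); zero-variance
#' samples mask nothing.
#'
#' @param m a raw-scale `AbundanceMatrix`.
#' @param n_sd SD multiplier (default 5).
#' @return the matrix with outlier cells set to `NA`.
#' @export
mask_within_sample_outliers <- function(m, n_sd = 5) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  v <- m$values
  for (i in seq_len(nrow(v))) {
    x <- v[i, ]
    obs <- !is.na(x)
    if (sum(obs) < 3) {
      warning("sample ", rownames(v)[i],
              " has < 3 observed cells; outlier masking skipped")
      next
    }
    mu <- mean(x[obs]); s <- sd(x[obs])
    if (s == 0) next
    v[i, obs & abs(x - mu) > n_sd * s] <- NA
  }
  replace_values(m, v)
}

#' Exclude samples by missingness fraction
#'
#' @param m an `AbundanceMatrix` (mask current).
#' @param max_frac samples with missing fraction strictly above this are
#'   removed (default 0.20).
#' @return list with the filtered `matrix`, `excluded` sample ids, and the
#'   per-sample missing `fractions`.
#' @export
filter_samples_by_missingness <- function(m, max_frac = 0.20) {
  frac <- rowMeans(is.na(m$values))
  drop <- frac > max_frac
  if (all(drop)) stop("all samples excluded by the missingness filter")
  list(matrix = subset_samples(m, !drop),
       excluded = rownames(m$values)[drop],
       fractions = frac)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum gap between the empirical distribution functions of the two
#' vectors, in \[0, 1\].
#'
#' @param sample_values,pooled_values non-empty numeric vectors (no NA).
#' @return the KS statistic.
#' @export
ks_distance <- function(sample_values, pooled_values) {
  x <- sample_values[!is.na(sample_values)]
  y <- pooled_values[!is.na(pooled_values)]
  if (!length(x) || !length(y)) stop("empty vector in ks_distance")
  # evaluate both ECDFs over the merged support
  z <- sort(unique(c(x, y)))
  fx <- findInterval(z, sort(x)) / length(x)
  fy <- findInterval(z, sort(y)) / length(y)
  max(abs(fx - fy))
}

#' Exclude distribution-outlier samples by KS fence
#'
#' Computes the KS distance of each sample's observed values against the
#' pooled observed values of all current samples (the tested sample
#' included), then excludes samples above the fence
#' Q3 + `fence_multiplier` x IQR of the per-sample distances. With fewer
#' than 4 samples the fence is not computable and nothing is excluded.
#'
#' @param m an `AbundanceMatrix` (sample-missingness filter already applied
#'   for proteins).
#' @param fence_multiplier IQR multiplier (default 1.5).
#' @return list with the filtered `matrix`, `excluded` ids, per-sample
#'   `distances`, and the `fence` value.
#' @export
filter_samples_by_ks <- function(m, fence_multiplier = 1.5) {
  v <- m$values
  pooled <- v[!is.na(v)]
  d <- vapply(seq_len(nrow(v)), function(i) {
    xi <- v[i, ]
    ks_distance(xi[!is.na(xi)], pooled)
  }, numeric(1))
  names(d) <- rownames(v)
  if (nrow(v) < 4) {
    warning("fewer than 4 samples; KS fence not computable, nothing excluded")
    return(list(matrix = m, excluded = character(0), distances = d,
                fence = NA_real_))
  }
  q <- quantile(d, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + fence_multiplier * (q[2] - q[1])
  drop <- d > fence
  list(matrix = subset_samples(m, !drop),
       excluded = rownames(v)[drop], distances = d, fence = fence)
}

#' Exclude features by missingness fraction
#'
#' @param m an `AbundanceMatrix` (sample filters applied).
#' @param max_frac features missing in strictly more than this fraction of
#'   samples are removed.
#' @return list with the filtered `matrix`, `excluded` feature ids and the
#'   per-feature missing `fractions`.
#' @export
filter_features_by_missingness <- function(m, max_frac) {
  frac <- colMeans(is.na(m$values))
  drop <- frac > max_frac
  list(matrix = subset_features(m, !drop),
       excluded = colnames(m$values)[drop],
       fractions = frac)
}

#' Log2-transform a raw abundance matrix
#'
#' @param m a raw-scale `AbundanceMatrix` with strictly positive observed
#'   values.
#' @return the matrix on log2 scale.
#' @export
log2_transform <- function(m) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (m$scale != "raw") stop("matrix is already on log2 scale")
  bad <- which(!is.na(m$values) & m$values <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-positive abundance at sample %s, feature %s",
                 rownames(m$values)[bad[1, 1]],
                 colnames(m$values)[bad[1, 2]]))
  }
  m$values <- log2(m$values)
  m$scale <- "log2"
  m
}

#' Predictive mean matching imputation
#'
#' Single-imputation chained equations with PMM donors: missing cells are
#' initialised by random draws from their feature's observed values; then
#' for `n_cycles` passes, features with missing cells are visited in order
#' of ascending missingness, the target is regressed on its
#' `n_predictors` most-correlated features (correlations frozen on the
#' initialised matrix; full-width regressions are singular at p >> n), and
#' each missing cell receives the observed value of one of the `n_donors`
#' rows with the nearest regression predictions, drawn uniformly. Observed
#' cells are never modified; rank-deficient regressions fall back to a
#' ridge penalty of 1e-6.
#'
#' @param m a log2-scale `AbundanceMatrix`; every feature needs at least
#'   `n_donors` observed values and every sample at least one.
#' @param n_donors donor pool size (default 5).
#' @param n_cycles chained-equation cycles (default 10).
#' @param seed integer seed; the result is deterministic given the seed.
#' @param n_predictors size of the correlation-screened predictor set.
#' @return the completed matrix (no missing cells).
#' @export
pmm_impute <- function(m, n_donors = 5, n_cycles = 10, seed = 1L,
                       n_predictors = 20) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (m$scale != "log2") stop("pmm_impute expects a log2-scale matrix")
  v <- m$values
  if (!anyNA(v)) return(m)
  obs <- !is.na(v)
  n_obs_feat <- colSums(obs)
  if (any(n_obs_feat < n_donors)) {
    stop("feature(s) with fewer than n_donors observed values: ",
         paste(head(colnames(v)[n_obs_feat < n_donors], 5), collapse = ", "))
  }
  if (any(rowSums(obs) == 0)) stop("sample(s) with no observed values")

  with_seed(seed, {
    targets <- which(colSums(!obs) > 0)
    targets <- targets[order(colSums(!obs)[targets])]

    # initialise by feature-wise random observed draws
    for (j in targets) {
      mis <- which(!obs[, j])
      v[mis, j] <- sample(v[obs[, j], j], length(mis), replace = TRUE)
    }

    # predictor sets frozen on the initialised (complete) matrix
    cm <- cor(v)
    diag(cm) <- 0
    pred_of <- lapply(targets, function(j) {
      k <- min(n_predictors, ncol(v) - 1L)
      order(abs(cm[, j]), decreasing = TRUE)[seq_len(k)]
    })
    names(pred_of) <- as.character(targets)

    for (cycle in seq_len(n_cycles)) {
      for (j in targets) {
        pred <- pred_of[[as.character(j)]]
        rows_obs <- which(obs[, j])
        rows_mis <- which(!obs[, j])
        A <- cbind(1, v[, pred, drop = FALSE])
        Ao <- A[rows_obs, , drop = FALSE]
        yo <- v[rows_obs, j]
        cf <- tryCatch({
          fit <- qr(Ao)
          if (fit$rank < ncol(Ao)) stop("rank deficient")
          qr.coef(fit, yo)
        }, error = function(e) {
          g <- crossprod(Ao) + diag(1e-6, ncol(Ao))
          solve(g, crossprod(Ao, yo))
        })
        yhat <- drop(A %*% cf)
        for (r in rows_mis) {
          d <- abs(yhat[rows_obs] - yhat[r])
          donors <- rows_obs[order(d)[seq_len(min(n_donors,
                                                  length(rows_obs)))]]
          v[r, j] <- v[donors[sample.int(length(donors), 1)], j]
        }
      }
    }
    replace_values(m, v)
  })
}

#' Cyclic loess normalization
#'
#' Pairwise MA-trend removal: for every unordered pair of samples the loess
#' fit of M = x_i - x_j on A = (x_i + x_j)/2 is split half-and-half between
#' the two samples, iterated over all pairs. Backed by
#' `limma::normalizeCyclicLoess(method = "pairs")`, the implementation the
#' normalization is defined against.
#'
#' @param m a complete log2-scale `AbundanceMatrix`.
#' @param span loess span (default 0.7).
#' @param iterations cycles over all pairs (default 3).
#' @return the normalized matrix.
#' @export
cyclic_loess_normalize <- function(m, span = 0.7, iterations = 3) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (m$scale != "log2") stop("cyclic loess expects log2 scale")
  if (anyNA(m$values)) stop("matrix has missing cells; impute first")
  out <- limma::normalizeCyclicLoess(t(m$values), span = span,
                                     iterations = iterations,
                                     method = "pairs")
  out <- t(out)
  dimnames(out) <- dimnames(m$values)
  replace_values(m, out)
}

#' Run the full QC branch for one omic layer
#'
#' Order of operations: mask within-sample outliers, exclude over-missing
#' samples (proteins only; metabolite profiles carry too few missing values
#' for this filter to apply), exclude KS distribution outliers, drop
#' over-missing features, log2-transform, PMM imputation, cyclic loess
#' normalization. KS distances are computed on the raw (pre-log2) scale.
#'
#' @param m a raw-scale `AbundanceMatrix`.
#' @param thresholds a `QCThresholds`; defaults to `qc_thresholds(m$omic)`.
#' @param seed seed for the imputation stage.
#' @param pmm_donors,pmm_cycles,loess_span imputation / normalization tuning.
#' @return list with the processed `matrix` (log2, complete, normalized)
#'   and the `report` (a `QCReport`).
#' @export
run_qc <- function(m, thresholds = NULL, seed = 1L,
                   pmm_donors = 5, pmm_cycles = 10, loess_span = 0.7) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  if (is.null(thresholds)) thresholds <- qc_thresholds(m$omic)
  t0 <- c(samples = nrow(m$values), features = ncol(m$values))
  stages <- list(input = t0)
  raw_input <- m$scale == "raw"   # outlier mask and KS are raw-scale steps

  n_missing_before <- sum(is.na(m$values))
  m1 <- if (raw_input) mask_within_sample_outliers(m, thresholds$outlier_sd) else m
  n_outlier_masked <- sum(is.na(m1$values)) - n_missing_before
  stages$outlier_mask <- c(samples = nrow(m1$values),
                           features = ncol(m1$values))

  excluded_samples <- data.frame(sample = character(0), reason = character(0),
                                 value = numeric(0), threshold = numeric(0),
                                 stringsAsFactors = FALSE)
  sample_missing_frac <- rowMeans(is.na(m1$values))

  if (thresholds$apply_sample_missing_filter) {
    fs <- filter_samples_by_missingness(m1, thresholds$max_sample_missing_frac)
    if (length(fs$excluded)) {
      excluded_samples <- rbind(excluded_samples, data.frame(
        sample = fs$excluded, reason = "missingness",
        value = fs$fractions[fs$excluded],
        threshold = thresholds$max_sample_missing_frac,
        stringsAsFactors = FALSE))
    }
    m2 <- fs$matrix
  } else {
    m2 <- m1
  }
  stages$sample_missingness <- c(samples = nrow(m2$values),
                                 features = ncol(m2$values))

  if (raw_input) {
    ks <- filter_samples_by_ks(m2, thresholds$ks_fence_multiplier)
  } else {
    ks <- list(matrix = m2, excluded = character(0),
               distances = setNames(numeric(0), character(0)),
               fence = NA_real_)
  }
  if (length(ks$excluded)) {
    excluded_samples <- rbind(excluded_samples, data.frame(
      sample = ks$excluded, reason = "ks_outlier",
      value = ks$distances[ks$excluded], threshold = ks$fence,
      stringsAsFactors = FALSE))
  }
  m3 <- ks$matrix
  stages$ks_filter <- c(samples = nrow(m3$values), features = ncol(m3$values))

  ff <- filter_features_by_missingness(m3, thresholds$max_feature_missing_frac)
  excluded_features <- data.frame(
    feature = ff$excluded,
    missing_frac = unname(ff$fractions[ff$excluded]),
    threshold = rep(thresholds$max_feature_missing_frac,
                    length(ff$excluded)),
    stringsAsFactors = FALSE)
  m4 <- ff$matrix
  stages$feature_missingness <- c(samples = nrow(m4$values),
                                  features = ncol(m4$values))

  m5 <- if (m4$scale == "raw") log2_transform(m4) else m4
  m6 <- pmm_impute(m5, n_donors = pmm_donors, n_cycles = pmm_cycles,
                   seed = derive_seed(seed, paste0("pmm-", m$omic)))
  m7 <- cyclic_loess_normalize(m6, span = loess_span)
  stages$final <- c(samples = nrow(m7$values), features = ncol(m7$values))

  report <- structure(list(
    omic = m$omic,
    thresholds = thresholds,
    sample_missing_frac = sample_missing_frac,
    ks_distances = ks$distances,
    ks_fence = ks$fence,
    excluded_samples = excluded_samples,
    excluded_features = excluded_features,
    n_outlier_cells_masked = n_outlier_masked,
    stage_counts = do.call(rbind, stages)), class = "QCReport")

  list(matrix = m7, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QCReport [%s]\n", x$omic))
  print(x$stage_counts)
  cat(sprintf("outlier cells masked: %d; samples excluded: %d; features excluded: %d\n",
              x$n_outlier_cells_masked, nrow(x$excluded_samples),
              nrow(x$excluded_features)))
  if (!is.na(x$ks_fence)) cat(sprintf("KS fence: %.4f\n", x$ks_fence))
  invisible(x)
}

#' Serialize a QC report to JSON
#' @param report a `QCReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  out <- unclass(report)
  out$thresholds <- unclass(out$thresholds)
  out$stage_counts <- as.data.frame(out$stage_counts)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
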