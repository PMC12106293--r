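#' Screen clinical variables for AMS association
#'
#' Continuous variables are compared between AMS and non-AMS groups by the
#' two-sided Mann-Whitney U test (exact for small samples without ties,
#' normal approximation with tie correction otherwise); categorical
#' variables (Smoke, or any variable taking only values 0/1) by Fisher's
#' exact test. Variables with unadjusted p below `alpha` are selected; no
#' multiplicity correction is applied at this screening stage.
#'
#' @param clinical data.frame with the clinical variables and binary `AMS`.
#' @param alpha selection level on raw p (default 0.05).
#' @param variables columns to test (default: the 26 schema variables
#'   present).
#' @return data.frame (variable, test, statistic, p, selected).
#' @export
screen_clinical <- function(clinical, alpha = 0.05, variables = NULL) {
  if (is.null(variables)) {
    variables <- intersect(ams_clinical_variables(), names(clinical))
  }
  y <- clinical$AMS
  if (is.null(y) || length(unique(stats::na.omit(y))) != 2) {
    stop("clinical table must carry a binary AMS label")
  }
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; yy <- y[ok]
    if (min(table(yy)) < 2) {
      warning("variable ", v, " has < 2 observations in a group; skipped")
      return(data.frame(variable = v, test = NA_character_,
                        statistic = NA_real_, p = NA_real_,
                        selected = FALSE, stringsAsFactors = FALSE))
    }
    categorical <- v == "Smoke" || all(x %in% c(0, 1))
    if (categorical) {
      ft <- fisher.test(table(factor(x, levels = sort(unique(x))),
                              factor(yy, levels = c(0, 1))))
      data.frame(variable = v, test = "fisher", statistic = NA_real_,
                 p = ft$p.value, selected = ft$p.value < alpha,
                 stringsAsFactors = FALSE)
    } else {
      wt <- suppressWarnings(wilcox.test(x[yy == 1], x[yy == 0],
                                         alternative = "two.sided"))
      data.frame(variable = v, test = "mann-whitney",
                 statistic = unname(wt$statistic), p = wt$p.value,
                 selected = wt$p.value < alpha, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Mutual information between a continuous feature and a binary label
#'
#' Nearest-neighbor estimator for the continuous-discrete case: for each
#' point, the distance to its `k`-th nearest neighbor within its own class
#' defines a radius; the estimate averages digamma terms of the full-sample
#' counts inside those radii,
#' MI = psi(N) - <psi(N_y)> + psi(k) - <psi(m_i)>, in nats, clipped at 0.
#'
#' @param x numeric vector (length >= 10).
#' @param y binary label vector (both classes present).
#' @param k neighbor count (default 3).
#' @return non-negative MI estimate in nats.
#' @export
mutual_information <- function(x, y, k = 3) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 10) stop("need at least 10 observations")
  y <- as.integer(as.factor(y))
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (sd(x) == 0) return(0)
  max(mi_cd_cpp(as.numeric(x), y, as.integer(k)), 0)
}

# MI for every column of a matrix against y (compiled core)
mi_all_features <- function(x, y, k = 3) {
  y <- as.integer(as.factor(y))
  pmax(mi_cd_matrix(x, y, as.integer(k)), 0)
}

#' Mutual-information radial-SVM recursive feature elimination
#'
#' Iterative elimination driven by fold-averaged mutual-information ranks:
#' each round draws a fresh stratified k-fold partition, computes the MI of
#' every surviving feature against the label on each fold's training
#' portion, ranks features per fold (descending MI) and averages the ranks
#' across folds; while more than `halve_above` features survive, the worst
#' half (floor(p/2)) is eliminated per round, then one feature per round.
#' The final rank is the reverse elimination order (rank 1 = eliminated
#' last). Deterministic given `seed`.
#'
#' @param x samples x features matrix (the molecular pool from the
#'   AMS-associated modules).
#' @param y binary labels.
#' @param k_folds folds per round (default 3).
#' @param halve_above halving threshold (default 100).
#' @param seed integer seed.
#' @param k_mi MI neighbor count.
#' @return a `FeatureRanking`: list with `elimination_order`, `final_rank`
#'   (named, 1 = best), `rounds` (per-round survivors / averaged ranks /
#'   eliminated), and `seed`.
#' @export
mi_svm_rfe <- function(x, y, k_folds = 3, halve_above = 100, seed = 1L,
                       k_mi = 3) {
  stopifnot(is.matrix(x), ncol(x) >= 2, nrow(x) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) != 2) stop("y must be binary with both classes")
  features <- colnames(x)
  if (is.null(features)) features <- paste0("F", seq_len(ncol(x)))

  with_seed(seed, {
    surviving <- seq_len(ncol(x))
    elimination <- integer(0)
    rounds <- list()
    while (length(surviving) > 1) {
      p <- length(surviving)
      # fresh stratified partition; every training portion needs both classes
      for (attempt in 1:100) {
        fold <- stratified_folds(y, k_folds)
        ok <- all(vapply(seq_len(k_folds), function(f) {
          length(unique(y[fold != f])) == 2L
        }, logical(1)))
        if (ok) break
        if (attempt == 100) stop("could not draw folds with both classes")
      }
      ranks <- matrix(0, nrow = p, ncol = k_folds)
      for (f in seq_len(k_folds)) {
        tr <- fold != f
        mi <- mi_all_features(x[tr, surviving, drop = FALSE], y[tr], k_mi)
        ranks[, f] <- rank(-mi, ties.method = "average")
      }
      avg_rank <- rowMeans(ranks)
      n_drop <- if (p > halve_above) p %/% 2 else 1L
      # ties broken by feature name so the result is invariant to the
      # column order of the input matrix
      drop_idx <- order(-avg_rank, features[surviving])[seq_len(n_drop)]
      eliminated <- surviving[drop_idx]
      rounds[[length(rounds) + 1]] <- list(
        surviving = features[surviving],
        avg_rank = setNames(avg_rank, features[surviving]),
        eliminated = features[eliminated])
      elimination <- c(elimination, eliminated)
      surviving <- surviving[-drop_idx]
    }
    elimination <- c(elimination, surviving)
    final_rank <- setNames(rev(seq_along(elimination)),
                           features[elimination])
    final_rank <- final_rank[features]
    structure(list(elimination_order = features[elimination],
                   final_rank = final_rank,
                   rounds = rounds, seed = seed),
              class = "FeatureRanking")
  })
}

#' @export
print.FeatureRanking <- function(x, ...) {
  cat(sprintf("FeatureRanking over %d features (%d rounds); top 5: %s\n",
              length(x$final_rank), length(x$rounds),
              paste(names(sort(x$final_rank))[1:min(5, length(x$final_rank))],
                    collapse = ", ")))
  invisible(x)
}

#' Generalization-error curve over model sizes
#'
#' For each k in 1..`k_max`, estimates the misclassification error of a
#' radial-kernel SVM trained on the top-k ranked features by repeated
#' stratified cross-validation (features standardized with training-fold
#' statistics; C = 1, gamma = 1/k). The chosen model size minimises the
#' mean error, smallest k on ties.
#'
#' @param x samples x features matrix.
#' @param y binary labels.
#' @param ranking a `FeatureRanking` covering the columns of `x`.
#' @param k_max largest model size (default 30; truncated to p with a
#'   warning).
#' @param k_folds CV folds (default 3).
#' @param n_repeats CV repetitions (default 20).
#' @param seed integer seed.
#' @param cost SVM cost parameter.
#' @return a `CvErrorCurve`: data.frame `curve` (k, mean_error, sd_error)
#'   plus `chosen_k`.
#' @export
estimate_error_curve <- function(x, y, ranking, k_max = 30, k_folds = 3,
                                 n_repeats = 20, seed = 1L, cost = 1) {
  stopifnot(inherits(ranking, "FeatureRanking"))
  y <- as.integer(y)
  p <- ncol(x)
  if (k_max > p) {
    warning("k_max exceeds feature count; truncated to ", p)
    k_max <- p
  }
  ord <- names(sort(ranking$final_rank))
  if (!all(ord[seq_len(k_max)] %in% colnames(x))) {
    stop("ranking does not cover the feature matrix")
  }
  with_seed(seed, {
    res <- matrix(NA_real_, nrow = k_max, ncol = n_repeats)
    for (r in seq_len(n_repeats)) {
      fold <- stratified_folds(y, k_folds)
      for (k in seq_len(k_max)) {
        feats <- ord[seq_len(k)]
        err <- 0; n_test <- 0
        for (f in seq_len(k_folds)) {
          tr <- fold != f
          xt <- x[tr, feats, drop = FALSE]
          ctr <- colMeans(xt); scl <- apply(xt, 2, sd)
          scl[scl == 0] <- 1
          xt <- sweep(sweep(xt, 2, ctr), 2, scl, "/")
          xv <- sweep(sweep(x[!tr, feats, drop = FALSE], 2, ctr), 2, scl, "/")
          fit <- svm_fit(xt, y[tr], C = cost, gamma = 1 / k, scale = FALSE)
          pred <- as.integer(svm_decision(fit, xv) > 0)
          err <- err + sum(pred != y[!tr])
          n_test <- n_test + sum(!tr)
        }
        res[k, r] <- err / n_test
      }
    }
    curve <- data.frame(k = seq_len(k_max),
                        mean_error = rowMeans(res),
                        sd_error = apply(res, 1, sd))
    chosen <- which.min(curve$mean_error)  # which.min takes smallest index on ties
    structure(list(curve = curve, chosen_k = chosen, n_repeats = n_repeats,
                   seed = seed),
              class = "CvErrorCurve")
  })
}

#' @export
print.CvErrorCurve <- function(x, ...) {
  cat(sprintf("CvErrorCurve: k = 1..%d, chosen k = %d (mean error %.3f)\n",
              nrow(x$curve), x$chosen_k,
              x$curve$mean_error[x$chosen_k]))
  invisible(x)
}

#' Univariate logistic biomarker filter
#'
#' Fits one logistic regression per standardized candidate feature and
#' keeps those whose two-sided Wald slope p-value survives Bonferroni
#' correction over the whole candidate family. Complete separation
#' (diverging slope or non-convergence) is flagged and the p-value replaced
#' by a likelihood-ratio test.
#'
#' @param candidates samples x candidates numeric matrix.
#' @param y binary labels.
#' @param alpha family-wise level (default 0.05).
#' @param types optional per-candidate type tags carried into the panel.
#' @return a `BiomarkerPanel`: data.frame (feature, type, slope, p,
#'   p_bonferroni, separation, selected) with attribute `m` (family size).
#' @export
univariate_logistic_filter <- function(candidates, y, alpha = 0.05,
                                       types = NULL) {
  stopifnot(is.matrix(candidates))
  y <- as.integer(y)
  if (length(unique(y)) != 2 || !all(y %in% c(0L, 1L))) {
    stop("y must be binary 0/1")
  }
  m <- ncol(candidates)
  if (is.null(types)) types <- rep(NA_character_, m)
  rows <- lapply(seq_len(m), function(j) {
    x <- candidates[, j]
    ok <- !is.na(x)
    xx <- x[ok]; yy <- y[ok]
    s <- sd(xx)
    if (s == 0) {
      return(data.frame(feature = colnames(candidates)[j], type = types[j],
                        slope = 0, p = 1, separation = FALSE,
                        stringsAsFactors = FALSE))
    }
    xx <- (xx - mean(xx)) / s
    fit <- suppressWarnings(glm(yy ~ xx, family = binomial(),
                                control = list(maxit = 50, epsilon = 1e-8)))
    slope <- coef(fit)[2]
    separation <- !fit$converged || abs(slope) > 10
    if (separation) {
      p <- pchisq(fit$null.deviance - fit$deviance, df = 1,
                  lower.tail = FALSE)
    } else {
      p <- summary(fit)$coefficients[2, 4]
    }
    data.frame(feature = colnames(candidates)[j], type = types[j],
               slope = unname(slope), p = unname(p),
               separation = separation, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$p_bonferroni <- pmin(1, tab$p * m)
  tab$selected <- tab$p_bonferroni < alpha
  tab <- tab[, c("feature", "type", "slope", "p", "p_bonferroni",
                 "separation", "selected")]
  structure(tab, m = m, class = c("BiomarkerPanel", "data.frame"))
}
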