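#' Train the radial-SVM prediction model with probability calibration
#'
#' Fits a radial-kernel SVM on the (internally standardized) panel matrix,
#' then fits a Platt-style sigmoid on cross-validated decision values so
#' that predicted probabilities are honest for calibration and decision
#' curve analysis.
#'
#' @param x samples x features panel matrix.
#' @param y binary labels (0/1), both classes present.
#' @param C soft-margin cost (default 1).
#' @param gamma kernel width (default 1/ncol(x)).
#' @param calib_folds folds for the cross-validated decision values
#'   feeding the sigmoid (default 5).
#' @param seed integer seed for the calibration folds.
#' @return an `SvmModel`.
#' @export
train_radial_svm <- function(x, y, C = 1, gamma = 1 / ncol(x),
                             calib_folds = 5, seed = 1L) {
  stopifnot(is.matrix(x))
  y <- as.integer(y)
  if (length(unique(y)) != 2) stop("y must contain both classes")
  fit <- svm_fit(x, y, C = C, gamma = gamma, scale = TRUE)
  dv_cv <- with_seed(seed, {
    fold <- stratified_folds(y, calib_folds)
    dv <- numeric(length(y))
    for (f in seq_len(calib_folds)) {
      tr <- fold != f
      if (length(unique(y[tr])) < 2) next
      fit_f <- svm_fit(x[tr, , drop = FALSE], y[tr], C = C, gamma = gamma)
      dv[!tr] <- svm_decision(fit_f, x[!tr, , drop = FALSE])
    }
    dv
  })
  cal <- suppressWarnings(glm(y ~ dv_cv, family = binomial()))
  structure(list(svm = fit,
                 calibration = unname(coef(cal)),
                 C = C, gamma = gamma, features = colnames(x),
                 n_train = length(y)),
            class = "SvmModel")
}

#' Predict from an `SvmModel`
#'
#' @param object an `SvmModel`.
#' @param newdata samples x features matrix (original scale).
#' @param type "prob" (calibrated probability), "decision" (raw SVM
#'   decision value) or "class" (probability thresholded at 0.5).
#' @param ... unused.
#' @return numeric vector (or integer for "class").
#' @export
predict.SvmModel <- function(object, newdata, type = c("prob", "decision",
                                                       "class"), ...) {
  type <- match.arg(type)
  dv <- svm_decision(object$svm, newdata)
  if (type == "decision") return(dv)
  p <- plogis(object$calibration[1] + object$calibration[2] * dv)
  if (type == "prob") p else as.integer(p >= 0.5)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores with trapezoidal AUC; ties get
#' half credit, so the AUC equals the Mann-Whitney identity U/(n1 n0).
#'
#' @param scores numeric scores (higher = more class-1).
#' @param y binary labels (0/1), both present.
#' @return list with `roc` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  # cumulative counts at each unique threshold
  uniq <- !duplicated(s)
  tp <- cumsum(yy == 1); fp <- cumsum(yy == 0)
  last <- which(c(uniq[-1], TRUE))
  roc <- data.frame(threshold = s[last],
                    fpr = fp[last] / n0, tpr = tp[last] / n1)
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0), roc)
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Calibration curve
#'
#' Equal-width bins on \[0, 1\]; per bin the mean predicted probability and
#' observed event rate. Empty bins are omitted.
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param y binary labels.
#' @param bins number of bins (default 10).
#' @return data.frame (bin, n, mean_pred, obs_rate).
#' @export
calibration_curve <- function(probs, y, bins = 10) {
  if (any(probs < 0 | probs > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  y <- as.integer(y)
  bin <- pmin(floor(probs * bins) + 1L, bins)
  out <- lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin = b, n = sum(sel), mean_pred = mean(probs[sel]),
               obs_rate = mean(y[sel]))
  })
  do.call(rbind, out)
}

shapley_kernel_weights <- function(p, sizes) {
  (p - 1) / (choose(p, sizes) * sizes * (p - sizes))
}

#' Exact kernel SHAP attributions
#'
#' Shapley additive explanations by full coalition enumeration (2^p
#' coalitions, p <= 20): absent features are marginalised by replacing
#' them with background rows and averaging; attributions solve the
#' Shapley-kernel weighted least squares with the local-accuracy
#' constraints (phi_0 = E f over background, sum phi = f(x) - phi_0) built
#' in, which at full enumeration reproduces exact Shapley values.
#'
#' @param model an `SvmModel`, or any function mapping a samples x features
#'   matrix to a numeric prediction vector.
#' @param background samples x features background matrix (marginalisation
#'   reference).
#' @param explain samples x features matrix of points to explain.
#' @param predict_fun optional override of the model's prediction function.
#' @return list with `shap` (explain-rows x features matrix) and
#'   `base_value` (mean model output over the background).
#' @export
kernel_shap <- function(model, background, explain, predict_fun = NULL) {
  if (is.null(predict_fun)) {
    predict_fun <- if (is.function(model)) {
      model
    } else if (inherits(model, "SvmModel")) {
      function(X) predict(model, X, type = "prob")
    } else stop("unsupported model; supply predict_fun")
  }
  background <- as.matrix(background)
  explain <- as.matrix(explain)
  p <- ncol(background)
  if (p > 20) stop("p > 20: full enumeration infeasible; sampling mode not implemented")
  if (ncol(explain) != p) stop("explain and background must share features")
  nb <- nrow(background)

  # all 2^p coalitions as a logical matrix
  Z <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  colnames(Z) <- colnames(background)
  sizes <- rowSums(Z)
  base_value <- mean(predict_fun(background))

  shap <- matrix(NA_real_, nrow(explain), p,
                 dimnames = list(rownames(explain), colnames(background)))
  mid <- which(sizes > 0 & sizes < p)
  w <- shapley_kernel_weights(p, sizes[mid])

  for (e in seq_len(nrow(explain))) {
    x <- explain[e, ]
    v <- numeric(nrow(Z))
    for (s in seq_len(nrow(Z))) {
      if (sizes[s] == 0) { v[s] <- base_value; next }
      Xb <- background
      on <- Z[s, ]
      Xb[, on] <- matrix(x[on], nb, sum(on), byrow = TRUE)
      v[s] <- mean(predict_fun(Xb))
    }
    v_full <- v[sizes == p]
    delta <- v_full - base_value
    # eliminate phi_p via the efficiency constraint, then solve the WLS
    Zm <- Z[mid, , drop = FALSE] * 1
    u <- v[mid] - base_value - Zm[, p] * delta
    A <- Zm[, -p, drop = FALSE] - Zm[, p]
    WA <- A * w
    phi_rest <- solve(crossprod(WA, A), crossprod(WA, u))
    phi <- c(phi_rest, delta - sum(phi_rest))
    shap[e, ] <- phi
  }
  list(shap = shap, base_value = base_value)
}

#' Decision curve analysis
#'
#' Net benefit NB(p_t) = TP/n - FP/n * p_t/(1 - p_t) over a threshold
#' grid, for one or several probability vectors, with treat-all and
#' treat-none reference policies.
#'
#' @param prob_sets named list of probability vectors (or one vector).
#' @param y binary labels.
#' @param thresholds decision thresholds (default 0.01..0.80 by 0.01);
#'   values >= 1 are excluded.
#' @return data.frame (model, threshold, net_benefit).
#' @export
decision_curve <- function(prob_sets, y, thresholds = seq(0.01, 0.80, 0.01)) {
  if (!is.list(prob_sets)) prob_sets <- list(model = prob_sets)
  y <- as.integer(y)
  n <- length(y)
  prev <- mean(y)
  thresholds <- thresholds[thresholds < 1 & thresholds >= 0]
  nb_of <- function(pred_pos, pt) {
    tp <- sum(pred_pos & y == 1); fp <- sum(pred_pos & y == 0)
    tp / n - fp / n * pt / (1 - pt)
  }
  out <- list()
  for (nm in names(prob_sets)) {
    probs <- prob_sets[[nm]]
    if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
    nb <- vapply(thresholds, function(pt) nb_of(probs >= pt, pt), numeric(1))
    out[[nm]] <- data.frame(model = nm, threshold = thresholds,
                            net_benefit = nb, stringsAsFactors = FALSE)
  }
  out$treat_all <- data.frame(
    model = "treat_all", threshold = thresholds,
    net_benefit = prev - (1 - prev) * thresholds / (1 - thresholds),
    stringsAsFactors = FALSE)
  out$treat_none <- data.frame(model = "treat_none", threshold = thresholds,
                               net_benefit = 0, stringsAsFactors = FALSE)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

evaluate_predictions <- function(probs, y, bins = 10) {
  ra <- roc_auc(probs, y)
  list(roc = ra$roc, auc = ra$auc,
       accuracy = mean(as.integer(probs >= 0.5) == as.integer(y)),
       calibration = calibration_curve(probs, y, bins))
}

#' Train and evaluate per-phenotype-type sub-models and the full model
#'
#' Trains one radial SVM per feature type (clinical / protein / metabolite)
#' plus the full panel, evaluates each on the training and validation
#' cohorts (ROC/AUC, accuracy, calibration), and adds logistic-regression
#' probability sets for decision curve analysis, mirroring the split
#' between SVM sub-model ROC panels and logistic DCA.
#'
#' @param x_train,x_valid samples x panel-features matrices.
#' @param y_train,y_valid binary labels.
#' @param types per-feature type tags aligned with the panel columns.
#' @param C,gamma,seed SVM settings; gamma defaults per sub-model to
#'   1/p_type.
#' @return list of per-model evaluation blocks (`full` plus one per type),
#'   each holding `model`, `train`, `valid`, and DCA probability sets.
#' @export
evaluate_submodels <- function(x_train, y_train, x_valid, y_valid, types,
                               C = 1, gamma = NULL, seed = 1L) {
  stopifnot(ncol(x_train) == length(types))
  groups <- c(list(full = seq_along(types)),
              split(seq_along(types), types))
  out <- list()
  dca_train <- list(); dca_valid <- list()
  for (nm in names(groups)) {
    idx <- groups[[nm]]
    if (!length(idx)) { warning("type ", nm, " has no features; skipped"); next }
    xt <- x_train[, idx, drop = FALSE]
    xv <- x_valid[, idx, drop = FALSE]
    g <- if (is.null(gamma)) 1 / length(idx) else gamma
    model <- train_radial_svm(xt, y_train, C = C, gamma = g,
                              seed = derive_seed(seed, paste0("sub-", nm)))
    pt <- predict(model, xt, type = "prob")
    pv <- predict(model, xv, type = "prob")
    # logistic version for DCA
    df_t <- data.frame(y = y_train, xt)
    lg <- suppressWarnings(glm(y ~ ., data = df_t, family = binomial()))
    lp_t <- predict(lg, type = "response")
    lp_v <- suppressWarnings(
      predict(lg, newdata = data.frame(xv), type = "response"))
    out[[nm]] <- list(features = colnames(x_train)[idx], model = model,
                      train = evaluate_predictions(pt, y_train),
                      valid = evaluate_predictions(pv, y_valid))
    dca_train[[nm]] <- pmin(pmax(lp_t, 0), 1)
    dca_valid[[nm]] <- pmin(pmax(lp_v, 0), 1)
  }
  out$dca <- list(train = decision_curve(dca_train, y_train),
                  valid = decision_curve(dca_valid, y_valid))
  out
}

#' Univariate clinical ROC with best threshold
#'
#' Per clinical variable: univariate logistic score, ROC AUC, and the best
#' decision threshold by Youden's J, reported on the original variable
#' scale with its direction.
#'
#' @param clinical clinical data.frame with `AMS`.
#' @param variables variables to evaluate.
#' @return data.frame (variable, n, auc, threshold, direction).
#' @export
univariate_clinical_roc <- function(clinical, variables) {
  y_all <- as.integer(clinical$AMS)
  rows <- lapply(variables, function(v) {
    x <- clinical[[v]]
    ok <- !is.na(x) & !is.na(y_all)
    x <- x[ok]; y <- y_all[ok]
    fit <- suppressWarnings(glm(y ~ x, family = binomial()))
    score <- predict(fit, type = "response")
    auc <- roc_auc(score, y)$auc
    # Youden over candidate cutpoints (midpoints of sorted unique values)
    ux <- sort(unique(x))
    cuts <- (head(ux, -1) + tail(ux, -1)) / 2
    direction <- if (coef(fit)[2] >= 0) ">=" else "<="
    j <- vapply(cuts, function(ct) {
      pos <- if (direction == ">=") x >= ct else x <= ct
      mean(pos[y == 1]) - mean(pos[y == 0])
    }, numeric(1))
    best <- if (length(cuts)) cuts[which.max(j)] else NA_real_
    data.frame(variable = v, n = length(y), auc = auc, threshold = best,
               direction = direction, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize an `SvmModel` to a JSON-ready list (and back)
#'
#' Round-trips all numeric content at full precision so that predictions
#' reproduce bit-exactly.
#'
#' @param model an `SvmModel`.
#' @return a plain list.
#' @export
svm_model_to_list <- function(model) {
  list(sv_x = model$svm$sv_x, sv_coef = model$svm$sv_coef, b = model$svm$b,
       gamma = model$svm$gamma, C = model$svm$C,
       center = model$svm$center, scale = model$svm$scale,
       features = model$svm$features, calibration = model$calibration,
       n_train = model$n_train)
}

#' @rdname svm_model_to_list
#' @param lst list produced by `svm_model_to_list` (possibly via JSON).
#' @export
svm_model_from_list <- function(lst) {
  sv_x <- as.matrix(lst$sv_x)
  colnames(sv_x) <- lst$features
  svm <- structure(list(sv_x = sv_x, sv_coef = as.numeric(lst$sv_coef),
                        b = lst$b, C = lst$C, gamma = lst$gamma,
                        center = setNames(as.numeric(lst$center),
                                          lst$features),
                        scale = setNames(as.numeric(lst$scale),
                                         lst$features),
                        features = lst$features),
                   class = "radial_svm")
  structure(list(svm = svm, calibration = as.numeric(lst$calibration),
                 C = lst$C, gamma = lst$gamma, features = lst$features,
                 n_train = lst$n_train),
            class = "SvmModel")
}

#' Write / read an `SvmModel` as JSON
#' @param model an `SvmModel`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_svm_model <- function(model, path) {
  # digits = I(17): %.17g significant digits, the shortest width that
  # guarantees a bit-exact double round trip (digits = NA truncates at 15)
  jsonlite::write_json(svm_model_to_list(model), path, digits = I(17),
                       auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  svm_model_from_list(jsonlite::read_json(path, simplifyVector = TRUE))
}
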