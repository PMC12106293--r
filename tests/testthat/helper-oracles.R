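# Independent oracles used across the suite. These deliberately take the
# slow, obvious route (double loops, full enumeration) and never share code
# with the implementation they check.

# brute-force two-sample KS: evaluate both ECDFs at every observed point
brute_ks <- function(x, y) {
  pts <- c(x, y)
  fx <- vapply(pts, function(p) mean(x <= p), numeric(1))
  fy <- vapply(pts, function(p) mean(y <= p), numeric(1))
  max(abs(fx - fy))
}

# AUC by explicit pair counting (Mann-Whitney identity, half credit on ties)
pair_auc <- function(scores, y) {
  s1 <- scores[y == 1]
  s0 <- scores[y == 0]
  tot <- 0
  for (a in s1) for (b in s0) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(s1) * length(s0))
}

# Benjamini-Hochberg step-up, written from the definition
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

bonferroni_oracle <- function(p) pmin(p * length(p), 1)

# naive O(n^3) agglomeration under the ward.D2 Lance-Williams recurrence:
# operate on squared dissimilarities, report sqrt heights and the full
# cophenetic matrix
naive_ward_cophenetic <- function(d) {
  n <- nrow(d)
  d2 <- d^2
  active <- as.list(seq_len(n))
  D <- d2
  coph <- matrix(0, n, n)
  sizes <- rep(1, n)
  repeat {
    k <- length(active)
    if (k == 1) break
    best <- c(NA, NA); bestv <- Inf
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      if (D[a, b] < bestv) { bestv <- D[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    h <- sqrt(bestv)
    coph[active[[a]], active[[b]]] <- h
    coph[active[[b]], active[[a]]] <- h
    na <- sizes[a]; nb <- sizes[b]
    newD <- numeric(k)
    for (c in seq_len(k)) {
      if (c == a || c == b) next
      nc <- sizes[c]
      newD[c] <- ((na + nc) * D[a, c] + (nb + nc) * D[b, c] -
                    nc * D[a, b]) / (na + nb + nc)
    }
    D[a, ] <- newD; D[, a] <- newD; D[a, a] <- 0
    sizes[a] <- na + nb
    active[[a]] <- c(active[[a]], active[[b]])
    D <- D[-b, -b, drop = FALSE]
    sizes <- sizes[-b]
    active[[b]] <- NULL
  }
  coph
}

# exact Shapley values by the permutation-weight sum over all coalitions,
# with marginalisation by background averaging (same value function as
# kernel SHAP, independent solver)
direct_shapley <- function(f, background, x) {
  p <- ncol(background)
  nb <- nrow(background)
  subsets <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), p)))
  v <- apply(subsets, 1, function(on) {
    Xb <- background
    if (any(on)) Xb[, on] <- matrix(x[on], nb, sum(on), byrow = TRUE)
    mean(f(Xb))
  })
  key <- subsets %*% 2^(seq_len(p) - 1)
  vof <- function(on) v[match(sum(2^(which(on) - 1)), key)]
  phi <- numeric(p)
  for (j in seq_len(p)) {
    rest <- setdiff(seq_len(p), j)
    for (s in 0:(p - 1)) {
      combs <- if (s == 0) list(integer(0)) else
        utils::combn(rest, s, simplify = FALSE)
      w <- factorial(s) * factorial(p - s - 1) / factorial(p)
      for (S in combs) {
        on <- rep(FALSE, p); on[S] <- TRUE
        v0 <- vof(on)
        on[j] <- TRUE
        phi[j] <- phi[j] + w * (vof(on) - v0)
      }
    }
  }
  phi
}

# planted-block feature matrix: `blocks` latent factors, `block_size`
# features each, within-block correlation set by `loading`, plus optional
# pure-noise features
make_block_matrix <- function(n_samples, blocks, block_size, loading = 0.7,
                              n_noise = 0, seed = 1) {
  amsomics:::with_seed(seed, {
    f <- matrix(rnorm(blocks * n_samples), blocks, n_samples)
    p <- blocks * block_size
    member <- rep(seq_len(blocks), each = block_size)
    x <- t(f[member, , drop = FALSE]) * loading +
      matrix(rnorm(n_samples * p, 0, sqrt(1 - loading^2)), n_samples, p)
    if (n_noise > 0) {
      x <- cbind(x, matrix(rnorm(n_samples * n_noise), n_samples))
      member <- c(member, rep(0L, n_noise))
    }
    colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
    rownames(x) <- sprintf("s%03d", seq_len(n_samples))
    list(x = x, member = member)
  })
}

# small abundance matrix helper
toy_abundance <- function(values, omic = "protein", scale = "raw") {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("s%02d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("f%02d", seq_len(ncol(values)))
  }
  abundance_matrix(values, omic = omic, scale = scale)
}

# numeric quadrature of the closed-form MI for a two-Gaussian mixture with
# class means 0 and d, unit SD, class-1 probability p1
mi_gaussian_quadrature <- function(d, p1 = 0.5) {
  integrand <- function(x) {
    f0 <- dnorm(x, 0, 1); f1 <- dnorm(x, d, 1)
    fm <- (1 - p1) * f0 + p1 * f1
    t0 <- ifelse(f0 > 0, (1 - p1) * f0 * log(f0 / fm), 0)
    t1 <- ifelse(f1 > 0, p1 * f1 * log(f1 / fm), 0)
    t0 + t1
  }
  stats::integrate(integrand, -10, 10 + d, subdivisions = 500)$value
}

# map each true module id to the detected label by feature majority
majority_map <- function(truth_labels, detected_labels) {
  vapply(split(detected_labels, truth_labels), function(v) {
    tb <- table(v)
    as.integer(names(tb)[which.max(tb)])
  }, integer(1))
}

prefixed_ids <- function(truth, features = NULL) {
  ids <- names(truth$module_of_feature)
  pref <- ifelse(truth$feature_omic == "protein", "protein:", "metabolite:")
  out <- setNames(paste0(pref, ids), ids)
  if (is.null(features)) out else unname(out[features])
}
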