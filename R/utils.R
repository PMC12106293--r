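#' @useDynLib amsomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats aggregate approx coef complete.cases cor cutree dist
#'   fisher.test glm hclust lowess median model.matrix pchisq plogis pnorm
#'   pt qnorm quantile rbinom rmultinom rnorm runif sd setNames var
#'   wilcox.test as.dist binomial cophenetic predict
#' @importFrom utils head read.delim write.table packageVersion tail
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed`, so library code never clobbers the
#' caller's random stream. All stochastic operations in this package route
#' their `seed` argument through here.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministic and stable across platforms; keeps the result in the 32-bit
#' signed integer range so it is a valid `set.seed()` argument.
#'
#' @param seed global integer seed.
#' @param tag character stage tag.
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483587) + 1L
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b integer/character label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# stratified k-fold assignment; returns integer fold id per observation.
# Errors only if a class has fewer members than requested folds would allow
# a training portion for.
stratified_folds <- function(y, k) {
  y <- as.integer(y)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# Benjamini-Hochberg / Bonferroni via stats::p.adjust kept behind one name so
# the correction used is greppable at call sites.
adjust_p <- function(p, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  stats::p.adjust(p, method = method)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 15)
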