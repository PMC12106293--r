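#' Concatenate protein and metabolite matrices
#'
#' Column-binds the two omic layers over the samples that passed both QC
#' branches (order of the protein matrix preserved). Feature ids are
#' prefixed with their omic tag to guarantee uniqueness.
#'
#' @param p,m complete log2-scale `AbundanceMatrix` objects (protein and
#'   metabolite respectively).
#' @return an `IntegratedMatrix`: list with `values` (samples x features)
#'   and `omic` (per-feature tag).
#' @export
concatenate_omics <- function(p, m) {
  stopifnot(inherits(p, "AbundanceMatrix"), inherits(m, "AbundanceMatrix"))
  if (anyNA(p$values) || anyNA(m$values)) {
    stop("matrices must be complete before integration")
  }
  common <- intersect(rownames(p$values), rownames(m$values))
  if (!length(common)) stop("no samples passed both QC branches")
  pv <- p$values[common, , drop = FALSE]
  mv <- m$values[common, , drop = FALSE]
  colnames(pv) <- paste0(p$omic, ":", colnames(pv))
  colnames(mv) <- paste0(m$omic, ":", colnames(mv))
  structure(list(values = cbind(pv, mv),
                 omic = rep(c(p$omic, m$omic), c(ncol(pv), ncol(mv)))),
            class = "IntegratedMatrix")
}

#' @export
print.IntegratedMatrix <- function(x, ...) {
  cat(sprintf("IntegratedMatrix: %d samples x %d features (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%d %s", table(x$omic)[unique(x$omic)],
                            unique(x$omic)), collapse = " + ")))
  invisible(x)
}

#' Spearman correlation dissimilarity between features
#'
#' d(a, b) = 1 - Spearman rho(a, b), in \[0, 2\]; anti-correlated features
#' are maximally distant (signed convention). Ties receive average ranks.
#'
#' @param x an `IntegratedMatrix` (or samples x features matrix) with at
#'   least 3 samples and no constant feature.
#' @return symmetric feature x feature dissimilarity matrix with zero
#'   diagonal.
#' @export
spearman_dissimilarity <- function(x) {
  v <- if (inherits(x, "IntegratedMatrix")) x$values else x
  if (nrow(v) < 3) stop("need at least 3 samples")
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    stop("constant feature(s): ",
         paste(head(colnames(v)[sds == 0], 5), collapse = ", "))
  }
  d <- 1 - cor(v, method = "spearman")
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomeration under the Ward variance-minimising Lance-Williams update
#' applied to squared dissimilarities, with square-rooted output heights
#' (the `ward.D2` convention). Heights are non-decreasing.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal.
#' @return an `hclust` object.
#' @export
ward_cluster <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("dissimilarity not symmetric")
  hclust(as.dist(d), method = "ward.D2")
}

mean_within <- function(d, idx) {
  k <- length(idx)
  if (k < 2) return(0)
  (sum(d[idx, idx]) / 2) / (k * (k - 1) / 2)
}

mean_cross <- function(d, a, b) mean(d[a, b])

#' Dynamic hybrid tree cut
#'
#' Branch-shape-aware module detection in two stages. Detection: the
#' dendrogram is first over-segmented into small coherent chunks, which are
#' then greedily re-merged while any pair of chunks is no further apart
#' than the looser of the two is internally (`gap` slack); surviving
#' clusters are accepted as modules only if they reach `min_cluster_size`
#' and their mean internal dissimilarity stays below `max_core_dissim`
#' (pure-noise branches fail this core-tightness test and stay unassigned).
#' Assignment: each unassigned leaf joins the module with the smallest
#' average dissimilarity, provided that distance is within the module's
#' assignment radius (mean + 3 SD of its members' own average
#' within-module dissimilarity); otherwise it keeps label 0.
#'
#' @param dendrogram an `hclust` object from [ward_cluster()].
#' @param d the dissimilarity matrix the tree was built from.
#' @param min_cluster_size minimum module size (default 45).
#' @param gap slack added to the internal dissimilarity when testing
#'   whether two branches are separated.
#' @param max_core_dissim maximum mean internal dissimilarity of an
#'   accepted module.
#' @param assign_unlabeled run the assignment stage (default TRUE).
#' @return integer vector of module labels (0 = unassigned), named by
#'   feature, with modules numbered 1..K in decreasing size order.
#' @export
dynamic_tree_cut <- function(dendrogram, d, min_cluster_size = 45,
                             gap = 0.15, max_core_dissim = 0.8,
                             assign_unlabeled = TRUE) {
  n <- length(dendrogram$order)
  if (min_cluster_size > n / 2) {
    stop("min_cluster_size exceeds half the number of features")
  }
  # stage 1: over-segment so no chunk straddles two modules
  k_init <- max(2L, min(n, as.integer(floor(2 * n / min_cluster_size))))
  chunks <- cutree(dendrogram, k = k_init)
  groups <- split(seq_len(n), chunks)

  # stage 2: coherence merge; merge the closest admissible pair each step.
  # Pairwise dissimilarity sums are maintained incrementally so each pass is
  # O(K^2) on scalars.
  K <- length(groups)
  if (K >= 2) {
    cs <- rowsum(d, chunks)
    S <- t(rowsum(t(cs), chunks))      # S[a,b] = sum of d over a x b
    sz <- vapply(groups, length, integer(1))
    active <- rep(TRUE, K)
    repeat {
      idx <- which(active)
      if (length(idx) < 2) break
      w <- ifelse(sz[idx] > 1,
                  diag(S)[idx] / (sz[idx] * (sz[idx] - 1)), 0)
      best <- NULL; best_cross <- Inf
      for (ai in seq_along(idx)) {
        a <- idx[ai]
        if (ai == length(idx)) break
        bs <- idx[(ai + 1):length(idx)]
        cr <- S[a, bs] / (sz[a] * sz[bs])
        adm <- cr <= pmax(w[ai], w[(ai + 1):length(idx)]) + gap
        if (any(adm)) {
          bmin <- which.min(ifelse(adm, cr, Inf))
          if (cr[bmin] < best_cross) {
            best <- c(a, bs[bmin]); best_cross <- cr[bmin]
          }
        }
      }
      if (is.null(best)) break
      a <- best[1]; b <- best[2]
      # after the row then column add, S[a,a] = Saa + Sbb + 2*Sab as required
      S[a, ] <- S[a, ] + S[b, ]
      S[, a] <- S[, a] + S[, b]
      groups[[a]] <- c(groups[[a]], groups[[b]])
      sz[a] <- sz[a] + sz[b]
      active[b] <- FALSE
    }
    groups <- groups[active]
  }

  # acceptance: size and core tightness
  assignment <- integer(n)
  accepted <- Filter(function(g) {
    length(g) >= min_cluster_size && mean_within(d, g) <= max_core_dissim
  }, groups)
  if (length(accepted)) {
    accepted <- accepted[order(vapply(accepted, length, integer(1)),
                               decreasing = TRUE)]
    for (k in seq_along(accepted)) assignment[accepted[[k]]] <- k
  }

  # assignment stage for outlying leaves
  if (assign_unlabeled && length(accepted)) {
    radius <- vapply(seq_along(accepted), function(k) {
      g <- accepted[[k]]
      a_i <- vapply(g, function(i) mean(d[i, setdiff(g, i)]), numeric(1))
      mean(a_i) + 3 * sd(a_i)
    }, numeric(1))
    for (i in which(assignment == 0L)) {
      avg <- vapply(accepted, function(g) mean(d[i, g]), numeric(1))
      k <- which.min(avg)
      if (is.finite(radius[k]) && avg[k] <= radius[k]) assignment[i] <- k
    }
    # renumber by size after assignment
    sizes <- table(factor(assignment[assignment > 0],
                          levels = seq_along(accepted)))
    remap <- order(order(sizes, decreasing = TRUE))
    assignment[assignment > 0] <- remap[assignment[assignment > 0]]
  }

  names(assignment) <- dendrogram$labels
  assignment
}

#' Module eigengene
#'
#' Each member feature is z-scored across samples; the eigengene is the
#' first right singular vector of the members x samples z-matrix
#' (equivalently, the first principal component of the module expression),
#' unit-norm, with its sign chosen so it correlates non-negatively with the
#' member-averaged z-profile.
#'
#' @param x an `IntegratedMatrix` (or samples x features matrix).
#' @param members feature ids (or column indices) of the module; at least 2.
#' @return named numeric sample vector with unit L2 norm.
#' @export
module_eigengene <- function(x, members) {
  v <- if (inherits(x, "IntegratedMatrix")) x$values else x
  z <- v[, members, drop = FALSE]
  if (ncol(z) < 2) stop("module must have at least 2 features")
  sds <- apply(z, 2, sd)
  if (any(sds == 0)) stop("constant feature in module")
  z <- scale(z)
  e <- svd(t(z), nu = 0, nv = 1)$v[, 1]
  avg <- rowMeans(z)
  if (sum(e * avg) < 0) e <- -e
  setNames(e, rownames(v))
}

eigengene_matrix <- function(x, assignment) {
  mods <- sort(unique(assignment[assignment > 0]))
  v <- if (inherits(x, "IntegratedMatrix")) x$values else x
  E <- t(vapply(mods, function(k) {
    module_eigengene(v, which(assignment == k))
  }, numeric(nrow(v))))
  rownames(E) <- paste0("M", mods)
  colnames(E) <- rownames(v)
  E
}

#' Merge modules with similar eigengenes
#'
#' Iteratively clusters module eigengenes by 1 - Pearson correlation with
#' average linkage and merges all modules within any subtree below
#' `cut_height`, recomputing eigengenes after each pass, until no merge
#' occurs (at most `max_iter` passes).
#'
#' @param x an `IntegratedMatrix`.
#' @param assignment module labels from [dynamic_tree_cut()].
#' @param cut_height eigengene-dissimilarity merge height (default 0.4,
#'   i.e. modules correlated above 0.6 merge).
#' @param max_iter safety cap on merge passes.
#' @return a `ModuleSet`: list with `assignment` (renumbered by size),
#'   `eigengenes` (module x sample matrix), `sizes`, and `merge_history`.
#' @export
merge_close_modules <- function(x, assignment, cut_height = 0.4,
                                max_iter = 10) {
  history <- list()
  for (iter in seq_len(max_iter)) {
    mods <- sort(unique(assignment[assignment > 0]))
    if (length(mods) < 2) break
    E <- eigengene_matrix(x, assignment)
    diss <- 1 - cor(t(E))
    hc <- hclust(as.dist(diss), method = "average")
    grp <- cutree(hc, h = cut_height)
    if (max(grp) == length(mods)) break
    history[[length(history) + 1]] <- split(rownames(E), grp)
    relabel <- setNames(grp[match(mods, as.integer(sub("M", "", rownames(E))))],
                        mods)
    assignment[assignment > 0] <- relabel[as.character(
      assignment[assignment > 0])]
  }
  # renumber by decreasing size
  mods <- sort(unique(assignment[assignment > 0]))
  sizes <- vapply(mods, function(k) sum(assignment == k), integer(1))
  remap <- setNames(order(order(sizes, decreasing = TRUE)), mods)
  assignment[assignment > 0] <- remap[as.character(assignment[assignment > 0])]
  E <- eigengene_matrix(x, assignment)
  structure(list(assignment = assignment,
                 eigengenes = E,
                 sizes = table(assignment[assignment > 0]),
                 merge_history = history),
            class = "ModuleSet")
}

#' @export
print.ModuleSet <- function(x, ...) {
  cat(sprintf("ModuleSet: %d modules (sizes %s), %d unassigned\n",
              nrow(x$eigengenes),
              paste(range(as.integer(x$sizes)), collapse = "-"),
              sum(x$assignment == 0)))
  invisible(x)
}

#' Module-trait association
#'
#' Pearson correlation of each module eigengene with each trait (AMS degree
#' plus the clinical variables), pairwise-complete, with two-sided t-based
#' p-values and multiplicity correction by Benjamini-Hochberg, applied over
#' the whole module x trait grid (default) or per trait. Modules whose
#' adjusted AMS-degree association is below `alpha` are flagged as
#' AMS-modules. Pairs with fewer than 4 complete observations are marked
#' not computable.
#'
#' @param eigengenes module x sample matrix (e.g. from a `ModuleSet`).
#' @param clinical clinical data.frame with `sample_id`, `AMS_degree` and
#'   the clinical variables.
#' @param traits trait columns to test (default: AMS_degree + all 26).
#' @param alpha significance level on adjusted p (default 0.05).
#' @param fdr_family "grid" (BH over all module x trait cells) or
#'   "per-trait".
#' @return list with `table` (module, trait, n, r, p, p_adj, significant)
#'   and `ams_modules` (module names flagged on AMS_degree).
#' @export
module_trait_association <- function(eigengenes, clinical,
                                     traits = NULL, alpha = 0.05,
                                     fdr_family = c("grid", "per-trait")) {
  fdr_family <- match.arg(fdr_family)
  if (is.null(traits)) {
    traits <- c("AMS_degree", intersect(ams_clinical_variables(),
                                        names(clinical)))
  }
  samp <- colnames(eigengenes)
  idx <- match(samp, clinical$sample_id)
  if (anyNA(idx)) stop("eigengene samples missing from the clinical table")
  rows <- list()
  for (mod in rownames(eigengenes)) {
    e <- eigengenes[mod, ]
    for (tr in traits) {
      x <- as.numeric(clinical[[tr]][idx])
      ok <- !is.na(x) & !is.na(e)
      n <- sum(ok)
      if (n < 4 || sd(x[ok]) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          module = mod, trait = tr, n = n, r = NA_real_, p = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      r <- cor(e[ok], x[ok])
      tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
      p <- 2 * pt(abs(tt), df = n - 2, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = mod, trait = tr, n = n, r = r, p = p,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (fdr_family == "grid") {
    tab$p_adj <- adjust_p(tab$p, "BH")
  } else {
    tab$p_adj <- NA_real_
    for (tr in unique(tab$trait)) {
      sel <- tab$trait == tr
      tab$p_adj[sel] <- adjust_p(tab$p[sel], "BH")
    }
  }
  tab$significant <- !is.na(tab$p_adj) & tab$p_adj < alpha
  ams <- tab$module[tab$trait == "AMS_degree" & tab$significant]
  list(table = tab, ams_modules = ams)
}
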