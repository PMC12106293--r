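#' Reference clinical schema for the AMS cohort
#'
#' Per-variable generation anchors for the 26 baseline clinical variables:
#' group medians and quartiles (continuous variables, generated log-normal),
#' smoking rates (Bernoulli), and the per-variable observation count out of
#' 66 training subjects, which sets the clinical missingness rate. Units
#' follow routine clinical practice (mmHg, L, L/s, cell counts, enzyme
#' activities).
#'
#' @return data.frame with one row per clinical variable.
#' @export
ams_clinical_reference <- function() {
  # variable, med/q1/q3 for non-AMS then AMS group, n observed of 66
  tab <- rbind(
    c("Age",      22.5, 21.0, 24.0,   23.0, 21.0, 25.8,  66),
    c("BMI",      21.0, 21.0, 24.0,   22.0, 21.0, 23.0,  65),
    c("SBP",      116,  109,  120,    120,  120,  125,   48),
    c("DBP",      76.0, 70.0, 86.0,   75.0, 70.5, 80.0,  48),
    c("HR",       80.0, 69.0, 85.0,   73.0, 65.5, 84.0,  57),
    c("SpO2",     99.0, 97.5, 99.0,   99.0, 98.0, 99.0,  57),
    c("FVC",      3.29, 2.77, 4.17,   3.63, 2.70, 4.74,  54),
    c("FEV1",     3.29, 2.67, 4.09,   2.34, 1.86, 3.21,  54),
    c("PEF",      509,  423,  553,    366,  212,  484,   54),
    c("FEV1_FVC", 1.00, 0.93, 1.00,   0.93, 0.57, 1.00,  54),
    c("WBC",      6.07, 5.42, 6.52,   5.70, 5.07, 6.19,  66),
    c("NE",       2.93, 2.40, 3.44,   2.65, 2.28, 3.35,  66),
    c("LY",       2.40, 2.16, 2.76,   2.23, 1.94, 2.44,  66),
    c("RBC",      5.28, 5.10, 5.46,   5.31, 5.06, 5.49,  66),
    c("HGB",      158,  152,  162,    154,  148,  161,   66),
    c("PLT",      233,  209,  250,    224,  198,  254,   66),
    c("ALT",      0.27, 0.22, 0.36,   0.27, 0.23, 0.32,  66),
    c("AST",      0.33, 0.27, 0.39,   0.31, 0.28, 0.39,  66),
    c("TBIL",     16.9, 12.7, 21.4,   14.6, 12.7, 23.9,  66),
    c("UA",       384,  339,  414,    366,  347,  413,   66),
    c("UREA",     5.57, 4.73, 6.27,   5.51, 4.62, 6.37,  66),
    c("CREA",     76.3, 67.6, 81.5,   77.2, 69.0, 82.3,  66),
    c("CKMB",     0.26, 0.22, 0.32,   0.27, 0.24, 0.34,  66),
    c("LDH",      2.99, 2.71, 3.25,   2.94, 2.65, 3.35,  66),
    c("GLU",      4.48, 4.11, 4.84,   4.53, 4.25, 4.92,  66)
  )
  out <- data.frame(
    variable = tab[, 1],
    med_non = as.numeric(tab[, 2]), q1_non = as.numeric(tab[, 3]),
    q3_non = as.numeric(tab[, 4]),
    med_ams = as.numeric(tab[, 5]), q1_ams = as.numeric(tab[, 6]),
    q3_ams = as.numeric(tab[, 7]),
    n_obs = as.numeric(tab[, 8]),
    stringsAsFactors = FALSE
  )
  # Smoke: Bernoulli; rates from observed smokers / observed subjects
  smoke <- data.frame(variable = "Smoke",
                      med_non = 9 / 23, q1_non = NA, q3_non = NA,
                      med_ams = 12 / 24, q1_ams = NA, q3_ams = NA,
                      n_obs = 47, stringsAsFactors = FALSE)
  rbind(out[1:2, ], smoke, out[-(1:2), ])
}

#' Clinical variable names in canonical order
#' @return character vector of the 26 variable names.
#' @export
ams_clinical_variables <- function() ams_clinical_reference()$variable

#' Configuration for the synthetic AMS cohort generator
#'
#' The defaults encode the study design the downstream analysis assumes:
#' a training cohort of 66 subjects plus an independent validation cohort of
#' 24, 429 proteins and 984 metabolites organised in 17 co-expression
#' modules of at least 45 features, 6 of which shift with AMS status, with
#' a small set of individually informative molecular features and the four
#' clinical shifts (SBP up, FEV1 / PEF / FEV1-FVC ratio down in AMS).
#'
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @param n_train,n_valid cohort sizes.
#' @param n_proteins,n_metabolites features per omic layer.
#' @param n_modules number of latent co-expression modules.
#' @param min_module_size minimum features per module.
#' @param n_ams_modules number of label-associated modules.
#' @param n_informative_features molecular features given an individual
#'   label effect (drawn from AMS-associated modules; proteins and
#'   metabolites in roughly a 6:4 ratio).
#' @param effect_size_d standardized mean difference of each informative
#'   feature between AMS and non-AMS, on the log2 scale.
#' @param ams_module_effect shift of an AMS-module latent factor between
#'   the two label groups (in latent-factor SD units).
#' @param clinical_effects either NULL (use the full [ams_clinical_reference()]
#'   schema), "none" (both groups share the non-AMS distributions), or a
#'   data.frame overriding reference rows by `variable`.
#' @param degree_prob probabilities of AMS degree 0/1/2 (none/mild/moderate).
#' @param missing_rate_mcar MCAR missingness per cell; either one rate or a
#'   named vector `c(protein = , metabolite = )`.
#' @param outlier_cell_rate fraction of cells displaced far outside their
#'   sample's distribution.
#' @param n_shifted_samples training samples given a global location/scale
#'   distortion (to be caught by the KS sample filter).
#' @param sample_scale_sd SD of the per-sample additive log2 offset.
#' @param loading_range uniform range of module loadings.
#' @param noise_sd SD of feature-level noise; the default targets a
#'   within-module correlation of about 0.5.
#' @return a validated `ams_generator_config` object.
#' @export
generator_config <- function(seed = 1L,
                             n_train = 66L, n_valid = 24L,
                             n_proteins = 429L, n_metabolites = 984L,
                             n_modules = 17L, min_module_size = 45L,
                             n_ams_modules = 6L,
                             n_informative_features = 10L,
                             effect_size_d = 1.2,
                             ams_module_effect = 1.6,
                             clinical_effects = NULL,
                             degree_prob = c(0.494, 0.446, 0.060),
                             missing_rate_mcar = c(protein = 0.05,
                                                   metabolite = 0.005),
                             outlier_cell_rate = 0.002,
                             n_shifted_samples = 0L,
                             sample_scale_sd = 0.2,
                             loading_range = c(0.6, 0.95),
                             noise_sd = 0.775) {
  cfg <- list(seed = as.integer(seed), n_train = as.integer(n_train),
              n_valid = as.integer(n_valid),
              n_proteins = as.integer(n_proteins),
              n_metabolites = as.integer(n_metabolites),
              n_modules = as.integer(n_modules),
              min_module_size = as.integer(min_module_size),
              n_ams_modules = as.integer(n_ams_modules),
              n_informative_features = as.integer(n_informative_features),
              effect_size_d = effect_size_d,
              ams_module_effect = ams_module_effect,
              clinical_effects = clinical_effects,
              degree_prob = degree_prob / sum(degree_prob),
              missing_rate_mcar = missing_rate_mcar,
              outlier_cell_rate = outlier_cell_rate,
              n_shifted_samples = as.integer(n_shifted_samples),
              sample_scale_sd = sample_scale_sd,
              loading_range = loading_range,
              noise_sd = noise_sd)
  validate_generator_config(cfg)
  structure(cfg, class = "ams_generator_config")
}

validate_generator_config <- function(cfg) {
  p_total <- cfg$n_proteins + cfg$n_metabolites
  fail <- function(what) stop("invalid generator config: ", what, call. = FALSE)
  if (cfg$n_modules * cfg$min_module_size > p_total) {
    fail("n_modules * min_module_size exceeds total feature count")
  }
  if (cfg$n_ams_modules > cfg$n_modules) fail("n_ams_modules > n_modules")
  rates <- c(cfg$missing_rate_mcar, cfg$outlier_cell_rate)
  if (any(rates < 0 | rates >= 1)) fail("rates must lie in [0, 1)")
  if (cfg$effect_size_d < 0) fail("effect_size_d must be >= 0")
  if (cfg$n_train < 4 || cfg$n_valid < 2) fail("cohorts too small")
  if (cfg$n_shifted_samples < 0 || cfg$n_shifted_samples > cfg$n_train) {
    fail("n_shifted_samples outside [0, n_train]")
  }
  if (cfg$sample_scale_sd < 0) fail("sample_scale_sd must be >= 0")
  invisible(cfg)
}

mcar_rate_for <- function(cfg, omic) {
  r <- cfg$missing_rate_mcar
  if (length(r) == 1L && is.null(names(r))) return(unname(r))
  if (!is.null(names(r)) && omic %in% names(r)) return(unname(r[[omic]]))
  unname(r[[1L]])
}

# log-normal draw matched to a printed median and quartiles
rlnorm_match <- function(n, med, q1, q3) {
  sdlog <- (log(q3) - log(q1)) / (2 * qnorm(0.75))
  if (!is.finite(sdlog) || sdlog <= 0) sdlog <- 1e-6
  exp(rnorm(n, mean = log(med), sd = sdlog))
}

clinical_schema <- function(cfg) {
  ref <- ams_clinical_reference()
  eff <- cfg$clinical_effects
  if (identical(eff, "none")) {
    ref$med_ams <- ref$med_non
    ref$q1_ams <- ref$q1_non
    ref$q3_ams <- ref$q3_non
  } else if (is.data.frame(eff)) {
    for (i in seq_len(nrow(eff))) {
      j <- match(eff$variable[i], ref$variable)
      if (is.na(j)) stop("unknown clinical variable: ", eff$variable[i])
      for (col in intersect(names(eff), names(ref))) ref[j, col] <- eff[i, col]
    }
  }
  ref
}

generate_clinical <- function(cfg, y, inject_missing = TRUE) {
  ref <- clinical_schema(cfg)
  n <- length(y)
  out <- data.frame(row.names = seq_len(n))
  for (i in seq_len(nrow(ref))) {
    v <- ref$variable[i]
    x <- numeric(n)
    for (grp in c(0L, 1L)) {
      idx <- which(y == grp)
      if (!length(idx)) next
      if (v == "Smoke") {
        p <- if (grp == 1L) ref$med_ams[i] else ref$med_non[i]
        x[idx] <- rbinom(length(idx), 1L, p)
      } else if (grp == 1L) {
        x[idx] <- rlnorm_match(length(idx), ref$med_ams[i], ref$q1_ams[i],
                               ref$q3_ams[i])
      } else {
        x[idx] <- rlnorm_match(length(idx), ref$med_non[i], ref$q1_non[i],
                               ref$q3_non[i])
      }
    }
    if (v == "FEV1_FVC") x <- pmin(x, 1)      # spirometry ratio ceiling
    if (inject_missing && ref$n_obs[i] < 66) {
      rate <- 1 - ref$n_obs[i] / 66
      x[runif(n) < rate] <- NA
    }
    out[[v]] <- x
  }
  out
}

#' Generate a synthetic AMS cohort
#'
#' Draws training and validation cohorts from a latent-factor block model:
#' each feature belongs to one module whose per-sample factor is standard
#' normal (shifted between label groups for AMS-associated modules); the
#' feature's log2 abundance is loading x factor + label effect (informative
#' features only) + independent noise + a per-sample offset, exponentiated
#' to a strictly positive raw scale. Clinical variables follow the Table-1
#' style schema of [ams_clinical_reference()]. A ground-truth manifest
#' records module membership, informative features, planted clinical shifts
#' and the latent factors.
#'
#' @param config an `ams_generator_config` from [generator_config()].
#' @return list with elements `proteins`, `metabolites` (raw-scale
#'   [abundance_matrix()] objects over all train + validation samples),
#'   `clinical` (data.frame with `sample_id`, `cohort`, the 26 clinical
#'   variables, `AMS` and `AMS_degree`), and `truth` (manifest).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "ams_generator_config"))
  validate_generator_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n <- cfg$n_train + cfg$n_valid
    cohort <- rep(c("train", "valid"), c(cfg$n_train, cfg$n_valid))
    ids <- sprintf("S%03d", seq_len(n))

    # AMS degree 0/1/2; redraw until both classes occur in both cohorts
    for (attempt in 1:100) {
      degree <- sample(0:2, n, replace = TRUE, prob = cfg$degree_prob)
      y <- as.integer(degree > 0)
      ok <- all(vapply(split(y, cohort), function(v) length(unique(v)) == 2L,
                       logical(1)))
      if (ok) break
      if (attempt == 100) stop("could not draw both classes in both cohorts")
    }

    p_total <- cfg$n_proteins + cfg$n_metabolites
    feat_omic <- rep(c("protein", "metabolite"),
                     c(cfg$n_proteins, cfg$n_metabolites))
    feat_id <- c(sprintf("P%04d", seq_len(cfg$n_proteins)),
                 sprintf("MB%04d", seq_len(cfg$n_metabolites)))

    # module sizes: min_module_size each, remainder spread multinomially
    base <- rep(cfg$min_module_size, cfg$n_modules)
    extra <- p_total - sum(base)
    if (extra > 0) {
      base <- base + as.integer(rmultinom(1, extra,
                                          rep(1 / cfg$n_modules,
                                              cfg$n_modules)))
    }
    module_of <- rep(seq_len(cfg$n_modules), base)[sample.int(p_total)]

    ams_modules <- seq_len(cfg$n_ams_modules)
    # each AMS module shifts up or down with AMS status
    module_sign <- setNames(integer(cfg$n_modules), paste0("M", seq_len(cfg$n_modules)))
    module_sign[ams_modules] <- sample(c(-1L, 1L), length(ams_modules),
                                       replace = TRUE)

    # informative features: from AMS modules, ~6:4 protein:metabolite
    inf_idx <- integer(0)
    if (cfg$n_informative_features > 0) {
      pool_p <- which(module_of %in% ams_modules & feat_omic == "protein")
      pool_m <- which(module_of %in% ams_modules & feat_omic == "metabolite")
      n_p <- min(length(pool_p), round(cfg$n_informative_features * 0.6))
      n_m <- min(length(pool_m), cfg$n_informative_features - n_p)
      inf_idx <- c(sample(pool_p, n_p), sample(pool_m, n_m))
    }
    beta <- numeric(p_total)

    loading <- runif(p_total, cfg$loading_range[1], cfg$loading_range[2])
    feat_sd <- sqrt(loading^2 + cfg$noise_sd^2)
    if (length(inf_idx)) {
      # the individual effect reinforces the feature's module-level shift
      # (informative features are the module members most strongly coupled
      # to the label); with no module shift the sign is random
      sgn <- module_sign[module_of[inf_idx]]
      sgn[sgn == 0 | cfg$ams_module_effect == 0] <-
        sample(c(-1L, 1L), sum(sgn == 0 | cfg$ams_module_effect == 0),
               replace = TRUE)
      beta[inf_idx] <- sgn * cfg$effect_size_d * feat_sd[inf_idx]
    }

    # latent module factors, shifted (with sign) for AMS modules
    factors <- matrix(rnorm(cfg$n_modules * n), cfg$n_modules, n,
                      dimnames = list(paste0("M", seq_len(cfg$n_modules)), ids))
    for (m in ams_modules) {
      factors[m, ] <- factors[m, ] + module_sign[m] * cfg$ams_module_effect * y
    }

    mu <- runif(p_total, 10, 20)   # log2 baseline abundance
    offset <- rnorm(n, 0, cfg$sample_scale_sd)

    x_log2 <- t(factors[module_of, , drop = FALSE]) *
      rep(loading, each = n)
    x_log2 <- x_log2 + outer(rep(1, n), mu) + outer(y, beta) +
      matrix(rnorm(n * p_total, 0, cfg$noise_sd), n, p_total) +
      offset
    dimnames(x_log2) <- list(ids, feat_id)

    raw <- 2^x_log2
    proteins <- abundance_matrix(raw[, feat_omic == "protein", drop = FALSE],
                                 omic = "protein", scale = "raw")
    metabolites <- abundance_matrix(raw[, feat_omic == "metabolite",
                                        drop = FALSE],
                                    omic = "metabolite", scale = "raw")

    clin <- generate_clinical(cfg, y)
    clinical <- data.frame(sample_id = ids, cohort = cohort, clin,
                           AMS = y, AMS_degree = degree,
                           stringsAsFactors = FALSE)

    ref <- clinical_schema(cfg)
    planted_clin <- ref[ref$variable %in% c("SBP", "FEV1", "PEF", "FEV1_FVC") &
                          ref$med_ams != ref$med_non,
                        c("variable", "med_non", "med_ams")]

    truth <- structure(list(
      module_of_feature = setNames(module_of, feat_id),
      feature_omic = setNames(feat_omic, feat_id),
      ams_modules = ams_modules,
      module_sign = module_sign,
      informative_features = data.frame(
        feature = feat_id[inf_idx], omic = feat_omic[inf_idx],
        module = module_of[inf_idx], effect = beta[inf_idx],
        stringsAsFactors = FALSE),
      planted_clinical = planted_clin,
      shifted_samples = character(0),
      outlier_cells = list(),
      latent_factors = factors,
      loadings = setNames(loading, feat_id),
      sample_offsets = setNames(offset, ids),
      labels = setNames(y, ids),
      cohort = setNames(cohort, ids),
      seed = cfg$seed), class = "ams_truth")

    list(proteins = proteins, metabolites = metabolites,
         clinical = clinical, truth = truth)
  })
}

#' Inject MCAR missingness, outlier cells and shifted samples
#'
#' Creates exactly the data pathologies the QC stage is designed to remove:
#' missing-completely-at-random cells, cells displaced far (> 5 within-sample
#' SDs) from their sample's distribution, and whole-sample location/scale
#' distortions large enough to trip the Kolmogorov-Smirnov exclusion fence.
#'
#' @param m a raw-scale `AbundanceMatrix`.
#' @param config an `ams_generator_config`; the rates
#'   (`missing_rate_mcar` for `m$omic`, `outlier_cell_rate`,
#'   `n_shifted_samples`) come from here.
#' @param truth optional ground-truth manifest to update.
#' @return list with the modified `matrix` and the updated `truth`.
#' @export
inject_missing_and_outliers <- function(m, config, truth = NULL) {
  stopifnot(inherits(m, "AbundanceMatrix"))
  validate_generator_config(config)
  if (anyNA(m$values)) stop("input matrix must be complete")
  rate <- mcar_rate_for(config, m$omic)
  with_seed(derive_seed(config$seed, paste0("inject-", m$omic)), {
    v <- m$values
    n <- nrow(v); p <- ncol(v)
    outliers <- NULL

    if (config$n_shifted_samples > 0) {
      k <- min(config$n_shifted_samples, n)
      shift_idx <- sample.int(n, k)
      lv <- log2(v[shift_idx, , drop = FALSE])
      med <- apply(lv, 1, median)
      # scale x1.5 about the sample median, then shift +3 log2 units
      lv <- sweep(sweep(lv, 1, med) * 1.5, 1, med + 3, `+`)
      v[shift_idx, ] <- 2^lv
      if (!is.null(truth)) {
        truth$shifted_samples <- union(truth$shifted_samples,
                                       rownames(v)[shift_idx])
      }
    }

    if (config$outlier_cell_rate > 0) {
      pick <- which(matrix(runif(n * p) < config$outlier_cell_rate, n, p),
                    arr.ind = TRUE)
      if (nrow(pick)) {
        mu_s <- rowMeans(v)
        sd_s <- apply(v, 1, sd)
        sgn <- sample(c(-1, 1), nrow(pick), replace = TRUE)
        # displaced to 12 pre-displacement SDs so the deviation still
        # exceeds 5 SDs after the outliers themselves inflate the sample SD
        target <- mu_s[pick[, 1]] + sgn * 12 * sd_s[pick[, 1]]
        # raw abundances are strictly positive; a negative-side displacement
        # that would leave the support flips to the positive side
        flip <- target <= 0
        target[flip] <- mu_s[pick[flip, 1]] + 12 * sd_s[pick[flip, 1]]
        v[pick] <- target
        outliers <- data.frame(sample = rownames(v)[pick[, 1]],
                               feature = colnames(v)[pick[, 2]],
                               stringsAsFactors = FALSE)
        if (!is.null(truth)) truth$outlier_cells[[m$omic]] <- outliers
      }
    }

    if (rate > 0) {
      miss <- matrix(runif(n * p) < rate, n, p)
      # keep every feature with enough observed values for imputation and
      # every sample with at least one observation
      v[miss] <- NA
    }

    list(matrix = replace_values(m, v), truth = truth)
  })
}

#' Write a generated cohort to disk
#'
#' Writes `proteins.tsv`, `metabolites.tsv`, `clinical.tsv` and the
#' ground-truth manifest `truth.json` into `dir`.
#'
#' @param cohort list from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_abundance_tsv(cohort$proteins, file.path(dir, "proteins.tsv"))
  write_abundance_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"))
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$latent_factors <- as.data.frame(truth$latent_factors)
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}
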