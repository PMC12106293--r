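#' Pipeline configuration
#'
#' One object drives the whole analysis. Every stage parameter defaults to
#' the value the analysis is defined with (QC cuts, minClusterSize 45,
#' merge cutHeight 0.4, k = 3 folds, halve.above = 100, top 1..30 curve,
#' alpha 0.05, radial SVM with C = 1).
#'
#' @param seed global seed; per-stage seeds are derived deterministically.
#' @param simulate NULL, or an `ams_generator_config` (then inputs are
#'   simulated rather than read).
#' @param input_dir directory holding `proteins.tsv`, `metabolites.tsv`,
#'   `clinical.tsv` when not simulating.
#' @param out_dir output directory for stage artifacts.
#' @param outlier_sd,max_sample_missing,max_feature_missing_protein,max_feature_missing_metabolite,ks_fence_mult
#'   QC thresholds.
#' @param pmm_donors,pmm_cycles,loess_span imputation / normalization.
#' @param min_module_size,cut_height,fdr_family module discovery.
#' @param k_folds,halve_above,k_max,n_repeats,alpha feature selection.
#' @param svm_cost,calib_folds model settings.
#' @return a `PipelineConfig` object.
#' @export
pipeline_config <- function(seed = 1L, simulate = generator_config(seed = seed),
                            input_dir = NULL, out_dir = "ams_run",
                            outlier_sd = 5, max_sample_missing = 0.20,
                            max_feature_missing_protein = 0.50,
                            max_feature_missing_metabolite = 0.10,
                            ks_fence_mult = 1.5,
                            pmm_donors = 5, pmm_cycles = 10,
                            loess_span = 0.7,
                            min_module_size = 45, cut_height = 0.4,
                            fdr_family = "grid",
                            k_folds = 3, halve_above = 100, k_max = 30,
                            n_repeats = 20, alpha = 0.05,
                            svm_cost = 1, calib_folds = 5) {
  if (k_folds < 2) stop("k_folds must be at least 2 (CV requires >= 2)")
  if (calib_folds < 2) stop("calib_folds must be at least 2")
  if (is.null(simulate) && is.null(input_dir)) {
    stop("either simulate or input_dir must be given")
  }
  structure(as.list(environment()), class = "PipelineConfig")
}

config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$simulate <- if (is.null(cfg$simulate)) NULL else unclass(cfg$simulate)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

write_stage_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' simulate (optional) -> per-omic QC (train and validation separately) ->
#' integration -> module discovery -> module-trait association ->
#' MI-radialSVM-RFE feature selection -> univariate logistic filter ->
#' radial-SVM training -> evaluation on both cohorts (ROC/AUC, accuracy,
#' calibration, sub-models, SHAP, DCA). All stage artifacts are written as
#' TSV/JSON under `config$out_dir`, together with a run manifest of
#' dimensions and file checksums.
#'
#' @param config a `PipelineConfig`.
#' @param shap compute kernel SHAP for the validation cohort (default
#'   TRUE; the slowest optional stage).
#' @return list with the stage results and the `manifest`.
#' @export
run_pipeline <- function(config, shap = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   package_version = as.character(packageVersion("amsomics")),
                   started = format(t_start, usetz = TRUE), stages = list())
  log_stage <- function(name, ...) {
    manifest$stages[[name]] <<- list(...)
  }

  # ---- inputs --------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort <- generate_cohort(config$simulate)
    inj_p <- inject_missing_and_outliers(cohort$proteins, config$simulate,
                                         cohort$truth)
    inj_m <- inject_missing_and_outliers(cohort$metabolites, config$simulate,
                                         inj_p$truth)
    proteins <- inj_p$matrix; metabolites <- inj_m$matrix
    clinical <- cohort$clinical
    truth <- inj_m$truth
  } else {
    proteins <- read_abundance_tsv(file.path(config$input_dir, "proteins.tsv"),
                                   "protein")
    metabolites <- read_abundance_tsv(
      file.path(config$input_dir, "metabolites.tsv"), "metabolite")
    clinical <- read.delim(file.path(config$input_dir, "clinical.tsv"),
                           check.names = FALSE)
    truth <- NULL
  }
  if (!"cohort" %in% names(clinical)) clinical$cohort <- "train"
  log_stage("input", proteins = dim(proteins$values),
            metabolites = dim(metabolites$values),
            subjects = nrow(clinical))

  # ---- QC per omic and per cohort -----------------------------------
  qc_branch <- function(m, omic, cohort_name) {
    ids <- clinical$sample_id[clinical$cohort == cohort_name]
    ids <- intersect(rownames(m$values), ids)
    res <- run_qc(subset_samples(m, rownames(m$values) %in% ids),
                  qc_thresholds(
                    omic, outlier_sd = config$outlier_sd,
                    max_sample_missing_frac = config$max_sample_missing,
                    max_feature_missing_frac =
                      if (omic == "protein") config$max_feature_missing_protein
                      else config$max_feature_missing_metabolite,
                    ks_fence_multiplier = config$ks_fence_mult),
                  seed = derive_seed(config$seed,
                                     paste0("qc-", omic, "-", cohort_name)),
                  pmm_donors = config$pmm_donors,
                  pmm_cycles = config$pmm_cycles,
                  loess_span = config$loess_span)
    write_qc_report(res$report,
                    file.path(config$out_dir,
                              sprintf("qc_%s_%s.json", omic, cohort_name)))
    res
  }
  qc_p_train <- qc_branch(proteins, "protein", "train")
  qc_m_train <- qc_branch(metabolites, "metabolite", "train")
  has_valid <- any(clinical$cohort == "valid")
  if (has_valid) {
    qc_p_valid <- qc_branch(proteins, "protein", "valid")
    qc_m_valid <- qc_branch(metabolites, "metabolite", "valid")
  }
  log_stage("qc",
            protein_train = dim(qc_p_train$matrix$values),
            metabolite_train = dim(qc_m_train$matrix$values))

  # ---- integration and module discovery -----------------------------
  integrated <- concatenate_omics(qc_p_train$matrix, qc_m_train$matrix)
  d <- spearman_dissimilarity(integrated)
  hc <- ward_cluster(d)
  assignment <- dynamic_tree_cut(hc, d,
                                 min_cluster_size = config$min_module_size)
  modules <- merge_close_modules(integrated, assignment,
                                 cut_height = config$cut_height)
  clin_train <- clinical[match(rownames(integrated$values),
                               clinical$sample_id), ]
  assoc <- module_trait_association(modules$eigengenes, clin_train,
                                    alpha = config$alpha,
                                    fdr_family = config$fdr_family)
  write_stage_tsv(data.frame(feature = names(modules$assignment),
                             omic = integrated$omic,
                             module = modules$assignment),
                  file.path(config$out_dir, "modules.tsv"))
  write_stage_tsv(data.frame(module = rownames(modules$eigengenes),
                             modules$eigengenes, check.names = FALSE),
                  file.path(config$out_dir, "eigengenes.tsv"))
  write_stage_tsv(assoc$table,
                  file.path(config$out_dir, "module_trait.tsv"))
  log_stage("modules", n_modules = nrow(modules$eigengenes),
            n_unassigned = sum(modules$assignment == 0),
            ams_modules = assoc$ams_modules)
  if (!length(assoc$ams_modules)) {
    stop("pipeline aborted at module-trait stage: no AMS-associated module")
  }

  # ---- clinical screen and molecular feature selection --------------
  screen <- screen_clinical(clin_train, alpha = config$alpha)
  clin_selected <- screen$variable[which(screen$selected)]
  pool <- names(modules$assignment)[
    paste0("M", modules$assignment) %in% assoc$ams_modules]
  y_train <- as.integer(clin_train$AMS)
  x_pool <- integrated$values[, pool, drop = FALSE]
  ranking <- mi_svm_rfe(x_pool, y_train, k_folds = config$k_folds,
                        halve_above = config$halve_above,
                        seed = derive_seed(config$seed, "rfe"))
  curve <- estimate_error_curve(x_pool, y_train, ranking,
                                k_max = config$k_max,
                                k_folds = config$k_folds,
                                n_repeats = config$n_repeats,
                                seed = derive_seed(config$seed, "curve"),
                                cost = config$svm_cost)
  top_mol <- names(sort(ranking$final_rank))[seq_len(curve$chosen_k)]

  # candidates: chosen top molecular features + screened clinical; clinical
  # missing entries imputed with training medians (frozen for validation)
  clin_medians <- vapply(clin_selected, function(v) {
    median(clin_train[[v]], na.rm = TRUE)
  }, numeric(1))
  clin_mat <- function(clin_df) {
    if (!length(clin_selected)) {
      return(matrix(numeric(0), nrow(clin_df), 0))
    }
    mm <- as.matrix(clin_df[, clin_selected, drop = FALSE])
    for (j in seq_len(ncol(mm))) {
      mm[is.na(mm[, j]), j] <- clin_medians[j]
    }
    mm
  }
  cand_train <- cbind(clin_mat(clin_train),
                      integrated$values[, top_mol, drop = FALSE])
  cand_types <- c(rep("clinical", length(clin_selected)),
                  ifelse(startsWith(top_mol, "protein:"), "protein",
                         "metabolite"))
  panel <- univariate_logistic_filter(cand_train, y_train,
                                      alpha = config$alpha,
                                      types = cand_types)
  write_stage_tsv(data.frame(feature = names(ranking$final_rank),
                             final_rank = unname(ranking$final_rank)),
                  file.path(config$out_dir, "ranking.tsv"))
  write_stage_tsv(curve$curve, file.path(config$out_dir, "error_curve.tsv"))
  write_stage_tsv(as.data.frame(panel), file.path(config$out_dir, "panel.tsv"))
  log_stage("selection", clinical_screened = clin_selected,
            chosen_k = curve$chosen_k, panel_size = sum(panel$selected))
  if (sum(panel$selected) == 0) {
    stop("pipeline aborted at selection stage: empty biomarker panel")
  }

  # ---- final model and evaluation -----------------------------------
  sel <- panel$feature[panel$selected]
  sel_types <- panel$type[panel$selected]
  x_train <- cand_train[, sel, drop = FALSE]
  model <- train_radial_svm(x_train, y_train, C = config$svm_cost,
                            calib_folds = config$calib_folds,
                            seed = derive_seed(config$seed, "train"))
  write_svm_model(model, file.path(config$out_dir, "model.json"))

  results <- list(truth = truth, qc = list(protein = qc_p_train$report,
                                           metabolite = qc_m_train$report),
                  modules = modules, module_trait = assoc,
                  clinical_screen = screen, ranking = ranking,
                  error_curve = curve, panel = panel, model = model)

  eval_train <- evaluate_predictions(predict(model, x_train), y_train)
  results$evaluation <- list(train = eval_train)

  if (has_valid) {
    iv <- concatenate_omics(qc_p_valid$matrix, qc_m_valid$matrix)
    clin_valid <- clinical[match(rownames(iv$values), clinical$sample_id), ]
    mol_sel <- sel[sel_types != "clinical"]
    missing_mol <- setdiff(mol_sel, colnames(iv$values))
    if (length(missing_mol)) {
      stop("panel feature(s) absent from validation cohort after QC: ",
           paste(missing_mol, collapse = ", "))
    }
    x_valid <- cbind(clin_mat(clin_valid),
                     iv$values[, mol_sel, drop = FALSE])[, sel, drop = FALSE]
    y_valid <- as.integer(clin_valid$AMS)
    results$evaluation$valid <- evaluate_predictions(
      predict(model, x_valid), y_valid)
    results$submodels <- evaluate_submodels(
      x_train, y_train, x_valid, y_valid, sel_types,
      C = config$svm_cost, seed = derive_seed(config$seed, "submodels"))
    write_stage_tsv(results$submodels$dca$train,
                    file.path(config$out_dir, "dca_train.tsv"))
    write_stage_tsv(results$submodels$dca$valid,
                    file.path(config$out_dir, "dca_valid.tsv"))
    if (shap) {
      sh <- kernel_shap(model, x_train, x_valid)
      results$shap <- sh
      write_stage_tsv(data.frame(sample = rownames(x_valid), sh$shap,
                                 check.names = FALSE),
                      file.path(config$out_dir, "shap.tsv"))
    }
  }

  # ---- manifest ------------------------------------------------------
  arts <- list.files(config$out_dir, full.names = TRUE)
  arts <- arts[!grepl("manifest\\.json$", arts)]
  manifest$checksums <- as.list(tools::md5sum(sort(arts)))
  names(manifest$checksums) <- basename(sort(arts))
  manifest$finished <- format(Sys.time(), usetz = TRUE)
  manifest$elapsed_s <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
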