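#' Pipeline configuration
#'
#' A single flat configuration for the end-to-end analysis. Every
#' stochastic stage has an explicit seed derived from `seed`; every
#' default mirrors the study layout (per-condition totals 190 after
#' augmentation, 20-sample CRC training subsets, 10% balanced extraction
#' subset, 64 extracted features, 80:20 split, 10 folds).
#'
#' @param out_dir run directory for all artifacts.
#' @param seed master seed; per-stage seeds are derived from it.
#' @param fixture a [fixture_config()], or `NULL` when `counts_path` is
#'   given.
#' @param counts_path,meta_path optional real input TSVs (samples as
#'   rows) instead of a fixture.
#' @param plan an [augmentation_plan()].
#' @param qc_alpha KS family-wise significance level.
#' @param qc_ceiling adversarial accuracy ceiling for the pass verdict.
#' @param qc_k screened feature count for the adversarial classifiers.
#' @param svc_trials random-search trials for the adversarial SVC
#'   (0 disables tuning and uses defaults).
#' @param activations activations to sweep for the extraction network;
#'   a single name skips the sweep.
#' @param net_spec a [dense_net_spec()].
#' @param lrp an [lrp_config()].
#' @param extraction_fraction balanced extraction-subset fraction.
#' @param k number of features to extract.
#' @param reference_taxa optional path to a one-per-line taxa list to
#'   intersect with the extracted features.
#' @param split_ratio training fraction of the final split.
#' @param folds cross-validation folds for extraction and classification.
#' @param shap_method `"auto"` (tree-exact when the winning model is the
#'   boosted ensemble, sampled otherwise), `"tree_exact"` or
#'   `"permutation_sampled"`.
#' @param force continue past a QC gate failure.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, fixture = NULL,
                            counts_path = NULL, meta_path = NULL,
                            plan = augmentation_plan(),
                            qc_alpha = 0.05, qc_ceiling = 0.75, qc_k = 500,
                            svc_trials = 0,
                            activations = "leaky_relu",
                            net_spec = dense_net_spec(),
                            lrp = lrp_config(),
                            extraction_fraction = 0.10, k = 64,
                            reference_taxa = NULL,
                            split_ratio = 0.8, folds = 10,
                            shap_method = "auto", force = FALSE) {
  if (is.null(fixture) && is.null(counts_path))
    stop("pipeline_config: provide either a fixture config or counts_path")
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Recognized keys match the [pipeline_config()] arguments; nested
#' `fixture` and `plan` sections are passed to [fixture_config()] and
#' [augmentation_plan()].
#'
#' @param path YAML file path.
#' @param out_dir override for the run directory (optional).
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  args <- y
  if (!is.null(y$fixture)) {
    fx <- y$fixture
    if (!is.null(fx$group_sizes)) fx$group_sizes <- unlist(fx$group_sizes)
    if (!is.null(fx$specimen_shift)) fx$specimen_shift <- unlist(fx$specimen_shift)
    args$fixture <- do.call(fixture_config, fx)
  }
  if (!is.null(y$plan)) {
    pl <- y$plan
    if (!is.null(pl$target_totals)) pl$target_totals <- unlist(pl$target_totals)
    args$plan <- do.call(augmentation_plan, pl)
  }
  if (!is.null(y$net_spec)) args$net_spec <- do.call(dense_net_spec, y$net_spec)
  if (!is.null(y$lrp)) args$lrp <- do.call(lrp_config, y$lrp)
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

plog <- function(cfg, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " [otusynth] ", ...)
  message(msg)
  logf <- file.path(cfg$out_dir, "pipeline.log")
  cat(msg, "\n", file = logf, append = TRUE)
}

stage_seeds <- function(seed) {
  s <- with_seed(seed, sample.int(.Machine$integer.max %/% 2, 6))
  stats::setNames(s, c("fixture", "augment", "qc", "extract", "betadiv", "classify"))
}

read_stage_table <- function(dir, name) {
  read_otu_table(file.path(dir, "tables", paste0(name, "_counts.tsv")),
                 meta_path = file.path(dir, "tables", paste0(name, "_meta.tsv")))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input (fixture generation or TSV load),
#' copula augmentation, the synthetic-data quality gate (adversarial
#' classification plus the Bonferroni-KS battery; a failing gate halts
#' the run unless `force`), balanced extraction-subset selection and
#' cross-validated LRP feature extraction, beta-diversity ordination on
#' the full and reduced feature sets, and the final specimen-balanced
#' split, model comparison, holdout evaluation and Shapley attribution.
#' All artifacts are written under `config$out_dir`; a manifest with
#' structural counts, stage timings and output file hashes is returned
#' and written as `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param stages which stages to run (default all, in order). Later
#'   stages read earlier stages' serialized outputs from the run
#'   directory, so a stage can be re-run standalone.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("input", "synthesize", "qc", "extract",
                                    "betadiv", "classify")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("tables", "qc", "extraction", "ordination", "classification"))
    dir.create(file.path(config$out_dir, d), showWarnings = FALSE)
  seeds <- stage_seeds(config$seed)
  manifest <- list(config = utils::capture.output(utils::str(config, give.head = FALSE)),
                   seed = config$seed, stages = list(), counts = list())
  mpath <- file.path(config$out_dir, "manifest.json")
  run_stage <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) e)
    elapsed <- round(proc.time()[["elapsed"]] - t0, 2)
    ok <- !inherits(res, "error")
    manifest$stages[[name]] <<- list(
      status = if (ok) "ok" else "failed",
      elapsed_sec = elapsed,
      error = if (ok) NULL else conditionMessage(res))
    if (!ok) {
      jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
      stop("pipeline stage '", name, "' failed: ", conditionMessage(res))
    }
    res
  }

  if ("input" %in% stages) run_stage("input", function() {
    if (!is.null(config$counts_path)) {
      inp <- read_otu_table(config$counts_path, meta_path = config$meta_path)
      if (is.null(inp$meta)) stop("real input requires a metadata file")
    } else {
      plog(config, "generating fixture (seed ", config$fixture$seed, ")")
      inp <- make_fixture(config$fixture)
      writeLines(inp$truth$planted_feature_ids,
                 file.path(config$out_dir, "tables", "planted_features.txt"))
    }
    write_otu_table(inp$table, file.path(config$out_dir, "tables", "real_counts.tsv"),
                    meta = inp$meta,
                    meta_path = file.path(config$out_dir, "tables", "real_meta.tsv"))
    manifest$counts$real_samples <<- nrow(inp$table$counts)
    manifest$counts$features <<- ncol(inp$table$counts)
    invisible(NULL)
  })

  if ("synthesize" %in% stages) run_stage("synthesize", function() {
    real <- read_stage_table(config$out_dir, "real")
    plan <- config$plan
    plan$seed <- seeds[["augment"]]
    plog(config, "augmenting: per-specimen per-condition totals ",
         paste(plan$target_totals, collapse = "/"),
         " (totals per condition after augmentation; they sum to ",
         sum(plan$target_totals), ")")
    aug <- augment_dataset(real$table, real$meta, plan)
    write_otu_table(aug$table,
                    file.path(config$out_dir, "tables", "augmented_counts.tsv"),
                    meta = aug$meta,
                    meta_path = file.path(config$out_dir, "tables", "augmented_meta.tsv"))
    data.table::fwrite(aug$counts,
                       file.path(config$out_dir, "tables", "augmentation_counts.tsv"),
                       sep = "\t")
    tot <- tapply(rep(1, nrow(aug$meta)), aug$meta$condition, sum)
    manifest$counts$per_condition_total <<- as.list(tot)
    invisible(NULL)
  })

  if ("qc" %in% stages) run_stage("qc", function() {
    aug <- read_stage_table(config$out_dir, "augmented")
    k <- min(config$qc_k, ncol(aug$table$counts))
    by_cond <- partition_otu(aug$table, aug$meta, by = c("condition", "provenance"))
    svc_params <- NULL
    verdicts <- list(); ks_all <- list(); sim_all <- list()
    for (cond in c("AP", "CRC")) {
      rn <- paste0(cond, ".real"); sn <- paste0(cond, ".synthetic")
      if (!rn %in% names(by_cond) || !sn %in% names(by_cond)) next
      real_t <- by_cond[[rn]]$table; syn_t <- by_cond[[sn]]$table
      if (config$svc_trials > 0 && is.null(svc_params)) {
        merged <- rbind(real_t$counts, syn_t$counts)
        yy <- rep(c("real", "synthetic"), c(nrow(real_t$counts), nrow(syn_t$counts)))
        sel <- screen_features_chi2(merged, yy, k)
        svc_params <- tune_polynomial_svc(merged[, sel, drop = FALSE], yy,
                                          n_trials = config$svc_trials,
                                          seed = seeds[["qc"]])
      }
      rep_ <- adversarial_report(real_t, syn_t, svc_params = svc_params, k = k,
                                 ceiling = config$qc_ceiling, seed = seeds[["qc"]])
      verdicts[[cond]] <- rep_
      ks <- ks_battery(real_t, syn_t, alpha = config$qc_alpha, seed = seeds[["qc"]])
      ks$condition <- cond
      ks_all[[cond]] <- ks
      n <- min(nrow(real_t$counts), nrow(syn_t$counts))
      sim <- column_similarity(real_t$counts[seq_len(n), , drop = FALSE],
                               syn_t$counts[seq_len(n), , drop = FALSE])
      sim_all[[cond]] <- c(condition = cond, round(sim$aggregate, 4))
    }
    ks_df <- do.call(rbind, ks_all)
    data.table::fwrite(ks_df, file.path(config$out_dir, "qc", "ks_battery.tsv"), sep = "\t")
    met <- do.call(rbind, lapply(names(verdicts), function(cond)
      cbind(condition = cond, verdicts[[cond]]$metrics)))
    data.table::fwrite(met, file.path(config$out_dir, "qc", "adversarial_metrics.tsv"), sep = "\t")
    summary <- list(
      ks_rejections = sum(ks_df$reject),
      ks_min_p_adjusted = min(ks_df$p_adjusted),
      adversarial = lapply(verdicts, function(v)
        list(best_accuracy = v$best_accuracy, verdict = v$verdict)),
      column_similarity = sim_all,
      verdict = if (all(vapply(verdicts, function(v) v$verdict == "pass", TRUE)))
        "pass" else "fail")
    jsonlite::write_json(summary, file.path(config$out_dir, "qc", "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    manifest$counts$qc_verdict <<- summary$verdict
    plog(config, "QC gate: ", summary$verdict)
    if (summary$verdict == "fail" && !isTRUE(config$force))
      stop("synthetic data failed the QC gate (use force = TRUE to continue)")
    invisible(NULL)
  })

  if ("extract" %in% stages) run_stage("extract", function() {
    aug <- read_stage_table(config$out_dir, "augmented")
    parts <- select_extraction_subset(aug$table, aug$meta,
                                      fraction = config$extraction_fraction,
                                      seed = seeds[["extract"]])
    writeLines(parts$subset$meta$sample_id,
               file.path(config$out_dir, "extraction", "subset_ids.txt"))
    writeLines(parts$remainder$meta$sample_id,
               file.path(config$out_dir, "extraction", "remainder_ids.txt"))
    manifest$counts$extraction_subset_per_condition <<-
      as.list(table(parts$subset$meta$condition))
    manifest$counts$remainder_per_condition <<-
      as.list(table(parts$remainder$meta$condition))
    manifest$counts$per_specimen_training <<-
      as.list(table(paste(parts$remainder$meta$condition,
                          parts$remainder$meta$specimen, sep = ".")))
    spec <- config$net_spec
    y <- parts$subset$meta$condition
    if (length(config$activations) > 1) {
      sw <- activation_sweep(parts$subset$table, condition_factor(y),
                             activations = config$activations, spec = spec,
                             folds = config$folds, seed = seeds[["extract"]])
      data.table::fwrite(sw$results,
                         file.path(config$out_dir, "extraction", "activation_sweep.tsv"),
                         sep = "\t")
      spec$activation <- sw$best
      plog(config, "activation sweep winner: ", sw$best)
    }
    ext <- cross_validated_extraction(parts$subset$table, condition_factor(y),
                                      spec = spec, config = config$lrp,
                                      folds = config$folds, k = config$k,
                                      seed = seeds[["extract"]])
    data.table::fwrite(ext$relevance,
                       file.path(config$out_dir, "extraction", "relevance.tsv"),
                       sep = "\t")
    writeLines(ext$top_features,
               file.path(config$out_dir, "extraction", "top_features.txt"))
    manifest$counts$extracted_features <<- length(ext$top_features)
    manifest$counts$extraction_cv_accuracy <<- round(ext$mean_accuracy, 4)
    if (!is.null(config$reference_taxa)) {
      ref <- readLines(config$reference_taxa)
      common <- intersect_with_reference(ext$top_features, ref)
      writeLines(common,
                 file.path(config$out_dir, "extraction", "common_features.txt"))
      manifest$counts$common_features <<- length(common)
    }
    invisible(NULL)
  })

  if ("betadiv" %in% stages) run_stage("betadiv", function() {
    aug <- read_stage_table(config$out_dir, "augmented")
    sets <- list(full = NULL)
    topf <- file.path(config$out_dir, "extraction", "top_features.txt")
    if (file.exists(topf)) sets$extracted <- readLines(topf)
    commonf <- file.path(config$out_dir, "extraction", "common_features.txt")
    if (file.exists(commonf)) {
      cf <- readLines(commonf)
      if (length(cf)) sets$common <- cf
    }
    for (nm in names(sets)) {
      bd <- beta_diversity(aug$table, features = sets[[nm]])
      coords <- as.data.frame(bd$ordination$coordinates[, seq_len(min(2, ncol(bd$ordination$coordinates))), drop = FALSE])
      coords <- cbind(sample_id = rownames(coords), coords,
                      aug$meta[match(rownames(coords), aug$meta$sample_id),
                               c("condition", "specimen", "provenance")])
      data.table::fwrite(coords,
                         file.path(config$out_dir, "ordination",
                                   paste0("pcoa_", nm, ".tsv")), sep = "\t")
    }
    invisible(NULL)
  })

  if ("classify" %in% stages) run_stage("classify", function() {
    aug <- read_stage_table(config$out_dir, "augmented")
    rem_ids <- readLines(file.path(config$out_dir, "extraction", "remainder_ids.txt"))
    top <- readLines(file.path(config$out_dir, "extraction", "top_features.txt"))
    idx <- which(aug$table$sample_ids %in% rem_ids)
    tab <- subset_otu(aug$table, samples = idx, features = top)
    meta <- aug$meta[match(tab$sample_ids, aug$meta$sample_id), , drop = FALSE]
    split <- stratified_split(tab, meta, ratio = config$split_ratio,
                              seed = seeds[["classify"]])
    tr <- which(tab$sample_ids %in% split$train_ids)
    ho <- which(tab$sample_ids %in% split$holdout_ids)
    ytr <- meta$condition[tr]; yho <- meta$condition[ho]
    cv <- compare_models_cv(tab$counts[tr, , drop = FALSE], ytr,
                            folds = config$folds, seed = seeds[["classify"]])
    rep_ <- fit_final_and_evaluate(cv$best_model,
                                   tab$counts[tr, , drop = FALSE], ytr,
                                   tab$counts[ho, , drop = FALSE], yho,
                                   seed = seeds[["classify"]])
    cvdf <- data.frame(model = rownames(cv$fold_accuracy), cv$fold_accuracy,
                       mean = cv$mean_accuracy, row.names = NULL)
    data.table::fwrite(cvdf, file.path(config$out_dir, "classification", "cv_accuracy.tsv"),
                       sep = "\t")
    data.table::fwrite(rep_$roc, file.path(config$out_dir, "classification", "roc.tsv"),
                       sep = "\t")
    data.table::fwrite(rep_$class_report,
                       file.path(config$out_dir, "classification", "class_report.tsv"),
                       sep = "\t")
    method <- config$shap_method
    if (method == "auto")
      method <- if (cv$best_model == "xgboost") "tree_exact" else "permutation_sampled"
    attr_rep <- shap_attributions(
      rep_$model, tab$counts[ho, , drop = FALSE],
      background = matrix(colMeans(tab$counts[tr, , drop = FALSE]), 1,
                          dimnames = list(NULL, tab$feature_ids)),
      method = method, seed = seeds[["classify"]],
      meta = meta[ho, , drop = FALSE])
    export_plot_data(attr_rep, tab$counts[ho, , drop = FALSE],
                     meta = meta[ho, , drop = FALSE],
                     dir = file.path(config$out_dir, "classification"))
    manifest$counts$best_model <<- cv$best_model
    manifest$counts$holdout_accuracy <<- round(rep_$accuracy, 4)
    manifest$counts$holdout_auc <<- round(rep_$auc, 4)
    plog(config, "best model ", cv$best_model, "; holdout accuracy ",
         round(rep_$accuracy, 3), ", AUC ", round(rep_$auc, 3))
    invisible(NULL)
  })

  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!basename(files) %in% c("manifest.json", "pipeline.log")]
  manifest$hashes <- as.list(stats::setNames(unname(tools::md5sum(files)),
                                             sub(paste0(config$out_dir, "/?"), "", files)))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}

#' Command-line entry point
#'
#' Subcommands: `fixture`, `synthesize`, `qc`, `extract`, `betadiv`,
#' `classify`, `run-all`. Flags: `--config <yaml>` (required),
#' `--out <dir>` (overrides the config's run directory),
#' `--seed <int>`, `--force`, `--log-level <level>`.
#' A thin launcher script is installed at
#' `system.file("scripts", "otu_pipeline.R", package = "otusynth")`.
#'
#' @param argv character vector of arguments (e.g.
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return integer exit code: 0 on success, 1 on stage failure, 2 on
#'   usage errors.
#' @export
cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: otu_pipeline.R <fixture|synthesize|qc|extract|betadiv|classify|run-all>",
    "         --config <yaml> [--out <dir>] [--seed <int>] [--force] [--log-level <l>]",
    sep = "\n")
  subcmds <- c(fixture = "input", synthesize = "synthesize", qc = "qc",
               extract = "extract", betadiv = "betadiv", classify = "classify",
               `run-all` = "all")
  if (length(argv) < 1 || !argv[1] %in% names(subcmds)) {
    message(usage); return(2L)
  }
  sub <- argv[1]; argv <- argv[-1]
  opts <- list(config = NULL, out = NULL, seed = NULL, force = FALSE,
               log_level = "info")
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    take <- function() { i <<- i + 1; if (i > length(argv)) stop("missing value for ", a); argv[i] }
    res <- tryCatch({
      switch(a,
             "--config" = opts$config <- take(),
             "--out" = opts$out <- take(),
             "--seed" = opts$seed <- as.integer(take()),
             "--force" = opts$force <- TRUE,
             "--log-level" = opts$log_level <- take(),
             { message("unknown flag: ", a, "\n", usage); return(2L) })
      NULL
    }, error = function(e) { message(conditionMessage(e), "\n", usage); 2L })
    if (is.numeric(res)) return(res)
    i <- i + 1
  }
  if (is.null(opts$config)) { message("--config is required\n", usage); return(2L) }
  if (!file.exists(opts$config)) {
    message("config file not found: ", opts$config); return(2L)
  }
  cfg <- tryCatch(read_pipeline_config(opts$config, out_dir = opts$out),
                  error = function(e) { message(conditionMessage(e)); NULL })
  if (is.null(cfg)) return(2L)
  if (!is.null(opts$seed)) cfg$seed <- opts$seed
  if (opts$force) cfg$force <- TRUE
  stages <- if (sub == "run-all") c("input", "synthesize", "qc", "extract",
                                    "betadiv", "classify") else subcmds[[sub]]
  res <- tryCatch({ run_pipeline(cfg, stages = stages); 0L },
                  error = function(e) { message("error: ", conditionMessage(e)); 1L })
  res
}
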