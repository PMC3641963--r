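#' Pipeline run configuration
#'
#' Collects everything one end-to-end run needs: either a synthetic
#' scenario (two tissue variants of a [sim_config()]) or paths to real
#' input files, plus the curation and modelling options. All randomness
#' flows from the single root `seed` through named per-module sub-streams.
#'
#' The default synthetic scenario mimics the brain/blood contrast: tissue A
#' ("brain-like") has higher gene body methylation and a lower noise
#' intercept than tissue B ("blood-like"), so the between-tissue
#' comparisons have a planted signal.
#'
#' @param seed root integer seed.
#' @param n_genes genes in the synthetic scenario.
#' @param n_arrays replicate arrays per tissue.
#' @param qc_threshold median pairwise-correlation threshold for
#'   [qc_filter()].
#' @param min_coverage minimum CpG coverage for [feature_methylation()].
#' @param losses robust losses to fit.
#' @param tau quantile level for median regression.
#' @param nboot bootstrap replicates for quantile-regression SEs.
#' @param tissues named list of two tissue variants; each may override
#'   `beta_intercept` and `body_shape`.
#' @param inputs optional list of real input paths
#'   (`genes`, `tes`, and per tissue `calls` and `expr`); when given, the
#'   synthetic generators are skipped.
#' @param ... further [sim_config()] arguments shared by both tissues.
#' @return list of class `"run_config"`.
#' @export
run_config <- function(seed = 1L, n_genes = 500L, n_arrays = 12L,
                       qc_threshold = 0.8, min_coverage = 1L,
                       losses = c("huber", "bisquare", "hampel"),
                       tau = 0.5, nboot = 100L,
                       tissues = list(
                         tissueA = list(beta_intercept = 1.3,
                                        body_shape = c(4.5, 1.5)),
                         tissueB = list(beta_intercept = 1.7,
                                        body_shape = c(2.8, 2.0))),
                       inputs = NULL, ...) {
  if (length(tissues) != 2L || is.null(names(tissues))) {
    stop("'tissues' must be a named list of two tissue variants",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 n_arrays = as.integer(n_arrays),
                 qc_threshold = qc_threshold,
                 min_coverage = as.integer(min_coverage),
                 losses = losses, tau = tau, nboot = as.integer(nboot),
                 tissues = tissues, inputs = inputs,
                 sim_args = list(...)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML scenario file
#'
#' The YAML keys mirror the [run_config()] arguments.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y),
                      c("seed", "n_genes", "n_arrays", "qc_threshold",
                        "min_coverage", "losses", "tau", "nboot",
                        "tissues", "inputs"))]
  extra <- y[setdiff(names(y), names(args))]
  do.call(run_config, c(args, extra))
}

tissue_sim_config <- function(config, tissue_name) {
  ov <- config$tissues[[tissue_name]]
  args <- c(list(n_genes = config$n_genes, n_arrays = config$n_arrays,
                 seed = sub_seed(config$seed, tissue_name)),
            config$sim_args)
  if (!is.null(ov$body_shape)) args$body_shape <- ov$body_shape
  cfg <- do.call(sim_config, args)
  if (!is.null(ov$beta_intercept)) {
    cfg$beta[["intercept"]] <- ov$beta_intercept
  }
  cfg
}

write_fit_tsv <- function(fit, path) {
  write_table_tsv(fit$coefficients, path)
}

#' Run the full analysis pipeline
#'
#' Sequences the whole analysis: (synthetic or file) inputs, per-gene
#' feature methylation, expression QC / quantile normalization / CV noise,
#' a merged per-gene analysis table per tissue, the regression suite (OLS
#' with and without TE methylation, robust losses, median regression), the
#' nested biological/technical decomposition models, the
#' individual-by-methylation ANOVA, and the between-tissue comparisons.
#' Every stage output is written as plain text under `out_dir` and listed
#' with an md5 checksum in `manifest.json`, so a run is fully auditable
#' and reproducible from its seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the per-stage results (`methylation`,
#'   `noise`, `merged`, `fits`, `decomposition`, `anova`, `comparison`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir = tempfile("methnoise_run_")) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$inputs)) {
    paths <- unlist(config$inputs, use.names = TRUE)
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      stop("input file(s) not found: ",
           paste(names(missing), "=", missing, collapse = "; "),
           call. = FALSE)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tissue_names <- names(config$tissues)
  counts <- list()
  files <- character(0)
  emit <- function(obj, name, writer = write_table_tsv) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    files <<- c(files, p)
    p
  }

  # --- stage: inputs (synthetic scenario or files) -----------------------
  synth <- is.null(config$inputs)
  data <- list()
  for (tn in tissue_names) {
    if (synth) {
      cfg <- tissue_sim_config(config, tn)
      truth <- simulate_truth(cfg)
      if (tn == tissue_names[1]) {
        ann <- simulate_annotations(cfg, truth)
        lengths0 <- truth$length
      } else {
        # the two tissues share one genome: same annotation and lengths
        truth$log_cv <- truth$log_cv +
          cfg$beta[["length"]] * (log(lengths0) - log(truth$length))
        truth$length <- lengths0
      }
      calls <- simulate_methylome(cfg, ann, truth)
      expr <- simulate_expression(cfg, truth, tissue = tn)
      data[[tn]] <- list(cfg = cfg, truth = truth, calls = calls,
                         expr = expr)
      emit(truth, paste0("truth_", tn, ".tsv"))
      emit(calls, paste0("cpg_calls_", tn, ".tsv"), write_cpg_calls)
      emit(expr, paste0("expression_", tn, ".tsv"), write_matrix_tsv)
    } else {
      ann <- list(genes = read_gene_models(config$inputs$genes),
                  tes = read_bed6(config$inputs$tes))
      data[[tn]] <- list(
        calls = read_cpg_calls(config$inputs[[tn]]$calls),
        expr = read_matrix_tsv(config$inputs[[tn]]$expr))
    }
  }
  if (synth) {
    emit(ann$genes, "gene_models.bed12", write_gene_models_bed12)
    emit(ann$tes, "te_intervals.bed", write_bed6)
  }

  # --- stage: methylome aggregation and expression curation --------------
  results <- list()
  for (tn in tissue_names) {
    meth <- feature_methylation(data[[tn]]$calls, ann$genes, ann$tes,
                                min_coverage = config$min_coverage)
    qc <- qc_filter(data[[tn]]$expr, threshold = config$qc_threshold)
    norm <- quantile_normalize(qc$matrix)
    noise <- expression_noise(norm)
    lengths <- data.frame(
      gene_id = S4Vectors::mcols(select_longest_transcript(ann$genes))$gene_id,
      length = GenomicRanges::width(select_longest_transcript(ann$genes)))
    merged <- Reduce(function(a, b) merge(a, b, by = "gene_id"),
                     list(noise, meth, lengths))
    merged$log_length <- log(merged$length)
    merged <- merged[complete.cases(
      merged[c("log_cv", "log_abundance", "body_meth", "promoter_meth",
               "log_length")]), , drop = FALSE]
    counts[[tn]] <- list(genes_in = if (synth) config$n_genes
                                    else nrow(meth),
                         genes_retained = nrow(merged),
                         arrays_kept = ncol(qc$matrix))
    emit(meth, paste0("feature_methylation_", tn, ".tsv"))
    emit(qc$report, paste0("qc_report_", tn, ".tsv"))
    emit(noise, paste0("noise_", tn, ".tsv"))
    emit(merged, paste0("analysis_table_", tn, ".tsv"))

    fits <- list(
      main = fit_ols(log_cv ~ log_abundance + body_meth + promoter_meth +
                       log_length, merged),
      with_te = if (all(!is.na(merged$te_meth)))
        fit_ols(log_cv ~ log_abundance + body_meth + te_meth +
                  promoter_meth + log_length, merged) else NULL,
      quantile = fit_quantile(log_cv ~ log_abundance + body_meth +
                                promoter_meth + log_length, merged,
                              tau = config$tau, nboot = config$nboot,
                              boot_seed = sub_seed(config$seed, "boot"))
    )
    for (loss in config$losses) {
      fits[[loss]] <- fit_m_estimator(
        log_cv ~ log_abundance + body_meth + promoter_meth + log_length,
        merged, loss = loss)
    }
    for (fn in names(fits)) {
      if (!is.null(fits[[fn]])) {
        emit(fits[[fn]], sprintf("fit_%s_%s.tsv", fn, tn), write_fit_tsv)
      }
    }
    results[[tn]] <- list(methylation = meth, qc = qc, noise = noise,
                          merged = merged, fits = fits)
  }

  # --- stage: variance decomposition (first tissue) ----------------------
  decomp_models <- NULL
  anova_fit <- NULL
  if (synth) {
    tn <- tissue_names[1]
    nested <- simulate_nested_replicates(data[[tn]]$cfg, data[[tn]]$truth)
    decomp <- decompose_replicates(nested)
    preds <- results[[tn]]$merged[c("gene_id", "log_abundance",
                                    "body_meth", "promoter_meth")]
    decomp_models <- list(
      decomposition = decomp,
      model1 = fit_biological_model(decomp, preds),
      model2 = fit_technical_adjusted_model(decomp, preds))
    emit(nested, "nested_replicates.tsv")
    emit(decomp, "decomposition.tsv")
    emit(decomp_models$model1, "fit_model1_biological.tsv", write_fit_tsv)
    emit(decomp_models$model2, "fit_model2_adjusted.tsv", write_fit_tsv)

    ind <- simulate_individual_table(data[[tn]]$cfg, data[[tn]]$truth)
    anova_fit <- fit_individual_anova(ind)
    emit(anova_fit$table, "anova_individual.tsv")
  }

  # --- stage: between-tissue comparison ----------------------------------
  comparison <- compare_tissues(results[[tissue_names[1]]]$merged,
                                results[[tissue_names[2]]]$merged,
                                labels = tissue_names)
  emit(comparison, "tissue_comparison.tsv")

  manifest <- list(
    seed = config$seed,
    tissues = tissue_names,
    synthetic = synth,
    stage_counts = counts,
    files = lapply(setNames(files, basename(files)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, decomposition = decomp_models,
                 anova = anova_fit, comparison = comparison,
                 manifest = manifest, out_dir = out_dir))
}
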