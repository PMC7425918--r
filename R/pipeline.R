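#' Configuration for a full MSFS run
#'
#' Bundles every stage's settings. The defaults reproduce the pipeline's
#' structural constants: ten normalization methods, five selected by
#' Analysis 1, ten features selected by Analysis 2, hybrid widths scanned
#' from 10 down to 2, the top-3 hybrids plus the rank-1 single-feature
#' reference classified with three classifiers under 10-fold
#' cross-validation.
#'
#' @param acquisition an [acquisition_config()].
#' @param alpha significance level for every selection step.
#' @param k_methods normalization methods kept by Analysis 1.
#' @param k_features feature columns kept by Analysis 2.
#' @param m_range hybrid widths to scan (clipped to the number of
#'   selected features).
#' @param classifiers model specs for [train_predict()].
#' @param cv_k cross-validation folds.
#' @param seed master seed; the dataset, ICA and fold seeds derive from
#'   it.
#' @param min_components floor of the Stage-1 backward elimination.
#' @param feature_params a [feature_params()] list (its `ica_seed` is
#'   overridden from `seed`).
#' @param classify_datasets `"top3"` (the three best hybrid widths plus
#'   the rank-1 feature reference) or explicit widths, e.g. `c(10, 8)`;
#'   the reference is always added.
#' @param output_dir optional directory; when set, stage artifacts are
#'   written there as CSV/JSON.
#' @return A `run_config` list.
#' @export
msfs_config <- function(acquisition = acquisition_config(),
                        alpha = 0.05, k_methods = 5L, k_features = 10L,
                        m_range = 10:2,
                        classifiers = c("svm_linear", "pnn", "gaussian_nb"),
                        cv_k = 10L, seed = 1L, min_components = 1L,
                        feature_params = msfs::feature_params(),
                        classify_datasets = "top3",
                        output_dir = NULL) {
  structure(list(acquisition = acquisition, alpha = alpha,
                 k_methods = as.integer(k_methods),
                 k_features = as.integer(k_features),
                 m_range = as.integer(m_range), classifiers = classifiers,
                 cv_k = as.integer(cv_k), seed = as.integer(seed),
                 min_components = as.integer(min_components),
                 feature_params = feature_params,
                 classify_datasets = classify_datasets,
                 output_dir = output_dir),
            class = "run_config")
}

#' Run the full multi-stage feature selection pipeline
#'
#' Executes, in order: synthetic acquisition ([generate_dataset()]); the
#' ten-method normalization bank; per-method PCA with backward
#' elimination under the ANOVA significance rule; the ten-feature
#' extraction per method; Analysis 1 (matrix-level ANOVA, select
#' `k_methods` normalization methods); Analysis 2 (column-level ANOVA
#' over the selected methods' features, select and rank `k_features`
#' columns); SVD repetition collapse and the hybrid-width scan; stratified
#' k-fold classification of the top hybrid datasets and the rank-1
#' single-feature reference. Selection statistics use the tumor records
#' only; the tumor-free records join at classification. Fully reproducible
#' from `config$seed`.
#'
#' @param config a [msfs_config()].
#' @param quiet suppress progress messages.
#' @return A `run_report`: list with `dataset_summary`, `analysis1`,
#'   `analysis2`, `ranking`, `p_traces`, `hybrid_scan`, `hybrids`,
#'   `evaluation` (data.frame dataset x classifier), `eval_reports`,
#'   `config`, `seed`, `wall_time_s`.
#' @export
run_msfs <- function(config = msfs_config(), quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  t0 <- proc.time()[3]
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  acq <- config$acquisition
  acq$rng_seed <- config$seed
  fp <- config$feature_params
  fp$ica_seed <- config$seed + 1L

  say("simulating %d records (%d points)", protocol_record_count(acq),
      acq$n_points)
  set <- generate_dataset(acq)
  labels <- signal_labels(set)
  tumor <- set$meta$size_mm > 0
  tumor_labels <- droplevels(labels[tumor])
  reference <- compute_reference(set)

  features <- list()
  p_traces <- list()
  for (method in normalization_methods()) {
    say("stage 1-2: %s (normalize, PCA-reduce, extract)", method)
    nset <- normalize_set(set, method, reference = reference, labels = labels)
    pca <- fit_pca(nset$matrix)
    scores <- pca_scores(pca, nset$matrix)
    red <- reduce_by_significance(scores[tumor, , drop = FALSE], tumor_labels,
                                  alpha = config$alpha,
                                  min_components = config$min_components)
    p_traces[[method]] <- red$p_trace
    kept <- scores[, seq_len(red$retained_count), drop = FALSE]
    features[[method]] <- build_feature_matrix(kept, fp,
                                               signals = nset$matrix,
                                               labels = labels,
                                               method_name = method)
    if (length(features[[method]]$dropped)) {
      stopf("non-finite features under %s; inspect the normalization", method)
    }
  }
  rm(set, nset, pca, scores, red, kept)

  say("stage 3 / analysis 1: selecting %d normalization methods",
      config$k_methods)
  cand1 <- do.call(rbind, lapply(normalization_methods(), function(m) {
    res <- matrix_statistic(features[[m]]$values[tumor, , drop = FALSE],
                            tumor_labels)
    data.frame(name = m, F = res$F, p = res$p)
  }))
  sel1 <- select_top(cand1, alpha = config$alpha, k = config$k_methods)
  methods_kept <- sel1$selected$name
  if (length(methods_kept) == 0L) {
    stopf(paste("analysis 1: no normalization method reached p < %g;",
                "the dataset carries no detectable class structure",
                "(too few records or too much noise)"), config$alpha)
  }

  say("stage 3 / analysis 2: ranking features over {%s}",
      paste(methods_kept, collapse = ", "))
  cand2 <- do.call(rbind, lapply(methods_kept, function(m) {
    vals <- features[[m]]$values[tumor, , drop = FALSE]
    do.call(rbind, lapply(colnames(vals), function(f) {
      res <- anova_column(vals[, f], tumor_labels)
      data.frame(name = paste0(f, "-", m), feature = f, method = m,
                 F = res$F, p = res$p)
    }))
  }))
  sel2 <- select_top(cand2, alpha = config$alpha, k = config$k_features)
  ranking <- sel2$selected
  if (nrow(ranking) < 2L) {
    stopf("analysis 2: fewer than 2 feature columns reached p < %g; cannot fuse",
          config$alpha)
  }
  ranking$rank <- seq_len(nrow(ranking))

  # per-record rank-ordered columns over all records (incl. tumor-free)
  ranked_all <- vapply(seq_len(nrow(ranking)), function(i) {
    features[[ranking$method[i]]]$values[, ranking$feature[i]]
  }, numeric(length(labels)))
  colnames(ranked_all) <- ranking$name

  say("stage 4: scanning hybrid widths")
  m_range <- config$m_range[config$m_range <= nrow(ranking) &
                              config$m_range >= 2L]
  if (length(m_range) == 0L) stopf("no valid hybrid widths to scan")
  scan <- scan_hybrid_widths(ranked_all[tumor, , drop = FALSE],
                             m_range = m_range, labels = tumor_labels,
                             block_size = acq$reps_per_point)

  widths <- if (identical(config$classify_datasets, "top3")) {
    scan$m[!is.na(scan$dataset_name)]
  } else {
    ws <- as.integer(config$classify_datasets)
    ws[ws %in% scan$m]
  }
  datasets <- lapply(widths, function(m) ranked_all[, seq_len(m), drop = FALSE])
  names(datasets) <- paste0(widths, "-HybridFeature")
  ref_name <- paste0("reference (rank-1 feature ", ranking$name[1], ")")
  datasets[[ref_name]] <- ranked_all[, 1L, drop = FALSE]

  say("classification: %d datasets x %d classifiers, %d-fold CV",
      length(datasets), length(config$classifiers), config$cv_k)
  eval_reports <- list()
  eval_rows <- list()
  for (dn in names(datasets)) {
    for (cls in config$classifiers) {
      spec <- as_model_spec(cls)
      say("  %s / %s", dn, spec$name)
      rep_ <- cross_validate(datasets[[dn]], labels, spec, k = config$cv_k,
                             seed = config$seed + 2L)
      eval_reports[[paste(dn, spec$name, sep = " / ")]] <- rep_
      eval_rows[[length(eval_rows) + 1L]] <-
        data.frame(dataset = dn, classifier = spec$name,
                   accuracy = rep_$average["accuracy"],
                   macro_accuracy = rep_$average["macro_accuracy"],
                   sensitivity = rep_$average["sensitivity"],
                   specificity = rep_$average["specificity"],
                   row.names = NULL)
    }
  }
  evaluation <- do.call(rbind, eval_rows)

  report <- structure(list(
    dataset_summary = list(n_records = length(labels),
                           n_tumor = sum(tumor),
                           n_tumor_free = sum(!tumor),
                           n_points = acq$n_points,
                           class_counts = table(labels)),
    analysis1 = sel1, analysis2 = sel2,
    ranking = ranking[, c("rank", "feature", "method", "F", "name")],
    p_traces = p_traces,
    hybrid_scan = scan[, c("m", "F", "p", "dataset_name")],
    hybrids = attr(scan, "hybrids"),
    evaluation = evaluation,
    eval_reports = eval_reports,
    config = config, seed = config$seed,
    wall_time_s = unname(proc.time()[3] - t0)), class = "run_report")
  if (!is.null(config$output_dir)) write_run_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d records; methods: %s\n",
              x$dataset_summary$n_records,
              paste(x$analysis1$selected$name, collapse = ", ")))
  cat("top-ranked features:",
      paste(head(x$ranking$name, 5), collapse = ", "), "...\n")
  print(x$evaluation, row.names = FALSE, digits = 4)
  cat(sprintf("wall time: %.1f s\n", x$wall_time_s))
  invisible(x)
}

#' Write the stage artifacts of a run to disk
#'
#' Emits the Analysis-1 and Analysis-2 tables, the feature ranking, the
#' hybrid-width scan and the evaluation table as CSV, the p-value traces
#' and a run summary as JSON.
#'
#' @param report a [run_msfs()] report.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(dir, f)
  data.table::fwrite(report$analysis1$candidates, out("analysis1_methods.csv"))
  data.table::fwrite(report$analysis2$candidates, out("analysis2_features.csv"))
  data.table::fwrite(report$ranking, out("feature_ranking.csv"))
  data.table::fwrite(report$hybrid_scan, out("hybrid_scan.csv"))
  data.table::fwrite(report$evaluation, out("evaluation.csv"))
  jsonlite::write_json(report$p_traces, out("p_traces.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = report$seed,
         n_records = report$dataset_summary$n_records,
         methods_selected = report$analysis1$selected$name,
         features_selected = report$ranking$name,
         wall_time_s = report$wall_time_s),
    out("run_summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
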