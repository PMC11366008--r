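#' Analysis run configuration
#'
#' Bundles everything a full 12-model run needs: the data source (a
#' container path or a [generator_config()]), the model grid to evaluate,
#' cross-validation shape, permutation count and master seed. The resolved
#' configuration is echoed into the output directory for audit.
#'
#' @param input a container path (see [load_dataset()]) or a
#'   [generator_config()].
#' @param contrasts,components,valences subsets of the model grid.
#' @param cutoffs named list of [assign_groups()] cutoffs.
#' @param grid a [hyper_grid()].
#' @param r,k repeated-CV shape; `k_select` selection folds.
#' @param B permutations per model (0 disables the permutation test).
#' @param seed master seed; all fold, permutation and generator seeds are
#'   derived from it.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input,
                       contrasts = c("depression", "anxiety"),
                       components = c("delta", "theta", "erp"),
                       valences = c("positive", "negative"),
                       cutoffs = list(), grid = hyper_grid(),
                       r = 10, k = 10, k_select = 3, B = 999L, seed = 1L) {
  structure(list(input = input, contrasts = contrasts,
                 components = components, valences = valences,
                 cutoffs = cutoffs, grid = grid, r = r, k = k,
                 k_select = k_select, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "run_config")
}

resolve_dataset <- function(input, seed) {
  if (inherits(input, "generator_config")) {
    generate_dataset(input, return = "erps")
  } else if (is.character(input)) {
    ds <- load_dataset(input)
    erps <- lapply(ds$epochs, function(ep)
      average_by_condition(baseline_correct(ep)))
    list(erps = erps, meta = ds$meta)
  } else if (is.list(input) && !is.null(input$erps)) {
    input
  } else stopf("run_config input must be a container path, a generator_config, or a prepared dataset")
}

config_digest <- function(config) {
  # order-stable fingerprint of the resolved configuration
  js <- jsonlite::toJSON(list(contrasts = config$contrasts,
                              components = config$components,
                              valences = config$valences,
                              cutoffs = config$cutoffs,
                              grid = config$grid, r = config$r, k = config$k,
                              k_select = config$k_select, B = config$B,
                              seed = config$seed),
                         auto_unbox = TRUE, digits = NA)
  sprintf("%08x", sum(utf8ToInt(as.character(js)) *
                        (seq_along(utf8ToInt(as.character(js))) %% 97 + 1)) %% 0xFFFFFFF)
}

#' Run the full multi-model analysis
#'
#' Executes [run_model()] for every configured contrast x component x
#' valence combination, writes a summary table (one row per model: train
#' ACC, mean CV balanced accuracy, permutation p, ROC AUC, recall,
#' precision), the pairwise reward-vs-punishment comparisons per
#' delta/theta component and contrast (corrected paired t-test on the
#' paired 10 x 10 balanced-accuracy and ROC-AUC vectors), and CSP pattern
#' tables. A failing combination is recorded and skipped; the run
#' continues.
#'
#' @param config a [run_config()].
#' @param output_dir directory to create for CSVs, JSON and the log
#'   (`NULL` = no files, results only returned).
#' @return List: `models` (per-model results), `summary` (data frame),
#'   `comparisons` (data frame), `failures`.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  dataset <- resolve_dataset(config$input, config$seed)
  digest <- config_digest(config)
  log_lines <- character()
  logit <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  logit("run %s: %d subjects with ERPs", digest, length(dataset$erps))

  plan <- enumerate_models(config$components, config$valences,
                           config$contrasts)
  models <- list()
  failures <- list()
  rows <- list()
  for (i in seq_len(nrow(plan))) {
    key <- paste(plan$contrast[i], plan$component[i], plan$valence[i],
                 sep = "_")
    res <- tryCatch(
      run_model(dataset, plan$component[i], plan$valence[i],
                plan$contrast[i], grid = config$grid,
                k_select = config$k_select, r = config$r, k = config$k,
                B = config$B, seed = config$seed, cutoffs = config$cutoffs),
      error = function(e) e)
    if (inherits(res, "error")) {
      logit("model %s FAILED: %s", key, conditionMessage(res))
      failures[[key]] <- conditionMessage(res)
      next
    }
    models[[key]] <- res
    rows[[key]] <- data.frame(
      contrast = plan$contrast[i], component = plan$component[i],
      valence = plan$valence[i],
      train_acc = res$train_acc,
      acc = mean(res$cv$ba),
      p_acc = if (is.null(res$permutation)) NA_real_ else res$permutation$p,
      roc_auc = mean(res$cv$auc),
      recall = mean(res$cv$recall),
      precision = mean(res$cv$precision))
    logit("model %s: ACC = %.3f, AUC = %.3f", key, mean(res$cv$ba),
          mean(res$cv$auc))
  }
  summary <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
             else NULL

  comp_rows <- list()
  for (contrast in config$contrasts) {
    for (component in intersect(config$components, c("delta", "theta"))) {
      ka <- paste(contrast, component, "positive", sep = "_")
      kb <- paste(contrast, component, "negative", sep = "_")
      if (is.null(models[[ka]]) || is.null(models[[kb]])) next
      for (metric in c("ba", "auc")) {
        ct <- corrected_paired_ttest(models[[ka]]$cv[[metric]],
                                     models[[kb]]$cv[[metric]],
                                     k = attr(models[[ka]]$cv, "k"),
                                     r = attr(models[[ka]]$cv, "r"))
        comp_rows[[paste(contrast, component, metric)]] <- data.frame(
          contrast = contrast, component = component, metric = metric,
          mean_positive = mean(models[[ka]]$cv[[metric]]),
          mean_negative = mean(models[[kb]]$cv[[metric]]),
          t = ct$t, df = ct$df, p = ct$p)
      }
    }
  }
  comparisons <- if (length(comp_rows))
    do.call(rbind, c(comp_rows, make.row.names = FALSE)) else NULL

  patterns <- list()
  for (key in names(models)) {
    res <- models[[key]]
    if (!res$component %in% c("delta", "theta")) next
    ids <- res$subjects
    inputs <- prepare_inputs(dataset$erps, ids, res$component, res$valence,
                             window = res$window)
    pos <- ids[res$labels == "symptomatic"]
    mdl <- csp_fit(inputs[ids %in% pos], inputs[!(ids %in% pos)],
                   lambda = res$hyper$csp_lambda,
                   m = res$hyper$csp_components,
                   meta = list(component = res$component,
                               valence = res$valence, contrast = res$contrast))
    patterns[[key]] <- export_patterns(mdl,
                                       dataset$erps[[ids[1]]]$positive$montage)
  }

  elapsed <- as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  logit("run %s finished in %.1f s (%d model(s), %d failure(s))", digest,
        elapsed, length(models), length(failures))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(summary))
      utils::write.csv(summary,
                       file.path(output_dir,
                                 sprintf("summary_%s.csv", digest)),
                       row.names = FALSE)
    if (!is.null(comparisons))
      utils::write.csv(comparisons,
                       file.path(output_dir,
                                 sprintf("comparisons_%s.csv", digest)),
                       row.names = FALSE)
    for (key in names(patterns))
      utils::write.csv(patterns[[key]],
                       file.path(output_dir,
                                 sprintf("patterns_%s_%s.csv", key, digest)),
                       row.names = FALSE)
    cfg <- config
    cfg$grid <- as.list(config$grid)
    cfg$input <- if (is.character(config$input)) config$input else "generator_config"
    jsonlite::write_json(unclass(cfg),
                         file.path(output_dir,
                                   sprintf("config_%s.json", digest)),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(log_lines, file.path(output_dir,
                                    sprintf("run_%s.log", digest)))
  }
  list(models = models, summary = summary, comparisons = comparisons,
       patterns = patterns, failures = failures, digest = digest)
}

#' Render a run summary as markdown
#'
#' Mirrors the results-table layout of the analysis: one row per model with
#' its scores, with models whose permutation p-value falls below 0.05 shown
#' in bold.
#'
#' @param results_dir directory written by [run_pipeline()], or the result
#'   list itself.
#' @param alpha significance threshold for bolding (default 0.05).
#' @return Character vector of markdown lines (invisibly written to
#'   `report.md` when given a directory).
#' @export
report_markdown <- function(results_dir, alpha = 0.05) {
  if (is.character(results_dir)) {
    files <- list.files(results_dir, pattern = "^summary_.*\\.csv$",
                        full.names = TRUE)
    if (!length(files))
      stopf("no summary CSV found in '%s'; run the pipeline first",
            results_dir)
    summary <- utils::read.csv(files[1])
    cfiles <- list.files(results_dir, pattern = "^comparisons_.*\\.csv$",
                         full.names = TRUE)
    comparisons <- if (length(cfiles)) utils::read.csv(cfiles[1]) else NULL
    write_out <- TRUE
  } else {
    summary <- results_dir$summary
    comparisons <- results_dir$comparisons
    results_dir <- NULL
    write_out <- FALSE
  }
  fmt <- function(x) sprintf("%.3f", x)
  lines <- c("# Classification results", "",
             "| Contrast | Component | Valence | Train ACC | ACC | p | R-AUC | Recall | Precision |",
             "|---|---|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    sig <- !is.na(s$p_acc) && s$p_acc < alpha
    acc <- if (sig) sprintf("**%s**", fmt(s$acc)) else fmt(s$acc)
    lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
                              s$contrast, s$component, s$valence,
                              fmt(s$train_acc), acc,
                              ifelse(is.na(s$p_acc), "-", fmt(s$p_acc)),
                              fmt(s$roc_auc), fmt(s$recall),
                              fmt(s$precision)))
  }
  lines <- c(lines, "",
             sprintf("Models with permutation p < %.2f in bold.", alpha))
  if (!is.null(comparisons) && nrow(comparisons)) {
    lines <- c(lines, "", "## Reward vs punishment model comparisons", "",
               "| Contrast | Component | Metric | Mean (reward) | Mean (punishment) | t | p |",
               "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(comparisons))) {
      cmp <- comparisons[i, ]
      star <- if (cmp$p < alpha) " *" else ""
      lines <- c(lines, sprintf("| %s | %s | %s | %s | %s | %.2f | %s%s |",
                                cmp$contrast, cmp$component, cmp$metric,
                                fmt(cmp$mean_positive), fmt(cmp$mean_negative),
                                cmp$t, fmt(cmp$p), star))
    }
  }
  if (write_out)
    writeLines(lines, file.path(results_dir, "report.md"))
  invisible(lines)
}
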