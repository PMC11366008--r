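# Classifier training and evaluation: hyperparameter selection by k-fold CV,
# repeated stratified k-fold scoring, and the glue that turns band-filtered
# subject ERPs into model inputs. Every data-dependent fitting step (class
# covariance averaging, CSP eigendecomposition, SVM fitting and its internal
# feature scaling) sees training-fold subjects only.

#' Hyperparameter grid
#'
#' The analysis grid: number of CSP components 1-4, CSP shrinkage
#' `lambda` log-spaced in `[1e-3, 1e-1]`, SVC kernel linear/radial, and SVC
#' cost `C` log-spaced in `[1e-5, 1e1]`. Shrinkage below 1e-3 is refused:
#' the 26-sample analysis window makes per-subject covariances rank
#' deficient, so some regularization is numerically mandatory.
#'
#' @param csp_components integer vector (ignored for feature-input models).
#' @param csp_lambda numeric vector in `[1e-3, 1]`.
#' @param kernel character subset of `c("linear", "radial")`.
#' @param cost positive numeric vector.
#' @return Data frame of grid points.
#' @export
hyper_grid <- function(csp_components = 1:4,
                       csp_lambda = 10^seq(-3, -1, length.out = 3),
                       kernel = c("linear", "radial"),
                       cost = 10^seq(-5, 1, length.out = 7)) {
  stopifnot(length(csp_components) > 0, length(csp_lambda) > 0,
            length(kernel) > 0, length(cost) > 0, all(cost > 0))
  if (any(csp_lambda < 1e-3))
    stopf("csp_lambda below 1e-3 is not allowed (rank-deficient covariances)")
  kernel <- match.arg(kernel, c("linear", "radial"), several.ok = TRUE)
  g <- expand.grid(csp_components = as.integer(csp_components),
                   csp_lambda = csp_lambda, kernel = kernel, cost = cost,
                   stringsAsFactors = FALSE)
  g[order(g$csp_lambda, g$csp_components, g$kernel, g$cost), , drop = FALSE]
}

#' Stratified fold assignment
#'
#' Random assignment of subjects to `k` folds, separately within each class,
#' so every fold contains both classes. If the smaller class has fewer than
#' `k` members, `k` is reduced to that size with a warning. Uses the current
#' RNG stream.
#'
#' @param labels binary label vector.
#' @param k requested folds.
#' @return Integer fold id per subject, with attribute `k` (effective fold
#'   count).
#' @export
stratified_folds <- function(labels, k) {
  pos <- as_binary(labels)
  n_min <- min(sum(pos), sum(!pos))
  if (n_min < 2) stopf("stratified folds need >= 2 subjects per class")
  if (n_min < k) {
    warnf("smallest class has %d subjects; reducing k from %d to %d",
          n_min, k, n_min)
    k <- n_min
  }
  fold <- integer(length(labels))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(pos == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  structure(fold, k = as.integer(k))
}

# ---- internal engine -------------------------------------------------------

is_feature_input <- function(data) is.matrix(data) || is.data.frame(data)

# trace-normalized raw covariances, computed once per dataset
cov_cache <- function(data) lapply(data, function(x) {
  cc <- tcrossprod(x)
  tr <- sum(diag(cc))
  if (tr <= 0) stopf("zero-variance window matrix in CSP input")
  cc / tr
})

shrink <- function(c0, lambda) {
  d <- nrow(c0)
  (1 - lambda) * c0 + lambda * diag(d) / d
}

# full CSP eigensystem of two average covariances (whitening route)
csp_solve <- function(c1, c2) {
  d <- nrow(c1)
  cs <- c1 + c2
  es <- eigen((cs + t(cs)) / 2, symmetric = TRUE)
  ev <- pmax(es$values, .Machine$double.eps * max(es$values))
  P <- es$vectors %*% diag(1 / sqrt(ev), d) %*% t(es$vectors)
  S <- P %*% c1 %*% P
  eu <- eigen((S + t(S)) / 2, symmetric = TRUE)
  mu <- pmin(pmax(eu$values, 0), 1)
  list(W = t(eu$vectors) %*% P, mu = mu,
       order = order_by_discriminability(mu))
}

# per-subject projected variances for all filters: n_subjects x d
proj_var <- function(W, covs) {
  t(vapply(covs, function(c0) diag(W %*% c0 %*% t(W)), numeric(nrow(W))))
}

logvar_features <- function(V, sel) {
  v <- V[, sel, drop = FALSE]
  log(v / rowSums(v))
}

# Feature standardization is done here (not via svm(scale = TRUE)) so the
# training-fold statistics are explicit and constant features (e.g. the
# degenerate one-component log-variance ratio) are handled without noise.
fit_svm <- function(feats, labels, kernel, cost) {
  mu <- colMeans(feats)
  sg <- apply(feats, 2, stats::sd)
  sg[!is.finite(sg) | sg <= 0] <- 1
  model <- e1071::svm(x = sweep(sweep(feats, 2, mu), 2, sg, "/"),
                      y = labels, kernel = kernel, cost = cost,
                      scale = FALSE)
  list(svm = model, center = mu, scale = sg)
}

svm_scores <- function(fit, feats, positive) {
  z <- sweep(sweep(feats, 2, fit$center), 2, fit$scale, "/")
  pr <- stats::predict(fit$svm, z, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  first <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  score <- if (first == positive) dv[, 1] else -dv[, 1]
  list(pred = pr, score = as.numeric(score))
}

# Fit the full pipeline (CSP where applicable + SVM) on the training subset
# and score the test subset. `cache` holds per-subject covariances for the
# CSP route; eig is an optional precomputed csp_solve for (train, lambda).
eval_split <- function(data, labels, train, test, hyper, cache = NULL,
                       eig = NULL) {
  positive <- levels(labels)[nlevels(labels)]
  if (is_feature_input(data)) {
    ftr <- as.matrix(data)[train, , drop = FALSE]
    fte <- as.matrix(data)[test, , drop = FALSE]
  } else {
    if (is.null(eig)) {
      pos_tr <- train[labels[train] == positive]
      neg_tr <- setdiff(train, pos_tr)
      c1 <- shrink(Reduce(`+`, cache[pos_tr]) / length(pos_tr), hyper$csp_lambda)
      c2 <- shrink(Reduce(`+`, cache[neg_tr]) / length(neg_tr), hyper$csp_lambda)
      eig <- csp_solve(c1, c2)
    }
    sel <- eig$order[seq_len(hyper$csp_components)]
    Vtr <- proj_var(eig$W, cache[train])
    Vte <- proj_var(eig$W, cache[test])
    ftr <- logvar_features(Vtr, sel)
    fte <- logvar_features(Vte, sel)
  }
  model <- fit_svm(ftr, labels[train], hyper$kernel, hyper$cost)
  out <- svm_scores(model, fte, positive)
  list(pred = out$pred, score = out$score, truth = labels[test])
}

split_metrics <- function(res) {
  c(ba = balanced_accuracy(res$truth, res$pred),
    auc = roc_auc(res$score, res$truth),
    precision = as.numeric(precision_score(res$truth, res$pred)),
    recall = recall_score(res$truth, res$pred))
}

# ---- selection -------------------------------------------------------------

#' Select hyperparameters by stratified k-fold cross-validation
#'
#' For every grid point the full pipeline -- CSP fitted on the training fold
#' only, then the SVM -- is refit per fold; the winning grid point has the
#' highest mean cross-validated balanced accuracy. Ties are broken towards
#' fewer CSP components, then smaller cost, then the linear kernel.
#'
#' @param data either a list of channels x samples window matrices (CSP
#'   pipeline) or a numeric feature matrix with one row per subject.
#' @param labels factor with levels `control`, `symptomatic` (or any binary
#'   coding; the second level is the positive class).
#' @param grid a [hyper_grid()]; CSP columns are ignored for feature input.
#' @param k selection folds (default 3).
#' @param seed integer; fixes the fold assignment.
#' @return List: `best` (the selected grid row), `best_score` (its mean CV
#'   balanced accuracy), `grid_scores` (per-point mean scores), `folds`, `k`.
#' @export
fit_select <- function(data, labels, grid = hyper_grid(), k = 3, seed = 1L) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stopf("binary labels required")
  feature_mode <- is_feature_input(data)
  if (feature_mode) {
    grid <- unique(grid[, c("kernel", "cost")])
    grid$csp_components <- NA_integer_
    grid$csp_lambda <- NA_real_
  }
  folds <- with_seed(seed, function() stratified_folds(labels, k))
  k <- attr(folds, "k")
  cache <- if (!feature_mode) cov_cache(data)
  positive <- levels(labels)[2]
  acc <- matrix(NA_real_, nrow(grid), k)
  for (fold in seq_len(k)) {
    test <- which(folds == fold)
    train <- which(folds != fold)
    if (feature_mode) {
      for (gi in seq_len(nrow(grid))) {
        res <- eval_split(data, labels, train, test, grid[gi, ])
        acc[gi, fold] <- balanced_accuracy(res$truth, res$pred)
      }
    } else {
      pos_tr <- train[labels[train] == positive]
      neg_tr <- setdiff(train, pos_tr)
      c1_0 <- Reduce(`+`, cache[pos_tr]) / length(pos_tr)
      c2_0 <- Reduce(`+`, cache[neg_tr]) / length(neg_tr)
      for (lam in unique(grid$csp_lambda)) {
        eig <- csp_solve(shrink(c1_0, lam), shrink(c2_0, lam))
        gidx <- which(grid$csp_lambda == lam)
        for (gi in gidx) {
          res <- eval_split(data, labels, train, test, grid[gi, ],
                            cache = cache, eig = eig)
          acc[gi, fold] <- balanced_accuracy(res$truth, res$pred)
        }
      }
    }
  }
  mean_acc <- rowMeans(acc)
  ord <- order(-mean_acc, grid$csp_components, grid$cost,
               grid$kernel == "radial")
  best <- grid[ord[1], , drop = FALSE]
  gs <- cbind(grid, mean_balanced_accuracy = mean_acc)
  list(best = best, best_score = mean_acc[ord[1]], grid_scores = gs,
       folds = as.integer(folds), k = k, seed = as.integer(seed))
}

#' Balanced accuracy on the full training data
#'
#' Fits the pipeline on all subjects with fixed hyperparameters and scores it
#' on the same subjects (no cross-validation) -- the optimistic "train ACC"
#' used to gauge overfitting.
#'
#' @inheritParams fit_select
#' @param hyper single-row data frame of hyperparameters.
#' @return Scalar balanced accuracy.
#' @export
train_accuracy <- function(data, labels, hyper) {
  labels <- as.factor(labels)
  all_idx <- seq_along(labels)
  cache <- if (!is_feature_input(data)) cov_cache(data)
  res <- eval_split(data, labels, all_idx, all_idx, hyper, cache = cache)
  balanced_accuracy(res$truth, res$pred)
}

#' Repeated stratified k-fold scoring
#'
#' `r` independent stratified `k`-fold partitions; per split the full
#' pipeline is refit on the training folds and scored on the held-out fold,
#' yielding `r * k` values of balanced accuracy, ROC AUC, precision and
#' recall. The split sequence is a pure function of `labels` and `seed`, so
#' two models evaluated with the same seed on the same subjects see
#' identical splits (the paired design required by
#' [corrected_paired_ttest()]).
#'
#' @inheritParams train_accuracy
#' @param r repeats (default 10).
#' @param k folds (default 10; reduced with a warning if a class is
#'   smaller).
#' @return A `cv_report`: data frame with columns `rep`, `fold`, `ba`,
#'   `auc`, `precision`, `recall`; attributes `hyper`, `r`, `k`, `seed`.
#' @export
repeated_cv_score <- function(data, labels, hyper, r = 10, k = 10,
                              seed = 1L) {
  labels <- as.factor(labels)
  folds_per_rep <- with_seed(seed, function()
    lapply(seq_len(r), function(i) stratified_folds(labels, k)))
  k_eff <- attr(folds_per_rep[[1]], "k")
  cache <- if (!is_feature_input(data)) cov_cache(data)
  rows <- list()
  for (i in seq_len(r)) {
    folds <- folds_per_rep[[i]]
    for (fold in seq_len(k_eff)) {
      test <- which(folds == fold)
      train <- which(folds != fold)
      res <- eval_split(data, labels, train, test, hyper, cache = cache)
      rows[[length(rows) + 1L]] <-
        data.frame(rep = i, fold = fold, t(split_metrics(res)))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_report", "data.frame")
  attr(out, "hyper") <- hyper
  attr(out, "r") <- as.integer(r)
  attr(out, "k") <- k_eff
  attr(out, "seed") <- as.integer(seed)
  out
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d x %d CV: mean BA = %.3f, AUC = %.3f, precision = %.3f, recall = %.3f\n",
              attr(x, "r"), attr(x, "k"), mean(x$ba), mean(x$auc),
              mean(x$precision), mean(x$recall)))
  invisible(x)
}

# ---- model assembly --------------------------------------------------------

#' Build model inputs from subject ERPs
#'
#' For `delta`/`theta`, applies the band-separation FIR to each subject's
#' full-length broadband ERP of the requested valence, then extracts the
#' analysis window, yielding one channels x samples matrix per subject. For
#' `erp`, returns the single FCz mean-amplitude feature (RewP for positive
#' feedback, FRN for negative).
#'
#' @param erps named list (by subject id): each element has `positive` and
#'   `negative` broadband [subject_erp()]s.
#' @param subject_ids subjects to include, in order.
#' @param component `"delta"`, `"theta"` or `"erp"`.
#' @param valence `"positive"` or `"negative"`.
#' @param window analysis window in ms.
#' @param channel electrode for the ERP feature.
#' @return List of window matrices, or a one-column feature matrix.
#' @export
prepare_inputs <- function(erps, subject_ids, component, valence,
                           window = c(200, 300), channel = "FCz") {
  component <- match.arg(component, c("delta", "theta", "erp"))
  valence <- match.arg(valence, c("positive", "negative"))
  missing <- setdiff(subject_ids, names(erps))
  if (length(missing))
    stopf("no ERPs for subject(s): %s", paste(missing, collapse = ", "))
  sel <- lapply(subject_ids, function(id) erps[[id]][[valence]])
  if (component == "erp") {
    feats <- matrix(vapply(sel, erp_amplitude, 0, channel = channel,
                           window = window), ncol = 1,
                    dimnames = list(subject_ids, "mean_amplitude"))
    return(feats)
  }
  srate <- sel[[1]]$srate
  spec <- if (component == "delta") delta_filter_spec(srate)
          else theta_filter_spec(srate)
  design <- design_fir(spec)
  out <- lapply(sel, function(e) extract_window(apply_filter(e, design),
                                                window))
  names(out) <- subject_ids
  out
}

#' Run one band/valence/contrast classification model
#'
#' The full single-model procedure: select the symptomatic-vs-control
#' subjects, build the component's inputs, choose hyperparameters by
#' stratified 3-fold CV (highest mean balanced accuracy), report the
#' training-set score, score the selected configuration under 10 x 10
#' repeated CV, and (optionally) assess significance of the selection-stage
#' score with a label-permutation test that re-runs the entire selection per
#' permutation on identical folds.
#'
#' Splits for the repeated CV are seeded from `(seed, contrast)` only, so
#' models of different components/valences on the same contrast are paired.
#'
#' @param dataset list with `erps` (as in [prepare_inputs()]) and `meta` (a
#'   [subject_meta()] table).
#' @param component `"delta"`, `"theta"` or `"erp"`.
#' @param valence `"positive"` or `"negative"`.
#' @param contrast `"depression"` or `"anxiety"`.
#' @param grid a [hyper_grid()].
#' @param window,channel analysis window (ms) and ERP electrode.
#' @param k_select selection folds (default 3).
#' @param r,k repeated-CV shape (default 10 x 10).
#' @param B permutations for the significance test (0 disables).
#' @param seed master seed for folds and permutations.
#' @param cutoffs optional named list passed on to [assign_groups()].
#' @return Object of class `model_result`: selection output, `train_acc`,
#'   `cv` ([repeated_cv_score()] report), `permutation`, subjects, labels
#'   and the configuration.
#' @export
run_model <- function(dataset, component, valence, contrast,
                      grid = hyper_grid(), window = c(200, 300),
                      channel = "FCz", k_select = 3, r = 10, k = 10,
                      B = 999L, seed = 1L, cutoffs = list()) {
  groups <- do.call(assign_groups, c(list(meta = dataset$meta), cutoffs))
  sel <- select_contrast(groups, contrast)
  labels <- sel$label
  data <- prepare_inputs(dataset$erps, sel$subject_id, component, valence,
                         window = window, channel = channel)
  sel_seed <- derive_seed(seed, paste0("select-", contrast))
  cv_seed <- derive_seed(seed, paste0("cv-", contrast))
  perm_seed <- derive_seed(seed, paste0("perm-", contrast, "-", component,
                                        "-", valence))
  selection <- fit_select(data, labels, grid, k = k_select, seed = sel_seed)
  train_acc <- train_accuracy(data, labels, selection$best)
  cv <- repeated_cv_score(data, labels, selection$best, r = r, k = k,
                          seed = cv_seed)
  permutation <- NULL
  if (B > 0) {
    evaluator <- function(lab)
      fit_select(data, lab, grid, k = k_select, seed = sel_seed)$best_score
    permutation <- permutation_test(evaluator, labels, B = B,
                                    seed = perm_seed)
  }
  structure(list(component = component, valence = valence,
                 contrast = contrast, subjects = sel$subject_id,
                 labels = labels, selection = selection,
                 hyper = selection$best, train_acc = train_acc, cv = cv,
                 permutation = permutation, window = window,
                 channel = channel, seed = as.integer(seed)),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s / %s / %s (n = %d)\n", x$component,
              x$valence, x$contrast, length(x$subjects)))
  cat(sprintf("  selection ACC = %.3f; train ACC = %.3f; 10x10 CV ACC = %.3f, AUC = %.3f\n",
              x$selection$best_score, x$train_acc, mean(x$cv$ba),
              mean(x$cv$auc)))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation p = %.4g (B = %d)\n", x$permutation$p,
                x$permutation$B))
  invisible(x)
}

#' Enumerate the analysis model grid
#'
#' The 2 (contrast) x 3 (component) x 2 (valence) combinations evaluated by
#' the pipeline.
#'
#' @param components,valences,contrasts optional subsets.
#' @return Data frame with one row per model.
#' @export
enumerate_models <- function(components = c("delta", "theta", "erp"),
                             valences = c("positive", "negative"),
                             contrasts = c("depression", "anxiety")) {
  expand.grid(contrast = contrasts, component = components,
              valence = valences, stringsAsFactors = FALSE)
}
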