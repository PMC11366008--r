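test_that("the hyperparameter grid enforces the printed ranges", {
  g <- hyper_grid()
  expect_equal(sort(unique(g$csp_components)), 1:4)
  expect_equal(range(g$csp_lambda), c(1e-3, 1e-1))
  expect_equal(range(g$cost), c(1e-5, 1e1))
  expect_setequal(unique(g$kernel), c("linear", "radial"))
  expect_error(hyper_grid(csp_lambda = 1e-4), "1e-3")
})

test_that("the analysis enumerates the full 2 x 3 x 2 model grid", {
  m <- enumerate_models()
  expect_equal(nrow(m), 12)
  expect_equal(nrow(unique(m)), 12)
  expect_equal(nrow(enumerate_models(components = "theta",
                                     valences = "positive")), 2)
})

test_that("stratified folds partition both classes across every fold", {
  labels <- factor(rep(c("control", "symptomatic"), c(14, 9)))
  set.seed(2)
  f <- stratified_folds(labels, 3)
  expect_equal(sort(unique(f)), 1:3)
  for (k in 1:3) {
    expect_true(any(labels[f == k] == "control"))
    expect_true(any(labels[f == k] == "symptomatic"))
  }
  expect_warning(f2 <- stratified_folds(labels, 10), "reducing k")
  expect_equal(attr(f2, "k"), 9L)
})

test_that("linearly separable features are classified perfectly", {
  set.seed(4)
  labels <- factor(rep(c("control", "symptomatic"), each = 9))
  feats <- matrix(ifelse(labels == "symptomatic", 1, -1) +
                    rnorm(18, 0, 0.01), ncol = 1)
  selres <- fit_select(feats, labels,
                       hyper_grid(kernel = "linear", cost = c(0.1, 1)),
                       k = 3, seed = 1)
  expect_equal(selres$best_score, 1.0)
  expect_equal(train_accuracy(feats, labels, selres$best), 1.0)
})

test_that("uninformative features score at chance under fixed hyperparameters", {
  set.seed(6)
  labels <- factor(rep(c("control", "symptomatic"), each = 15))
  feats <- matrix(rnorm(30), ncol = 1)
  hyper <- data.frame(csp_components = NA, csp_lambda = NA,
                      kernel = "linear", cost = 1, stringsAsFactors = FALSE)
  cv <- repeated_cv_score(feats, labels, hyper, r = 4, k = 3, seed = 3)
  expect_equal(mean(cv$ba), 0.5, tolerance = 0.15)
})

test_that("repeated CV yields r * k scores, reproducibly", {
  set.seed(8)
  labels <- factor(rep(c("control", "symptomatic"), each = 12))
  feats <- matrix(rnorm(48), ncol = 2)
  hyper <- data.frame(csp_components = NA, csp_lambda = NA,
                      kernel = "radial", cost = 1, stringsAsFactors = FALSE)
  a <- repeated_cv_score(feats, labels, hyper, r = 10, k = 10, seed = 21)
  expect_equal(nrow(a), 100)
  expect_true(all(a$ba >= 0 & a$ba <= 1))
  expect_true(all(a$auc >= 0 & a$auc <= 1))
  b <- repeated_cv_score(feats, labels, hyper, r = 10, k = 10, seed = 21)
  expect_identical(a$ba, b$ba)
  expect_identical(a$auc, b$auc)
  # class smaller than k: fold count is reduced (warned once per repeat)
  # and recorded
  small <- factor(rep(c("control", "symptomatic"), each = 4))
  sf <- matrix(rnorm(16), ncol = 2)
  ws <- capture_warnings(cc <- repeated_cv_score(sf, small, hyper, r = 2,
                                                 k = 10, seed = 1))
  expect_true(any(grepl("reducing k", ws)))
  expect_equal(nrow(cc), 2 * 4)
  expect_equal(attr(cc, "k"), 4L)
})

test_that("CSP-route selection evaluates the full grid per fold", {
  cfg <- quick_config(n_per_group = 8, trials_per_valence = 5, seed = 15,
                      effects = effect_spec("theta", "positive",
                                            amplitude_shift = 10,
                                            base_amplitude = 1))
  ds <- generate_dataset(cfg, return = "erps")
  grp <- assign_groups(ds$meta)
  sel <- select_contrast(grp, "depression")
  X <- prepare_inputs(ds$erps, sel$subject_id, "theta", "positive")
  grid <- hyper_grid(csp_components = c(2, 4), csp_lambda = c(1e-2, 1e-1),
                     kernel = "linear", cost = c(0.1, 1))
  selres <- fit_select(X, sel$label, grid, k = 3, seed = 2)
  expect_equal(nrow(selres$grid_scores), nrow(grid))
  expect_true(all(!is.na(selres$grid_scores$mean_balanced_accuracy)))
  expect_true(selres$best_score ==
                max(selres$grid_scores$mean_balanced_accuracy))
})

test_that("the ERP model on label-independent data averages chance over seeds", {
  bas <- sapply(1:5, function(s) {
    cfg <- quick_config(n_per_group = 10, trials_per_valence = 5,
                        seed = 22 + s)
    ds <- generate_dataset(cfg, return = "erps")
    res <- run_model(ds, "erp", "positive", "depression",
                     grid = hyper_grid(kernel = "linear", cost = c(0.1, 1)),
                     r = 3, k = 5, B = 0, seed = 9)
    mean(res$cv$ba)
  })
  expect_equal(mean(bas), 0.5, tolerance = 0.12 / 0.5)
})

test_that("run_model is deterministic and paired across components", {
  cfg <- quick_config(n_per_group = 8, trials_per_valence = 5, seed = 27)
  ds <- generate_dataset(cfg, return = "erps")
  grid <- hyper_grid(csp_components = 2, csp_lambda = 1e-2,
                     kernel = "linear", cost = 1)
  a <- run_model(ds, "theta", "positive", "depression", grid = grid,
                 r = 2, k = 4, B = 0, seed = 31)
  b <- run_model(ds, "theta", "positive", "depression", grid = grid,
                 r = 2, k = 4, B = 0, seed = 31)
  expect_identical(a$cv$ba, b$cv$ba)
  # same contrast + seed -> same split sequence for another component,
  # which is what makes the corrected paired t-test valid
  d <- run_model(ds, "delta", "positive", "depression", grid = grid,
                 r = 2, k = 4, B = 0, seed = 31)
  expect_identical(attr(a$cv, "seed"), attr(d$cv, "seed"))
})

test_that("permutation machinery plugs into the selection stage", {
  cfg <- quick_config(n_per_group = 6, trials_per_valence = 5, seed = 33)
  ds <- generate_dataset(cfg, return = "erps")
  res <- suppressWarnings(
    run_model(ds, "erp", "positive", "depression",
              grid = hyper_grid(kernel = "linear", cost = 1),
              r = 2, k = 3, B = 19, seed = 3))
  expect_s3_class(res$permutation, "permutation_result")
  expect_equal(res$permutation$observed, res$selection$best_score)
  expect_gte(res$permutation$p, 1 / 20)
})
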