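#' Trace-normalized, shrinkage-regularized subject covariance
#'
#' Spatial covariance of a windowed (channels x samples) data matrix:
#' `C0 = X X' / trace(X X')`, then shrunk towards the scaled identity,
#' `(1 - lambda) C0 + lambda (trace(C0)/d) I`. Trace normalization removes
#' inter-subject amplitude scale before class averaging; shrinkage makes the
#' matrix strictly positive definite, which is mandatory here because a
#' 26-sample window cannot support a full-rank 64-channel covariance.
#'
#' @param x numeric matrix, channels x samples (>= 2 samples).
#' @param lambda shrinkage weight in `[0, 1]`.
#' @return Symmetric channels x channels matrix.
#' @export
subject_covariance <- function(x, lambda = 0) {
  stopifnot(is.matrix(x), ncol(x) >= 2, lambda >= 0, lambda <= 1)
  d <- nrow(x)
  if (lambda == 1) return(diag(d) / d)
  cc <- tcrossprod(x)
  tr <- sum(diag(cc))
  if (tr <= 0) {
    if (lambda == 0)
      stopf("zero-variance input and lambda = 0: covariance is singular")
    c0 <- matrix(0, d, d)
  } else c0 <- cc / tr
  (1 - lambda) * c0 + lambda * diag(d) / d
}

# Component order: pairs from the two ends of the eigenvalue spectrum,
# interleaved, starting with the end of larger discriminability |mu - 0.5|
# (ties towards the larger eigenvalue). Taking both ends matters because the
# normalized log-variance features only carry information through contrasts
# BETWEEN selected components: components drawn from one end alone rise and
# fall together across subjects and cancel in the ratio.
order_by_discriminability <- function(mu) {
  hi <- order(-mu)   # class-1-heavy end first
  lo <- order(mu)    # class-2-heavy end first
  first_hi <- abs(mu[hi[1]] - 0.5) >= abs(mu[lo[1]] - 0.5)
  a <- if (first_hi) hi else lo
  b <- if (first_hi) lo else hi
  out <- integer(0)
  for (i in seq_along(mu)) {
    out <- c(out, a[i], b[i])
    if (length(unique(out)) >= length(mu)) break
  }
  unique(out)[seq_along(mu)]
}

#' Fit Common Spatial Patterns on two classes of covariance matrices
#'
#' Averages the (shrunk, trace-normalized) class covariances `C1`, `C2` and
#' solves the generalized eigenproblem `C1 w = mu (C1 + C2) w` via symmetric
#' whitening of `C1 + C2`. Eigenvalues `mu` lie in `[0, 1]` and give the
#' share of class-1 variance captured by each spatial filter; filters are
#' ranked by discriminability `|mu - 0.5|` (descending, ties to the larger
#' `mu`), which interleaves the two ends of the spectrum. Spatial patterns
#' (the forward model used for topographic interpretation) are recovered
#' through the filter-pattern duality `A = (C1+C2) W (W'(C1+C2)W)^-1`.
#'
#' @param class1,class2 lists of channels x samples matrices (one per
#'   subject), or lists of precomputed covariance matrices.
#' @param lambda shrinkage weight (see [subject_covariance()]).
#' @param m number of components to keep (1-4 in the analysis grid; at most
#'   the channel count).
#' @param meta optional named list recorded on the model (band, valence,
#'   contrast).
#' @return An object of class `csp_model`: `W` (m x channels filters), `mu`
#'   (per-component class-1 variance share), `patterns` (channels x m),
#'   `mu_all`, `lambda`, `m`, `meta`.
#' @export
csp_fit <- function(class1, class2, lambda = 0.01, m = 2L, meta = list()) {
  avg_cov <- function(xs) {
    if (length(xs) < 2) stopf("each class needs at least 2 subjects")
    covs <- lapply(xs, function(x) {
      if (nrow(x) == ncol(x) && isTRUE(all.equal(x, t(x), tolerance = 1e-8)))
        x else subject_covariance(x, lambda)
    })
    Reduce(`+`, covs) / length(covs)
  }
  c1 <- avg_cov(class1)
  c2 <- avg_cov(class2)
  d <- nrow(c1)
  if (!all(is.finite(c1)) || !all(is.finite(c2)))
    stopf("non-finite class covariance")
  if (m > d) stopf("m = %d exceeds the channel count (%d)", m, d)
  cs <- c1 + c2
  es <- eigen((cs + t(cs)) / 2, symmetric = TRUE)
  ev <- pmax(es$values, .Machine$double.eps * max(es$values))
  P <- es$vectors %*% diag(1 / sqrt(ev), d) %*% t(es$vectors)  # whitener
  S <- P %*% c1 %*% P
  eu <- eigen((S + t(S)) / 2, symmetric = TRUE)
  mu_all <- pmin(pmax(eu$values, 0), 1)
  W_all <- t(eu$vectors) %*% P  # rows are spatial filters
  ord <- order_by_discriminability(mu_all)
  sel <- ord[seq_len(m)]
  W <- W_all[sel, , drop = FALSE]
  G <- W %*% cs %*% t(W)
  A <- cs %*% t(W) %*% solve(G)
  structure(list(W = W, mu = mu_all[sel], patterns = A, mu_all = mu_all,
                 lambda = lambda, m = as.integer(m), meta = meta),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat(sprintf("<csp_model> %d component(s) of %d channels, lambda = %g\n",
              x$m, ncol(x$W), x$lambda))
  cat("  mu:", sprintf("%.3f", x$mu), "\n")
  if (length(x$meta))
    cat("  fitted on:", paste(names(x$meta), unlist(x$meta), sep = "=",
                              collapse = ", "), "\n")
  invisible(x)
}

#' Log-variance CSP features
#'
#' Projects a windowed data matrix through the fitted spatial filters and
#' returns the normalized log-variance features
#' `f_j = log(var_j / sum_k var_k)`, where `var_j` is the mean square of the
#' j-th filtered signal. The ratio makes the features invariant to overall
#' amplitude scale.
#'
#' @param model a [csp_fit()] model.
#' @param x channels x samples matrix (same montage as training).
#' @return Numeric vector of length `m`.
#' @export
csp_transform <- function(model, x) {
  stopifnot(inherits(model, "csp_model"))
  if (nrow(x) != ncol(model$W))
    stopf("data has %d channels but model was fitted on %d",
          nrow(x), ncol(model$W))
  pr <- model$W %*% x
  v <- rowMeans(pr^2)
  tot <- sum(v)
  if (tot <= 0)
    stopf("zero projected variance: input window carries no signal")
  log(v / tot)
}

#' Export CSP spatial patterns for topographic plotting
#'
#' @param model a [csp_fit()] model.
#' @param montage the [montage()] the model was trained on.
#' @return Data frame: channel label, head-plane x/y (if available), one
#'   column of pattern weights per component.
#' @export
export_patterns <- function(model, montage) {
  stopifnot(inherits(model, "csp_model"))
  if (length(montage) != nrow(model$patterns))
    stopf("montage size (%d) does not match pattern rows (%d)",
          length(montage), nrow(model$patterns))
  out <- data.frame(channel = montage$labels, stringsAsFactors = FALSE)
  if (!is.null(montage$positions)) {
    out$x <- montage$positions$x
    out$y <- montage$positions$y
  }
  for (j in seq_len(model$m))
    out[[sprintf("pattern_%d", j)]] <- model$patterns[, j]
  out
}

#' Serialize / restore a CSP model as JSON
#'
#' @param model a [csp_fit()] model.
#' @param path file to write / read.
#' @return `read_csp()` returns the restored `csp_model`.
#' @export
write_csp <- function(model, path) {
  stopifnot(inherits(model, "csp_model"))
  obj <- list(W = model$W, mu = model$mu, patterns = model$patterns,
              mu_all = model$mu_all, lambda = model$lambda, m = model$m,
              meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_csp
#' @export
read_csp <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(W = as.matrix(obj$W), mu = obj$mu,
                 patterns = as.matrix(obj$patterns),
                 mu_all = obj$mu_all, lambda = obj$lambda,
                 m = as.integer(obj$m),
                 meta = as.list(obj$meta)),
            class = "csp_model")
}
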