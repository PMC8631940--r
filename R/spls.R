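# Lasso-regularized partial least squares between a founder-probability
# genotype block and flattened shape coordinates. Both blocks are
# column-standardized, the cross-correlation matrix is soft-thresholded
# entrywise, and the first singular pair of the thresholded matrix gives
# the genetic (u) and phenotypic (v) loadings. Only the first paired
# axes are computed; shape is then regressed on the genotype score to
# obtain predicted shapes and a trace-ratio R^2.

#' Cross-correlation matrix of two blocks
#'
#' Columns of both blocks are centered and scaled to unit variance
#' (zero-variance columns become zero vectors), giving
#' `C = X' Y / (n - 1)` with entries in `[-1, 1]`: the entrywise Pearson
#' correlation between block columns.
#'
#' @param X n x p matrix.
#' @param Y n x q matrix.
#' @return p x q correlation matrix.
#' @export
cross_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_mgp("X and Y must have the same rows")
  if (nrow(X) < 3L) stop_mgp("need at least 3 specimens")
  sx <- std_cols(X); sy <- std_cols(Y)
  crossprod(sx$X, sy$X) / (nrow(X) - 1L)
}

#' Soft-thresholding (lasso) operator
#'
#' Entrywise `sign(c) * max(|c| - lambda, 0)`: drives small
#' cross-correlations to exactly zero, the sparsity mechanism of the
#' regularized PLS.
#'
#' @param C numeric matrix (or vector).
#' @param lambda threshold, `>= 0`.
#' @return Thresholded object of the same shape.
#' @export
soft_threshold <- function(C, lambda) {
  if (lambda < 0) stop_mgp("lambda must be non-negative")
  sign(C) * pmax(abs(C) - lambda, 0)
}

# Leading singular triple of a matrix. Dense LAPACK SVD for moderate
# sizes; deterministic power iteration on crossprod for large ones.
leading_triple <- function(C, tol = 1e-10, max_iter = 1000L) {
  p <- nrow(C); q <- ncol(C)
  if (p + q <= 2000L) {
    s <- svd(C, nu = 1L, nv = 1L)
    return(list(u = s$u[, 1L], d = s$d[1L], v = s$v[, 1L]))
  }
  # power method on C'C; deterministic start: column of C with largest norm
  cn <- colSums(C^2)
  v <- C[, which.max(cn)]
  v <- crossprod(C, v)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(list(u = rep(0, p), d = 0, v = rep(0, q)))
  v <- v / nv
  d_old <- 0
  for (i in seq_len(max_iter)) {
    w <- C %*% v
    v_new <- crossprod(C, w)
    nn <- sqrt(sum(v_new^2))
    if (nn == 0) return(list(u = rep(0, p), d = 0, v = rep(0, q)))
    v_new <- as.vector(v_new / nn)
    d_est <- sqrt(sum((C %*% v_new)^2))
    if (abs(d_est - d_old) < tol) { v <- v_new; break }
    d_old <- d_est
    v <- v_new
  }
  u <- as.vector(C %*% v)
  d <- sqrt(sum(u^2))
  list(u = u / d, d = d, v = v)
}

# Core fit on pre-standardized blocks; shared by fit_spls and the
# permutation/drop engines which reuse a standardized Y.
fit_core <- function(Xs, Yc, y_tr, lambda, C = NULL) {
  n <- nrow(Xs)
  if (is.null(C)) C <- crossprod(Xs, Yc_std(Yc)) / (n - 1L)
  Cl <- soft_threshold(C, lambda)
  if (all(Cl == 0)) {
    return(list(u = rep(0, nrow(C)), v = rep(0, ncol(C)), d = 0,
                scores = rep(0, n), b = rep(0, ncol(C)), r2 = 0))
  }
  tri <- leading_triple(Cl)
  u <- tri$u; v <- tri$v; d <- tri$d
  # sign convention: largest-|v| entry positive
  i_max <- which.max(abs(v))
  if (v[i_max] < 0) { v <- -v; u <- -u }
  scores <- as.vector(Xs %*% u)
  ss <- sum(scores^2)
  b <- if (ss > 0) as.vector(crossprod(Yc, scores)) / ss else rep(0, ncol(Yc))
  r2 <- if (ss > 0 && y_tr > 0) {
    tc <- scores - mean(scores)
    (sum(tc^2) / (n - 1L)) * sum(b^2) / y_tr
  } else 0
  list(u = u, v = v, d = d, scores = scores, b = b, r2 = r2)
}

Yc_std <- function(Yc) {
  sds <- sqrt(colSums(Yc^2) / max(1L, nrow(Yc) - 1L))
  ok <- sds > 0
  Ys <- Yc
  Ys[, ok] <- sweep(Yc[, ok, drop = FALSE], 2L, sds[ok], "/")
  Ys[, !ok] <- 0
  Ys
}

#' Fit the regularized PLS model
#'
#' Computes the cross-correlation of the standardized genotype and shape
#' blocks, soft-thresholds it at `lambda`, and extracts the leading
#' singular triple `(u, d, v)`. Genotype scores are `t = X_std u`; the
#' length-3K shape regression `b = Y_c' t / t't` maps scores back to
#' shape, and R^2 is the trace ratio of predicted to observed shape
#' covariance. When `lambda` saturates (all entries thresholded to
#' zero) the fit is all-zero with R^2 = 0. The sign of `v` is fixed so
#' its largest-magnitude entry is positive.
#'
#' @param X genotype block (`genotype_block` or plain n x p matrix).
#' @param Y n x q matrix of flattened shapes.
#' @param lambda regularization strength on the correlation scale,
#'   `>= 0`.
#' @return An object of class `mgp_pls`: `lambda`, `u`, `v`, `d`,
#'   `scores`, `b`, `r2`, standardization records (`x_center`,
#'   `x_scale`, `y_center`, `y_scale`), `x_labels`, `genes`.
#' @export
fit_spls <- function(X, Y, lambda = 0.06) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_mgp("X and Y must have the same rows")
  if (anyNA(X) || anyNA(Y)) stop_mgp("NA values in input blocks")
  if (lambda < 0) stop_mgp("lambda must be non-negative")
  if (nrow(X) < 10L) warning("fewer than 10 specimens; fit will be unstable",
                             call. = FALSE)
  sx <- std_cols(X)
  y_ctr <- colMeans(Y)
  Yc <- sweep(Y, 2L, y_ctr, "-")
  y_sds <- sqrt(colSums(Yc^2) / max(1L, nrow(Y) - 1L))
  y_tr <- sum(y_sds^2)
  core <- fit_core(sx$X, Yc, y_tr, lambda)
  structure(list(lambda = lambda, u = core$u, v = core$v, d = core$d,
                 scores = core$scores, b = core$b, r2 = core$r2,
                 x_center = sx$center, x_scale = sx$scale,
                 y_center = y_ctr, y_scale = y_sds,
                 x_labels = colnames(X),
                 genes = attr(X, "genes")),
            class = "mgp_pls")
}

#' @export
print.mgp_pls <- function(x, ...) {
  cat(sprintf("<mgp_pls> lambda = %.4g, d = %.4g, R^2 = %.4g (%d x-cols, %d y-cols)\n",
              x$lambda, x$d, x$r2, length(x$u), length(x$v)))
  nz <- sum(x$u != 0)
  cat(sprintf("  non-zero genetic loadings: %d of %d\n", nz, length(x$u)))
  invisible(x)
}

#' Per-gene loading norms
#'
#' Importance of each gene: the Euclidean norm of its 8 founder
#' loadings in `u`.
#'
#' @param fit an `mgp_pls` fit whose genotype block had `gene.founder`
#'   column structure.
#' @return Named numeric vector, one entry per gene, in block order.
#' @export
gene_loading_norms <- function(fit) {
  genes <- fit$genes
  if (is.null(genes)) {
    if (length(fit$u) %% 8L != 0L) stop_mgp("fit has no per-gene structure")
    genes <- unique(sub("\\.[A-H]$", "", fit$x_labels))
  }
  m <- length(genes)
  U <- matrix(fit$u, nrow = 8L, ncol = m)
  stats::setNames(sqrt(colSums(U^2)), genes)
}

#' Predict shapes from a fitted model
#'
#' Standardizes new genotype rows with the training record, forms
#' scores, and returns `t b' +` training shape column means.
#'
#' @param fit an `mgp_pls` fit.
#' @param X genotype block with the same columns as at training.
#' @return n x q matrix of predicted flattened shapes.
#' @export
predict_shapes <- function(fit, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(fit$x_center)) {
    stop_mgp("X has ", ncol(X), " columns; fit expects ", length(fit$x_center))
  }
  if (!is.null(fit$x_labels) && !is.null(colnames(X)) &&
      !identical(colnames(X), fit$x_labels)) {
    stop_mgp("X column labels do not match the fit's training block")
  }
  Xs <- sweep(sweep(X, 2L, fit$x_center, "-"), 2L, fit$x_scale, "/")
  scores <- as.vector(Xs %*% fit$u)
  outer(scores, fit$b) + matrix(fit$y_center, nrow(X), length(fit$y_center),
                                byrow = TRUE)
}

#' Trace-ratio variance explained
#'
#' `R^2 = trace(cov(Y_hat)) / trace(cov(Y))` over specimens, where
#' `Y_hat` are the model-predicted shapes for the training scores.
#'
#' @param fit an `mgp_pls` fit.
#' @param Y the shape matrix the fit was trained on.
#' @return Fraction in `[0, 1]`.
#' @export
variance_explained <- function(fit, Y) {
  Y <- as.matrix(Y)
  if (ncol(Y) != length(fit$b)) stop_mgp("Y dimensionality does not match fit")
  tr_y <- sum(col_vars(Y))
  if (tr_y <= 0) stop_mgp("degenerate: zero total shape variance")
  tc <- fit$scores - mean(fit$scores)
  tr_hat <- (sum(tc^2) / max(1L, nrow(Y) - 1L)) * sum(fit$b^2)
  tr_hat / tr_y
}

#' Cross-validate the regularization parameter
#'
#' k-fold cross-validation at the specimen level with a seeded shuffle.
#' For each fold and each candidate lambda, the model (including
#' standardization) is refit on the training portion and scored by mean
#' squared held-out prediction error on the original shape scale. The
#' chosen lambda minimizes the mean error; ties go to the larger
#' (sparser) lambda.
#'
#' @param X genotype block.
#' @param Y shape matrix.
#' @param lambda_grid candidate lambdas (default 0.01..0.20 step 0.01).
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @return An object of class `mgp_cv`: `lambda_grid`, `mean_error`,
#'   `fold_errors` (k x |grid|), `chosen_lambda`, `folds`.
#' @export
cross_validate <- function(X, Y, lambda_grid = seq(0.01, 0.20, by = 0.01),
                           k = 10L, seed = 1L) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (length(lambda_grid) == 0L) stop_mgp("empty lambda grid")
  if (k > n) stop_mgp("more folds than specimens")
  lambda_grid <- sort(lambda_grid)
  folds <- with_seed(seed, {
    idx <- sample.int(n)
    split(idx, rep_len(seq_len(k), n))
  })
  errs <- matrix(NA_real_, k, length(lambda_grid))
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    Xtr <- X[train, , drop = FALSE]; Ytr <- Y[train, , drop = FALSE]
    sx <- std_cols(Xtr)
    y_ctr <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2L, y_ctr, "-")
    y_tr <- sum(colSums(Yc^2) / max(1L, nrow(Yc) - 1L))
    Ys <- Yc_std(Yc)
    C <- crossprod(sx$X, Ys) / (length(train) - 1L)
    Xte <- sweep(sweep(X[test, , drop = FALSE], 2L, sx$center, "-"),
                 2L, sx$scale, "/")
    for (li in seq_along(lambda_grid)) {
      core <- fit_core(sx$X, Yc, y_tr, lambda_grid[li], C = C)
      pred <- outer(as.vector(Xte %*% core$u), core$b) +
        matrix(y_ctr, length(test), ncol(Y), byrow = TRUE)
      errs[f, li] <- mean((Y[test, , drop = FALSE] - pred)^2)
    }
  }
  mean_err <- colMeans(errs)
  best <- which(mean_err == min(mean_err))
  chosen <- lambda_grid[max(best)]
  structure(list(lambda_grid = lambda_grid, mean_error = mean_err,
                 fold_errors = errs, chosen_lambda = chosen, folds = folds),
            class = "mgp_cv")
}

#' @export
print.mgp_cv <- function(x, ...) {
  cat(sprintf("<mgp_cv> %d-fold CV over %d lambdas; chosen lambda = %.4g\n",
              nrow(x$fold_errors), length(x$lambda_grid), x$chosen_lambda))
  invisible(x)
}
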