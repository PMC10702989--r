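# Row-wise group soft-thresholding: shrink each row of V toward zero by thr
# in l2 norm; rows with norm <= thr vanish jointly across modalities.
row_group_prox <- function(V, thr) {
  nrm <- sqrt(rowSums(V^2))
  shrink <- pmax(0, 1 - thr / pmax(nrm, .Machine$double.eps))
  V * shrink
}

l21_norm <- function(W) sum(sqrt(rowSums(W^2)))

l21_objective <- function(W, y, Xs) {
  f <- 0
  for (m in seq_along(Xs)) {
    r <- y - Xs[[m]] %*% W[, m]
    f <- f + 0.5 * sum(r^2)
  }
  f
}

#' Smallest penalty giving the all-zero L2,1 solution
#'
#' From the optimality conditions of the L2,1 model, `W = 0` is optimal
#' exactly when `lambda >= max_j || (X^1' y, ..., X^M' y)_j ||_2` (with `y`
#' centered). Useful as the top of a penalty grid.
#'
#' @param y Response vector.
#' @param Xs List of N x d design matrices.
#' @return Nonnegative scalar.
#' @export
lambda_max_l21 <- function(y, Xs) {
  if (!is.list(Xs)) Xs <- list(Xs)
  yc <- y - mean(y)
  G <- vapply(Xs, function(X) drop(crossprod(X, yc)), numeric(ncol(Xs[[1L]])))
  G <- matrix(G, ncol = length(Xs))
  max(sqrt(rowSums(G^2)))
}

#' Multi-modality association with L2,1 joint feature selection
#'
#' Fits the group-sparse multi-task regression
#' `min_W 0.5 * sum_m ||y - X^m w^m||^2 + lambda * sum_j ||W_j.||_2`,
#' where column `w^m` of the d x M matrix `W` is the coefficient vector for
#' modality m and the row-wise L2,1 penalty selects ROI features jointly
#' across modalities. The response is centered before fitting (intercept
#' implicit); no sign constraint is imposed. Solved by FISTA with
#' backtracking line search from a zero (or warm-start) initialization;
#' iteration stops when the relative objective change drops below `tol`.
#'
#' @param y Length-N response (e.g. additively coded genotypes).
#' @param Xs List of M design matrices, each N x d (a single matrix is
#'   promoted to a one-element list).
#' @param lambda Nonnegative penalty.
#' @param tol Relative objective-change tolerance (default 1e-10).
#' @param max_iter Maximum FISTA iterations (default 5000).
#' @param w_init Optional d x M warm start.
#' @return Object of class `"assoc_fit"`: list with `weights` (d x M),
#'   `row_norms` (per-ROI l2 norm across modalities), `lambda`, `y_center`,
#'   `objective` (final value), `obj_trace`, `n_iter`.
#' @export
#' @examples
#' X <- matrix(rnorm(60), 20, 3)
#' y <- X %*% c(1, 0, -1) + rnorm(20, sd = 0.1)
#' fit <- fit_l21(y, list(X, X), lambda = 0.5)
#' fit$row_norms
fit_l21 <- function(y, Xs, lambda, tol = 1e-10, max_iter = 5000L,
                    w_init = NULL) {
  if (!is.list(Xs)) Xs <- list(Xs)
  M <- length(Xs)
  Xs <- lapply(Xs, as.matrix)
  N <- nrow(Xs[[1L]])
  d <- ncol(Xs[[1L]])
  if (any(vapply(Xs, function(X) nrow(X) != N || ncol(X) != d, logical(1L)))) {
    stop("all modality matrices must share dimensions N x d")
  }
  y <- as.numeric(y)
  if (length(y) != N) stop("response length must equal the number of subjects")
  if (N == 0L) stop("zero subjects")
  if (!all(is.finite(y)) || !all(vapply(Xs, function(X) all(is.finite(X)), logical(1L)))) {
    stop("non-finite values in inputs")
  }
  if (lambda < 0) stop("lambda must be nonnegative")

  ybar <- mean(y)
  yc <- y - ybar

  # spectral-norm estimate of the largest modality Gram -> initial step 1/L;
  # the backtracking line search in the compiled loop corrects any slack
  Ss <- lapply(Xs, crossprod)
  L <- max(vapply(Ss, function(S) {
    v <- rep(1 / sqrt(d), d)
    nv <- 1
    for (k in 1:25) {
      v <- S %*% v
      nv <- sqrt(sum(v^2))
      if (nv == 0) return(0)
      v <- v / nv
    }
    nv
  }, numeric(1L)))
  step <- if (L > 0) 1 / L else 1

  W0 <- if (is.null(w_init)) matrix(0, d, M) else as.matrix(w_init)
  res <- l21_fista_cpp(Xs, yc, lambda, step, tol, as.integer(max_iter), W0)
  W <- res$W
  trace <- res$obj_trace
  obj <- res$objective
  n_iter <- res$n_iter

  rn <- sqrt(rowSums(W^2))
  labs <- colnames(Xs[[1L]])
  if (!is.null(labs)) {
    rownames(W) <- labs
    names(rn) <- labs
  }
  structure(list(weights = W, row_norms = rn, lambda = lambda,
                 y_center = ybar, objective = obj, obj_trace = trace,
                 n_iter = n_iter), class = "assoc_fit")
}

#' LASSO baseline on a single (or concatenated) modality
#'
#' Standard l1-penalized least squares
#' `min_w 0.5 ||y - X w||^2 + lambda ||w||_1`, used by the single-modality
#' and concatenated-modality rungs of the comparison ladder. With one
#' modality the L2,1 penalty reduces exactly to the l1 norm, so this is the
#' M = 1 case of [fit_l21()].
#'
#' @inheritParams fit_l21
#' @param X Single N x d design matrix (concatenate modalities column-wise
#'   for the concatenated baseline).
#' @return `"assoc_fit"` object with a d x 1 weight matrix.
#' @export
fit_lasso <- function(y, X, lambda, tol = 1e-10, max_iter = 5000L) {
  fit_l21(y, list(as.matrix(X)), lambda, tol = tol, max_iter = max_iter)
}

#' Per-modality predictions from an association fit
#'
#' @param object `"assoc_fit"` object.
#' @param newdata List of test design matrices (one per modality; a single
#'   matrix is promoted).
#' @param ... Unused.
#' @return List of per-modality predicted response vectors `X^m w^m`.
#' @export
predict.assoc_fit <- function(object, newdata, ...) {
  if (!is.list(newdata)) newdata <- list(newdata)
  M <- ncol(object$weights)
  if (length(newdata) != M) stop("expected ", M, " modality matrices")
  lapply(seq_len(M), function(m) {
    X <- as.matrix(newdata[[m]])
    if (ncol(X) != nrow(object$weights)) stop("feature dimension mismatch")
    drop(X %*% object$weights[, m])
  })
}
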