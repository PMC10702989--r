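# Nonnegative sparse coding by cyclic coordinate descent on the Gram matrix.
# Solves min_{w >= 0} 0.5 * ||x - D w||^2 + lambda * sum(w), where G = D'D
# (donors x donors) and c0 = D'x. Coordinates are visited in fixed (donor
# index) order so degenerate instances resolve deterministically. The loop
# is compiled (src/solvers.cpp).
nn_lasso_cd <- function(G, c0, lambda, tol = 1e-8, max_sweeps = 10000L) {
  drop(nn_lasso_cd_cpp(as.matrix(G), as.numeric(c0), lambda, tol,
                       as.integer(max_sweeps)))
}

#' Largest useful sparsity penalty for diagnosis-restricted sparse coding
#'
#' The smallest penalty at which every subject's nonnegative sparse code
#' against its same-diagnosis donors is identically zero: the maximum over
#' subjects of the largest positive inner product with a same-class donor.
#' The package default for the self-expressive penalty is `0.1 * lambda_max`.
#'
#' @param X Subjects x features matrix.
#' @param labels Diagnosis label per subject.
#' @return Nonnegative scalar.
#' @export
lambda_max_sen <- function(X, labels) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  lmax <- 0
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < 2L) next
    G <- tcrossprod(X[idx, , drop = FALSE])
    diag(G) <- -Inf
    lmax <- max(lmax, max(G))
  }
  max(lmax, 0)
}

#' Sparse self-expressive code of one subject
#'
#' Expresses subject `i` as a nonnegative sparse combination of the other
#' subjects carrying the same diagnosis label, by solving
#' `min_{w >= 0} 0.5 ||x_i - X_C w||^2 + lambda ||w||_1` where `X_C` holds the
#' same-class donors (subject `i` excluded). The nonnegativity is a solver
#' constraint, not post-hoc truncation. Coefficients for subject `i` itself
#' and for subjects of other classes are exactly zero.
#'
#' @param i Subject index (row of `X`).
#' @param X Subjects x features matrix.
#' @param labels Diagnosis label per subject.
#' @param lambda Nonnegative sparsity penalty. The default (`NULL`) is
#'   subject-adaptive: `0.1 * lambda_max_i`, where `lambda_max_i` is the
#'   smallest penalty zeroing subject i's own code (its largest positive
#'   inner product with a same-class donor). Each subject's coding problem
#'   is a separate optimization, so scaling the penalty to the subject's own
#'   zero-threshold keeps donor counts balanced across subjects; a scalar
#'   `lambda` applies one penalty to everyone.
#' @return Numeric coefficient vector of length `nrow(X)`.
#' @export
sparse_code_one <- function(i, X, labels, lambda = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (!is.null(lambda) && lambda < 0) stop("lambda must be nonnegative")
  N <- nrow(X)
  w <- numeric(N)
  donors <- setdiff(which(labels == labels[i]), i)
  if (length(donors) == 0L) {
    warning("subject ", i, " has no same-class donors; returning zero code")
    return(w)
  }
  D <- X[donors, , drop = FALSE]
  G <- tcrossprod(D)
  c0 <- drop(D %*% X[i, ])
  if (is.null(lambda)) lambda <- 0.1 * max(c0, 0)
  w[donors] <- nn_lasso_cd(G, c0, lambda)
  w
}

#' Diagnosis-restricted sparse self-expressive network
#'
#' Stacks the per-subject nonnegative sparse codes (see [sparse_code_one()])
#' into a matrix `Wt` and symmetrizes it as `W = Wt + t(Wt)` with the diagonal
#' forced to zero. The result is a symmetric nonnegative subject-by-subject
#' reconstruction-weight network that is zero across diagnosis classes by
#' construction.
#'
#' @inheritParams sparse_code_one
#' @param modality Optional modality name stored with the network.
#' @return Object of class `"sen"`: list with elements `W` (N x N matrix),
#'   `lambda` (the scalar penalty, or the per-subject penalties used by the
#'   adaptive default), `modality`.
#' @export
#' @examples
#' X <- matrix(rnorm(40), 8, 5)
#' s <- build_sen(X, rep(c("HC", "MD"), each = 4))
#' max(abs(s$W - t(s$W)))
build_sen <- function(X, labels, lambda = NULL, modality = NULL) {
  X <- as.matrix(X)
  labels <- as.character(labels)
  N <- nrow(X)
  if (N < 2L) stop("need at least 2 subjects")
  if (length(labels) != N) stop("labels must align with rows of X")
  adaptive <- is.null(lambda)
  lam_used <- rep(if (adaptive) NA_real_ else lambda, N)

  Wt <- matrix(0, N, N)
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    nc <- length(idx)
    if (nc < 2L) {
      warning("class '", cl, "' has a single subject; its row stays zero")
      next
    }
    Xc <- X[idx, , drop = FALSE]
    G <- tcrossprod(Xc)
    for (a in seq_len(nc)) {
      lam <- if (adaptive) 0.1 * max(G[-a, a], 0) else lambda
      lam_used[idx[a]] <- lam
      w <- nn_lasso_cd(G[-a, -a, drop = FALSE], G[-a, a], lam)
      Wt[idx[a], idx[-a]] <- w
    }
  }
  W <- Wt + t(Wt)
  diag(W) <- 0
  if (!is.null(rownames(X))) dimnames(W) <- list(rownames(X), rownames(X))
  structure(list(W = W, lambda = if (adaptive) lam_used else lambda,
                 modality = modality), class = "sen")
}

#' Nonnegative sparse codes of new subjects against a training set
#'
#' Codes each row of `Xnew` as a nonnegative sparse combination of all rows
#' of `Xtrain`, without any class restriction (held-out subjects have unknown
#' diagnosis). Used to map test-fold subjects into the reconstructed training
#' feature space.
#'
#' @param Xnew,Xtrain Feature matrices with matching columns.
#' @param lambda Penalty; default per-subject `0.1 * max(Xtrain %*% x)`.
#' @return `nrow(Xnew)` x `nrow(Xtrain)` coefficient matrix.
#' @export
sparse_code_against <- function(Xnew, Xtrain, lambda = NULL) {
  Xnew <- as.matrix(Xnew)
  Xtrain <- as.matrix(Xtrain)
  if (ncol(Xnew) != ncol(Xtrain)) stop("feature dimensions differ")
  G <- tcrossprod(Xtrain)
  C0 <- Xtrain %*% t(Xnew)
  out <- matrix(0, nrow(Xnew), nrow(Xtrain))
  for (a in seq_len(nrow(Xnew))) {
    lam <- if (is.null(lambda)) 0.1 * max(C0[, a], 0) else lambda
    out[a, ] <- nn_lasso_cd(G, C0[, a], lam)
  }
  out
}

#' Self-expressive reconstruction of a feature matrix
#'
#' Applies the self-expressiveness property `X ~ W X`: row i of the result is
#' the weighted combination `sum_j W[i, j] * X[j, ]`.
#'
#' @param W N x N weight matrix (a `"sen"` or `"fusion_network"` object is
#'   also accepted).
#' @param X N x d feature matrix.
#' @return N x d reconstructed matrix.
#' @export
reconstruct <- function(W, X) {
  if (inherits(W, "sen") || inherits(W, "fusion_network")) W <- W$W
  W <- as.matrix(W)
  X <- as.matrix(X)
  if (ncol(W) != nrow(X) || nrow(W) != ncol(W)) {
    stop("shape mismatch: W must be N x N and X N x d")
  }
  W %*% X
}
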