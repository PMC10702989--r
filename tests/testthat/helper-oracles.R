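# Independent oracles used to cross-check the package's numerics. These are
# deliberately naive (loops, textbook formulas, generic solvers) and share no
# code with the implementation paths they validate.

# Textbook Pearson coefficient, pair by pair.
pearson_brute <- function(ts) {
  r <- ncol(ts)
  out <- matrix(1, r, r)
  for (i in seq_len(r)) for (j in seq_len(r)) {
    x <- ts[, i]; y <- ts[, j]
    num <- sum((x - mean(x)) * (y - mean(y)))
    den <- sqrt(sum((x - mean(x))^2)) * sqrt(sum((y - mean(y))^2))
    out[i, j] <- num / den
  }
  out
}

# Onnela weighted clustering coefficient by exhaustive triangle enumeration.
cc_brute <- function(fc, negatives = "abs") {
  w <- if (negatives == "abs") abs(fc) else pmax(fc, 0)
  diag(w) <- 0
  w <- w / max(w)
  r <- nrow(w)
  out <- numeric(r)
  for (i in seq_len(r)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(r)) for (h in seq_len(r)) {
      if (j != i && h != i && j != h) {
        acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    out[i] <- acc / (k * (k - 1))
  }
  out
}

# Nonnegative-lasso objective and its glmnet solution (generic constrained
# solver; glmnet scales the loss by 1/n, hence lambda/n).
nn_lasso_objective <- function(w, D, x, lambda) {
  0.5 * sum((x - drop(crossprod(D, w)))^2) + lambda * sum(w)
}

nn_lasso_glmnet <- function(D, x, lambda) {
  # D: donors x features; design for coding x is t(D)
  fit <- glmnet::glmnet(t(D), x, lambda = lambda / length(x),
                        lower.limits = 0, intercept = FALSE,
                        standardize = FALSE, thresh = 1e-14, maxit = 1e7)
  as.numeric(fit$beta)
}

# L2,1 objective on raw (uncentered-design, centered-response) data.
l21_objective_raw <- function(W, y, Xs, lambda) {
  yc <- y - mean(y)
  f <- 0
  for (m in seq_along(Xs)) f <- f + 0.5 * sum((yc - Xs[[m]] %*% W[, m])^2)
  f + lambda * sum(sqrt(rowSums(W^2)))
}

# Independent L2,1 solver: block coordinate descent over feature rows with
# the exact per-row minimizer found by scalar root finding. Each row update
# solves min_v sum_m (0.5 a_m v_m^2 - b_m v_m) + lambda ||v||_2.
l21_bcd_oracle <- function(y, Xs, lambda, sweeps = 2000, tol = 1e-12) {
  yc <- y - mean(y)
  M <- length(Xs)
  d <- ncol(Xs[[1]])
  W <- matrix(0, d, M)
  res <- lapply(seq_len(M), function(m) yc - Xs[[m]] %*% W[, m])
  a <- vapply(seq_len(M), function(m) colSums(Xs[[m]]^2), numeric(d))
  a <- matrix(a, nrow = d)
  obj_prev <- Inf
  for (s in seq_len(sweeps)) {
    for (j in seq_len(d)) {
      b <- vapply(seq_len(M), function(m) {
        sum(Xs[[m]][, j] * res[[m]]) + a[j, m] * W[j, m]
      }, numeric(1))
      old <- W[j, ]
      if (sqrt(sum(b^2)) <= lambda) {
        v <- rep(0, M)
      } else {
        g <- function(s0) {
          vv <- b / (a[j, ] + lambda / s0)
          sqrt(sum(vv^2)) - s0
        }
        hi <- sqrt(sum((b / pmax(a[j, ], 1e-12))^2)) + 1
        s0 <- stats::uniroot(g, c(1e-14, hi), tol = 1e-14)$root
        v <- b / (a[j, ] + lambda / s0)
      }
      if (any(v != old)) {
        for (m in seq_len(M)) {
          res[[m]] <- res[[m]] - Xs[[m]][, j] * (v[m] - old[m])
        }
        W[j, ] <- v
      }
    }
    obj <- l21_objective_raw(W, y, Xs, lambda)
    if (obj_prev - obj < tol * max(1, abs(obj))) break
    obj_prev <- obj
  }
  W
}

# Naive quadruple-loop evaluation of the fusion recursion (local affinity,
# class-restricted update, off-diagonal modality average).
fuse_quadloop <- function(Ws, labels, n_iter) {
  N <- nrow(Ws[[1]])
  M <- length(Ws)
  Cs <- lapply(seq_len(N), function(i) which(labels == labels[i]))
  A <- lapply(Ws, function(W) {
    Ai <- matrix(0, N, N)
    for (i in seq_len(N)) {
      s <- sum(W[i, Cs[[i]]])
      if (s > 0) for (j in Cs[[i]]) Ai[i, j] <- W[i, j] / s
    }
    Ai
  })
  for (t in seq_len(n_iter)) {
    Wn <- vector("list", M)
    for (m in seq_len(M)) {
      Wm <- matrix(0, N, N)
      for (i in seq_len(N)) for (j in seq_len(N)) {
        acc <- 0
        for (k in Cs[[i]]) for (l in Cs[[i]]) {
          P <- 0
          for (q in seq_len(M)) if (q != m) P <- P + Ws[[q]][k, l]
          acc <- acc + A[[m]][i, k] * A[[m]][j, l] * P / (M - 1)
        }
        Wm[i, j] <- acc
      }
      Wn[[m]] <- Wm
    }
    Ws <- Wn
  }
  Wf <- Reduce(`+`, Ws) / M
  diag(Wf) <- 0
  Wf
}

# Plain double-loop reconstruction, x_tilde_i = sum_j W[i, j] x_j.
reconstruct_loops <- function(W, X) {
  out <- matrix(0, nrow(W), ncol(X))
  for (i in seq_len(nrow(W))) for (j in seq_len(ncol(W))) {
    out[i, ] <- out[i, ] + W[i, j] * X[j, ]
  }
  out
}
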