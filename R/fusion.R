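#' Within-class local affinity of a self-expressive network
#'
#' Row-normalizes the network within diagnosis classes:
#' `A[i, j] = W[i, j] / sum_{k in C_i} W[i, k]` for `j` in subject i's class
#' `C_i`, and 0 otherwise (including the diagonal, which is 0 in any valid
#' self-expressive network). Rows whose within-class weights sum to zero are
#' left as all-zero rows with a warning; all other rows sum to exactly 1.
#' The local affinity is the fixed diffusion kernel of [fuse()].
#'
#' @param W N x N self-expressive weight matrix or `"sen"` object.
#' @param labels Diagnosis label per subject.
#' @return N x N local-affinity matrix.
#' @export
local_affinity <- function(W, labels) {
  if (inherits(W, "sen")) W <- W$W
  W <- as.matrix(W)
  labels <- as.character(labels)
  N <- nrow(W)
  if (length(labels) != N) stop("labels must align with W")
  same <- outer(labels, labels, "==")
  A <- W * same
  rs <- rowSums(A)
  zero <- rs <= 0
  if (any(zero)) {
    warning(sum(zero), " subject(s) with no within-class weight; affinity rows set to zero")
    rs[zero] <- 1
  }
  A <- A / rs
  A[zero, ] <- 0
  dimnames(A) <- dimnames(W)
  A
}

#' Fuse per-modality self-expressive networks by class-guided diffusion
#'
#' Iteratively diffuses M self-expressive networks through their fixed
#' within-class local affinities. At each step the update for modality m is
#' `W^m_{t+1}(i,j) = sum_{k,l in C_i} A^m(i,k) A^m(j,l) * P(k,l)` with
#' `P = mean of the other modalities' current networks`; after every step the
#' fused network `W^f` is the off-diagonal average over modalities with a
#' zero diagonal, and convergence is monitored through the relative Frobenius
#' change `||W^f_{t+1} - W^f_t|| / ||W^f_t||`. Iteration stops when the
#' relative change falls below `tol` or after `max_iter` steps.
#'
#' Because the affinities are class-restricted and the inputs are zero across
#' classes, every iterate (and the fused network) is symmetric, nonnegative
#' and supported on the same-class blocks only. With `mode = "within"` the
#' summation indices k, l both range over C_i (cross-class entries are zeroed
#' explicitly); `mode = "cross"` uses l in C_j as in classical similarity
#' network fusion -- the two modes coincide whenever the inputs are
#' class-restricted, since the cross-class blocks of P vanish.
#'
#' @param networks List of M >= 2 `"sen"` objects or N x N matrices sharing
#'   subjects and labels. A single network is returned unchanged with a
#'   warning.
#' @param labels Diagnosis label per subject.
#' @param max_iter Maximum diffusion steps (default 10, hard cap 25).
#' @param tol Relative-change threshold (default 1e-6).
#' @param mode `"within"` (default) or `"cross"`; see Details.
#' @return Object of class `"fusion_network"`: list with `W` (fused N x N
#'   matrix), `n_iter`, `rel_change` (per-iteration trace), `mode`.
#' @export
fuse <- function(networks, labels, max_iter = 10L, tol = 1e-6,
                 mode = c("within", "cross")) {
  mode <- match.arg(mode)
  if (inherits(networks, "sen")) networks <- list(networks)
  Ws <- lapply(networks, function(w) if (inherits(w, "sen")) w$W else as.matrix(w))
  M <- length(Ws)
  labels <- as.character(labels)
  N <- nrow(Ws[[1L]])
  if (any(vapply(Ws, function(w) nrow(w) != N || ncol(w) != N, logical(1L)))) {
    stop("all networks must be N x N over the same subjects")
  }
  if (length(labels) != N) stop("labels must align with the networks")
  if (max_iter < 1L) stop("max_iter must be >= 1")
  if (max_iter > 25L) max_iter <- 25L
  if (tol <= 0) stop("tol must be positive")

  fused <- function(ws) {
    Wf <- Reduce(`+`, ws) / length(ws)
    diag(Wf) <- 0
    Wf
  }

  if (M == 1L) {
    warning("single modality: nothing to fuse, returning the network unchanged")
    Wf <- Ws[[1L]]
    diag(Wf) <- 0
    return(structure(list(W = Wf, n_iter = 0L, rel_change = numeric(0),
                          mode = mode), class = "fusion_network"))
  }

  As <- lapply(Ws, local_affinity, labels = labels)
  same <- outer(labels, labels, "==")
  Wf_prev <- fused(Ws)
  rel <- numeric(0)
  for (t in seq_len(max_iter)) {
    total <- Reduce(`+`, Ws)
    Ws_new <- vector("list", M)
    for (m in seq_len(M)) {
      P <- (total - Ws[[m]]) / (M - 1)
      Wm <- As[[m]] %*% P %*% t(As[[m]])
      if (mode == "within") Wm <- Wm * same
      Ws_new[[m]] <- Wm
    }
    Ws <- Ws_new
    Wf <- fused(Ws)
    denom <- sqrt(sum(Wf_prev^2))
    change <- if (denom == 0) 0 else sqrt(sum((Wf - Wf_prev)^2)) / denom
    rel <- c(rel, change)
    Wf_prev <- Wf
    if (change < tol || denom == 0) break
  }
  dimnames(Wf_prev) <- dimnames(Ws[[1L]])
  structure(list(W = Wf_prev, n_iter = length(rel), rel_change = rel,
                 mode = mode), class = "fusion_network")
}
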