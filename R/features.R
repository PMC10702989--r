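#' Pearson functional-connectivity matrix from ROI time series
#'
#' Computes the r x r Pearson correlation matrix between the average BOLD
#' time series of r regions. Each series is standardized to zero mean and
#' unit variance before correlation (which Pearson correlation performs
#' implicitly); the diagonal is exactly 1.
#'
#' @param ts Numeric matrix, T timepoints x r ROIs (T >= 3, r >= 2).
#'   Column names, when present, are used as ROI labels.
#' @return Symmetric r x r correlation matrix with unit diagonal.
#' @export
#' @examples
#' ts <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("ROI", 1:4)))
#' fc <- compute_fc(ts)
#' range(diag(fc))
compute_fc <- function(ts) {
  ts <- as.matrix(ts)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (anyNA(ts)) stop("time series contain missing values")
  if (nrow(ts) < 3L) stop("need at least 3 timepoints")
  if (ncol(ts) < 2L) stop("need at least 2 ROIs")
  v <- apply(ts, 2L, stats::var)
  if (any(v <= 0)) {
    bad <- colnames(ts)[v <= 0]
    if (is.null(bad)) bad <- which(v <= 0)
    stop("zero-variance time series for ROI(s): ", paste(bad, collapse = ", "))
  }
  fc <- stats::cor(ts)
  fc <- (fc + t(fc)) / 2
  diag(fc) <- 1
  fc
}

#' Threshold-free weighted clustering coefficients of a connectivity matrix
#'
#' Per-ROI weighted clustering coefficient of the fully weighted (no edge
#' threshold) connectivity graph, using the Onnela geometric-mean-of-triangles
#' form: c_i = (1 / (k_i (k_i - 1))) * sum_{j != h} (w_ij w_ih w_jh)^(1/3),
#' with weights first mapped to [0, 1] by taking absolute values (or zeroing
#' negatives) and dividing by the maximum off-diagonal weight. k_i counts the
#' nonzero weights incident to node i; nodes with k_i < 2 get coefficient 0.
#'
#' @param fc Symmetric r x r connectivity matrix, r >= 3 (e.g. from
#'   [compute_fc()]).
#' @param negatives How negative weights enter: `"abs"` (default; absolute
#'   value) or `"zero"` (treated as absent edges).
#' @return Numeric vector of length r with values in \[0, 1\], named after
#'   the ROI labels when `fc` has dimnames.
#' @export
clustering_coefficients <- function(fc, negatives = c("abs", "zero")) {
  negatives <- match.arg(negatives)
  fc <- as.matrix(fc)
  r <- nrow(fc)
  if (r != ncol(fc)) stop("connectivity matrix must be square")
  if (r < 3L) stop("need at least 3 ROIs to form triangles")
  if (max(abs(fc - t(fc))) > 1e-8) stop("connectivity matrix must be symmetric")
  w <- if (negatives == "abs") abs(fc) else pmax(fc, 0)
  diag(w) <- 0
  mx <- max(w)
  cc <- numeric(r)
  if (mx > 0) {
    w <- w / mx
    k <- rowSums(w > 0)
    w3 <- w^(1 / 3)
    tri <- diag(w3 %*% w3 %*% w3)   # sum over ordered pairs j != h
    ok <- k >= 2
    cc[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  }
  names(cc) <- rownames(fc)
  cc
}

#' Column z-scoring with reusable centering/scaling
#'
#' Standardizes each feature to zero mean and unit variance. When `center`
#' and `scale` are supplied (e.g. moments learned on training subjects) they
#' are applied as-is, so held-out subjects can be mapped into the training
#' feature scale without leakage.
#'
#' @param x Numeric matrix, subjects x features.
#' @param center,scale Optional numeric vectors of length `ncol(x)`.
#' @return Matrix with attributes `"center"` and `"scale"`.
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2L, stats::sd)
    if (any(scale <= 0)) {
      bad <- colnames(x)[scale <= 0]
      if (is.null(bad)) bad <- which(scale <= 0)
      stop("constant feature column(s): ", paste(bad, collapse = ", "))
    }
  }
  out <- sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
  attr(out, "center") <- center
  attr(out, "scale") <- scale
  out
}

#' Assemble aligned multi-modality phenotype matrices
#'
#' Builds the list of subject x ROI modality matrices the downstream models
#' consume. The node modality is a per-subject regional gray-matter volume
#' table; the edge modality is either a precomputed per-subject clustering
#' coefficient table or is derived here from per-subject ROI time series
#' (Pearson connectivity followed by [clustering_coefficients()]). Subjects
#' are aligned by id across modalities and every feature column is z-scored
#' across subjects.
#'
#' @param node_table Numeric matrix/data frame, subjects x ROIs, rownames =
#'   subject ids.
#' @param edge_source Either a subjects x ROIs table like `node_table`, or a
#'   named list of per-subject time-series matrices (T x r, shared column
#'   labels) from which edge features are computed.
#' @param standardize Z-score each feature column (default TRUE).
#' @param negatives Passed to [clustering_coefficients()] when edge features
#'   are computed from time series.
#' @return Named list of numeric matrices (`node`, `edge`), aligned by
#'   subject, with a `"standardization"` attribute holding the per-modality
#'   centers and scales.
#' @export
assemble_modalities <- function(node_table, edge_source, standardize = TRUE,
                                negatives = "abs") {
  node <- as.matrix(node_table)
  if (is.null(rownames(node))) stop("node table must carry subject ids as rownames")

  if (is.list(edge_source) && !is.data.frame(edge_source)) {
    if (is.null(names(edge_source))) stop("time-series list must be named by subject id")
    edge <- t(vapply(edge_source, function(ts) {
      clustering_coefficients(compute_fc(as.matrix(ts)), negatives = negatives)
    }, numeric(ncol(as.matrix(edge_source[[1L]])))))
    first <- as.matrix(edge_source[[1L]])
    if (!is.null(colnames(first))) colnames(edge) <- colnames(first)
  } else {
    edge <- as.matrix(edge_source)
  }
  if (is.null(rownames(edge))) stop("edge source must carry subject ids")

  ids <- rownames(node)
  if (!setequal(ids, rownames(edge))) {
    stop("subject ids differ between node and edge modalities")
  }
  edge <- edge[ids, , drop = FALSE]
  if (!is.null(colnames(node)) && !is.null(colnames(edge)) &&
      ncol(node) == ncol(edge) && !identical(colnames(node), colnames(edge))) {
    stop("ROI labels differ between node and edge modalities")
  }

  out <- list(node = node, edge = edge)
  if (standardize) {
    std <- lapply(out, standardize_features)
    attr_std <- lapply(std, function(m) {
      list(center = attr(m, "center"), scale = attr(m, "scale"))
    })
    out <- lapply(std, function(m) {
      attr(m, "center") <- NULL; attr(m, "scale") <- NULL; m
    })
    attr(out, "standardization") <- attr_std
  }
  out
}
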