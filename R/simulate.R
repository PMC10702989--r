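#' Simulate a class-structured multi-modality imaging-genetics dataset
#'
#' Generates subjects whose phenotype features lie near class-specific
#' low-dimensional subspaces in every modality (so within-class
#' self-expression holds by construction), together with a genotype-like
#' response driven by a small set of ROIs shared across modalities.
#'
#' For each class and modality an orthonormal basis of `subspace_dim`
#' directions in d-space is drawn; a subject is a random combination of its
#' class basis (scaled so features have roughly unit variance) plus i.i.d.
#' Gaussian measurement noise of SD `noise_sd_features`. On top of the
#' subspace structure, the response-relevant ROIs carry a diagnosis-severity
#' gradient: class c shifts the mean of support ROI j by
#' `class_sep * grade_c * sign(w_jm)`, where the grades are centered class
#' ranks (e.g. -1, 0, 1 for HC/MD/SD). This mirrors the premise of
#' diagnosis-guided association analysis -- the same regions that
#' distinguish severity grades also carry the genotype signal; with
#' `class_sep = 0` diagnosis labels are uninformative about the response.
#'
#' The latent response is built from the noise-free features: a coefficient
#' matrix with `support_size` nonzero rows shared across modalities
#' (entries of magnitude `effect_size`, random sign) gives
#' `l_i = mean_m(clean_x_i^m . w^m) + noise`, the biologically sensible
#' direction -- genotype drives the underlying phenotype, while imaging
#' noise is measurement error on top. `response_mode = "additive_012"`
#' discretizes `l` at its empirical tertiles into balanced 0/1/2 codes;
#' `"continuous"` returns `l` itself.
#'
#' Defaults mirror the target study's design: three diagnosis classes of
#' 64/78/29 subjects (HC/MD/SD pooled over two sites), two modalities, and
#' 116 ROI features carrying the AAL labels.
#'
#' @param n_per_class Integer vector of class sizes.
#' @param d Features (ROIs) per modality.
#' @param M Number of modalities.
#' @param subspace_dim Dimension of each class subspace (< d).
#' @param support_size Number of response-relevant ROIs (<= d).
#' @param effect_size Magnitude of each nonzero coefficient.
#' @param class_sep Strength of the diagnosis-severity mean shift at the
#'   support ROIs (default 0.3; 0 disables it).
#' @param noise_sd_features,noise_sd_response Gaussian noise SDs (>= 0).
#' @param response_mode `"additive_012"` (default) or `"continuous"`.
#' @param seed Integer seed; identical configs and seeds give identical
#'   datasets.
#' @return Object of class `"synthetic_dataset"`: list with `modalities`
#'   (named list of N x d matrices), `labels`, `response`, `snp_id`, and
#'   `truth` (support indices, true d x M coefficients, class bases, clean
#'   features, latent response, the config).
#' @export
#' @examples
#' ds <- simulate_dataset(n_per_class = c(10, 10, 10), d = 20, seed = 1)
#' table(ds$labels, ds$response)
simulate_dataset <- function(n_per_class = c(64L, 78L, 29L), d = 116L, M = 2L,
                             subspace_dim = 4L, support_size = 6L,
                             effect_size = 1, class_sep = 0.3,
                             noise_sd_features = 0.5,
                             noise_sd_response = 0.5,
                             response_mode = c("additive_012", "continuous"),
                             seed = 1L) {
  response_mode <- match.arg(response_mode)
  n_per_class <- as.integer(n_per_class)
  c_classes <- length(n_per_class)
  if (subspace_dim >= d) stop("subspace_dim must be smaller than d")
  if (support_size > d) stop("support_size cannot exceed d")
  if (noise_sd_features < 0 || noise_sd_response < 0) stop("noise SDs must be >= 0")
  if (any(n_per_class < 2L)) stop("each class needs at least 2 subjects")

  set.seed(seed)
  N <- sum(n_per_class)
  class_names <- if (c_classes == 3L) c("HC", "MD", "SD")
                 else paste0("C", seq_len(c_classes))
  labels <- rep(class_names, n_per_class)
  subject_ids <- sprintf("S%03d", seq_len(N))
  feat_labels <- if (d == 116L) aal116_labels() else sprintf("ROI_%03d", seq_len(d))

  support <- sort(sample.int(d, support_size))
  Wtrue <- matrix(0, d, M)
  for (m in seq_len(M)) {
    Wtrue[support, m] <- sample(c(-1, 1), support_size, replace = TRUE) * effect_size
  }

  bases <- vector("list", M)
  clean <- vector("list", M)
  class_means <- vector("list", M)
  modalities <- vector("list", M)
  scale_f <- sqrt(d / subspace_dim)  # roughly unit feature variance
  grade <- seq_len(c_classes) - (c_classes + 1) / 2  # centered severity ranks
  for (m in seq_len(M)) {
    bases[[m]] <- vector("list", c_classes)
    mu <- matrix(0, c_classes, d)
    mu[, support] <- outer(grade, sign(Wtrue[support, m])) * class_sep
    class_means[[m]] <- mu
    Xc <- matrix(0, N, d)
    offset <- 0L
    for (cl in seq_len(c_classes)) {
      B <- qr.Q(qr(matrix(stats::rnorm(d * subspace_dim), d, subspace_dim)))
      bases[[m]][[cl]] <- B
      n_c <- n_per_class[cl]
      Z <- matrix(stats::rnorm(n_c * subspace_dim), n_c, subspace_dim)
      # severity gradient expressed at the response-relevant ROIs
      block <- scale_f * Z %*% t(B) + rep(mu[cl, ], each = n_c)
      Xc[offset + seq_len(n_c), ] <- block
      offset <- offset + n_c
    }
    clean[[m]] <- Xc
    noisy <- Xc + matrix(stats::rnorm(N * d, sd = noise_sd_features), N, d)
    dimnames(noisy) <- list(subject_ids, feat_labels)
    modalities[[m]] <- noisy
  }
  names(modalities) <- if (M == 2L) c("node", "edge") else paste0("modality", seq_len(M))

  signal <- Reduce(`+`, lapply(seq_len(M), function(m) clean[[m]] %*% Wtrue[, m])) / M
  latent <- drop(signal) + stats::rnorm(N, sd = noise_sd_response)
  response <- if (response_mode == "continuous") {
    latent
  } else {
    cuts <- stats::quantile(latent, c(1 / 3, 2 / 3))
    as.numeric(cut(latent, c(-Inf, cuts, Inf), labels = FALSE)) - 1
  }
  names(response) <- subject_ids

  structure(list(
    modalities = modalities,
    labels = stats::setNames(labels, subject_ids),
    response = response,
    snp_id = "sim_snp",
    truth = list(support = support, coefficients = Wtrue, bases = bases,
                 class_means = class_means,
                 clean = clean, latent = latent, null = FALSE,
                 config = list(n_per_class = n_per_class, d = d, M = M,
                               subspace_dim = subspace_dim,
                               support_size = support_size,
                               effect_size = effect_size,
                               class_sep = class_sep,
                               noise_sd_features = noise_sd_features,
                               noise_sd_response = noise_sd_response,
                               response_mode = response_mode, seed = seed))
  ), class = "synthetic_dataset")
}

#' Permute the response of a synthetic dataset (null calibration)
#'
#' Returns the dataset with its response randomly permuted across subjects,
#' breaking any genotype-phenotype association while preserving the marginal
#' code distribution. The truth record is marked null.
#'
#' @param ds A `"synthetic_dataset"`.
#' @param seed Integer seed for the permutation.
#' @return A `"synthetic_dataset"` with permuted response.
#' @export
permute_response <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  set.seed(seed)
  perm <- sample.int(length(ds$response))
  ds$response <- stats::setNames(ds$response[perm], names(ds$response))
  ds$truth$null <- TRUE
  ds$truth$permutation <- perm
  ds
}
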