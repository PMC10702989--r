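#' Correlation-coefficient evaluation metric
#'
#' Pearson correlation between predicted and actual response values, the
#' score used throughout the cross-validation reports. When either vector
#' has zero variance (e.g. an all-zero fit predicting a constant) the metric
#' is defined as 0, which penalizes degenerate fits instead of propagating
#' NaN.
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return Scalar in \[-1, 1\].
#' @export
cc_metric <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("lengths differ")
  if (length(y_true) < 2L) stop("need at least 2 observations")
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) return(0)
  stats::cor(y_true, y_pred)
}

#' Class-stratified cross-validation folds
#'
#' Randomly assigns subjects to `k` folds, stratified by diagnosis class so
#' every fold mirrors the class composition. Errors if any class would be
#' absent from some training fold.
#'
#' @param labels Diagnosis label per subject.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed; the assignment is a pure function of
#'   `labels`, `k` and `seed`.
#' @return Integer vector of fold ids in 1..k.
#' @export
make_folds <- function(labels, k, seed) {
  labels <- as.character(labels)
  if (k < 2L) stop("need at least 2 folds")
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  for (f in seq_len(k)) {
    train_classes <- unique(labels[fold != f])
    if (!setequal(train_classes, unique(labels))) {
      stop("stratification error: some class is absent from the training side of fold ", f)
    }
  }
  fold
}

#' Cross-validation configuration
#'
#' Collects the knobs of the repeated nested cross-validation protocol. The
#' default penalty grid spans 1e-5 to 3 in alternating 1x/3x steps; penalties
#' are searched from the largest down with warm starts.
#'
#' @param outer_folds,inner_folds Fold counts (defaults 5 and 5).
#' @param repeats Independent repetitions of the outer split (default 5).
#' @param lambda_grid Strictly increasing positive penalties.
#' @param seed Integer base seed; repeat r uses `seed + r`.
#' @param variant Length-2 character vector: integration in
#'   `c("SM", "CM", "MM")` and network in `c("none", "SN", "FSN")`.
#' @param test_reconstruction How held-out subjects enter the reconstructed
#'   feature space: `"sparse_code_on_train"` (default; nonnegative sparse
#'   coding against all training subjects, no label use),
#'   `"raw"` (no test reconstruction), or `"transductive"` (networks built
#'   over all subjects with all labels -- label-leaking, for
#'   diagnostics only).
#' @param sen_lambda Self-expressive penalty; `NULL` = 0.1 * per-fold
#'   lambda_max.
#' @param fuse_iter,fuse_tol Diffusion iterations and tolerance for [fuse()].
#' @param fit_tol,fit_max_iter Solver controls passed to [fit_l21()].
#' @return List of class `"cv_config"`.
#' @export
cv_config <- function(outer_folds = 5L, inner_folds = 5L, repeats = 5L,
                      lambda_grid = default_lambda_grid(),
                      seed = 1L,
                      variant = c("MM", "FSN"),
                      test_reconstruction = c("sparse_code_on_train", "raw",
                                              "transductive"),
                      sen_lambda = NULL, fuse_iter = 10L, fuse_tol = 1e-6,
                      fit_tol = 1e-9, fit_max_iter = 2000L) {
  test_reconstruction <- match.arg(test_reconstruction)
  if (any(diff(lambda_grid) <= 0) || any(lambda_grid <= 0)) {
    stop("lambda_grid must be strictly increasing and positive")
  }
  if (outer_folds < 2L || inner_folds < 2L) stop("folds must be >= 2")
  integration <- match.arg(variant[1L], c("SM", "CM", "MM"))
  network <- match.arg(variant[2L], c("none", "SN", "FSN"))
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats),
                 lambda_grid = lambda_grid, seed = as.integer(seed),
                 integration = integration, network = network,
                 test_reconstruction = test_reconstruction,
                 sen_lambda = sen_lambda, fuse_iter = fuse_iter,
                 fuse_tol = fuse_tol, fit_tol = fit_tol,
                 fit_max_iter = as.integer(fit_max_iter)),
            class = "cv_config")
}

#' Default penalty grid (1e-5 to 3, alternating 1x/3x steps)
#' @return Increasing numeric vector.
#' @export
default_lambda_grid <- function() {
  as.numeric(outer(c(1, 3), 10^(-5:0)))
}

# Reconstruct the training blocks of all modalities for one fold and return
# the N_train x d matrices the regression consumes, plus the matrices needed
# to map test subjects into the same space.
.reconstruct_fold <- function(Xtr, labels_tr, cfg) {
  M <- length(Xtr)
  if (cfg$network == "none") {
    return(list(Xtr_rec = Xtr))
  }
  sens <- lapply(seq_len(M), function(m) {
    build_sen(Xtr[[m]], labels_tr, lambda = cfg$sen_lambda)
  })
  if (cfg$network == "SN") {
    Wrec <- lapply(sens, `[[`, "W")
  } else {
    Wf <- suppressWarnings(
      fuse(sens, labels_tr, max_iter = cfg$fuse_iter, tol = cfg$fuse_tol)
    )$W
    Wrec <- rep(list(Wf), M)
  }
  Xtr_rec <- lapply(seq_len(M), function(m) Wrec[[m]] %*% Xtr[[m]])
  list(Xtr_rec = Xtr_rec, Wrec = Wrec)
}

# Inner-CV penalty selection + refit for one integration strategy on already
# reconstructed training features. Returns chosen lambda(s), the refit(s),
# and per-modality train predictions.
.select_and_fit <- function(Xl, y, labels, cfg, inner_seed) {
  grid <- rev(cfg$lambda_grid)  # large -> small, warm starts
  fold <- make_folds(labels, cfg$inner_folds, inner_seed)
  score <- matrix(0, length(grid), cfg$inner_folds)
  for (f in seq_len(cfg$inner_folds)) {
    tr <- fold != f
    w <- NULL
    for (g in seq_along(grid)) {
      fit <- fit_l21(y[tr], lapply(Xl, function(X) X[tr, , drop = FALSE]),
                     grid[g], tol = cfg$fit_tol,
                     max_iter = cfg$fit_max_iter, w_init = w)
      w <- fit$weights
      preds <- predict(fit, lapply(Xl, function(X) X[!tr, , drop = FALSE]))
      score[g, f] <- sum(vapply(preds, function(p) cc_metric(y[!tr], p),
                                numeric(1L)))
    }
  }
  mean_score <- rowMeans(score)
  # ties broken toward the smaller penalty = later index in the reversed grid
  best <- max(which(mean_score == max(mean_score)))
  lambda <- grid[best]
  fit <- fit_l21(y, Xl, lambda, tol = cfg$fit_tol, max_iter = cfg$fit_max_iter)
  fit
}

#' Run one rung of the comparison ladder under repeated nested CV
#'
#' Evaluates one variant (integration strategy x network reconstruction) by
#' repeated, class-stratified, nested cross-validation. Within each outer
#' training fold: features are z-scored (moments from the training fold
#' only), the self-expressive networks and their fusion are estimated on
#' training subjects only, training features are reconstructed through the
#' network, the penalty is chosen by inner CV maximizing the mean inner-fold
#' test correlation (summed over modalities; ties toward the smaller
#' penalty), the model is refit on the full training fold, and held-out
#' subjects are scored. Per-repeat scores are fold averages; the report
#' gives their mean and SD across repeats.
#'
#' Integration strategies: `"SM"` fits each modality separately with a
#' LASSO; `"CM"` concatenates modalities column-wise before a LASSO;
#' `"MM"` fits all modalities jointly with the L2,1 penalty. Networks:
#' `"none"` (raw features), `"SN"` (per-modality self-expressive network),
#' `"FSN"` (fused network shared across modalities).
#'
#' @param Xs List of subject x feature modality matrices (aligned rows).
#' @param labels Diagnosis label per subject.
#' @param y Response vector (e.g. 0/1/2 genotype codes).
#' @param config A [cv_config()] object.
#' @param snp_id Optional identifier recorded in the report.
#' @return Object of class `"cv_report"`: list with `summary` (data frame of
#'   per-modality train/test CC mean and SD), `lambda` (chosen penalty per
#'   repeat x fold), `weights` (list of d x M weight matrices, one per
#'   repeat x fold), `variant`, `snp_id`, `config`.
#' @export
run_variant <- function(Xs, labels, y, config = cv_config(), snp_id = NA_character_) {
  if (!is.list(Xs)) Xs <- list(Xs)
  Xs <- lapply(Xs, as.matrix)
  labels <- as.character(labels)
  y <- as.numeric(y)
  N <- nrow(Xs[[1L]])
  stopifnot(length(labels) == N, length(y) == N)
  M <- length(Xs)
  cfg <- config
  mod_names <- names(Xs)
  if (is.null(mod_names)) mod_names <- paste0("modality", seq_len(M))

  eff_names <- if (cfg$integration == "CM") "combined" else mod_names
  train_cc <- array(NA_real_, c(cfg$repeats, cfg$outer_folds, length(eff_names)))
  test_cc <- train_cc
  lambda_rows <- list()
  weight_list <- list()

  for (rep_i in seq_len(cfg$repeats)) {
    fold <- make_folds(labels, cfg$outer_folds, cfg$seed + rep_i)
    for (f in seq_len(cfg$outer_folds)) {
      tr <- fold != f
      labels_tr <- labels[tr]
      std <- lapply(Xs, function(X) standardize_features(X[tr, , drop = FALSE]))
      Xtr <- lapply(std, function(m) {
        attributes(m)[c("center", "scale")] <- NULL
        m
      })
      Xte <- lapply(seq_len(M), function(m) {
        standardize_features(Xs[[m]][!tr, , drop = FALSE],
                             center = attr(std[[m]], "center"),
                             scale = attr(std[[m]], "scale"))
      })

      if (cfg$test_reconstruction == "transductive" && cfg$network != "none") {
        # label-leaking literal reading: networks over all N subjects
        Xall <- lapply(seq_len(M), function(m) rbind(Xtr[[m]], Xte[[m]]))
        lab_all <- c(labels_tr, labels[!tr])
        recon <- .reconstruct_fold(Xall, lab_all, cfg)
        ntr <- sum(tr)
        Xtr_use <- lapply(recon$Xtr_rec, function(X) X[seq_len(ntr), , drop = FALSE])
        Xte_use <- lapply(recon$Xtr_rec, function(X) X[-seq_len(ntr), , drop = FALSE])
      } else {
        recon <- .reconstruct_fold(Xtr, labels_tr, cfg)
        Xtr_use <- recon$Xtr_rec
        if (cfg$test_reconstruction == "raw" || cfg$network == "none") {
          Xte_use <- Xte
        } else {
          # code each held-out subject against all training subjects (raw
          # standardized features, no labels), then map through the same
          # reconstruction the training features received
          Xte_use <- lapply(seq_len(M), function(m) {
            C <- sparse_code_against(Xte[[m]], Xtr[[m]])
            C %*% Xtr_use[[m]]
          })
        }
      }

      if (cfg$integration == "CM") {
        Xtr_use <- list(do.call(cbind, Xtr_use))
        Xte_use <- list(do.call(cbind, Xte_use))
      }

      inner_seed <- (cfg$seed + rep_i) * 1000L + f
      if (cfg$integration == "SM") {
        Wmat <- matrix(0, ncol(Xs[[1L]]), M)
        lams <- numeric(M)
        for (m in seq_len(M)) {
          fit <- .select_and_fit(Xtr_use[m], y[tr], labels_tr, cfg, inner_seed)
          Wmat[, m] <- fit$weights[, 1L]
          lams[m] <- fit$lambda
          train_cc[rep_i, f, m] <-
            cc_metric(y[tr], drop(Xtr_use[[m]] %*% fit$weights[, 1L]))
          test_cc[rep_i, f, m] <-
            cc_metric(y[!tr], drop(Xte_use[[m]] %*% fit$weights[, 1L]))
          lambda_rows[[length(lambda_rows) + 1L]] <-
            data.frame(repeat_ = rep_i, fold = f, modality = eff_names[m],
                       lambda = fit$lambda)
        }
        weight_list[[length(weight_list) + 1L]] <- Wmat
      } else {
        fit <- .select_and_fit(Xtr_use, y[tr], labels_tr, cfg, inner_seed)
        ptr <- predict(fit, Xtr_use)
        pte <- predict(fit, Xte_use)
        for (m in seq_along(Xtr_use)) {
          train_cc[rep_i, f, m] <- cc_metric(y[tr], ptr[[m]])
          test_cc[rep_i, f, m] <- cc_metric(y[!tr], pte[[m]])
          lambda_rows[[length(lambda_rows) + 1L]] <-
            data.frame(repeat_ = rep_i, fold = f, modality = eff_names[m],
                       lambda = fit$lambda)
        }
        weight_list[[length(weight_list) + 1L]] <- fit$weights
      }
    }
  }

  per_repeat_train <- apply(train_cc, c(1L, 3L), mean)
  per_repeat_test <- apply(test_cc, c(1L, 3L), mean)
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  summary_df <- data.frame(
    variant = paste(ifelse(cfg$network == "none", "", paste0(cfg$network, "-")),
                    cfg$integration, sep = ""),
    modality = eff_names,
    train_cc_mean = colMeans(matrix(per_repeat_train, ncol = length(eff_names))),
    train_cc_sd = apply(matrix(per_repeat_train, ncol = length(eff_names)), 2L, sd0),
    test_cc_mean = colMeans(matrix(per_repeat_test, ncol = length(eff_names))),
    test_cc_sd = apply(matrix(per_repeat_test, ncol = length(eff_names)), 2L, sd0),
    snp_id = snp_id,
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary_df,
                 lambda = do.call(rbind, lambda_rows),
                 weights = weight_list,
                 variant = c(cfg$integration, cfg$network),
                 snp_id = snp_id, config = cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Nested cross-validation report (", x$summary$variant[1L],
      if (!is.na(x$snp_id)) paste0(", SNP ", x$snp_id), ")\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Screen a genotype table SNP-by-SNP
#'
#' Runs [run_variant()] once per SNP column of an additively coded genotype
#' table and collects the per-modality reports, sorted by decreasing mean
#' test correlation. Monomorphic SNPs are skipped with a warning; subjects
#' with a missing call are dropped for that SNP only.
#'
#' @param Xs,labels As in [run_variant()].
#' @param genotype_table Numeric matrix/data frame, subjects x SNPs, coded
#'   0/1/2 (NAs allowed).
#' @param config A [cv_config()].
#' @return Data frame with one row per SNP x modality, sorted by
#'   `test_cc_mean` within modality.
#' @export
screen_snps <- function(Xs, labels, genotype_table, config = cv_config()) {
  G <- as.matrix(genotype_table)
  snps <- colnames(G)
  if (is.null(snps)) snps <- paste0("snp", seq_len(ncol(G)))
  rows <- list()
  skipped <- 0L
  for (s in seq_len(ncol(G))) {
    y <- G[, s]
    keep <- !is.na(y)
    if (length(unique(y[keep])) < 2L) {
      skipped <- skipped + 1L
      next
    }
    rep_s <- run_variant(lapply(Xs, function(X) X[keep, , drop = FALSE]),
                         labels[keep], y[keep], config, snp_id = snps[s])
    rows[[length(rows) + 1L]] <- rep_s$summary
  }
  if (skipped > 0L) warning(skipped, " monomorphic SNP(s) skipped")
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  out[order(out$modality, -out$test_cc_mean), , drop = FALSE]
}

#' Rank ROI features by their selection weight
#'
#' Averages the absolute association weights over all fitted folds and
#' repeats, max-normalizes them, and returns the top-k ROIs per modality,
#' the top-k by the cross-modality row-group norm, and the consistent set
#' (ROIs in the per-modality top-k of every modality).
#'
#' @param x A `"cv_report"`, a list of d x M weight matrices, or a single
#'   matrix.
#' @param k How many ROIs to report.
#' @param feature_labels Optional length-d ROI names.
#' @return List with `per_modality` (list of data frames), `overall`
#'   (data frame ranked by normalized group norm), and `consistent`
#'   (character/integer vector of ROIs shared by all per-modality top-k
#'   sets).
#' @export
rank_rois <- function(x, k = 5L, feature_labels = NULL) {
  mats <- if (inherits(x, "cv_report")) x$weights
          else if (is.list(x)) x
          else list(x)
  mats <- lapply(mats, as.matrix)
  d <- nrow(mats[[1L]])
  M <- ncol(mats[[1L]])
  if (k > d) stop("k exceeds the number of features")
  if (is.null(feature_labels)) {
    feature_labels <- rownames(mats[[1L]])
    if (is.null(feature_labels)) feature_labels <- paste0("feature", seq_len(d))
  }
  A <- Reduce(`+`, lapply(mats, abs)) / length(mats)
  gn <- sqrt(rowSums(A^2))
  if (max(gn) == 0) {
    warning("all association weights are zero; empty ranking")
    return(list(per_modality = list(), overall = data.frame(),
                consistent = character(0)))
  }
  per_mod <- lapply(seq_len(M), function(m) {
    w <- A[, m]
    wn <- if (max(w) > 0) w / max(w) else w
    ord <- order(wn, decreasing = TRUE)[seq_len(k)]
    data.frame(roi = feature_labels[ord], index = ord, weight = wn[ord],
               stringsAsFactors = FALSE)
  })
  names(per_mod) <- colnames(mats[[1L]])
  gn_norm <- gn / max(gn)
  ordg <- order(gn_norm, decreasing = TRUE)[seq_len(k)]
  overall <- data.frame(roi = feature_labels[ordg], index = ordg,
                        weight = gn_norm[ordg], stringsAsFactors = FALSE)
  consistent <- Reduce(intersect, lapply(per_mod, `[[`, "roi"))
  list(per_modality = per_mod, overall = overall, consistent = consistent)
}

#' Strongest functional-connectivity edges at a region, by diagnosis group
#'
#' Averages the per-subject connectivity matrices within each diagnosis
#' group and returns, for each group, the k edges incident to the given ROI
#' with the largest mean connection values.
#'
#' @param fc_list Named or unnamed list of per-subject r x r connectivity
#'   matrices.
#' @param groups Group label per subject (e.g. MDD/HC).
#' @param roi ROI name (matching the matrices' dimnames) or index.
#' @param k Number of edges per group (k <= r - 1).
#' @return Named list (one element per group) of data frames with columns
#'   `roi_a`, `roi_b`, `weight`, sorted by decreasing weight.
#' @export
top_edges <- function(fc_list, groups, roi, k = 7L) {
  groups <- as.character(groups)
  stopifnot(length(fc_list) == length(groups))
  r <- nrow(fc_list[[1L]])
  labs <- rownames(fc_list[[1L]])
  if (is.null(labs)) labs <- paste0("ROI", seq_len(r))
  if (is.character(roi)) {
    ri <- match(roi, labs)
    if (is.na(ri)) stop("unknown ROI: ", roi)
  } else {
    ri <- as.integer(roi)
    if (ri < 1L || ri > r) stop("unknown ROI index: ", roi)
  }
  if (k > r - 1L) stop("k must be at most r - 1")
  out <- list()
  for (g in unique(groups)) {
    mean_fc <- Reduce(`+`, fc_list[groups == g]) / sum(groups == g)
    w <- mean_fc[ri, ]
    w[ri] <- -Inf
    ord <- order(w, decreasing = TRUE)[seq_len(k)]
    out[[g]] <- data.frame(roi_a = labs[ri], roi_b = labs[ord],
                           weight = w[ord], stringsAsFactors = FALSE)
  }
  out
}
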