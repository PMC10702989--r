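test_that("the correlation metric handles exact, affine and degenerate cases", {
  y <- c(0, 1, 2, 1, 0, 2)
  expect_equal(cc_metric(y, y), 1)
  expect_equal(cc_metric(y, 2 * y + 3), 1)
  expect_equal(cc_metric(y, rep(1.5, 6)), 0)
  expect_equal(cc_metric(y, -y), -1)
  expect_error(cc_metric(1, 1), "at least 2")
  expect_error(cc_metric(1:3, 1:4), "lengths")
})

test_that("folds are disjoint, exhaustive, stratified, and guard class coverage", {
  lab <- rep(c("HC", "MD", "SD"), times = c(10, 12, 8))
  fold <- make_folds(lab, 5, seed = 42)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(length(fold), 30)
  for (f in 1:5) {
    tab <- table(lab[fold == f])
    expect_true(all(tab >= 1))  # stratification puts every class in every fold
  }
  expect_identical(make_folds(lab, 5, seed = 42), fold)  # seeded determinism
  expect_false(identical(make_folds(lab, 5, seed = 43), fold))

  # a singleton class must trigger the stratification guard
  expect_error(make_folds(c("a", "a", "a", "b"), 2, seed = 1), "stratification")
})

test_that("a noiseless response linear in shared ROIs is recovered almost perfectly", {
  set.seed(77)
  X <- matrix(rnorm(60 * 15), 60, 15)
  w <- numeric(15); w[c(2, 5, 9, 14)] <- c(1, -1.5, 2, 1)
  y <- drop(X %*% w)
  lab <- rep(c("HC", "MD", "SD"), each = 20)
  cfg <- cv_config(outer_folds = 5, inner_folds = 3, repeats = 1,
                   variant = c("MM", "none"), seed = 3)
  r <- run_variant(list(node = X, edge = X), lab, y, cfg)
  expect_true(all(r$summary$test_cc_mean > 0.99))
})

test_that("reports are bitwise-reproducible under a fixed seed", {
  ds <- simulate_dataset(n_per_class = c(8, 8, 8), d = 12, subspace_dim = 3,
                         support_size = 3, seed = 11)
  cfg <- cv_config(outer_folds = 3, inner_folds = 2, repeats = 2,
                   lambda_grid = c(0.01, 0.1, 1), variant = c("MM", "FSN"),
                   seed = 5)
  r1 <- suppressWarnings(run_variant(ds$modalities, ds$labels, ds$response, cfg))
  r2 <- suppressWarnings(run_variant(ds$modalities, ds$labels, ds$response, cfg))
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$weights, r2$weights)
  expect_identical(r1$lambda, r2$lambda)
})

test_that("held-out subjects never influence training-fold estimation", {
  # corrupt one subject's features; every fold in which that subject is held
  # out must produce bitwise-identical training-fold weights
  ds <- simulate_dataset(n_per_class = c(8, 8, 8), d = 12, subspace_dim = 3,
                         support_size = 3, seed = 21)
  for (mode in c("raw", "sparse_code_on_train")) {
    cfg <- cv_config(outer_folds = 3, inner_folds = 2, repeats = 1,
                     lambda_grid = c(0.01, 0.1, 1), variant = c("MM", "FSN"),
                     test_reconstruction = mode, seed = 9)
    fold <- make_folds(ds$labels, 3, cfg$seed + 1L)
    victim <- 5L
    f_vic <- fold[victim]
    r1 <- suppressWarnings(run_variant(ds$modalities, ds$labels, ds$response, cfg))
    ds2 <- ds
    for (m in seq_along(ds2$modalities)) {
      ds2$modalities[[m]][victim, ] <- 99 + seq_len(ncol(ds2$modalities[[m]]))
    }
    r2 <- suppressWarnings(run_variant(ds2$modalities, ds2$labels, ds2$response, cfg))
    expect_identical(r1$weights[[f_vic]], r2$weights[[f_vic]])
  }
})

test_that("SNP screening ranks a planted causal SNP first and skips monomorphs", {
  set.seed(33)
  ds <- simulate_dataset(n_per_class = c(15, 15, 15), d = 12, subspace_dim = 3,
                         support_size = 3, noise_sd_features = 0.2,
                         noise_sd_response = 0.1, seed = 33)
  G <- cbind(causal = ds$response)
  for (k in 1:4) G <- cbind(G, sample(ds$response))
  colnames(G) <- c("causal", paste0("null", 1:4))
  G <- cbind(G, mono = rep(1, nrow(G)))
  cfg <- cv_config(outer_folds = 3, inner_folds = 2, repeats = 1,
                   lambda_grid = c(0.01, 0.1, 1), variant = c("MM", "none"),
                   seed = 2)
  expect_warning(tab <- screen_snps(ds$modalities, ds$labels, G, cfg),
                 "monomorphic")
  expect_false("mono" %in% tab$snp_id)
  agg <- aggregate(test_cc_mean ~ snp_id, tab, mean)
  expect_equal(agg$snp_id[which.max(agg$test_cc_mean)], "causal")

  # a duplicated causal column receives the identical score
  G2 <- cbind(causal = ds$response, twin = ds$response)
  tab2 <- screen_snps(ds$modalities, ds$labels, G2, cfg)
  cc_by <- split(tab2$test_cc_mean, tab2$snp_id)
  expect_equal(cc_by$causal, cc_by$twin)
})

test_that("ROI ranking normalizes, ranks, and intersects across modalities", {
  W <- matrix(0, 6, 2)
  W[3, ] <- c(2, -1)
  rk <- rank_rois(list(W), k = 1, feature_labels = paste0("R", 1:6))
  expect_equal(rk$overall$roi, "R3")
  expect_equal(rk$overall$weight, 1)
  expect_equal(rk$per_modality[[1]]$roi, "R3")
  expect_equal(rk$consistent, "R3")

  expect_warning(empty <- rank_rois(list(matrix(0, 4, 2)), k = 2), "zero")
  expect_equal(nrow(empty$overall), 0)
  expect_error(rank_rois(list(W), k = 10), "exceeds")

  # averaging across folds: a consistently selected row beats a one-off spike
  W1 <- matrix(0, 5, 1); W1[2, 1] <- 1
  W2 <- matrix(0, 5, 1); W2[2, 1] <- 1.2; W2[4, 1] <- 1.4
  rk2 <- rank_rois(list(W1, W2), k = 1)
  expect_equal(rk2$overall$index, 2L)
})

test_that("top_edges returns the strongest group-mean edges at a region", {
  set.seed(50)
  labs <- paste0("R", 1:6)
  mk <- function() {
    fc <- compute_fc(matrix(rnorm(40 * 6), 40, 6))
    dimnames(fc) <- list(labs, labs)
    fc
  }
  fcs <- replicate(10, mk(), simplify = FALSE)
  grp <- rep(c("MDD", "HC"), each = 5)

  res <- top_edges(fcs, grp, "R2", k = 3)
  mean_h <- Reduce(`+`, fcs[grp == "HC"]) / 5
  ord <- order(mean_h["R2", -2], decreasing = TRUE)
  expect_equal(res$HC$roi_b, labs[-2][ord][1:3])
  expect_equal(res$HC$weight, unname(sort(mean_h["R2", -2], decreasing = TRUE)[1:3]))

  # identical matrices: the group mean is the common matrix
  same <- replicate(4, fcs[[1]], simplify = FALSE)
  res2 <- top_edges(same, rep("g", 4), "R1", k = 1)
  expect_equal(res2$g$weight, unname(max(fcs[[1]]["R1", -1])))

  expect_error(top_edges(fcs, grp, "R99", k = 2), "unknown ROI")
  expect_error(top_edges(fcs, grp, "R2", k = 6), "at most")
})

test_that("the transductive mode differs from train-only reconstruction", {
  ds <- simulate_dataset(n_per_class = c(8, 8, 8), d = 10, subspace_dim = 3,
                         support_size = 3, seed = 13)
  base <- cv_config(outer_folds = 3, inner_folds = 2, repeats = 1,
                    lambda_grid = c(0.01, 0.1, 1), variant = c("MM", "FSN"),
                    seed = 4)
  trans <- cv_config(outer_folds = 3, inner_folds = 2, repeats = 1,
                     lambda_grid = c(0.01, 0.1, 1), variant = c("MM", "FSN"),
                     test_reconstruction = "transductive", seed = 4)
  r1 <- suppressWarnings(run_variant(ds$modalities, ds$labels, ds$response, base))
  r2 <- suppressWarnings(run_variant(ds$modalities, ds$labels, ds$response, trans))
  expect_false(identical(r1$summary$test_cc_mean, r2$summary$test_cc_mean))
})
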