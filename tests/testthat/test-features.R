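test_that("compute_fc matches the textbook Pearson formula and is a valid FC matrix", {
  set.seed(101)
  ts <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("A", "B", "C")))
  fc <- compute_fc(ts)
  expect_lt(max(abs(fc - pearson_brute(ts))), 1e-10)
  expect_identical(diag(fc), c(A = 1, B = 1, C = 1))
  expect_identical(fc, t(fc))
  expect_true(all(fc >= -1 & fc <= 1))

  ts2 <- cbind(x = rnorm(20), y = rnorm(20))
  ts2 <- cbind(ts2, same = ts2[, 1], neg = -ts2[, 1])
  fc2 <- compute_fc(ts2)
  expect_equal(fc2["x", "same"], 1)
  expect_equal(fc2["x", "neg"], -1)
})

test_that("compute_fc rejects degenerate input, naming the offending ROI", {
  ts <- cbind(good = rnorm(10), flat = rep(2, 10))
  expect_error(compute_fc(ts), "flat")
  expect_error(compute_fc(matrix(rnorm(4), 2, 2)), "timepoints")
  expect_error(compute_fc(matrix(rnorm(10), 10, 1)), "ROIs")
})

test_that("clustering coefficients match brute-force triangle enumeration", {
  set.seed(55)
  for (r in c(4, 5, 7)) {
    ts <- matrix(rnorm(30 * r), 30, r)
    fc <- compute_fc(ts)
    expect_lt(max(abs(clustering_coefficients(fc) - cc_brute(fc))), 1e-12)
    expect_lt(max(abs(clustering_coefficients(fc, "zero") -
                        cc_brute(fc, "zero"))), 1e-12)
  }
})

test_that("clustering coefficients handle the analytic corner cases", {
  # equal |weights| everywhere: every normalized triangle weight is 1
  fc <- matrix(0.4, 3, 3); diag(fc) <- 1
  expect_equal(unname(clustering_coefficients(fc)), rep(1, 3))

  # isolated node: no incident triangles
  fc4 <- matrix(0.5, 4, 4); diag(fc4) <- 1
  fc4[4, 1:3] <- 0; fc4[1:3, 4] <- 0
  cc <- clustering_coefficients(fc4)
  expect_equal(unname(cc[4]), 0)
  expect_equal(unname(cc[1:3]), rep(1, 3))

  expect_error(clustering_coefficients(diag(2)), "3 ROIs")
})

test_that("clustering coefficients are scale- and sign-invariant, bounded in [0,1]", {
  set.seed(7)
  fc <- compute_fc(matrix(rnorm(40 * 6), 40, 6))
  base <- clustering_coefficients(fc)
  expect_true(all(base >= 0 & base <= 1))
  expect_equal(clustering_coefficients(fc * 0.37), base)  # max-normalization
  flip <- fc
  flip[2, 5] <- -flip[2, 5]; flip[5, 2] <- -flip[5, 2]
  expect_equal(clustering_coefficients(flip), base)       # absolute values
})

test_that("assemble_modalities aligns, standardizes, and validates", {
  set.seed(12)
  ids <- sprintf("S%02d", 1:6)
  node <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(ids, paste0("R", 1:4)))
  edge <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(rev(ids), paste0("R", 1:4)))
  out <- assemble_modalities(node, edge)
  expect_named(out, c("node", "edge"))
  for (m in out) {
    expect_lt(max(abs(colMeans(m))), 1e-12)
    expect_lt(max(abs(apply(m, 2, var) - 1)), 1e-12)
  }
  # edge rows were re-aligned by subject id, not by row order
  expect_identical(rownames(out$edge), ids)
  expect_equal(unname(out$edge["S03", ]),
               unname(standardize_features(edge)[ "S03", ]))

  # identical raw rows standardize identically
  node2 <- node; node2["S02", ] <- node2["S01", ]
  out2 <- assemble_modalities(node2, edge)
  expect_identical(out2$node["S01", ], out2$node["S02", ])

  # degenerate feature column is an error naming the feature
  node3 <- node; node3[, "R2"] <- 5
  expect_error(assemble_modalities(node3, edge), "R2")

  # subject mismatch
  edge_bad <- edge; rownames(edge_bad)[1] <- "S99"
  expect_error(assemble_modalities(node, edge_bad), "subject ids")
})

test_that("assemble_modalities computes edge features from time series", {
  set.seed(3)
  ids <- c("a", "b", "c")
  ts_list <- lapply(ids, function(i) {
    matrix(rnorm(25 * 4), 25, 4, dimnames = list(NULL, paste0("R", 1:4)))
  })
  names(ts_list) <- ids
  node <- matrix(rnorm(12), 3, 4, dimnames = list(ids, paste0("R", 1:4)))
  out <- assemble_modalities(node, ts_list, standardize = FALSE)
  manual <- clustering_coefficients(compute_fc(ts_list[["b"]]))
  expect_equal(unname(out$edge["b", ]), unname(manual))
})

test_that("assemble_modalities is permutation-equivariant in subjects", {
  set.seed(21)
  ids <- sprintf("S%d", 1:8)
  node <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(ids, paste0("R", 1:3)))
  edge <- matrix(rnorm(8 * 3), 8, 3, dimnames = list(ids, paste0("R", 1:3)))
  out <- assemble_modalities(node, edge)
  perm <- sample(ids)
  out_p <- assemble_modalities(node[perm, ], edge[perm, ])
  expect_equal(out_p$node, out$node[perm, ])
  expect_equal(out_p$edge, out$edge[perm, ])
})

test_that("training-fold standardization maps held-out subjects without leakage", {
  set.seed(9)
  X <- matrix(rnorm(30), 10, 3)
  tr <- standardize_features(X[1:7, ])
  te <- standardize_features(X[8:10, , drop = FALSE],
                             center = attr(tr, "center"),
                             scale = attr(tr, "scale"))
  expect_equal(unname(te[1, 2]),
               (X[8, 2] - mean(X[1:7, 2])) / sd(X[1:7, 2]))
})
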