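# small gaussian feature table helper: planted shift on selected columns
gauss_table <- function(n_pos, n_neg, n_feat, shift_cols = integer(0),
                        delta = 1, seed = 1) {
  set.seed(seed)
  ids <- c(sprintf("pos%03d", seq_len(n_pos)),
           sprintf("neg%03d", seq_len(n_neg)))
  vals <- matrix(rnorm((n_pos + n_neg) * n_feat), n_pos + n_neg,
                 dimnames = list(ids, sprintf("f%02d", seq_len(n_feat))))
  vals[seq_len(n_pos), shift_cols] <- vals[seq_len(n_pos), shift_cols] + delta
  structure(list(gene_ids = ids, values = vals,
                 mask = matrix(FALSE, nrow(vals), ncol(vals)),
                 categories = setNames(rep("genomic", n_feat),
                                       colnames(vals)),
                 manifest = data.frame(feature = colnames(vals),
                                       category = "genomic"),
                 imputation = "none"),
            class = "feature_table")
}

test_that("roc_auc matches examples, the complement identity and the U oracle", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1.0)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0.0)
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(6)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), bf_auc(scores, labels),
                 tolerance = 1e-12)
    expect_equal(roc_auc(scores, labels), 1 - roc_auc(scores, 1 - labels),
                 tolerance = 1e-12)
  }
})

test_that("cross-validation is deterministic and saturates on a perfect feature", {
  tab <- gauss_table(30, 30, 5, shift_cols = 1, delta = 50, seed = 2)
  pos <- tab$gene_ids[1:30]; neg <- tab$gene_ids[31:60]
  for (alg in c("RF", "NB", "SVM", "LR", "KNN")) {
    auc <- crossval_auc(tab, pos, neg, alg, k = 10, seed = 4,
                        config = classifier_config(rf_num_trees = 100))
    expect_equal(auc, 1.0, info = alg)
  }
  a1 <- crossval_auc(tab, pos, neg, "RF", k = 10, seed = 7,
                     config = classifier_config(rf_num_trees = 100))
  a2 <- crossval_auc(tab, pos, neg, "RF", k = 10, seed = 7,
                     config = classifier_config(rf_num_trees = 100))
  expect_identical(a1, a2)
  expect_error(crossval_auc(tab, pos[1:5], neg, "RF", k = 10), "k")
})

test_that("permuted labels give chance-level AUC", {
  aucs <- vapply(1:10, function(s) {
    tab <- gauss_table(25, 25, 8, shift_cols = integer(0), seed = 100 + s)
    crossval_auc(tab, tab$gene_ids[1:25], tab$gene_ids[26:50], "RF",
                 k = 5, seed = s,
                 config = classifier_config(rf_num_trees = 150))
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("evaluate_algorithms aggregates per-set AUCs", {
  tab <- gauss_table(25, 60, 6, shift_cols = 1:2, delta = 1.2, seed = 3)
  pos <- tab$gene_ids[1:25]
  negs <- list(tab$gene_ids[26:50], tab$gene_ids[51:75])
  rep2 <- evaluate_algorithms(tab, pos, negs, algorithms = "RF", k = 5,
                              seed = 5,
                              config = classifier_config(rf_num_trees = 150))
  expect_equal(rep2$RF$mean_auc, mean(rep2$RF$per_set_auc))
  rep1 <- evaluate_algorithms(tab, pos, negs[1], algorithms = "RF", k = 5,
                              seed = 5,
                              config = classifier_config(rf_num_trees = 150))
  expect_equal(rep1$RF$mean_auc, rep1$RF$per_set_auc[1])
  expect_equal(rep1$RF$per_set_auc[1], rep2$RF$per_set_auc[1])
})

test_that("seed changes move per-set AUC less than the across-set spread", {
  tab <- gauss_table(30, 120, 10, shift_cols = 1:3, delta = 0.8, seed = 9)
  pos <- tab$gene_ids[1:30]
  negs <- lapply(0:3, function(i) tab$gene_ids[31:60 + i * 30])
  r1 <- evaluate_algorithms(tab, pos, negs, algorithms = "RF", k = 5,
                            seed = 1,
                            config = classifier_config(rf_num_trees = 200))
  r2 <- evaluate_algorithms(tab, pos, negs, algorithms = "RF", k = 5,
                            seed = 2,
                            config = classifier_config(rf_num_trees = 200))
  spread <- sd(r1$RF$per_set_auc)
  expect_lt(abs(r1$RF$mean_auc - r2$RF$mean_auc), 3 * max(spread, 0.02))
})

test_that("importance normalizes, finds a planted feature, noise in the tail", {
  hits <- 0L
  for (s in 1:10) {
    tab <- gauss_table(40, 40, 12, shift_cols = 4, delta = 2,
                       seed = 200 + s)
    imp <- feature_importance(tab, tab$gene_ids[1:40],
                              list(tab$gene_ids[41:80]),
                              num_trees = 200, seed = s)
    expect_equal(sum(imp$importance), 1, tolerance = 1e-12)
    expect_true(all(diff(imp$importance) <= 1e-12))
    if (imp$feature[1] == "f04") hits <- hits + 1L
    # pure-noise features: small, near-uniform importances
    noise <- imp$importance[imp$feature != "f04"]
    expect_lt(max(noise), 0.5 * imp$importance[imp$feature == "f04"])
  }
  expect_gte(hits, 9L)
})

test_that("importance_top_categories tallies by rank cut", {
  tab <- gauss_table(20, 20, 6, shift_cols = 1, delta = 3, seed = 5)
  tab$categories[] <- rep(c("genomic", "network"), 3)
  imp <- feature_importance(tab, tab$gene_ids[1:20],
                            list(tab$gene_ids[21:40]), num_trees = 100,
                            seed = 1)
  tc <- importance_top_categories(imp, top = c(2, 6))
  expect_equal(unname(rowSums(tc)), c(2, 6))
})

test_that("candidate prediction behaves at the edges", {
  tab <- gauss_table(30, 90, 6, shift_cols = 1:2, delta = 2.5, seed = 6)
  pos <- tab$gene_ids[1:30]
  negs <- list(tab$gene_ids[31:60], tab$gene_ids[61:90])
  unk <- tab$gene_ids[91:120]
  pred <- predict_candidates(tab, pos, negs, unk, threshold = 0.5,
                             seed = 3,
                             config = classifier_config(rf_num_trees = 150))
  expect_equal(pred$gene_id, unk)
  expect_true(all(pred$mean_probability >= 0 & pred$mean_probability <= 1))
  expect_equal(pred$is_candidate, pred$mean_probability > 0.5)
  expect_equal(unique(pred$n_models), 2L)
  # an unknown identical to a training positive scores clearly positive
  tab2 <- tab
  tab2$values[unk[1], ] <- tab2$values[pos[1], ]
  pred2 <- predict_candidates(tab2, pos, negs, unk[1], seed = 3,
                              config = classifier_config(rf_num_trees = 150))
  expect_gt(pred2$mean_probability, 0.5)
  # threshold 1.0 -> nothing called
  pred3 <- predict_candidates(tab, pos, negs, unk, threshold = 1.0,
                              seed = 3,
                              config = classifier_config(rf_num_trees = 150))
  expect_equal(sum(pred3$is_candidate), 0L)
  expect_equal(nrow(predict_candidates(tab, pos, negs, character(0))), 0L)
  expect_error(predict_candidates(tab, pos, negs, pos[1]), "disjoint")
  # single_best mode uses one model
  predb <- predict_candidates(tab, pos, negs, unk, mode = "single_best",
                              seed = 3, k = 5,
                              config = classifier_config(rf_num_trees = 150))
  expect_equal(unique(predb$n_models), 1L)
})
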