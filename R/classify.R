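# Classification: five algorithms trained over balanced resampled
# negative sets, ten-fold cross-validated AUC, extremely-randomized-trees
# feature importance, and candidate prediction.

ALGORITHMS <- c("RF", "NB", "SVM", "LR", "KNN")

#' Default classifier configuration
#'
#' Explicit, serializable hyperparameters: RF/extra-trees tree count,
#' KNN neighbor count, SVM kernel. Values follow the common library
#' defaults and are overridable everywhere.
#'
#' @param rf_num_trees Trees per random forest.
#' @param rf_mtry_frac Fraction of features offered at each split
#'   (mtry = max(1, floor(p * rf_mtry_frac))); 1/3 keeps informative
#'   features visible in wide tables.
#' @param knn_k Neighbors for KNN.
#' @param svm_kernel Kernel for the SVM.
#' @param et_num_trees Trees for the extra-trees importance forest.
#' @return Named list.
#' @export
classifier_config <- function(rf_num_trees = 500L, rf_mtry_frac = 1 / 3,
                              knn_k = 5L, svm_kernel = "radial",
                              et_num_trees = 500L) {
  list(rf_num_trees = as.integer(rf_num_trees), rf_mtry_frac = rf_mtry_frac,
       knn_k = as.integer(knn_k), svm_kernel = svm_kernel,
       et_num_trees = as.integer(et_num_trees))
}

.rf_mtry <- function(config, p) {
  frac <- config$rf_mtry_frac %||% (1 / 3)
  max(1L, min(p, floor(p * frac)))
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC, equivalent to the rank (Mann-Whitney) statistic:
#' the probability that a random positive outscores a random negative,
#' with tied scores counting one half.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary labels (0/1 or logical), both classes present.
#' @return AUC in \code{[0, 1]}.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# feature matrix rows for a set of gene ids, in order
.feature_rows <- function(table, ids) {
  stopifnot(inherits(table, "feature_table"))
  missing <- setdiff(ids, table$gene_ids)
  if (length(missing))
    stop("genes absent from feature table: ",
         paste(head(missing, 5L), collapse = ", "))
  table$values[match(ids, table$gene_ids), , drop = FALSE]
}

# drop zero-variance columns (judged on training rows); returns kept names
.informative_cols <- function(X) {
  colnames(X)[apply(X, 2L, function(v) sd(v) > 0)]
}

.standardize <- function(Xtr, Xte) {
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2L, sd)
  sdv[sdv == 0] <- 1
  list(tr = sweep(sweep(Xtr, 2L, mu), 2L, sdv, "/"),
       te = sweep(sweep(Xte, 2L, mu), 2L, sdv, "/"))
}

# Fit one algorithm on (Xtr, ytr) and return positive-class scores on Xte.
# Tree/NB models consume raw features; SVM/LR/KNN are standardized with
# training-fold statistics.
.fit_score <- function(algorithm, Xtr, ytr, Xte, config, seed) {
  keep <- .informative_cols(Xtr)
  Xtr <- Xtr[, keep, drop = FALSE]
  Xte <- Xte[, keep, drop = FALSE]
  yf <- factor(ytr, levels = c(0L, 1L))
  switch(algorithm,
    RF = {
      fit <- ranger::ranger(x = Xtr, y = yf, probability = TRUE,
                            num.trees = config$rf_num_trees,
                            mtry = .rf_mtry(config, ncol(Xtr)),
                            seed = seed, num.threads = 1L)
      predict(fit, data = Xte, num.threads = 1L)$predictions[, "1"]
    },
    NB = {
      fit <- e1071::naiveBayes(Xtr, yf)
      predict(fit, Xte, type = "raw")[, "1"]
    },
    SVM = {
      s <- .standardize(Xtr, Xte)
      fit <- e1071::svm(s$tr, yf, kernel = config$svm_kernel, scale = FALSE)
      dv <- attr(predict(fit, s$te, decision.values = TRUE),
                 "decision.values")
      if (colnames(dv)[1L] == "0/1") -dv[, 1L] else dv[, 1L]
    },
    LR = {
      s <- .standardize(Xtr, Xte)
      df <- as.data.frame(s$tr)
      df$.y <- ytr
      fit <- suppressWarnings(glm(.y ~ ., data = df, family = binomial()))
      suppressWarnings(
        predict(fit, newdata = as.data.frame(s$te), type = "response"))
    },
    KNN = {
      s <- .standardize(Xtr, Xte)
      pred <- with_seed(seed,
        class::knn(s$tr, s$te, cl = yf, k = config$knn_k, prob = TRUE))
      pr <- attr(pred, "prob")
      ifelse(pred == "1", pr, 1 - pr)
    },
    stop("unknown algorithm: ", algorithm))
}

# stratified fold assignment: within each class, shuffled round-robin
.stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, for (cls in unique(y)) {
    idx <- which(y == cls)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  })
  folds
}

#' Cross-validated AUC for one balanced training set
#'
#' Stratified k-fold cross-validation of positives vs one negative set;
#' out-of-fold scores are pooled into a single ROC and one AUC is
#' returned.
#'
#' @param table A \code{feature_table} (imputed).
#' @param positives Positive gene IDs.
#' @param negative_set Negative gene IDs.
#' @param algorithm One of RF, NB, SVM, LR, KNN.
#' @param k Folds (default 10); each class must have >= k members.
#' @param seed RNG seed (fold assignment and any stochastic fits).
#' @param config [classifier_config()].
#' @param features Optional feature-name subset (e.g. one category).
#' @return Pooled out-of-fold AUC.
#' @export
crossval_auc <- function(table, positives, negative_set,
                         algorithm = "RF", k = 10L, seed = 1L,
                         config = classifier_config(), features = NULL) {
  algorithm <- match.arg(algorithm, ALGORITHMS)
  if (length(positives) < k || length(negative_set) < k)
    stop("each class needs at least k = ", k, " members")
  ids <- c(positives, negative_set)
  y <- rep(c(1L, 0L), c(length(positives), length(negative_set)))
  X <- .feature_rows(table, ids)
  if (!is.null(features)) X <- X[, features, drop = FALSE]
  if (any(is.na(X)))
    stop("feature table contains missing values; impute before training")
  folds <- .stratified_folds(y, k, seed)
  scores <- numeric(length(y))
  for (f in seq_len(k)) {
    te <- folds == f
    scores[te] <- .fit_score(algorithm, X[!te, , drop = FALSE], y[!te],
                             X[te, , drop = FALSE], config,
                             seed = derive_seed(seed, f))
  }
  roc_auc(scores, y)
}

#' Cross-validate the five algorithms over all negative sets
#'
#' @param table A \code{feature_table}.
#' @param positives Positive gene IDs.
#' @param negative_sets List of negative-set ID vectors.
#' @param algorithms Algorithms to run (default all five).
#' @param k Folds.
#' @param seed Root seed; per-set fold seeds are derived from it.
#' @param config [classifier_config()].
#' @param features Optional feature-name subset (per-category runs).
#' @return Named list of \code{cv_report}s: per-set AUCs, their mean and
#'   SD, the algorithm, k and seed.
#' @export
evaluate_algorithms <- function(table, positives, negative_sets,
                                algorithms = ALGORITHMS, k = 10L, seed = 1L,
                                config = classifier_config(),
                                features = NULL) {
  if (length(negative_sets) < 1L) stop("need at least one negative set")
  out <- lapply(algorithms, function(alg) {
    aucs <- vapply(seq_along(negative_sets), function(i)
      crossval_auc(table, positives, negative_sets[[i]], alg, k = k,
                   seed = derive_seed(seed, i), config = config,
                   features = features), numeric(1))
    structure(list(algorithm = alg, per_set_auc = aucs,
                   mean_auc = mean(aucs), sd_auc = sd(aucs),
                   fold_count = as.integer(k), seed = as.integer(seed)),
              class = "cv_report")
  })
  setNames(out, algorithms)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report %s: mean AUC %.3f (sd %.3f) over %d sets, %d-fold\n",
              x$algorithm, x$mean_auc,
              if (is.na(x$sd_auc)) 0 else x$sd_auc,
              length(x$per_set_auc), x$fold_count))
  invisible(x)
}

#' Per-category cross-validated AUC
#'
#' Runs one algorithm restricted to each feature category (and optionally
#' combinations), as used to compare single-category against all-feature
#' performance.
#'
#' @param table A \code{feature_table}.
#' @param positives,negative_sets As in [evaluate_algorithms()].
#' @param algorithm Algorithm (default RF).
#' @param categories Character vector/list; each element may be one
#'   category or a vector of categories to combine.
#' @param ... Passed to [evaluate_algorithms()].
#' @return Named list of \code{cv_report}s (one per category set), plus
#'   \code{all} for the full table.
#' @export
category_auc <- function(table, positives, negative_sets, algorithm = "RF",
                         categories = unique(unname(table$categories)),
                         ...) {
  runs <- c(list(all = NULL),
            setNames(lapply(categories, identity),
                     vapply(categories, paste, character(1), collapse = "+")))
  lapply(runs, function(cats) {
    feats <- if (is.null(cats)) NULL
             else names(table$categories)[table$categories %in% cats]
    evaluate_algorithms(table, positives, negative_sets,
                        algorithms = algorithm, ...,
                        features = feats)[[1L]]
  })
}

#' Extremely-randomized-trees feature importance
#'
#' Impurity importance from an extra-trees forest fit on positives vs each
#' negative set, averaged over sets and normalized to sum to one.
#'
#' @param table A \code{feature_table}.
#' @param positives,negative_sets As in [evaluate_algorithms()].
#' @param num_trees Trees per forest.
#' @param seed Root seed.
#' @return An \code{importance_report}: data.frame (feature, importance,
#'   category) in descending importance order.
#' @export
feature_importance <- function(table, positives, negative_sets,
                               num_trees = 500L, seed = 1L) {
  imp <- numeric(ncol(table$values))
  names(imp) <- colnames(table$values)
  for (i in seq_along(negative_sets)) {
    ids <- c(positives, negative_sets[[i]])
    y <- factor(rep(c(1L, 0L), c(length(positives),
                                 length(negative_sets[[i]]))))
    X <- .feature_rows(table, ids)
    fit <- ranger::ranger(x = X, y = y, num.trees = num_trees,
                          splitrule = "extratrees", importance = "impurity",
                          mtry = ncol(X), min.node.size = 5L,
                          replace = FALSE, sample.fraction = 1,
                          seed = derive_seed(seed, i), num.threads = 1L)
    imp <- imp + fit$variable.importance[names(imp)]
  }
  imp <- pmax(imp / length(negative_sets), 0)
  imp <- imp / sum(imp)
  df <- data.frame(feature = names(imp), importance = unname(imp),
                   category = unname(table$categories[names(imp)]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$importance), ]
  rownames(df) <- NULL
  class(df) <- c("importance_report", "data.frame")
  df
}

#' Category tallies among top-ranked features
#' @param report An \code{importance_report}.
#' @param top Cut points (default 10, 20, 50).
#' @return data.frame of category counts per cut point.
#' @export
importance_top_categories <- function(report, top = c(10L, 20L, 50L)) {
  cats <- sort(unique(report$category))
  out <- sapply(top, function(k)
    table(factor(report$category[seq_len(min(k, nrow(report)))],
                 levels = cats)))
  colnames(out) <- paste0("top", top)
  as.data.frame.matrix(t(out))
}

#' Predict novel candidates with the balanced ensemble
#'
#' In \code{ensemble} mode one random forest is fit per negative set
#' (positives vs that set) and the mean predicted positive-class
#' probability across all models is reported per unknown gene. In
#' \code{single_best} mode only the negative set with the highest
#' cross-validated AUC is used.
#'
#' @param table A \code{feature_table}.
#' @param positives,negative_sets As in [evaluate_algorithms()].
#' @param unknown_ids Genes to score; must be disjoint from the training
#'   labels.
#' @param threshold Candidate probability cutoff (default 0.5).
#' @param mode \code{"ensemble"} or \code{"single_best"}.
#' @param seed Root seed.
#' @param config [classifier_config()].
#' @param k Folds used to pick the best set in \code{single_best} mode.
#' @return data.frame (gene_id, mean_probability, n_models, is_candidate),
#'   class \code{prediction_result}.
#' @export
predict_candidates <- function(table, positives, negative_sets, unknown_ids,
                               threshold = 0.5,
                               mode = c("ensemble", "single_best"),
                               seed = 1L, config = classifier_config(),
                               k = 10L) {
  mode <- match.arg(mode)
  if (length(unknown_ids) == 0L)
    return(structure(data.frame(gene_id = character(0),
                                mean_probability = numeric(0),
                                n_models = integer(0),
                                is_candidate = logical(0)),
                     class = c("prediction_result", "data.frame")))
  if (length(intersect(unknown_ids,
                       c(positives, unlist(negative_sets)))))
    stop("unknown_ids must be disjoint from training labels")
  Xu <- .feature_rows(table, unknown_ids)
  sets <- negative_sets
  if (mode == "single_best") {
    aucs <- vapply(seq_along(negative_sets), function(i)
      crossval_auc(table, positives, negative_sets[[i]], "RF", k = k,
                   seed = derive_seed(seed, i), config = config),
      numeric(1))
    sets <- negative_sets[which.max(aucs)]
  }
  probs <- matrix(0, nrow = length(unknown_ids), ncol = length(sets))
  for (i in seq_along(sets)) {
    ids <- c(positives, sets[[i]])
    y <- factor(rep(c(1L, 0L), c(length(positives), length(sets[[i]]))),
                levels = c(0L, 1L))
    X <- .feature_rows(table, ids)
    fit <- ranger::ranger(x = X, y = y, probability = TRUE,
                          num.trees = config$rf_num_trees,
                          mtry = .rf_mtry(config, ncol(X)),
                          seed = derive_seed(seed, 1000L + i),
                          num.threads = 1L)
    probs[, i] <- predict(fit, data = Xu, num.threads = 1L)$predictions[, "1"]
  }
  res <- data.frame(gene_id = unknown_ids,
                    mean_probability = rowMeans(probs),
                    n_models = length(sets),
                    is_candidate = rowMeans(probs) > threshold,
                    stringsAsFactors = FALSE)
  class(res) <- c("prediction_result", "data.frame")
  res
}
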