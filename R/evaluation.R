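#' Sensitivity and specificity of a DEG list against control panels
#'
#' Sensitivity is the percentage of positive-control genes (expected DE)
#' recovered in the DEG list; specificity the percentage of negative-control
#' genes (expected non-DE) absent from it.
#'
#' @param degs Character vector of called DEG identifiers.
#' @param positives,negatives Character vectors of control gene identifiers
#'   (non-overlapping, both non-empty).
#' @return Named numeric vector `c(sensitivity =, specificity =)` in percent.
#' @export
sensitivity_specificity <- function(degs, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stopf("both control panels must be non-empty")
  if (length(intersect(positives, negatives)))
    stopf("positive and negative control panels overlap")
  c(sensitivity = 100 * sum(positives %in% degs) / length(positives),
    specificity = 100 * sum(!(negatives %in% degs)) / length(negatives))
}

#' Select informative genes for classification
#'
#' The discriminating feature set: the top `floor(fraction * n_samples)`
#' genes by adjusted p-value (ties by input gene order).
#'
#' @param de A `de_result`.
#' @param n_samples Number of samples in the data set.
#' @param fraction Fraction of the sample count to select (default 0.75).
#' @return Character vector of gene identifiers.
#' @export
select_informative_genes <- function(de, n_samples, fraction = 0.75) {
  stopifnot(inherits(de, "de_result"))
  if (fraction <= 0 || fraction > 1) stopf("fraction must lie in (0, 1]")
  n_sel <- floor(fraction * n_samples)
  if (n_sel < 1L) stopf("informative-gene count is zero")
  ord <- order(de$adj_p_value, seq_len(nrow(de)))
  if (n_sel > nrow(de)) {
    warnf("requested %d genes but only %d available; returning all", n_sel, nrow(de))
    n_sel <- nrow(de)
  }
  de$gene_id[ord[seq_len(n_sel)]]
}

#' Leave-one-out cross-validation errors over five classifiers
#'
#' Fits naive Bayes, a single-hidden-layer neural network, k-nearest
#' neighbours, a radial-kernel support vector machine and a random forest to
#' log2(normalized count + 1) features of the informative genes, holding out
#' each of the n samples in turn. A training fold missing one class counts
#' its run as an error. The per-classifier error is
#' 100 * misclassified / n; the summary is the mean and median over the five
#' classifiers with a t-interval (4 degrees of freedom) for the mean.
#'
#' @param features Numeric matrix, samples in rows, genes (features) in
#'   columns — typically `t(log2(normalized[informative, ] + 1))`.
#' @param labels Two-level factor of group labels, length = rows of
#'   `features`.
#' @param seed Integer seed controlling the stochastic classifiers (neural
#'   network initialization, random forest).
#' @param knn_k Neighbours for k-NN (default 5).
#' @param nnet_size Hidden units (default 8).
#' @param rf_ntree Random-forest trees (default 500).
#' @return List with `per_classifier` (named error percentages), `mean`,
#'   `median`, `ci` (95% t-interval for the mean), `n_runs`.
#' @export
loocv_errors <- function(features, labels, seed = 1L, knn_k = 5L,
                         nnet_size = 8L, rf_ntree = 500L) {
  features <- as.matrix(features)
  labels <- factor(labels)
  n <- nrow(features)
  if (n < 3L) stopf("LOOCV needs at least 3 samples")
  if (length(labels) != n) stopf("labels length does not match samples")
  if (nlevels(labels) != 2L) stopf("exactly two classes required")
  colnames(features) <- paste0("f", seq_len(ncol(features)))  # safe names

  classifiers <- c("naive_bayes", "neural_network", "knn", "svm", "random_forest")
  errors <- matrix(FALSE, n, length(classifiers),
                   dimnames = list(NULL, classifiers))
  for (i in seq_len(n)) {
    train_x <- features[-i, , drop = FALSE]
    test_x <- features[i, , drop = FALSE]
    train_y <- droplevels(labels[-i])
    truth <- as.character(labels[i])
    if (nlevels(train_y) < 2L) {       # degenerate fold: counted as an error
      errors[i, ] <- TRUE
      next
    }
    errors[i, ] <- vapply(classifiers, function(cls) {
      pred <- predict_one(cls, train_x, train_y, test_x,
                          seed = seed + i, knn_k = knn_k,
                          nnet_size = nnet_size, rf_ntree = rf_ntree)
      !identical(pred, truth)
    }, logical(1))
  }
  err_pct <- 100 * colMeans(errors)
  ci <- tryCatch(as.numeric(stats::t.test(err_pct)$conf.int),
                 error = function(e) c(NA_real_, NA_real_))  # all-equal errors
  list(per_classifier = err_pct,
       mean = mean(err_pct),
       median = stats::median(err_pct),
       ci = ci,
       n_runs = n)
}

predict_one <- function(cls, train_x, train_y, test_x, seed,
                        knn_k, nnet_size, rf_ntree) {
  switch(cls,
    naive_bayes = {
      fit <- e1071::naiveBayes(train_x, train_y)
      as.character(stats::predict(fit, test_x))
    },
    neural_network = {
      set.seed(seed)
      # scale inputs for stable optimization; decay regularizes the perceptron
      mu <- colMeans(train_x)
      sdv <- pmax(apply(train_x, 2, stats::sd), 1e-8)
      tx <- scale(train_x, mu, sdv)
      fit <- nnet::nnet(tx, stats::model.matrix(~ train_y - 1)[, 2],
                        size = nnet_size, decay = 0.01, maxit = 200,
                        trace = FALSE)
      p <- stats::predict(fit, scale(test_x, mu, sdv))
      levels(train_y)[1 + (p > 0.5)]
    },
    knn = {
      set.seed(seed)
      as.character(class::knn(train_x, test_x, train_y, k = min(knn_k, nrow(train_x))))
    },
    svm = {
      fit <- e1071::svm(train_x, train_y, kernel = "radial")
      as.character(stats::predict(fit, test_x))
    },
    random_forest = {
      set.seed(seed)
      fit <- randomForest::randomForest(train_x, train_y, ntree = rf_ntree)
      as.character(stats::predict(fit, test_x))
    })
}

#' Pairwise common-DEG percentages between methods
#'
#' For methods i and j with DEG lists of sizes \eqn{D_i}, \eqn{D_j} sharing
#' \eqn{D_{ij}} genes, \eqn{P_{ij} = 100 D_{ij}/D_i}; each pair is
#' symmetrized by averaging \eqn{P_{ij}} and \eqn{P_{ji}}. A method's
#' common-DEG score is the mean of its pair averages over all partners —
#' higher means the method's calls are corroborated by the others.
#'
#' @param deg_lists Named list of character vectors (DEG identifiers per
#'   method). Methods with empty lists are excluded with a warning.
#' @return List of class `common_deg_matrix`: `methods`, `D` (list sizes),
#'   `D_pair` (shared counts), `P` (percentages), `P_avg` (symmetrized), and
#'   `score` (per-method mean of pair averages).
#' @export
common_deg_matrix <- function(deg_lists) {
  stopifnot(is.list(deg_lists), !is.null(names(deg_lists)))
  empty <- vapply(deg_lists, length, integer(1)) == 0L
  if (any(empty)) {
    warnf("method(s) with empty DEG lists excluded: %s",
          paste(names(deg_lists)[empty], collapse = ", "))
    deg_lists <- deg_lists[!empty]
  }
  k <- length(deg_lists)
  if (k < 2L) stopf("need at least two methods with non-empty DEG lists")
  methods <- names(deg_lists)
  D <- vapply(deg_lists, length, integer(1))
  D_pair <- matrix(0L, k, k, dimnames = list(methods, methods))
  for (i in seq_len(k)) for (j in seq_len(k))
    D_pair[i, j] <- length(intersect(deg_lists[[i]], deg_lists[[j]]))
  P <- 100 * D_pair / D              # rows divided by D_i
  P_avg <- (P + t(P)) / 2
  score <- vapply(seq_len(k), function(i) mean(P_avg[i, -i]), numeric(1))
  names(score) <- methods
  structure(list(methods = methods, D = D, D_pair = D_pair,
                 P = P, P_avg = P_avg, score = score),
            class = "common_deg_matrix")
}

#' @export
print.common_deg_matrix <- function(x, ...) {
  cat("common-DEG percentages (pair-averaged):\n")
  print(round(x$P_avg, 1))
  cat("per-method score (mean over partners):\n")
  print(round(x$score, 1))
  invisible(x)
}

#' Genes called DE by every method
#'
#' @param deg_lists Named list of >= 2 DEG identifier vectors.
#' @return Character vector of genes present in every list (order of the
#'   first list).
#' @export
intersect_all <- function(deg_lists) {
  stopifnot(is.list(deg_lists), length(deg_lists) >= 2L)
  Reduce(intersect, deg_lists)
}

#' Hierarchical clustering of methods by common-DEG ranks
#'
#' Restricts each method's differential-expression result to the genes called
#' DE by every method, ranks those genes per method by adjusted p-value
#' (ties by gene order), and clusters the methods on the Euclidean distances
#' between rank vectors with Ward's method (the squared-distance-updating
#' variant, `hclust(method = "ward.D2")`).
#'
#' @param de_results Named list of `de_result` objects, one per method.
#' @param alpha DEG-calling threshold (default 0.05).
#' @return List of class `method_dendrogram`: `hclust` (the tree),
#'   `common_genes`, `rank_matrix` (methods x genes), `dist`.
#' @export
method_rank_dendrogram <- function(de_results, alpha = 0.05) {
  stopifnot(is.list(de_results), length(de_results) >= 2L)
  deg_lists <- lapply(de_results, call_degs, alpha = alpha)
  common <- intersect_all(deg_lists)
  if (length(common) < 2L)
    stopf("fewer than 2 genes are DE under every method; loosen alpha")
  rank_matrix <- t(vapply(de_results, function(de) {
    idx <- match(common, de$gene_id)
    # rank among the common genes by adjusted p, ties broken by gene order
    as.numeric(order(order(de$adj_p_value[idx], idx)))
  }, numeric(length(common))))
  colnames(rank_matrix) <- common
  d <- stats::dist(rank_matrix, method = "euclidean")
  structure(list(hclust = stats::hclust(d, method = "ward.D2"),
                 common_genes = common,
                 rank_matrix = rank_matrix,
                 dist = d),
            class = "method_dendrogram")
}

#' Aggregate per-criterion values into ranks and a final recommendation
#'
#' Each criterion contributes one value per method; values are converted to
#' tie-averaged ranks (best = 1, respecting the criterion's direction) and
#' the final rank is the unweighted mean of the criterion ranks. The method
#' with the smallest final rank is recommended.
#'
#' @param criteria Named list; each element is a named numeric vector of one
#'   value per method. Criteria missing any method are dropped with a
#'   warning.
#' @param directions Named character vector mapping each criterion to
#'   `"lower_better"` or `"higher_better"`. Defaults cover the standard
#'   criteria (`bias`, `variance`, `prediction_error` lower-better;
#'   `sensitivity`, `specificity`, `common_degs` higher-better).
#' @return List of class `rank_summary`: `values` (criteria x methods),
#'   `ranks` (same shape), `final_rank` (named, ascending order),
#'   `recommended` (method label).
#' @export
summarize_ranks <- function(criteria, directions = NULL) {
  default_dir <- c(bias = "lower_better", variance = "lower_better",
                   prediction_error = "lower_better",
                   sensitivity = "higher_better",
                   specificity = "higher_better",
                   common_degs = "higher_better")
  directions <- c(directions, default_dir[setdiff(names(default_dir), names(directions))])
  stopifnot(is.list(criteria), length(criteria) >= 1L)
  methods <- Reduce(union, lapply(criteria, names))
  keep <- vapply(criteria, function(v) all(methods %in% names(v)), logical(1))
  if (!all(keep)) {
    warnf("criterion(s) missing methods dropped: %s",
          paste(names(criteria)[!keep], collapse = ", "))
    criteria <- criteria[keep]
  }
  if (length(criteria) == 0L) stopf("no complete criterion to rank")
  unknown <- setdiff(names(criteria), names(directions))
  if (length(unknown))
    stopf("no ranking direction known for: %s", paste(unknown, collapse = ", "))
  values <- do.call(rbind, lapply(criteria, function(v) v[methods]))
  colnames(values) <- methods
  ranks <- t(vapply(names(criteria), function(cr)
    rank_methods(values[cr, ], directions[[cr]]), numeric(length(methods))))
  final <- colMeans(ranks)
  ord <- order(final, seq_along(final))
  structure(list(values = values, ranks = ranks,
                 final_rank = final[ord],
                 recommended = methods[ord[1]]),
            class = "rank_summary")
}

#' @export
print.rank_summary <- function(x, ...) {
  cat("per-criterion ranks (best = 1):\n")
  print(round(x$ranks[, names(x$final_rank), drop = FALSE], 2))
  cat("final rank (mean of criterion ranks):\n")
  print(round(x$final_rank, 3))
  cat(sprintf("recommended method: %s\n", x$recommended))
  invisible(x)
}
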