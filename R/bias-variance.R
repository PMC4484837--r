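#' Bias of control genes under a normalization
#'
#' For a control (housekeeping) gene \eqn{i} the true log ratio to its own
#' mean is 0, so the bias (accuracy proxy) is the root mean square of the
#' observed log ratios:
#' \deqn{bias_i = \sqrt{\frac{1}{m}\sum_j \Big(\log_2 \frac{K_{ij}}{\bar K_{i\cdot}}\Big)^2}.}
#' Evaluated on normalized counts; a gene with a zero (or negative) normalized
#' count in any sample has an undefined log ratio and is dropped with a
#' warning.
#'
#' @param normalized_counts Matrix of normalized counts (genes x samples) with
#'   rownames.
#' @param hg Character vector of control gene identifiers.
#' @return Named numeric vector of per-gene biases (dropped genes absent).
#' @export
control_gene_bias <- function(normalized_counts, hg) {
  lr <- control_log_ratios(normalized_counts, hg)
  vapply(lr, function(x) sqrt(mean(x ^ 2)), numeric(1))
}

#' Variance of control genes under a normalization
#'
#' The precision proxy: the unbiased sample variance (divisor \eqn{m-1}) of a
#' control gene's per-sample log2 ratios to its own mean,
#' \deqn{variance_i = \frac{1}{m-1}\sum_j \Big(\log_2 \frac{K_{ij}}{\bar K_{i\cdot}}
#'   - \overline{\log_2 \frac{K_{ij}}{\bar K_{i\cdot}}}\Big)^2.}
#'
#' @inheritParams control_gene_bias
#' @return Named numeric vector of per-gene variances.
#' @export
control_gene_variance <- function(normalized_counts, hg) {
  lr <- control_log_ratios(normalized_counts, hg)
  vapply(lr, stats::var, numeric(1))
}

# shared: per-gene log2 ratios to the gene's own mean; drops genes with
# non-positive normalized counts (log undefined)
control_log_ratios <- function(normalized_counts, hg) {
  stopifnot(is.matrix(normalized_counts), !is.null(rownames(normalized_counts)))
  hg <- as.character(hg)
  missing <- setdiff(hg, rownames(normalized_counts))
  if (length(missing))
    stopf("control genes not in the matrix: %s", paste(missing, collapse = ", "))
  K <- normalized_counts[hg, , drop = FALSE]
  ok <- rowSums(K <= 0) == 0
  if (!all(ok))
    warnf("%d control gene(s) with non-positive normalized counts dropped", sum(!ok))
  if (!any(ok)) stopf("no control gene has all-positive normalized counts")
  K <- K[ok, , drop = FALSE]
  lr <- lapply(seq_len(nrow(K)), function(i) {
    x <- K[i, ]
    log2(x / mean(x))
  })
  names(lr) <- rownames(K)
  lr
}

#' Mean bias and variance of a normalization on the housekeeping set
#'
#' Applies a method's divisors, evaluates per-gene bias and variance on the
#' control genes, and averages them (unweighted) over the surviving genes.
#'
#' @param cm A `count_matrix`.
#' @param sf A `scaling_factors` object.
#' @param hg Character vector of control (housekeeping) gene identifiers.
#' @return A one-row data frame: `method`, `n_control_genes_used`,
#'   `mean_bias`, `mean_variance`.
#' @export
bias_variance <- function(cm, sf, hg) {
  norm <- normalize_counts(cm, sf)
  b <- control_gene_bias(norm, hg)
  v <- control_gene_variance(norm, hg)
  data.frame(method = sf$method,
             n_control_genes_used = length(b),
             mean_bias = mean(b),
             mean_variance = mean(v),
             stringsAsFactors = FALSE)
}

#' Tie-averaged competition ranks across methods
#'
#' Ranks one value per method so the best method gets rank 1; ties receive
#' the mean of the tied positions (e.g. two methods tied for best share rank
#' 1.5).
#'
#' @param values Named numeric vector, one finite value per method.
#' @param direction `"lower_better"` (bias, variance, prediction error) or
#'   `"higher_better"` (sensitivity, specificity, common-DEG percentage).
#' @return Named numeric vector of ranks.
#' @export
rank_methods <- function(values, direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  if (any(!is.finite(values))) stopf("all values must be finite to rank")
  x <- if (direction == "higher_better") -values else values
  rank(x, ties.method = "average")
}
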