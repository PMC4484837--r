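#' Per-gene stability scores for housekeeping-gene selection
#'
#' For each gene the mean squared deviation of its raw counts around the
#' gene's mean, \eqn{MSE_g = \sum_j (K_{gj} - \bar K_{g\cdot})^2 / m}
#' (divisor \eqn{m}), followed by min-max normalization of the scores to
#' [0, 1]. Scores are computed on raw, unnormalized counts: the housekeeping
#' set must not depend on the normalization under evaluation.
#'
#' The square root of \eqn{MSE_g} (an RMSE) is a strictly increasing
#' transform, so selecting the most stable genes by either quantity gives the
#' identical set; both are reported.
#'
#' @param cm A `count_matrix` with at least two samples.
#' @return A data frame of class `hk_scores` with columns `gene_id`, `mse`,
#'   `rmse`, `mse_normalized`.
#' @export
gene_stability_scores <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  K <- cm$counts
  m <- ncol(K)
  if (m < 2L) stopf("stability scores need at least two samples")
  mse <- rowSums((K - rowMeans(K)) ^ 2) / m
  rng <- range(mse)
  if (rng[1] == rng[2]) {
    warnf("all stability scores identical; min-max normalization undefined, returning zeros")
    mse_norm <- rep(0, length(mse))
  } else {
    mse_norm <- (mse - rng[1]) / (rng[2] - rng[1])
  }
  structure(data.frame(gene_id = rownames(K), mse = mse, rmse = sqrt(mse),
                       mse_normalized = mse_norm,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("hk_scores", "data.frame"))
}

#' Select the analytical housekeeping-gene set
#'
#' Returns the `floor(fraction * G)` genes with the lowest normalized
#' stability score — the analytically defined housekeeping set of genes whose
#' raw counts are most nearly constant across samples. Ties at the selection
#' boundary are broken by input gene order.
#'
#' @param scores Output of [gene_stability_scores()], or a `count_matrix`
#'   (scores are then computed internally).
#' @param fraction Fraction of genes to select, in (0, 1); default 0.01.
#' @return Character vector of gene identifiers with attribute
#'   `role = "housekeeping"`, in input gene order.
#' @export
select_housekeeping <- function(scores, fraction = 0.01) {
  if (inherits(scores, "count_matrix")) scores <- gene_stability_scores(scores)
  stopifnot(is.data.frame(scores))
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0, 1)")
  G <- nrow(scores)
  n_sel <- floor(fraction * G)
  if (n_sel < 1L)
    stopf("floor(%g * %d) = 0 genes selected; increase fraction", fraction, G)
  ord <- order(scores$mse_normalized, seq_len(G))   # stable: ties by input order
  sel <- sort(ord[seq_len(n_sel)])                  # back to input gene order
  structure(scores$gene_id[sel], role = "housekeeping")
}
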