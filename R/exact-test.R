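#' Moment-based common dispersion estimate
#'
#' Estimates a single negative-binomial dispersion \eqn{\phi} shared across
#' genes by matching within-group sample variance of divisor-normalized
#' counts to the NB variance function \eqn{\mu + \phi\mu^2}: for every gene
#' and group with at least two samples, \eqn{(s^2 - \bar x)/\bar x^2}
#' estimates \eqn{\phi}; estimates are averaged over genes and groups and
#' floored at 0.
#'
#' @param cm A `count_matrix` with groups assigned.
#' @param sf A `scaling_factors` object (use [raw_factors()] for none).
#' @param min_mean Genes whose normalized within-group mean falls below this
#'   value are skipped in a group (the moment ratio is too unstable there);
#'   default 1.
#' @return A single nonnegative dispersion estimate. With no within-group
#'   replication anywhere, returns 0 with a warning (Poisson fallback).
#' @export
estimate_common_dispersion <- function(cm, sf, min_mean = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.null(cm$group)) stopf("group labels are required")
  norm <- normalize_counts(cm, sf)
  groups <- levels(cm$group)
  ests <- c()
  for (g in groups) {
    cols <- cm$group == g
    if (sum(cols) < 2L) next
    X <- norm[, cols, drop = FALSE]
    mu <- rowMeans(X)
    v <- apply(X, 1, stats::var)
    ok <- mu >= min_mean
    ests <- c(ests, (v[ok] - mu[ok]) / mu[ok] ^ 2)
  }
  if (length(ests) == 0L) {
    warnf("no within-group replication; falling back to Poisson (dispersion 0)")
    return(0)
  }
  max(0, mean(ests))
}

#' Negative-binomial exact test for two-group differential expression
#'
#' Tests, per gene, whether expression differs between the two groups under
#' the model \eqn{K_{gj} \sim NB(d_j \lambda_{gj}, \phi)}: counts are divided
#' by the method's divisors to equalize effective library sizes
#' (pseudo-counts), summed within groups to \eqn{S_1} and \eqn{S_2}, and the
#' two-sided exact p-value is computed from the conditional distribution of
#' \eqn{S_1} given the total \eqn{S_1 + S_2} under the null of equal means.
#' The sum of \eqn{n} i.i.d. NB(\eqn{\mu}, \eqn{\phi}) variables is
#' NB(\eqn{n\mu}, \eqn{\phi/n}), so the conditional point masses are
#' proportional to \eqn{f_1(s) f_2(T - s)} over the splits
#' \eqn{s = 0, \dots, T}; at \eqn{\phi = 0} the conditional distribution is
#' Binomial(\eqn{T}, \eqn{n_1/(n_1+n_2)}). The p-value is the sum of the
#' probabilities of all outcomes at most as probable as the observed one.
#'
#' Totals larger than `total_cap` are rescaled (both group sums shrunk
#' proportionally and rounded) so the per-gene enumeration stays O(cap);
#' the default cap leaves typical filtered bulk RNA-seq genes untouched.
#'
#' @param cm A `count_matrix` with groups assigned (first factor level =
#'   group 1).
#' @param sf A `scaling_factors` object for the normalization under test.
#' @param phi Common NB dispersion (e.g. from
#'   [estimate_common_dispersion()]); `NULL` estimates it internally.
#' @param alpha Adjusted-p threshold used for the `is_deg` flag (default
#'   0.05).
#' @param pseudocount Added to normalized group means for the log2 fold
#'   change only (default 0.5).
#' @param total_cap Rescaling cap on the per-gene pseudo-count total
#'   (default 10000).
#' @param p_adjust_method Multiplicity adjustment, passed to
#'   [stats::p.adjust()] (default `"BH"`).
#' @return A data frame of class `de_result` with columns `gene_id`,
#'   `base_mean` (mean normalized count), `log2_fold_change` (group 2 vs
#'   group 1), `p_value`, `adj_p_value`, `is_deg`, plus attributes `method`,
#'   `phi`, `alpha`, `groups`.
#' @export
nb_exact_test <- function(cm, sf, phi = NULL, alpha = 0.05, pseudocount = 0.5,
                          total_cap = 10000, p_adjust_method = "BH") {
  stopifnot(inherits(cm, "count_matrix"), inherits(sf, "scaling_factors"))
  if (is.null(cm$group)) stopf("group labels are required")
  if (is.null(phi)) phi <- estimate_common_dispersion(cm, sf)
  if (phi < 0) stopf("dispersion must be nonnegative")
  norm <- normalize_counts(cm, sf)
  g1 <- cm$group == levels(cm$group)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  S1 <- rowSums(norm[, g1, drop = FALSE])
  S2 <- rowSums(norm[, !g1, drop = FALSE])
  mean1 <- S1 / n1
  mean2 <- S2 / n2
  G <- nrow(norm)
  p <- numeric(G)
  for (i in seq_len(G)) {
    p[i] <- exact_split_pvalue(S1[i], S2[i], n1, n2, phi, total_cap)
  }
  lfc <- log2((mean2 + pseudocount) / (mean1 + pseudocount))
  lfc[S1 + S2 == 0] <- 0
  adj <- adjust_p_values(p, method = p_adjust_method)
  res <- data.frame(gene_id = rownames(norm),
                    base_mean = rowMeans(norm),
                    log2_fold_change = lfc,
                    p_value = p,
                    adj_p_value = adj,
                    is_deg = adj < alpha,
                    zero_total = S1 + S2 == 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            method = sf$method, phi = phi, alpha = alpha,
            groups = levels(cm$group))
}

# two-sided exact p for the split (s1, s2) of a per-gene total between groups
# of sizes n1, n2 under a common-mean NB(phi) null; phi = 0 is the binomial
# limit. Outcomes with probability <= observed (up to a 1e-12 relative float
# guard) are summed.
exact_split_pvalue <- function(s1, s2, n1, n2, phi, total_cap) {
  tot <- s1 + s2
  if (tot <= 0) return(1)
  if (tot > total_cap) {   # rescale-and-round to keep enumeration bounded
    f <- total_cap / tot
    s1 <- round(s1 * f); s2 <- round(s2 * f)
  } else {
    s1 <- round(s1); s2 <- round(s2)
  }
  tot <- s1 + s2
  if (tot <= 0) return(1)
  x <- 0:tot
  if (phi == 0) {
    logm <- stats::dbinom(x, tot, n1 / (n1 + n2), log = TRUE)
  } else {
    mu <- tot / (n1 + n2)                # per-sample common mean given total
    logm <- stats::dnbinom(x, size = n1 / phi, mu = n1 * mu, log = TRUE) +
      stats::dnbinom(tot - x, size = n2 / phi, mu = n2 * mu, log = TRUE)
    logm <- logm - max(logm)
  }
  m <- exp(logm)
  m <- m / sum(m)
  obs <- m[s1 + 1]
  min(1, sum(m[m <= obs * (1 + 1e-12)]))
}

#' Benjamini-Hochberg (or other) p-value adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()].
#'
#' @param p Vector of p-values in [0, 1].
#' @param method Adjustment method (default `"BH"`).
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_p_values <- function(p, method = "BH") {
  if (anyNA(p) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = method)
}

#' Call differentially expressed genes at a threshold
#'
#' @param de A `de_result` from [nb_exact_test()].
#' @param alpha Adjusted-p threshold in (0, 1); default 0.05.
#' @return Character vector of DEG identifiers ordered by adjusted p-value
#'   (ascending, ties by input gene order).
#' @export
call_degs <- function(de, alpha = 0.05) {
  stopifnot(inherits(de, "de_result"))
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  hit <- which(de$adj_p_value < alpha)
  hit <- hit[order(de$adj_p_value[hit], hit)]
  de$gene_id[hit]
}

#' MA-plot coordinates from a differential-expression result
#'
#' @param de A `de_result`.
#' @return Data frame with `gene_id`, `A` (log10 base mean), `M` (log2 fold
#'   change) and `is_deg`, restricted to genes with positive base mean;
#'   attribute `n_omitted` counts genes dropped for zero base mean.
#' @export
ma_values <- function(de) {
  stopifnot(inherits(de, "de_result"))
  keep <- de$base_mean > 0
  out <- data.frame(gene_id = de$gene_id[keep],
                    A = log10(de$base_mean[keep]),
                    M = de$log2_fold_change[keep],
                    is_deg = de$is_deg[keep],
                    stringsAsFactors = FALSE)
  attr(out, "n_omitted") <- sum(!keep)
  out
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result [%s]: %d genes, %d DEGs at adjusted p < %g (phi = %.4g)\n",
              attr(x, "method"), nrow(x), sum(x$is_deg), attr(x, "alpha"),
              attr(x, "phi")))
  print(utils::head(as.data.frame(x)[order(x$adj_p_value), ], 6),
        row.names = FALSE, digits = 4)
  invisible(x)
}
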