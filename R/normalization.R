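#' @name scaling_factors
#' @title Per-sample scaling factors for a normalization method
#'
#' @description
#' All normalization functions in the package return a `scaling_factors`
#' object holding, per sample, the method's native factor \eqn{d_j} and a
#' count-scale divisor \eqn{s_j}. Counts are normalized by division,
#' \eqn{K'_{gj} = K_{gj} / s_j}, and divisors are rescaled to geometric mean
#' 1 so that methods are directly comparable in one plot and in the
#' housekeeping bias/variance criteria.
#'
#' The factor-to-divisor convention differs by method because the native
#' factors live on different scales:
#' \itemize{
#'   \item TMM and UQ factors correct the library size, so the divisor is the
#'     effective library size \eqn{N_j d_j};
#'   \item the median-of-ratios (DES), quantile (EBS) and PoissonSeq (PS)
#'     factors are already count-scale, so the divisor is \eqn{d_j} itself
#'     (for PS, \eqn{m d_j}, since the raw PS factors sum to about 1 over the
#'     \eqn{m} samples);
#'   \item raw data (RD) has every divisor equal to 1.
#' }
#' @keywords internal
NULL

new_scaling_factors <- function(method, factors, divisors, sample_id,
                                reference = NULL, internals = NULL) {
  if (any(!is.finite(factors)) || any(factors <= 0))
    stopf("%s produced non-positive or non-finite factors", method)
  divisors <- rescale_geomean(divisors)
  structure(list(method = method,
                 sample_id = sample_id,
                 factors = unname(factors),
                 divisors = unname(divisors),
                 reference = reference,
                 internals = internals),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("scaling_factors [%s] for %d samples\n", x$method, length(x$factors)))
  if (!is.null(x$reference)) cat(sprintf("reference sample: %s\n", x$reference))
  df <- data.frame(sample_id = x$sample_id, factor = x$factors,
                   divisor = x$divisors)
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
as.data.frame.scaling_factors <- function(x, ...) {
  data.frame(method = x$method, sample_id = x$sample_id,
             factor = x$factors, divisor = x$divisors,
             stringsAsFactors = FALSE)
}

#' Trimmed mean of M-values (TMM) scaling factors
#'
#' For each sample \eqn{j} against a reference sample \eqn{r}, the factor is
#' \deqn{\log_2 d_j = \frac{\sum_{g \in G'} w_{gj} M_{gj}}{\sum_{g \in G'} w_{gj}}}
#' with \eqn{M_{gj} = \log_2((K_{gj}/N_j)/(K_{gr}/N_r))},
#' \eqn{w_{gj} = (N_j-K_{gj})/(N_j K_{gj}) + (N_r-K_{gr})/(N_r K_{gr})}, and
#' \eqn{G'} the genes surviving two-sided trimming of the M (log-ratio) and A
#' (average abundance) distributions. Genes with a zero count in either member
#' of the pair are excluded before trimming. The trim removes the
#' `floor(n * trim)` smallest and largest values of each statistic by
#' tie-averaged rank.
#'
#' Note on the weights: the weighted mean uses \eqn{w_{gj}} itself, the
#' binomial delta-method variance expression, as the weight. Set
#' `inverse_variance = TRUE` to weight by \eqn{1/w_{gj}} (precision weighting,
#' the convention of the edgeR implementation of TMM).
#'
#' @param cm A `count_matrix`.
#' @param trim_M,trim_A Fraction trimmed from EACH tail of the M and A
#'   distributions (defaults 0.30 and 0.05).
#' @param reference `"auto"` (the sample whose upper quartile of library-size-
#'   scaled counts is closest to the mean of those upper quartiles) or a
#'   sample identifier.
#' @param inverse_variance Use \eqn{1/w} weighting instead of the default
#'   \eqn{w} weighting (see Details).
#' @return A `scaling_factors` object; the divisor is the effective library
#'   size \eqn{N_j d_j}, rescaled to geometric mean 1. `$internals` holds the
#'   per-sample M, w, A vectors and trimmed gene sets.
#' @export
tmm_factors <- function(cm, trim_M = 0.30, trim_A = 0.05, reference = "auto",
                        inverse_variance = FALSE) {
  stopifnot(inherits(cm, "count_matrix"))
  if (trim_M < 0 || trim_M >= 0.5 || trim_A < 0 || trim_A >= 0.5)
    stopf("trim fractions must lie in [0, 0.5)")
  K <- cm$counts
  N <- colSums(K)
  if (any(N == 0)) stopf("sample with zero library size: %s",
                         paste(colnames(K)[N == 0], collapse = ", "))
  if (identical(reference, "auto")) {
    uq_scaled <- apply(sweep(K, 2, N, "/"), 2, upper_quartile)
    r <- which.min(abs(uq_scaled - mean(uq_scaled)))
  } else {
    r <- match(reference, colnames(K))
    if (is.na(r)) stopf("reference sample '%s' not found", reference)
  }
  m <- ncol(K)
  log2d <- numeric(m)
  internals <- vector("list", m)
  for (j in seq_len(m)) {
    if (j == r) { log2d[j] <- 0; next }
    usable <- K[, j] > 0 & K[, r] > 0
    kj <- K[usable, j]; kr <- K[usable, r]
    if (!any(usable)) stopf("no genes shared at positive counts between %s and the reference",
                            colnames(K)[j])
    M <- log2((kj / N[j]) / (kr / N[r]))
    A <- 0.5 * log2((kj / N[j]) * (kr / N[r]))
    w <- (N[j] - kj) / (N[j] * kj) + (N[r] - kr) / (N[r] * kr)
    keep <- trim_keep(M, trim_M) & trim_keep(A, trim_A)
    if (!any(keep)) stopf("trimming removed every gene for sample %s", colnames(K)[j])
    wt <- if (inverse_variance) 1 / w[keep] else w[keep]
    log2d[j] <- sum(wt * M[keep]) / sum(wt)
    internals[[j]] <- list(M = M, w = w, A = A,
                           kept_genes = rownames(K)[usable][keep])
  }
  d <- 2 ^ log2d
  new_scaling_factors("TMM", d, N * d, colnames(K),
                      reference = colnames(K)[r], internals = internals)
}

# keep values whose tie-averaged rank survives removing floor(n*trim) from
# each tail: rank in [floor(n*trim)+1, n - floor(n*trim)]
trim_keep <- function(x, trim) {
  n <- length(x)
  lo <- floor(n * trim) + 1
  hi <- n + 1 - lo
  rk <- rank(x, ties.method = "average")
  rk >= lo & rk <= hi
}

#' Upper quartile (UQ) scaling factors
#'
#' After removing genes with zero counts in ALL libraries, the factor is the
#' 75th percentile of the sample's counts divided by its library size,
#' \eqn{d_j = UQ(K_{\cdot j}) / \sum_g K_{gj}}. The divisor is the implied
#' count scale \eqn{N_j d_j = UQ_j}, rescaled to geometric mean 1.
#'
#' @param cm A `count_matrix`.
#' @return A `scaling_factors` object.
#' @export
uq_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  K <- cm$counts
  K <- K[rowSums(K) > 0, , drop = FALSE]
  if (nrow(K) == 0) stopf("no gene is nonzero in any library")
  N <- colSums(K)
  uq <- apply(K, 2, upper_quartile)
  if (any(uq == 0))
    stopf("upper quartile is zero for sample(s): %s",
          paste(colnames(K)[uq == 0], collapse = ", "))
  d <- uq / N
  new_scaling_factors("UQ", d, uq, colnames(K))
}

#' Median-of-ratios (DES) scaling factors
#'
#' The factor for sample \eqn{j} is the median over genes of the ratio of the
#' sample's count to the gene's geometric mean across samples (the
#' pseudoreference): \eqn{d_j = \mathrm{median}_g\, K_{gj} / (\prod_v K_{gv})^{1/m}}.
#' Genes with a zero count in any sample have geometric mean zero and are
#' excluded from the median.
#'
#' @param cm A `count_matrix`.
#' @return A `scaling_factors` object; divisors are the factors rescaled to
#'   geometric mean 1.
#' @export
median_ratio_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  K <- cm$counts
  usable <- rowSums(K == 0) == 0
  if (!any(usable))
    stopf("no gene has strictly positive counts in every sample")
  Ku <- K[usable, , drop = FALSE]
  log_pseudo <- rowMeans(log(Ku))
  d <- apply(exp(log(Ku) - log_pseudo), 2, stats::median)
  new_scaling_factors("DES", d, d, colnames(K))
}

#' Quantile (EBS) scaling factors
#'
#' Estimates sequencing depth by the upper quartile of each sample's counts,
#' centred on the log scale:
#' \eqn{d_j = 10^{\log_{10} Q_j - (1/m)\sum_v \log_{10} Q_v}}, i.e. the upper
#' quartile divided by the geometric mean of upper quartiles. Factors have
#' geometric mean 1 by construction and serve directly as divisors.
#'
#' @param cm A `count_matrix`.
#' @return A `scaling_factors` object.
#' @export
quantile_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  K <- cm$counts
  Q <- apply(K, 2, upper_quartile)
  if (any(Q == 0))
    stopf("upper quartile is zero for sample(s): %s",
          paste(colnames(K)[Q == 0], collapse = ", "))
  d <- 10 ^ (log10(Q) - mean(log10(Q)))
  new_scaling_factors("EBS", d, d, colnames(K))
}

#' PoissonSeq-style (PS) scaling factors
#'
#' A single-pass goodness-of-fit depth estimator. First the total-count
#' factors \eqn{d_j^{TC} = N_j / \sum_v N_v} give each gene an expected count
#' share; the per-gene Pearson goodness-of-fit statistic
#' \deqn{GOF_g = \sum_j \frac{(K_{gj} - d_j^{TC} K_{g\cdot})^2}{d_j^{TC} K_{g\cdot}}}
#' measures departure from pure depth scaling. Genes whose GOF lies in the
#' central window of the empirical GOF distribution (default: between the
#' 25th and 75th percentiles) form the non-differential set \eqn{G''}, and
#' \deqn{d_j^{PS} = \frac{\sum_{g \in G''} K_{gj}}{\sum_{g \in G''} K_{g\cdot}}.}
#' Because the raw PS factors sum to 1 across samples, the count-scale divisor
#' is \eqn{m\, d_j^{PS}}, rescaled to geometric mean 1.
#'
#' @param cm A `count_matrix`.
#' @param gof_window Length-2 numeric, the lower/upper bounds of the GOF
#'   selection window (default `c(0.25, 0.75)`).
#' @param window_type `"quantile"` (default; bounds are probabilities applied
#'   to the empirical GOF distribution) or `"value"` (bounds are literal GOF
#'   values).
#' @return A `scaling_factors` object; `$internals` holds the per-gene GOF
#'   statistics, the selected gene set and the total-count factors.
#' @export
poissonseq_factors <- function(cm, gof_window = c(0.25, 0.75),
                               window_type = c("quantile", "value")) {
  stopifnot(inherits(cm, "count_matrix"))
  window_type <- match.arg(window_type)
  if (length(gof_window) != 2L || gof_window[1] >= gof_window[2])
    stopf("gof_window must be an increasing pair")
  K <- cm$counts
  m <- ncol(K)
  N <- colSums(K)
  d_tc <- N / sum(N)
  tot <- rowSums(K)
  expected <- outer(tot, d_tc)
  gof <- rowSums((K - expected) ^ 2 / expected)
  gof[tot == 0] <- NA_real_   # undefined for all-zero genes
  bounds <- if (window_type == "quantile") {
    stats::quantile(gof, probs = gof_window, na.rm = TRUE, type = 7)
  } else gof_window
  selected <- !is.na(gof) & gof >= bounds[1] & gof <= bounds[2]
  if (!any(selected))
    stopf("no gene fell in the GOF window; widen gof_window")
  d <- colSums(K[selected, , drop = FALSE]) / sum(K[selected, ])
  new_scaling_factors("PS", d, m * d, colnames(K),
                      internals = list(gof = gof,
                                       selected_genes = rownames(K)[selected],
                                       tc_factors = unname(d_tc)))
}

#' Raw-data (RD) passthrough factors
#'
#' The unnormalized benchmark: every factor and divisor is 1, so normalized
#' counts equal raw counts.
#'
#' @param cm A `count_matrix`.
#' @return A `scaling_factors` object with all divisors 1.
#' @export
raw_factors <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  m <- ncol(cm$counts)
  new_scaling_factors("RD", rep(1, m), rep(1, m), colnames(cm$counts))
}

#' Compute scaling factors by method label
#'
#' Dispatcher over the individual factor functions; `"all"` returns a named
#' list over the six methods.
#'
#' @param cm A `count_matrix`.
#' @param method One of `"TMM"`, `"UQ"`, `"DES"`, `"EBS"`, `"PS"`, `"RD"`,
#'   `"all"` (case-insensitive).
#' @param ... Passed to the method-specific function.
#' @return A `scaling_factors` object, or a named list of them for `"all"`.
#' @export
scaling_factors <- function(cm, method = "all", ...) {
  method <- toupper(method)
  if (method == "ALL") {
    methods <- c("TMM", "UQ", "DES", "EBS", "PS", "RD")
    out <- lapply(methods, function(m) scaling_factors(cm, m, ...))
    names(out) <- methods
    return(out)
  }
  switch(method,
         TMM = tmm_factors(cm, ...),
         UQ  = uq_factors(cm),
         DES = median_ratio_factors(cm),
         EBS = quantile_factors(cm),
         PS  = poissonseq_factors(cm, ...),
         RD  = raw_factors(cm),
         stopf("unknown method '%s'", method))
}

#' Normalize counts by a set of scaling factors
#'
#' Divides each sample's counts by its divisor: \eqn{K'_{gj} = K_{gj}/s_j}.
#'
#' @param cm A `count_matrix`.
#' @param sf A `scaling_factors` object computed from the same samples.
#' @return A numeric matrix of normalized counts (same dimensions/dimnames).
#' @export
normalize_counts <- function(cm, sf) {
  stopifnot(inherits(cm, "count_matrix"), inherits(sf, "scaling_factors"))
  if (!identical(colnames(cm$counts), sf$sample_id))
    stopf("sample sets of counts and scaling factors do not match")
  sweep(cm$counts, 2, sf$divisors, "/")
}
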