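#' Specification for a synthetic two-group RNA-seq count data set
#'
#' Describes a negative-binomial count generator,
#' \eqn{K_{gj} \sim NB(s_j \lambda_{gj}, \phi)}, with known per-sample size
#' factors, a designated set of true housekeeping genes (constant expected
#' expression, dispersion one tenth of the global value) and a designated set
#' of true differentially expressed genes whose expected expression is shifted
#' by \eqn{2^{\pm log2fc}} in the second group.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Integer vector of length 2, samples per group.
#' @param size_factors Per-sample positive size factors (length = total
#'   samples), or `NULL` to draw them log-normally with `sf_sigma`. Factors
#'   are rescaled to geometric mean 1 so they share the scale of the methods'
#'   divisors.
#' @param sf_sigma Log-scale standard deviation of drawn size factors
#'   (default 0.4, about a 2-3 fold spread across samples).
#' @param mean_meanlog,mean_sdlog Log-normal parameters of the baseline gene
#'   means \eqn{\lambda_g} (defaults `log(200)` and 1).
#' @param phi Common NB dispersion (default 0.1); 0 gives Poisson counts.
#' @param de_fraction Fraction of genes differentially expressed (default 0).
#' @param log2fc Absolute log2 fold change of DE genes (default 2).
#' @param de_up_fraction Fraction of DE genes up-regulated in group 2
#'   (default 0.5).
#' @param n_housekeeping Number of genes forced to constant mean and low
#'   dispersion (default 0). Housekeeping genes are never DE.
#' @param hk_mean Constant expected expression of the housekeeping genes;
#'   default `exp(mean_meanlog - 3 * mean_sdlog)`, i.e. three log-scale
#'   standard deviations below the median baseline. Raw-count stability
#'   selection favours low-abundance genes (their absolute mean-square
#'   deviation is smallest), so housekeeping-like genes are emulated at low
#'   constant abundance, as observed in real data.
#' @param seed Mandatory integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, n_per_group, size_factors = NULL,
                           sf_sigma = 0.4, mean_meanlog = log(200),
                           mean_sdlog = 1, phi = 0.1, de_fraction = 0,
                           log2fc = 2, de_up_fraction = 0.5,
                           n_housekeeping = 0,
                           hk_mean = exp(mean_meanlog - 3 * mean_sdlog), seed) {
  if (missing(seed)) stopf("a seed is mandatory for reproducible simulation")
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stopf("n_per_group must give two positive group sizes")
  if (de_fraction < 0 || de_fraction >= 1) stopf("de_fraction must lie in [0, 1)")
  if (phi < 0) stopf("phi must be nonnegative")
  n_de <- round(de_fraction * n_genes)
  if (n_housekeeping + n_de > n_genes)
    stopf("housekeeping plus DE genes exceed n_genes")
  m <- sum(n_per_group)
  if (!is.null(size_factors)) {
    if (length(size_factors) != m || any(size_factors <= 0))
      stopf("size_factors must be %d positive values", m)
  }
  structure(list(n_genes = as.integer(n_genes),
                 n_per_group = as.integer(n_per_group),
                 size_factors = size_factors, sf_sigma = sf_sigma,
                 mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
                 phi = phi, de_fraction = de_fraction, log2fc = log2fc,
                 de_up_fraction = de_up_fraction,
                 n_housekeeping = as.integer(n_housekeeping),
                 hk_mean = hk_mean,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic count matrix with ground truth
#'
#' Draws counts from the model described in [synthetic_spec()]. Gene roles
#' (housekeeping, DE, background) are assigned to random positions; the
#' returned truth object records the rescaled true size factors, the DE genes
#' with their signed log2 fold changes, and the housekeeping genes.
#'
#' @param spec A `synthetic_spec`.
#' @return List with `cm` (a `count_matrix` with groups `"g1"`, `"g2"`) and
#'   `truth` (list: `size_factors`, `de_genes`, `de_log2fc`, `housekeeping`,
#'   `spec`).
#' @export
generate_counts <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes
  m <- sum(spec$n_per_group)
  group <- rep(c("g1", "g2"), spec$n_per_group)

  sf <- spec$size_factors %||% stats::rlnorm(m, 0, spec$sf_sigma)
  sf <- rescale_geomean(sf)

  lambda <- stats::rlnorm(G, spec$mean_meanlog, spec$mean_sdlog)
  n_de <- round(spec$de_fraction * G)
  roles <- rep("background", G)
  pick <- sample.int(G, spec$n_housekeeping + n_de)
  hk_idx <- pick[seq_len(spec$n_housekeeping)]
  de_idx <- setdiff(pick, hk_idx)
  roles[hk_idx] <- "housekeeping"
  roles[de_idx] <- "de"
  lambda[hk_idx] <- spec$hk_mean   # constant low abundance, see synthetic_spec()

  # per-gene, per-sample expected expression
  L <- matrix(lambda, G, m)
  de_sign <- numeric(0)
  if (n_de > 0) {
    n_up <- round(spec$de_up_fraction * n_de)
    de_sign <- sample(rep(c(1, -1), c(n_up, n_de - n_up)))
    shift <- 2 ^ (de_sign * spec$log2fc)
    L[de_idx, group == "g2"] <- L[de_idx, group == "g2"] * shift
  }
  mu <- sweep(L, 2, sf, "*")
  if (any(mu == 0) && n_de > 0) stopf("zero expected count with DE present")

  phi_g <- rep(spec$phi, G)
  phi_g[hk_idx] <- spec$phi / 10        # housekeeping: low dispersion
  counts <- matrix(0L, G, m)
  for (g in seq_len(G)) {
    counts[g, ] <- if (phi_g[g] == 0) stats::rpois(m, mu[g, ])
                   else stats::rnbinom(m, size = 1 / phi_g[g], mu = mu[g, ])
  }
  rownames(counts) <- sprintf("gene_%05d", seq_len(G))
  colnames(counts) <- sprintf("sample_%02d", seq_len(m))

  cm <- count_matrix(counts, group = group)
  truth <- list(size_factors = sf,
                de_genes = rownames(counts)[de_idx],
                de_log2fc = stats::setNames(de_sign * spec$log2fc,
                                            rownames(counts)[de_idx]),
                housekeeping = rownames(counts)[hk_idx],
                spec = spec)
  list(cm = cm, truth = truth)
}

#' Presets emulating the benchmark data-set shapes
#'
#' Three ready-made simulation specs matching the gene and sample counts of
#' the public benchmark data sets (after filtering): `cheung_like` (41
#' samples, 12,410 genes, expression skewed low), `bodymap_like` (16 samples,
#' 13,131 genes, skewed high) and `aml_like` (27 samples, 12,749 genes,
#' middle abundance, DE skewed 70/30 towards up-regulation).
#'
#' @param name One of `"cheung_like"`, `"bodymap_like"`, `"aml_like"`.
#' @param seed Integer seed.
#' @param ... Overrides passed to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
preset <- function(name = c("cheung_like", "bodymap_like", "aml_like"),
                   seed, ...) {
  name <- match.arg(name)
  base <- switch(name,
    cheung_like = list(n_genes = 12410L, n_per_group = c(21L, 20L),
                       mean_meanlog = log(60), mean_sdlog = 1.2),
    bodymap_like = list(n_genes = 13131L, n_per_group = c(8L, 8L),
                        mean_meanlog = log(800), mean_sdlog = 1.2),
    aml_like = list(n_genes = 12749L, n_per_group = c(14L, 13L),
                    mean_meanlog = log(300), mean_sdlog = 1,
                    de_up_fraction = 0.7))
  args <- utils::modifyList(c(base,
                              list(phi = 0.1, de_fraction = 0.05, log2fc = 2,
                                   n_housekeeping = 130L, seed = seed)),
                            list(...))
  do.call(synthetic_spec, args)
}
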