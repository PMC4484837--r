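#' Diagnostic plots for a fitted normalization benchmark
#'
#' Plots are views of the fitted object and never recompute statistics.
#'
#' @param x A `norm_benchmark`.
#' @param which One of `"factors"` (per-sample divisors by method, samples
#'   ordered by their minimum divisor across methods), `"abundance"` (DEG
#'   counts per method stacked by raw-abundance bin), `"errors"` (LOOCV mean
#'   errors with 95% confidence bars), `"balloon"` (pairwise common-DEG
#'   percentages), `"dendrogram"` (method clustering on DEG ranks), `"ma"`
#'   (MA plots per method).
#' @param bins For `"abundance"`: explicit mean-count bin edges; default the
#'   quartiles of the filtered matrix's gene means.
#' @param ... Further graphical arguments (unused).
#' @return `x`, invisibly.
#' @export
plot.norm_benchmark <- function(x, which = c("factors", "abundance", "errors",
                                             "balloon", "dendrogram", "ma"),
                                bins = NULL, ...) {
  which <- match.arg(which)
  switch(which,
         factors = plot_factors(x$scaling_factors),
         abundance = plot_deg_abundance_bars(x$deg_lists, x$cm, bins = bins),
         errors = plot_error_ci_bars(x$loocv),
         balloon = plot_balloon(x$common_degs),
         dendrogram = plot_dendrogram(x$dendrogram),
         ma = plot_ma_panel(x$de_results))
  invisible(x)
}

#' Per-sample divisors across methods
#'
#' One series per method; samples ordered by their minimum divisor across
#' methods.
#'
#' @param sfs Named list of `scaling_factors` objects.
#' @return The sample ordering used, invisibly.
#' @export
plot_factors <- function(sfs) {
  stopifnot(length(sfs) >= 1L)
  div <- t(vapply(sfs, `[[`, numeric(length(sfs[[1]]$divisors)), "divisors"))
  ord <- order(apply(div, 2, min))
  div <- div[, ord, drop = FALSE]
  graphics::matplot(t(div), type = "b", pch = seq_len(nrow(div)), lty = 1,
                    xlab = "sample (ordered by minimum divisor)",
                    ylab = "count-scale divisor",
                    main = "Normalization divisors across samples")
  graphics::legend("topleft", legend = names(sfs), col = seq_len(nrow(div)),
                   pch = seq_len(nrow(div)), bty = "n", cex = 0.8)
  invisible(ord)
}

#' DEG counts per method stacked by raw-abundance bin
#'
#' @param deg_lists Named list of DEG identifier vectors.
#' @param cm The `count_matrix` the DEGs were called on.
#' @param bins Strictly increasing interior bin edges on the mean raw count;
#'   default: quartiles of the gene means.
#' @return The per-method bin count matrix, invisibly.
#' @export
plot_deg_abundance_bars <- function(deg_lists, cm, bins = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  means <- rowMeans(cm$counts)
  if (is.null(bins)) bins <- unname(stats::quantile(means, c(0.25, 0.5, 0.75)))
  if (is.unsorted(bins, strictly = TRUE)) stopf("bins must be strictly increasing")
  edges <- unique(c(-Inf, bins, Inf))
  labs <- levels(cut(means, edges))
  tab <- vapply(deg_lists, function(d) {
    if (length(d) == 0L) return(stats::setNames(rep(0, length(labs)), labs))
    table(cut(means[d], edges))
  }, numeric(length(labs)))
  graphics::barplot(tab, col = grDevices::gray.colors(length(labs)),
                    xlab = "method", ylab = "number of DEGs",
                    main = "DEG abundance composition",
                    legend.text = labs, args.legend = list(cex = 0.7, bty = "n"))
  invisible(t(tab))
}

#' LOOCV error bars with 95% confidence intervals
#'
#' Bars at the mean of the five classifier error percentages per method;
#' whiskers at the t-interval over classifiers.
#'
#' @param loocv Named list of [loocv_errors()] results.
#' @return Invisibly, the plotted means.
#' @export
plot_error_ci_bars <- function(loocv) {
  if (is.null(loocv)) stopf("no LOOCV results in this fit")
  means <- vapply(loocv, `[[`, numeric(1), "mean")
  ci <- vapply(loocv, `[[`, numeric(2), "ci")
  bp <- graphics::barplot(means, ylim = c(0, max(ci[2, ], means, na.rm = TRUE) * 1.15),
                          ylab = "classification error (%)",
                          main = "LOOCV prediction error (95% CI over classifiers)")
  ok <- !is.na(ci[1, ])
  if (any(ok))
    graphics::arrows(bp[ok], pmax(ci[1, ok], 0), bp[ok], ci[2, ok],
                     angle = 90, code = 3, length = 0.05)
  invisible(means)
}

#' Balloon plot of pairwise common-DEG percentages
#'
#' Circle size and shading encode the pair-averaged percentage of shared
#' DEGs.
#'
#' @param cd A `common_deg_matrix`.
#' @return Invisibly, the pair-averaged percentage matrix.
#' @export
plot_balloon <- function(cd) {
  if (is.null(cd)) stopf("no common-DEG matrix in this fit")
  P <- cd$P_avg
  k <- nrow(P)
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = c(0.5, k + 0.5),
                 xaxt = "n", yaxt = "n", xlab = "", ylab = "",
                 main = "Common DEGs between methods (%)")
  graphics::axis(1, seq_len(k), cd$methods)
  graphics::axis(2, seq_len(k), rev(cd$methods), las = 1)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    val <- P[i, j]
    graphics::symbols(j, k + 1 - i, circles = 0.45 * sqrt(val / 100),
                      inches = FALSE, add = TRUE,
                      bg = grDevices::gray(1 - val / 100 * 0.8))
    graphics::text(j, k + 1 - i, sprintf("%.0f", val), cex = 0.7)
  }
  invisible(P)
}

#' Venn-style intersection table of DEG lists
#'
#' Renders a Venn diagram for up to 3 lists; for 4-5 lists (or on request)
#' prints the full intersection-region table instead; more than 5 sets is an
#' error.
#'
#' @param deg_lists Named list of 2-5 DEG identifier vectors.
#' @return Data frame of region memberships and sizes, invisibly.
#' @export
plot_venn <- function(deg_lists) {
  k <- length(deg_lists)
  if (k > 5L) stopf("Venn rendering supports at most 5 sets; use the intersection table")
  if (k < 2L) stopf("need at least two lists")
  universe <- Reduce(union, deg_lists)
  memb <- vapply(deg_lists, function(d) universe %in% d, logical(length(universe)))
  key <- apply(memb, 1, function(r) paste(names(deg_lists)[r], collapse = "&"))
  regions <- as.data.frame(table(key), stringsAsFactors = FALSE)
  names(regions) <- c("region", "n_genes")
  if (k <= 3L) {
    # proportional-free schematic: circles on a triangle, region counts printed
    centers <- list(c(0, 0), c(1, 0), c(0.5, 0.87))[seq_len(k)]
    graphics::plot(NA, xlim = c(-1.2, 2.2), ylim = c(-1.2, 2.1), axes = FALSE,
                   xlab = "", ylab = "", main = "DEG overlap")
    for (i in seq_len(k)) {
      graphics::symbols(centers[[i]][1], centers[[i]][2], circles = 0.9,
                        inches = FALSE, add = TRUE)
      graphics::text(centers[[i]][1], centers[[i]][2] + 1.0, names(deg_lists)[i])
    }
    graphics::mtext(paste(sprintf("%s: %d", regions$region, regions$n_genes),
                          collapse = "   "), side = 1, cex = 0.7)
  } else {
    graphics::plot.new()
    graphics::title("DEG overlap (intersection table)")
    graphics::text(0.5, 0.5, paste(sprintf("%s: %d", regions$region, regions$n_genes),
                                   collapse = "\n"), cex = 0.8)
  }
  invisible(regions)
}

#' Dendrogram of methods clustered by DEG ranks
#'
#' @param dendro A `method_dendrogram`.
#' @return Invisibly, the `hclust` object.
#' @export
plot_dendrogram <- function(dendro) {
  if (is.null(dendro)) stopf("no dendrogram in this fit")
  graphics::plot(dendro$hclust, main = "Method clustering on common-DEG ranks",
                 xlab = "", sub = sprintf("%d common DEGs, Ward linkage",
                                          length(dendro$common_genes)))
  invisible(dendro$hclust)
}

#' Panel of MA plots, one per method
#'
#' @param de_results Named list of `de_result` objects.
#' @return Invisibly, `NULL`.
#' @export
plot_ma_panel <- function(de_results) {
  k <- length(de_results)
  old <- graphics::par(mfrow = grDevices::n2mfrow(k), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (mt in names(de_results)) {
    mv <- ma_values(de_results[[mt]])
    graphics::plot(mv$A, mv$M, pch = 16, cex = 0.3,
                   col = ifelse(mv$is_deg, "red", "grey50"),
                   xlab = "log10 base mean", ylab = "log2 fold change",
                   main = mt)
    graphics::abline(h = 0, lty = 2)
  }
  invisible(NULL)
}
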