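#' Benchmark normalization methods on a two-group count matrix
#'
#' The package's central fitting function. Given raw counts and a two-group
#' design it (i) computes scaling factors for each requested method, (ii)
#' selects the analytical housekeeping set and scores each method's bias and
#' variance on it, (iii) runs the negative-binomial exact test per method and
#' calls DEGs, (iv) scores sensitivity/specificity when control panels are
#' supplied, (v) estimates LOOCV classification error over five classifiers
#' on the informative genes, (vi) computes pairwise common-DEG percentages
#' and the rank dendrogram, and (vii) aggregates per-criterion tie-averaged
#' ranks into a final recommendation.
#'
#' @param cm A `count_matrix` with groups assigned, or a raw matrix plus
#'   `group`.
#' @param group Optional group labels when `cm` is a plain matrix.
#' @param methods Normalization methods to compare (default all six).
#' @param filter_cutoff Mean-count filter applied first (strictly greater
#'   than; default 0).
#' @param hg_fraction Housekeeping fraction (default 0.01).
#' @param alpha DEG threshold on adjusted p-values (default 0.05).
#' @param positives,negatives Optional control gene panels; when absent the
#'   sensitivity/specificity criterion is dropped.
#' @param informative_fraction Informative genes as a fraction of the sample
#'   count (default 0.75).
#' @param phi Common NB dispersion; `NULL` (default) estimates it per method.
#' @param seed Integer seed for the stochastic classifiers.
#' @param loocv Set `FALSE` to skip the classification criterion (e.g. for
#'   quick looks); default `TRUE`.
#' @param verbose Log stage-level progress (default `FALSE`).
#' @return An object of class `norm_benchmark`; see [print.norm_benchmark()],
#'   [summary.norm_benchmark()], [plot.norm_benchmark()], [coef.norm_benchmark()].
#' @examples
#' sim <- generate_counts(synthetic_spec(400, c(5, 5), phi = 0.05,
#'                                       de_fraction = 0.1, n_housekeeping = 20,
#'                                       seed = 1))
#' fit <- norm_benchmark(sim$cm, methods = c("DES", "EBS", "RD"),
#'                       loocv = FALSE, seed = 1)
#' fit
#' @export
norm_benchmark <- function(cm, group = NULL,
                           methods = c("TMM", "UQ", "DES", "EBS", "PS", "RD"),
                           filter_cutoff = 0, hg_fraction = 0.01, alpha = 0.05,
                           positives = NULL, negatives = NULL,
                           informative_fraction = 0.75, phi = NULL,
                           seed = 1L, loocv = TRUE, verbose = FALSE) {
  if (!inherits(cm, "count_matrix")) cm <- count_matrix(cm, group = group)
  else if (!is.null(group)) cm <- set_groups(cm, group)
  if (is.null(cm$group)) stopf("a two-group design is required")
  methods <- toupper(methods)
  say <- function(...) if (verbose) message(sprintf(...))

  n_before <- nrow(cm$counts)
  cm <- filter_by_mean_count(cm, filter_cutoff)
  say("filter: %d -> %d genes (mean count > %g)", n_before, nrow(cm$counts),
      filter_cutoff)
  m <- ncol(cm$counts)

  sfs <- lapply(methods, function(mt) scaling_factors(cm, mt))
  names(sfs) <- methods
  say("scaling factors computed for %s", paste(methods, collapse = ", "))

  hg <- select_housekeeping(gene_stability_scores(cm), hg_fraction)
  say("housekeeping set: %d genes", length(hg))

  bv <- do.call(rbind, lapply(sfs, function(sf)
    suppressWarnings(bias_variance(cm, sf, hg))))
  rownames(bv) <- NULL

  de_results <- lapply(sfs, function(sf)
    nb_exact_test(cm, sf, phi = phi, alpha = alpha))
  deg_lists <- lapply(de_results, call_degs, alpha = alpha)
  say("DEGs at adjusted p < %g: %s", alpha,
      paste(sprintf("%s=%d", methods, lengths(deg_lists)), collapse = ", "))

  criteria <- list(
    bias = stats::setNames(bv$mean_bias, bv$method),
    variance = stats::setNames(bv$mean_variance, bv$method))

  sens_spec <- NULL
  if (!is.null(positives) && !is.null(negatives)) {
    present <- rownames(cm$counts)
    sens_spec <- t(vapply(deg_lists, sensitivity_specificity,
                          numeric(2),
                          positives = intersect(positives, present),
                          negatives = intersect(negatives, present)))
    criteria$sensitivity <- sens_spec[, "sensitivity"]
    criteria$specificity <- sens_spec[, "specificity"]
  }

  loocv_results <- NULL
  if (isTRUE(loocv)) {
    loocv_results <- lapply(methods, function(mt) {
      informative <- select_informative_genes(de_results[[mt]], m,
                                              informative_fraction)
      feats <- t(log2(normalize_counts(cm, sfs[[mt]])[informative, , drop = FALSE] + 1))
      loocv_errors(feats, cm$group, seed = seed)
    })
    names(loocv_results) <- methods
    criteria$prediction_error <- vapply(loocv_results, `[[`, numeric(1), "mean")
    say("LOOCV mean errors: %s",
        paste(sprintf("%s=%.1f%%", methods, criteria$prediction_error),
              collapse = ", "))
  }

  cd <- tryCatch(suppressWarnings(common_deg_matrix(deg_lists)),
                 error = function(e) NULL)
  if (!is.null(cd) && setequal(names(cd$score), methods))
    criteria$common_degs <- cd$score[methods]

  dendro <- tryCatch(method_rank_dendrogram(de_results, alpha = alpha),
                     error = function(e) NULL)

  ranks <- summarize_ranks(criteria)
  say("recommended method: %s", ranks$recommended)

  structure(list(cm = cm, methods = methods, scaling_factors = sfs,
                 housekeeping = hg, bias_variance = bv,
                 de_results = de_results, deg_lists = deg_lists,
                 sens_spec = sens_spec, loocv = loocv_results,
                 common_degs = cd, dendrogram = dendro,
                 criteria = criteria, ranks = ranks,
                 alpha = alpha, seed = seed),
            class = "norm_benchmark")
}

#' @export
print.norm_benchmark <- function(x, ...) {
  cat(sprintf("norm_benchmark: %d genes x %d samples, %d methods\n",
              nrow(x$cm$counts), ncol(x$cm$counts), length(x$methods)))
  cat(sprintf("housekeeping genes: %d; DEGs at adjusted p < %g: %s\n",
              length(x$housekeeping), x$alpha,
              paste(sprintf("%s=%d", x$methods, lengths(x$deg_lists)),
                    collapse = ", ")))
  print(x$ranks)
  invisible(x)
}

#' Summary table of a normalization benchmark
#'
#' @param object A `norm_benchmark`.
#' @param ... Unused.
#' @return Data frame: one row per method with criterion values, criterion
#'   ranks and the final rank, sorted by final rank.
#' @export
summary.norm_benchmark <- function(object, ...) {
  v <- t(object$ranks$values)
  r <- t(object$ranks$ranks)
  colnames(r) <- paste0("rank_", colnames(r))
  out <- data.frame(method = rownames(v), v, r,
                    final_rank = colMeans(object$ranks$ranks)[rownames(v)],
                    check.names = FALSE, row.names = NULL)
  out[order(out$final_rank, out$method), , drop = FALSE]
}

#' Scaling-factor divisors of a fitted benchmark
#'
#' @param object A `norm_benchmark`.
#' @param ... Unused.
#' @return Matrix of count-scale divisors, methods x samples (geometric mean
#'   1 per method).
#' @export
coef.norm_benchmark <- function(object, ...) {
  t(vapply(object$scaling_factors, `[[`, numeric(ncol(object$cm$counts)),
           "divisors"))
}

#' Write the benchmark report to disk
#'
#' Emits the machine-readable artifacts of a fitted benchmark: scaling
#' factors, bias/variance, per-method DE tables, the criterion/rank summary
#' (TSV) and a JSON report. Output is deterministic given the fitted object.
#'
#' @param x A `norm_benchmark`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "norm_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  w(do.call(rbind, lapply(x$scaling_factors, as.data.frame)), "scaling_factors.tsv")
  w(x$bias_variance, "bias_variance.tsv")
  for (mt in x$methods)
    w(as.data.frame(x$de_results[[mt]]), sprintf("de_%s.tsv", mt))
  w(summary(x), "summary.tsv")
  report <- list(methods = x$methods,
                 n_genes = nrow(x$cm$counts),
                 n_samples = ncol(x$cm$counts),
                 n_housekeeping = length(x$housekeeping),
                 degs_per_method = lengths(x$deg_lists),
                 criteria = lapply(x$criteria, function(v) as.list(v)),
                 final_rank = as.list(x$ranks$final_rank),
                 recommended = x$ranks$recommended)
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the full benchmarking workflow and write artifacts
#'
#' Convenience wrapper: fit [norm_benchmark()] on a count matrix (or a
#' synthetic preset), write the TSV/JSON report, and optionally render the
#' diagnostic plots, under one output directory.
#'
#' @param cm A `count_matrix` with groups.
#' @param output_dir Directory for reports and figures.
#' @param plots Render diagnostic figures as PDFs (default `TRUE`).
#' @param ... Passed to [norm_benchmark()].
#' @return The fitted `norm_benchmark`, invisibly.
#' @export
run_workflow <- function(cm, output_dir, plots = TRUE, ...) {
  fit <- norm_benchmark(cm, ...)
  write_report(fit, output_dir)
  if (isTRUE(plots)) {
    for (which in c("factors", "abundance", "errors", "balloon", "dendrogram", "ma")) {
      f <- file.path(output_dir, paste0("plot_", which, ".pdf"))
      ok <- tryCatch({
        grDevices::pdf(f, width = 8, height = 6)
        plot(fit, which = which)
        TRUE
      }, error = function(e) FALSE, finally = grDevices::dev.off())
      if (!ok && file.exists(f)) unlink(f)
    }
  }
  invisible(fit)
}
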