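#' Construct a validated count matrix
#'
#' Bundles a genes-by-samples matrix of nonnegative integer read counts with
#' gene identifiers, sample identifiers and (optionally) a two-group sample
#' assignment. All downstream functions in the package consume this container.
#'
#' @param counts Numeric matrix, rows = genes, columns = samples. Entries must
#'   be nonnegative integers (checked exactly; read counts are integral by
#'   nature and no tolerance is applied). Row and column names supply gene and
#'   sample identifiers; if absent they are generated.
#' @param group Optional vector (length = number of samples) assigning each
#'   sample to one of exactly two groups. May be attached later with
#'   [set_groups()]; functions that need the design will error if it is
#'   missing.
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer-valued matrix with dimnames), and `group` (a two-level factor or
#'   `NULL`).
#' @examples
#' cm <- count_matrix(matrix(c(1, 2, 0, 0, 5, 5), nrow = 3, byrow = TRUE),
#'                    group = c("A", "B"))
#' dim(cm)
#' @export
count_matrix <- function(counts, group = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) stopf("counts must be numeric")
  if (nrow(counts) < 1L) stopf("need at least one gene")
  if (ncol(counts) < 2L) stopf("need at least two samples")
  if (anyNA(counts)) stopf("counts contain missing values")
  if (any(counts < 0)) stopf("counts contain negative entries")
  if (any(counts != trunc(counts)))
    stopf("counts must be integers (read counts); found non-integer entries")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample_", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stopf("duplicate sample identifiers")
  cm <- structure(list(counts = counts, group = NULL), class = "count_matrix")
  if (!is.null(group)) cm <- set_groups(cm, group)
  cm
}

#' Attach or replace the two-group sample assignment
#'
#' @param cm A `count_matrix`.
#' @param group Either a vector of group labels aligned to the samples, or a
#'   data frame with columns `sample_id` and `group` (order-free; matched by
#'   sample identifier).
#' @return The `count_matrix` with a validated two-level factor in `$group`.
#' @export
set_groups <- function(cm, group) {
  stopifnot(inherits(cm, "count_matrix"))
  if (is.data.frame(group)) {
    if (!all(c("sample_id", "group") %in% names(group)))
      stopf("metadata table needs columns 'sample_id' and 'group'")
    idx <- match(colnames(cm$counts), group$sample_id)
    if (anyNA(idx))
      stopf("metadata is missing samples: %s",
            paste(colnames(cm$counts)[is.na(idx)], collapse = ", "))
    group <- group$group[idx]
  }
  if (length(group) != ncol(cm$counts))
    stopf("group has length %d but there are %d samples",
          length(group), ncol(cm$counts))
  group <- factor(as.character(group))
  if (nlevels(group) != 2L)
    stopf("exactly two groups are required, got %d", nlevels(group))
  if (any(table(group) == 0L)) stopf("both groups must be non-empty")
  cm$group <- group
  cm
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n", nrow(x$counts), ncol(x$counts)))
  if (!is.null(x$group)) {
    tab <- table(x$group)
    cat(sprintf("groups: %s\n",
                paste(sprintf("%s (n=%d)", names(tab), tab), collapse = ", ")))
  } else {
    cat("groups: not assigned\n")
  }
  cat(sprintf("library sizes: %s\n",
              paste(format(colSums(x$counts), big.mark = ","), collapse = " ")))
  invisible(x)
}

gene_ids <- function(cm) rownames(cm$counts)
sample_ids <- function(cm) colnames(cm$counts)
library_sizes <- function(cm) colSums(cm$counts)

#' Read a count matrix from disk
#'
#' Accepts tab- or comma-separated tables (first column = gene identifiers,
#' header = sample identifiers) or MatrixMarket files with sidecar one-ID-per-
#' line gene/sample files.
#'
#' @param path Path to the count file.
#' @param format One of `"auto"`, `"tsv"`, `"csv"`, `"mtx"`; `"auto"` picks by
#'   file extension.
#' @param gene_file,sample_file For `mtx` input, paths to plain-text files with
#'   one gene / sample identifier per line.
#' @param group Optional group assignment passed to [count_matrix()].
#' @return A validated `count_matrix`.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                        gene_file = NULL, sample_file = NULL, group = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    if (is.null(gene_file) || is.null(sample_file))
      stopf("mtx input needs gene_file and sample_file sidecars")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(gene_file)
    colnames(m) <- readLines(sample_file)
    return(count_matrix(m, group = group))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                      check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e)))
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(apply(df, 2, function(col) any(is.na(suppressWarnings(as.numeric(col))))))
    stopf("non-numeric entries in column(s): %s", paste(names(df)[bad], collapse = ", "))
  }
  count_matrix(m, group = group)
}

#' Write a count matrix as a delimited table
#'
#' @param cm A `count_matrix`.
#' @param path Output path.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("tsv", "csv")) {
  stopifnot(inherits(cm, "count_matrix"))
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  df <- data.frame(gene_id = gene_ids(cm), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table (columns sample_id, group)
#' @param path Path to a TSV/CSV file with columns `sample_id` and `group`.
#' @return A data frame usable by [set_groups()].
#' @export
read_sample_info <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df)))
    stopf("metadata table needs columns 'sample_id' and 'group'")
  df
}

#' Read a gene list (one identifier per line)
#'
#' @param path Plain-text file, one gene ID per line; blank lines ignored.
#' @param role Label recording what the list is used for.
#' @return A character vector with attribute `role`.
#' @export
read_gene_list <- function(path, role = c("generic", "positive_control",
                                          "negative_control", "housekeeping")) {
  role <- match.arg(role)
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  ids <- trimws(ids)
  if (anyDuplicated(ids)) stopf("duplicate gene identifiers in %s", path)
  structure(ids, role = role)
}

#' Filter genes by mean raw count
#'
#' Keeps exactly the genes whose mean count across all samples is strictly
#' greater than `cutoff`. Used with `cutoff = 0` to drop all-zero genes and
#' with larger cutoffs (e.g. 50) to restrict to reliably quantified genes.
#' Gene order and the sample set are preserved.
#'
#' @param cm A `count_matrix`.
#' @param cutoff Nonnegative mean-count threshold (strict inequality).
#' @return The filtered `count_matrix`.
#' @export
filter_by_mean_count <- function(cm, cutoff = 0) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0)
    stopf("cutoff must be a single nonnegative number")
  keep <- rowMeans(cm$counts) > cutoff
  if (!any(keep))
    stopf("filtering at mean count > %g removed every gene", cutoff)
  cm$counts <- cm$counts[keep, , drop = FALSE]
  cm
}
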