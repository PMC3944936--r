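#' Construct an expression dataset
#'
#' The central container: a numeric matrix of continuous expression values
#' with samples in rows and genes in columns, plus one class label per
#' sample. All downstream functions (tree induction, PSO selection, the
#' evaluation harness) consume this type.
#'
#' @param values numeric matrix, samples x genes. No missing values.
#' @param gene_names character vector of unique gene identifiers, one per
#'   column. Defaults to `colnames(values)`.
#' @param sample_ids character vector of unique sample identifiers, one per
#'   row. Defaults to `rownames(values)` or `S1, S2, ...`.
#' @param labels class label per sample (factor or character). Factor level
#'   order is preserved; character input is converted with sorted levels.
#' @return an object of class `expression_dataset` with fields `values`,
#'   `gene_names`, `sample_ids`, `labels`.
#' @examples
#' x <- matrix(rnorm(12), 4, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
#' ds <- expression_dataset(x, labels = c("A", "A", "B", "B"))
#' ds
#' @export
expression_dataset <- function(values, gene_names = colnames(values),
                               sample_ids = rownames(values), labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_psodt("'values' must be a numeric matrix (samples x genes)")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(ncol(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  gene_names <- as.character(gene_names)
  sample_ids <- as.character(sample_ids)
  if (length(gene_names) != ncol(values))
    stop_psodt("length(gene_names) must equal ncol(values)")
  if (length(sample_ids) != nrow(values))
    stop_psodt("length(sample_ids) must equal nrow(values)")
  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stop_psodt("duplicate gene names: ", paste(dup, collapse = ", "))
  if (length(labels) != nrow(values))
    stop_psodt("length(labels) must equal nrow(values)")
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_psodt(sprintf("missing expression value at sample %d, gene %d",
                       bad[1], bad[2]))
  }
  labels <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (anyNA(labels)) stop_psodt("missing class labels are not allowed")
  dimnames(values) <- list(sample_ids, gene_names)
  structure(list(values = values, gene_names = gene_names,
                 sample_ids = sample_ids, labels = labels),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d samples x %d genes, %d classes (%s)\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels),
              paste(levels(x$labels), collapse = ", ")))
  invisible(x)
}

n_genes <- function(dataset) ncol(dataset$values)
n_samples <- function(dataset) nrow(dataset$values)

#' Read a delimited expression table
#'
#' Reads a plain delimited text file with one header row into an
#' [expression_dataset]. In `samples` orientation, rows are samples: the
#' first column holds sample identifiers, one column (default `"class"`)
#' holds the class labels, and all remaining columns are genes. In `genes`
#' orientation, rows are genes with the first column holding gene names and
#' one *row* (named `label_column` in the first column) holding the labels;
#' the table is transposed after reading so samples end up in rows.
#'
#' Missing or non-numeric expression cells and duplicate gene names are hard
#' errors: this package does not impute.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param label_column name of the label column (or label row in `genes`
#'   orientation). Default `"class"`.
#' @param orientation `"samples"` (samples in rows, default) or `"genes"`.
#' @return an [expression_dataset].
#' @export
read_expression_table <- function(path, delimiter = "\t",
                                  label_column = "class",
                                  orientation = c("samples", "genes")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_psodt("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delimiter,
                           check.names = FALSE, colClasses = "character",
                           quote = "\"", comment.char = "")
  if (ncol(raw) < 2) stop_psodt("expected at least two columns in ", path)

  if (orientation == "genes") {
    gene_col <- raw[[1]]
    body <- as.matrix(raw[, -1, drop = FALSE])
    lab_row <- which(gene_col == label_column)
    if (length(lab_row) != 1)
      stop_psodt("label row '", label_column, "' not found in ", path)
    labels <- as.character(body[lab_row, ])
    expr <- t(body[-lab_row, , drop = FALSE])
    gene_names <- gene_col[-lab_row]
    sample_ids <- colnames(raw)[-1]
  } else {
    sample_ids <- raw[[1]]
    lab_pos <- which(colnames(raw)[-1] == label_column) + 1L
    if (length(lab_pos) == 0)
      stop_psodt("label column '", label_column, "' not found in ", path)
    labels <- as.character(raw[[lab_pos[1]]])
    gene_pos <- setdiff(seq_along(raw)[-1], lab_pos[1])
    expr <- as.matrix(raw[, gene_pos, drop = FALSE])
    gene_names <- colnames(raw)[gene_pos]
  }

  dup <- unique(gene_names[duplicated(gene_names)])
  if (length(dup))
    stop_psodt("duplicate gene names in ", path, ": ",
               paste(dup, collapse = ", "))
  blank <- expr == "" | is.na(expr)
  if (any(blank)) {
    bad <- which(blank, arr.ind = TRUE)[1, ]
    stop_psodt(sprintf(
      "missing expression value in %s (sample '%s', gene '%s')",
      path, sample_ids[bad[1]], gene_names[bad[2]]))
  }
  num <- suppressWarnings(array(as.numeric(expr), dim = dim(expr)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop_psodt(sprintf(
      "non-numeric expression value '%s' in %s (sample '%s', gene '%s')",
      expr[bad[1], bad[2]], path, sample_ids[bad[1]], gene_names[bad[2]]))
  }
  expression_dataset(num, gene_names = gene_names,
                     sample_ids = sample_ids, labels = labels)
}

#' Write an expression dataset as delimited text
#'
#' Samples-in-rows layout: first column sample id, then the label column,
#' then one column per gene. Values are written with 17 significant digits
#' so a write/read round trip is exact.
#'
#' @param dataset an [expression_dataset].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @param label_column header for the label column (default `"class"`).
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(dataset, path, delimiter = "\t",
                                   label_column = "class") {
  vals <- apply(dataset$values, 2, function(col) sprintf("%.17g", col))
  if (n_samples(dataset) == 1) vals <- matrix(vals, nrow = 1)
  out <- cbind(sample = dataset$sample_ids,
               stats::setNames(data.frame(as.character(dataset$labels),
                                          stringsAsFactors = FALSE),
                               label_column),
               as.data.frame(vals, stringsAsFactors = FALSE))
  colnames(out) <- c("sample", label_column, dataset$gene_names)
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Restrict a dataset to the genes flagged by a binary mask
#'
#' @param dataset an [expression_dataset].
#' @param mask logical or 0/1 vector of length `ncol(dataset$values)`;
#'   columns with mask 1 are kept, in their original order.
#' @return an [expression_dataset] with the selected genes; labels and
#'   sample ids unchanged. An all-zero mask yields a zero-gene dataset.
#' @export
subset_genes <- function(dataset, mask) {
  mask <- as_mask(mask, n_genes(dataset))
  ds <- dataset
  ds$values <- dataset$values[, mask, drop = FALSE]
  ds$gene_names <- dataset$gene_names[mask]
  ds
}

#' Restrict a dataset to a subset of samples
#'
#' @param dataset an [expression_dataset].
#' @param idx logical or integer sample index.
#' @return an [expression_dataset]; unused label levels are kept so class
#'   count vectors stay comparable across folds.
#' @export
subset_samples <- function(dataset, idx) {
  ds <- dataset
  ds$values <- dataset$values[idx, , drop = FALSE]
  ds$sample_ids <- dataset$sample_ids[idx]
  ds$labels <- dataset$labels[idx]   # levels preserved deliberately
  ds
}

as_mask <- function(mask, n) {
  if (length(mask) != n)
    stop_psodt("mask length ", length(mask), " != number of genes ", n)
  if (is.logical(mask)) return(mask)
  if (!all(mask %in% c(0, 1)))
    stop_psodt("mask must be logical or contain only 0/1")
  mask == 1
}

#' Write the report files for a repeated-run selection experiment
#'
#' Writes, under `dir`: `runs.tsv` (one row per run: run index, outer-CV
#' accuracy in percent, number of selected genes; footer rows `Avg` and
#' `Std`), `gene_frequency.tsv` (per-gene selection frequency across all
#' outer folds of all runs with the `frequent` flag), and `best_tree.txt`
#' (the final decision tree of the best run, as indented text).
#'
#' @param summary a `psodt_runs` object from [repeat_runs()].
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_selection_report <- function(summary, dir) {
  if (!inherits(summary, "psodt_runs") || length(summary$results) == 0)
    stop_psodt("empty or invalid run summary; nothing written")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop_psodt("cannot create output directory: ", dir)

  runs_path <- file.path(dir, "runs.tsv")
  freq_path <- file.path(dir, "gene_frequency.tsv")
  tree_path <- file.path(dir, "best_tree.txt")

  tab <- summary$runs
  lines <- c("run\taccuracy_pct\tn_selected_genes",
             sprintf("%d\t%.4f\t%d", tab$run, tab$accuracy_pct,
                     tab$n_selected_genes),
             sprintf("Avg\t%.4f\t%.4f", summary$mean_accuracy_pct,
                     summary$mean_n_genes),
             sprintf("Std\t%.4f\t%.4f", summary$sd_accuracy_pct,
                     summary$sd_n_genes))
  writeLines(lines, runs_path)

  fr <- summary$frequency
  writeLines(c("gene\tfrequency\tfrequent",
               sprintf("%s\t%d\t%s", fr$gene, fr$frequency,
                       ifelse(fr$frequent, "yes", "no"))),
             freq_path)

  writeLines(format_tree(summary$best_tree), tree_path)
  invisible(c(runs_path, freq_path, tree_path))
}
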