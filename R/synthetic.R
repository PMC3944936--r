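#' Specification of a synthetic microarray-like dataset
#'
#' A Gaussian class-shift model: every gene's values are
#' `Normal(base_mean, noise_sd)`; each informative gene is assigned one
#' "up" class whose samples have mean `base_mean + effect_size * noise_sd`
#' instead. Defaults emulate a small two-class screen with a handful of
#' planted markers on a noisy background (60 samples, 100 genes, 5
#' informative, effect 3 standard deviations on a log-intensity-like scale).
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes.
#' @param n_informative number of planted informative genes
#'   (`<= n_genes`; 0 gives a pure-noise null dataset).
#' @param n_classes number of classes (>= 2).
#' @param class_proportions per-class proportions summing to 1 (default
#'   uniform). Class sizes are fixed by largest-remainder rounding, so the
#'   majority-class baseline is exact.
#' @param base_mean background mean `mu0` (default 8, log2-intensity-like;
#'   cosmetic only).
#' @param noise_sd within-class standard deviation `sigma` (> 0, default 1).
#' @param effect_size shift `delta` of an informative gene's "up" class, in
#'   units of `noise_sd` (default 3).
#' @return a `synth_spec` list.
#' @export
synth_spec <- function(n_samples = 60, n_genes = 100, n_informative = 5,
                       n_classes = 2, class_proportions = NULL,
                       base_mean = 8, noise_sd = 1, effect_size = 3) {
  if (n_informative > n_genes) stop_psodt("n_informative must be <= n_genes")
  if (n_classes < 2) stop_psodt("n_classes must be >= 2")
  if (noise_sd <= 0) stop_psodt("noise_sd must be > 0")
  if (is.null(class_proportions))
    class_proportions <- rep(1 / n_classes, n_classes)
  if (length(class_proportions) != n_classes ||
      abs(sum(class_proportions) - 1) > 1e-8)
    stop_psodt("class_proportions must have length n_classes and sum to 1")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 n_classes = as.integer(n_classes),
                 class_proportions = class_proportions,
                 base_mean = base_mean, noise_sd = noise_sd,
                 effect_size = effect_size),
            class = "synth_spec")
}

# largest-remainder apportionment of n into shares `prop`
apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    extra <- order(-frac, seq_along(prop))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Generate a synthetic dataset with a known planted gene set
#'
#' Class labels follow the spec proportions (exact counts, shuffled order).
#' Informative gene indices are sampled uniformly so they are interleaved
#' with noise genes, and each is assigned an "up" class in round-robin order
#' over the class levels. Fully deterministic given `seed`.
#'
#' @param spec a [synth_spec].
#' @param seed integer seed (the caller's RNG state is preserved).
#' @return a `synth_dataset`: `dataset` (an [expression_dataset] with gene
#'   names `G000001...` and classes `C1...`), `truth` (data frame of
#'   informative `gene_index`, `gene_name`, `up_class`), `spec`, `seed`.
#' @examples
#' sd1 <- synth_data(synth_spec(n_samples = 20, n_genes = 10,
#'                              n_informative = 2), seed = 1)
#' sd1$truth
#' @export
synth_data <- function(spec, seed) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(seed, {
    n <- spec$n_samples; p <- spec$n_genes
    classes <- paste0("C", seq_len(spec$n_classes))
    counts <- apportion(n, spec$class_proportions)
    if (any(counts < 1)) stop_psodt("every class needs at least one sample")
    labels <- sample(rep(classes, counts))
    values <- matrix(stats::rnorm(n * p, spec$base_mean, spec$noise_sd), n, p)
    info_idx <- sort(sample.int(p, spec$n_informative))
    up_class <- if (spec$n_informative > 0)
      classes[((seq_len(spec$n_informative) - 1L) %% spec$n_classes) + 1L]
    else character(0)
    shift <- spec$effect_size * spec$noise_sd
    for (j in seq_along(info_idx)) {
      rows <- labels == up_class[j]
      values[rows, info_idx[j]] <- values[rows, info_idx[j]] + shift
    }
    gene_names <- sprintf("G%06d", seq_len(p))
    ds <- expression_dataset(values, gene_names = gene_names,
                             sample_ids = sprintf("S%04d", seq_len(n)),
                             labels = factor(labels, levels = classes))
    structure(list(dataset = ds,
                   truth = data.frame(gene_index = info_idx,
                                      gene_name = gene_names[info_idx],
                                      up_class = up_class,
                                      stringsAsFactors = FALSE),
                   spec = spec, seed = seed),
              class = "synth_dataset")
  })
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf(
    "synthetic dataset: %d x %d, %d classes, %d informative genes, seed %d\n",
    x$spec$n_samples, x$spec$n_genes, x$spec$n_classes,
    x$spec$n_informative, x$seed))
  invisible(x)
}

#' Recall and precision of informative-gene recovery
#'
#' Compares a selection against the planted truth. A `selection_result`
#' contributes its union mask; a frequency table (from
#' [gene_selection_frequency()]) contributes its `frequent` genes; a
#' logical/0-1 mask or a character vector of gene names is used as is.
#'
#' @param selected a `selection_result`, a gene-frequency data frame, a
#'   mask, or gene names.
#' @param truth a `synth_dataset`, its `truth` data frame, or a character
#'   vector of informative gene names.
#' @return list with `recall` (`|selected & truth| / |truth|`) and
#'   `precision` (`|selected & truth| / |selected|`; `NA` when nothing is
#'   selected).
#' @export
recovery_metrics <- function(selected, truth) {
  sel_names <-
    if (inherits(selected, "selection_result"))
      selected$gene_names[selected$union_mask]
    else if (is.data.frame(selected) && all(c("gene", "frequent") %in%
                                            names(selected)))
      selected$gene[selected$frequent]
    else if (is.character(selected)) selected
    else if (is.logical(selected)) which(selected)
    else if (is.numeric(selected)) as.integer(selected)
    else stop_psodt("unsupported 'selected' input")
  truth_names <-
    if (inherits(truth, "synth_dataset")) truth$truth$gene_name
    else if (is.data.frame(truth)) truth$gene_name
    else if (is.character(truth)) truth
    else as.integer(truth)
  if (is.numeric(sel_names) != is.numeric(truth_names))
    stop_psodt("'selected' and 'truth' must both be names or both indices")
  hits <- length(intersect(sel_names, truth_names))
  list(recall = if (length(truth_names)) hits / length(truth_names) else NA_real_,
       precision = if (length(sel_names)) hits / length(sel_names) else NA_real_)
}
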