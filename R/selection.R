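#' Stratified k-fold assignment
#'
#' Assigns every sample to one of `k` folds. With stratification, members of
#' each class are shuffled and dealt round-robin, continuing the deal across
#' classes, so per-class fold counts differ by at most one and total fold
#' sizes differ by at most one.
#'
#' @param labels class labels (factor or character).
#' @param k number of folds, `2 <= k <= length(labels)`.
#' @param seed optional seed; caller's RNG state is preserved when given.
#' @param stratified logical (default `TRUE`).
#' @return integer vector of fold ids in `1:k`, one per sample.
#' @export
stratified_folds <- function(labels, k, seed = NULL, stratified = TRUE) {
  labels <- if (is.factor(labels)) labels else factor(labels)
  n <- length(labels)
  k <- as.integer(k)
  if (k < 2 || k > n) stop_psodt("k must be in [2, number of samples]")
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      pos <- 0L
      for (lvl in levels(labels)) {
        idx <- which(labels == lvl)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
        pos <- pos + length(idx)
      }
    } else {
      fold <- sample(rep_len(seq_len(k), n))
    }
    fold
  })
}

# Shared core: mean held-out C4.5 accuracy over precomputed folds.
cv_accuracy_over_folds <- function(dataset, fold_id, tree_params) {
  y <- as.integer(dataset$labels) - 1L
  K <- nlevels(dataset$labels)
  depth <- if (is.null(tree_params$max_depth)) -1L
           else as.integer(tree_params$max_depth)
  accs <- vapply(sort(unique(fold_id)), function(f) {
    te <- fold_id == f
    .cpp_holdout_accuracy(dataset$values[!te, , drop = FALSE], y[!te],
                          dataset$values[te, , drop = FALSE], y[te],
                          K, tree_params$min_samples_leaf, depth)
  }, numeric(1))
  mean(accs)
}

#' Cross-validated C4.5 fitness of a gene mask
#'
#' The PSO fitness: mean held-out accuracy of a C4.5 tree over a stratified
#' k-fold split of `train_data` restricted to the genes flagged by `mask`.
#' An all-zero mask scores the majority-class proportion of `train_data`
#' (the accuracy of the best constant classifier), so degenerate particles
#' are dominated but not fatal.
#'
#' @param mask logical or 0/1 gene-inclusion vector.
#' @param train_data an [expression_dataset].
#' @param k internal folds (default 3).
#' @param tree_params a [c45_params].
#' @param seed optional seed for the fold assignment (RNG state preserved).
#' @param folds optional precomputed fold-id vector, overriding `k`/`seed`.
#' @return fitness in \[0, 1\].
#' @export
cv_fitness <- function(mask, train_data, k = 3, tree_params = c45_params(),
                       seed = NULL, folds = NULL) {
  mask <- as_mask(mask, n_genes(train_data))
  if (!any(mask))
    return(max(table(train_data$labels)) / n_samples(train_data))
  if (is.null(folds)) folds <- stratified_folds(train_data$labels, k, seed)
  cv_accuracy_over_folds(subset_genes(train_data, mask), folds, tree_params)
}

#' Select genes on a training set with binary PSO
#'
#' Runs the binary PSO over gene-inclusion masks on `train_data` alone,
#' scoring each mask with [cv_fitness()] over a fixed internal stratified
#' `inner_k`-fold split. This is the per-fold building block of
#' [run_psodt()]; its result depends only on `train_data` and `seed`.
#'
#' @param train_data an [expression_dataset].
#' @param pso a [pso_params].
#' @param inner_k internal CV folds for the fitness (default 3).
#' @param tree_params a [c45_params].
#' @param seed integer seed covering fold assignment and the swarm.
#' @return list with `mask` (logical), `fitness`, `history`, `iterations`.
#' @export
select_on_training <- function(train_data, pso = pso_params(), inner_k = 3,
                               tree_params = c45_params(), seed) {
  with_seed(seed, {
    inner_folds <- stratified_folds(train_data$labels, inner_k)
    fit_fn <- function(mask)
      cv_fitness(mask, train_data, tree_params = tree_params,
                 folds = inner_folds)
    res <- pso_run(fit_fn, n_genes(train_data), pso)
    list(mask = res$position == 1L, fitness = res$fitness,
         history = res$history, iterations = res$iterations)
  })
}

#' Run the full PSO + decision-tree selection protocol
#'
#' In `"nested"` mode (default, leakage-free): an outer stratified `k`-fold
#' loop; within each fold, gene selection runs on the training portion only
#' ([select_on_training()] with a per-fold derived seed), a final C4.5 tree
#' is trained on the training portion restricted to the selected mask, and
#' accuracy is measured on the held-out fold. Test samples never influence
#' selection or fitting within their fold.
#'
#' In `"naive"` mode the PSO fitness is the k-fold CV accuracy on the whole
#' dataset and the reported accuracy is the best mask's fitness. This is
#' the most literal reading of classic wrapper-selection reports, and it is
#' optimistically biased — provided for comparison only.
#'
#' @param dataset an [expression_dataset].
#' @param pso a [pso_params].
#' @param k outer folds (default 5).
#' @param inner_k internal folds used by the fitness (default 3).
#' @param tree_params a [c45_params].
#' @param mode `"nested"` or `"naive"`.
#' @param seed integer seed (mandatory; everything is derived from it).
#' @param stratified stratify the outer folds (default `TRUE`).
#' @return a `selection_result` with per-fold masks, accuracies, PSO
#'   histories and trees, the mean accuracy, and the union/intersection
#'   masks across folds.
#' @export
run_psodt <- function(dataset, pso = pso_params(), k = 5, inner_k = 3,
                      tree_params = c45_params(),
                      mode = c("nested", "naive"), seed,
                      stratified = TRUE) {
  mode <- match.arg(mode)
  if (missing(seed)) stop_psodt("a seed is required")
  p <- n_genes(dataset)

  if (mode == "naive") {
    sel <- select_on_training(dataset, pso, inner_k = k,
                              tree_params = tree_params, seed = seed)
    tree <- grow_tree(subset_genes(dataset, sel$mask), tree_params)
    fold_masks <- list(sel$mask)
    fold_acc <- sel$fitness
    histories <- list(sel$history)
    trees <- list(tree)
    fold_id <- rep(1L, n_samples(dataset))
    fold_seeds <- seed
  } else {
    seeds <- derive_seeds(seed, k + 1L)
    fold_id <- stratified_folds(dataset$labels, k, seed = seeds[k + 1L],
                                stratified = stratified)
    fold_masks <- vector("list", k)
    fold_acc <- numeric(k)
    histories <- vector("list", k)
    trees <- vector("list", k)
    fold_seeds <- seeds[seq_len(k)]
    for (f in seq_len(k)) {
      te <- fold_id == f
      train <- subset_samples(dataset, !te)
      test <- subset_samples(dataset, te)
      sel <- select_on_training(train, pso, inner_k, tree_params,
                                seed = fold_seeds[f])
      tree <- grow_tree(subset_genes(train, sel$mask), tree_params)
      fold_masks[[f]] <- sel$mask
      fold_acc[f] <- classification_accuracy(tree, subset_genes(test, sel$mask))
      histories[[f]] <- sel$history
      trees[[f]] <- tree
    }
  }

  union_mask <- Reduce(`|`, fold_masks, rep(FALSE, p))
  inter_mask <- Reduce(`&`, fold_masks, rep(TRUE, p))
  structure(list(mode = mode, k = length(fold_masks), inner_k = inner_k,
                 gene_names = dataset$gene_names,
                 fold_id = fold_id, fold_masks = fold_masks,
                 fold_accuracy = fold_acc, histories = histories,
                 trees = trees,
                 mean_accuracy = mean(fold_acc),
                 union_mask = union_mask, n_union = sum(union_mask),
                 intersection_mask = inter_mask,
                 n_intersection = sum(inter_mask),
                 seed = seed, fold_seeds = fold_seeds,
                 pso = pso, tree_params = tree_params),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf(
    "PSODT selection (%s mode): %d fold(s), mean accuracy %.4f\n",
    x$mode, x$k, x$mean_accuracy))
  cat(sprintf("  per-fold accuracy: %s\n",
              paste(sprintf("%.3f", x$fold_accuracy), collapse = " ")))
  cat(sprintf("  genes selected: union %d, intersection %d (of %d)\n",
              x$n_union, x$n_intersection, length(x$gene_names)))
  invisible(x)
}

#' Summary statistics over repeated runs
#'
#' The reporting layer used by [repeat_runs()]: arithmetic mean and sample
#' (n-1) standard deviation of per-run accuracies (in percent) and selected
#' gene counts. With a single run the standard deviation is reported as 0.
#'
#' @param accuracy_pct per-run accuracies in percent.
#' @param n_genes_selected per-run selected-gene counts.
#' @return list `mean_accuracy_pct`, `sd_accuracy_pct`, `mean_n_genes`,
#'   `sd_n_genes`.
#' @export
summarize_runs <- function(accuracy_pct, n_genes_selected) {
  one <- length(accuracy_pct) == 1
  list(mean_accuracy_pct = mean(accuracy_pct),
       sd_accuracy_pct = if (one) 0 else stats::sd(accuracy_pct),
       mean_n_genes = mean(n_genes_selected),
       sd_n_genes = if (one) 0 else stats::sd(n_genes_selected))
}

#' Repeat the selection protocol over several seeded runs
#'
#' Runs [run_psodt()] `n_runs` times with seeds derived from `seed` and
#' reports, per run, the outer-CV accuracy (percent) and the number of
#' selected genes (size of the union of the run's fold masks), together
#' with their mean and sample standard deviation, the pooled gene-selection
#' frequency table, and the final tree of the best run (trained on the full
#' dataset restricted to that run's union mask).
#'
#' @inheritParams run_psodt
#' @param n_runs number of repeated runs (default 5).
#' @param frequency_threshold frequency cutoff for flagging genes as
#'   repeatedly selected (default 4).
#' @return a `psodt_runs` object: `runs` (data frame), summary statistics,
#'   `results` (list of `selection_result`), `frequency`, `best_tree`.
#' @export
repeat_runs <- function(dataset, pso = pso_params(), k = 5, inner_k = 3,
                        tree_params = c45_params(),
                        mode = c("nested", "naive"), n_runs = 5, seed,
                        frequency_threshold = 4) {
  mode <- match.arg(mode)
  if (missing(seed)) stop_psodt("a seed is required")
  if (n_runs < 1) stop_psodt("n_runs must be >= 1")
  run_seeds <- derive_seeds(seed, n_runs)
  results <- lapply(seq_len(n_runs), function(r)
    run_psodt(dataset, pso, k, inner_k, tree_params, mode,
              seed = run_seeds[r]))

  acc_pct <- vapply(results, function(r) 100 * r$mean_accuracy, numeric(1))
  n_sel <- vapply(results, function(r) r$n_union, integer(1))
  stats <- summarize_runs(acc_pct, n_sel)
  freq <- gene_selection_frequency(results, threshold = frequency_threshold)

  best <- which.max(acc_pct)
  best_tree <- grow_tree(subset_genes(dataset, results[[best]]$union_mask),
                         tree_params)

  structure(c(list(runs = data.frame(run = seq_len(n_runs),
                                     accuracy_pct = acc_pct,
                                     n_selected_genes = n_sel),
                   results = results, frequency = freq,
                   best_run = best, best_tree = best_tree,
                   seed = seed, run_seeds = run_seeds, mode = mode),
              stats),
            class = "psodt_runs")
}

#' @export
print.psodt_runs <- function(x, ...) {
  cat(sprintf("PSODT repeated runs (%s mode), seed %d\n", x$mode, x$seed))
  print(x$runs, row.names = FALSE)
  cat(sprintf("Avg accuracy %.2f%% (sd %.2f), avg genes %.1f (sd %.2f)\n",
              x$mean_accuracy_pct, x$sd_accuracy_pct,
              x$mean_n_genes, x$sd_n_genes))
  nf <- sum(x$frequency$frequent)
  cat(sprintf("%d gene(s) selected at least once; %d frequent (>= %d)\n",
              sum(x$frequency$frequency > 0), nf,
              attr(x$frequency, "threshold")))
  invisible(x)
}

#' Gene-selection frequency across folds and runs
#'
#' Counts, for every gene, in how many selection events (outer folds across
#' all supplied results) it was included, and flags genes whose frequency
#' reaches `threshold` — repeatedly selected genes are candidate
#' tissue-specific markers.
#'
#' @param results a `selection_result` or list of them, sharing one gene
#'   namespace.
#' @param threshold frequency cutoff for the `frequent` flag (default 4).
#' @return data frame with columns `gene`, `frequency`, `frequent`, sorted
#'   by decreasing frequency then gene name; attributes `n_events` and
#'   `threshold`.
#' @export
gene_selection_frequency <- function(results, threshold = 4) {
  if (inherits(results, "selection_result")) results <- list(results)
  genes <- results[[1]]$gene_names
  for (r in results)
    if (!identical(r$gene_names, genes))
      stop_psodt("results do not share a common gene namespace")
  freq <- rep(0L, length(genes))
  n_events <- 0L
  for (r in results) {
    for (m in r$fold_masks) freq <- freq + as.integer(m)
    n_events <- n_events + length(r$fold_masks)
  }
  ord <- order(-freq, genes)
  out <- data.frame(gene = genes[ord], frequency = freq[ord],
                    frequent = freq[ord] >= threshold,
                    stringsAsFactors = FALSE)
  attr(out, "n_events") <- n_events
  attr(out, "threshold") <- threshold
  out
}
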