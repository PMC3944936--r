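#' C4.5 hyperparameters
#'
#' @param min_samples_leaf minimum training samples each branch of a split
#'   must receive (default 2).
#' @param prune logical; apply pessimistic-error subtree replacement after
#'   growing (default `FALSE` — pruning is off inside the PSO fitness loop
#'   for speed and switched on, if desired, for final-model reporting).
#' @param confidence confidence parameter of the pessimistic error bound,
#'   in (0, 1) (default 0.25). Smaller values prune more aggressively.
#' @param max_depth optional depth cap (`NULL` = unlimited).
#' @return a `c45_params` list.
#' @export
c45_params <- function(min_samples_leaf = 2L, prune = FALSE,
                       confidence = 0.25, max_depth = NULL) {
  min_samples_leaf <- as.integer(min_samples_leaf)
  if (min_samples_leaf < 1L) stop_psodt("min_samples_leaf must be >= 1")
  if (!(confidence > 0 && confidence < 1))
    stop_psodt("confidence must be in (0, 1)")
  if (!is.null(max_depth) && max_depth < 0)
    stop_psodt("max_depth must be NULL or >= 0")
  structure(list(min_samples_leaf = min_samples_leaf, prune = prune,
                 confidence = confidence, max_depth = max_depth),
            class = "c45_params")
}

#' Shannon entropy of a class-count vector, in bits
#'
#' @param class_counts non-negative integer counts per class; at least one
#'   must be positive.
#' @return `-sum(p * log2(p))` over classes with positive count. 0 for a
#'   pure node; at most `log2(length(class_counts))`.
#' @examples
#' entropy(c(2, 2))  # 1
#' entropy(c(9, 5))  # 0.940286
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop_psodt("class counts must be non-negative")
  n <- sum(class_counts)
  if (n == 0) stop_psodt("entropy undefined for all-zero counts")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

#' Candidate split thresholds for a continuous feature
#'
#' Midpoints between consecutive distinct sorted values — the classic C4.5
#' treatment of continuous attributes.
#'
#' @param values numeric vector of observed values.
#' @return increasing numeric vector of thresholds; empty if fewer than two
#'   distinct values.
#' @export
candidate_thresholds <- function(values) {
  s <- sort(unique(values))
  if (length(s) < 2) return(numeric(0))
  (s[-1] + s[-length(s)]) / 2
}

#' Information gain, split information and gain ratio of one threshold test
#'
#' Scores the binary partition `values <= threshold` vs `> threshold`.
#'
#' @param values numeric feature vector.
#' @param labels class labels (factor or character), same length.
#' @param threshold split point; must leave both branches non-empty.
#' @return list with `information_gain`, `split_info`, `gain_ratio`
#'   (all in bits; `gain_ratio` is their quotient).
#' @export
split_scores <- function(values, labels, threshold) {
  labels <- if (is.factor(labels)) labels else factor(labels)
  left <- values <= threshold
  nL <- sum(left); nR <- sum(!left); n <- length(values)
  if (nL == 0 || nR == 0)
    stop_psodt("threshold leaves an empty branch; use candidate_thresholds()")
  hP <- entropy(tabulate(labels, nlevels(labels)))
  hL <- entropy(tabulate(labels[left], nlevels(labels)))
  hR <- entropy(tabulate(labels[!left], nlevels(labels)))
  gain <- hP - (nL / n) * hL - (nR / n) * hR
  si <- entropy(c(nL, nR))
  list(information_gain = gain, split_info = si, gain_ratio = gain / si)
}

#' Best gain-ratio split at a node
#'
#' Evaluates every gene and every candidate threshold; among candidates with
#' information gain > 0 and both branches receiving at least
#' `min_samples_leaf` samples, returns the one maximizing gain ratio.
#' Ties break to higher information gain, then lower gene index, then lower
#' threshold, so induction is fully deterministic.
#'
#' @param dataset an [expression_dataset] restricted to the node's samples.
#' @param params a [c45_params] object.
#' @return list with `gene_index`, `gene_name`, `threshold`, `gain`,
#'   `split_info`, `gain_ratio`, or `NULL` when no candidate qualifies.
#' @export
best_split <- function(dataset, params = c45_params()) {
  y <- as.integer(dataset$labels) - 1L
  res <- .cpp_best_split(dataset$values, y, nlevels(dataset$labels),
                         params$min_samples_leaf)
  if (is.null(res)) return(NULL)
  res$gene_name <- dataset$gene_names[res$gene_index]
  res
}

#' Grow a C4.5 decision tree
#'
#' Recursive induction with binary threshold tests chosen by [best_split()].
#' A node becomes a leaf when it is pure, no split qualifies, or the depth
#' cap is reached; the leaf predicts the majority class (tie: earliest label
#' level). A zero-gene dataset yields a single majority-class leaf. If
#' `params$prune` is set the grown tree is post-pruned with [prune_tree()].
#'
#' @param dataset an [expression_dataset].
#' @param params a [c45_params] object.
#' @return an object of class `c45_tree`.
#' @examples
#' ds <- expression_dataset(matrix(c(1, 2, 3, 4), 4, 1,
#'                                 dimnames = list(NULL, "g1")),
#'                          labels = c("A", "A", "B", "B"))
#' tr <- grow_tree(ds)
#' print(tr)
#' @export
grow_tree <- function(dataset, params = c45_params()) {
  if (n_samples(dataset) == 0) stop_psodt("cannot grow a tree on 0 samples")
  y <- as.integer(dataset$labels) - 1L
  depth <- if (is.null(params$max_depth)) -1L else as.integer(params$max_depth)
  flat <- .cpp_grow(dataset$values, y, nlevels(dataset$labels),
                    params$min_samples_leaf, depth)
  colnames(flat$counts) <- levels(dataset$labels)
  tree <- structure(c(flat, list(labels = levels(dataset$labels),
                                 gene_names = dataset$gene_names,
                                 params = params)),
                    class = "c45_tree")
  if (isTRUE(params$prune)) tree <- prune_tree(tree, params)
  tree
}

n_nodes <- function(tree) length(tree$gene)

is_leaf_node <- function(tree, i) is.na(tree$gene[i])

#' Pessimistic-error subtree replacement
#'
#' Bottom-up pruning in the C4.5 spirit: a subtree is replaced by a leaf
#' when the leaf's pessimistic error count is no larger than the sum of its
#' leaves' pessimistic error counts. The pessimistic error rate of a node
#' with `n` samples and `e` training errors is the exact binomial
#' (Clopper-Pearson) upper confidence limit `qbeta(1 - confidence, e + 1,
#' n - e)`; the error count is `n` times that rate. No-op unless
#' `params$prune` is `TRUE`.
#'
#' @param tree a `c45_tree`.
#' @param params a [c45_params]; `confidence` sets the bound level.
#' @return a `c45_tree` with at most as many nodes as the input.
#' @export
prune_tree <- function(tree, params = c45_params()) {
  if (!isTRUE(params$prune)) return(tree)
  conf <- params$confidence

  pess <- function(counts) {
    n <- sum(counts)
    e <- n - max(counts)
    u <- if (e >= n) 1 else stats::qbeta(1 - conf, e + 1, n - e)
    n * u
  }

  # returns list(keep_ids); collapse decided per subtree
  out <- list(gene = integer(0), threshold = numeric(0), left = integer(0),
              right = integer(0), pred = integer(0),
              counts = matrix(0L, 0, ncol(tree$counts)))

  build_leaf <- function(counts) {
    id <- length(out$gene) + 1L
    out$gene[id] <<- NA_integer_
    out$threshold[id] <<- NA_real_
    out$left[id] <<- NA_integer_
    out$right[id] <<- NA_integer_
    out$pred[id] <<- which.max(counts)
    out$counts <<- rbind(out$counts, counts)
    id
  }

  # prune node i of the original tree; append to `out`; return
  # list(id in out, summed pessimistic error of its leaves)
  recurse <- function(i) {
    counts <- tree$counts[i, ]
    if (is_leaf_node(tree, i))
      return(list(id = build_leaf(counts), err = pess(counts)))
    id <- length(out$gene) + 1L
    out$gene[id] <<- tree$gene[i]
    out$threshold[id] <<- tree$threshold[i]
    out$left[id] <<- NA_integer_; out$right[id] <<- NA_integer_
    out$pred[id] <<- tree$pred[i]
    out$counts <<- rbind(out$counts, counts)
    l <- recurse(tree$left[i])
    r <- recurse(tree$right[i])
    subtree_err <- l$err + r$err
    leaf_err <- pess(counts)
    if (leaf_err <= subtree_err) {
      # drop everything appended for this subtree; emit a leaf instead
      keep <- seq_len(id - 1L)
      out$gene <<- out$gene[keep]; out$threshold <<- out$threshold[keep]
      out$left <<- out$left[keep]; out$right <<- out$right[keep]
      out$pred <<- out$pred[keep]
      out$counts <<- out$counts[keep, , drop = FALSE]
      return(list(id = build_leaf(counts), err = leaf_err))
    }
    out$left[id] <<- l$id
    out$right[id] <<- r$id
    list(id = id, err = subtree_err)
  }

  recurse(1L)
  colnames(out$counts) <- colnames(tree$counts)
  rownames(out$counts) <- NULL
  structure(c(out, list(labels = tree$labels, gene_names = tree$gene_names,
                        params = params)),
            class = "c45_tree")
}

# Resolve newdata (dataset, matrix/data.frame with named columns, or a named
# numeric vector = one sample) into a matrix aligned with the tree's
# training gene order; absent genes become NA and only fault if a traversal
# actually needs them.
resolve_newdata <- function(tree, newdata) {
  if (inherits(newdata, "expression_dataset")) {
    m <- newdata$values
  } else if (is.numeric(newdata) && is.null(dim(newdata))) {
    m <- matrix(newdata, nrow = 1, dimnames = list(NULL, names(newdata)))
  } else {
    m <- as.matrix(newdata)
  }
  X <- matrix(NA_real_, nrow(m), length(tree$gene_names))
  if (is.null(colnames(m))) {
    if (ncol(m) != length(tree$gene_names))
      stop_psodt("unnamed newdata must have one column per training gene")
    X[] <- m
  } else {
    hit <- match(tree$gene_names, colnames(m))
    found <- !is.na(hit)
    X[, found] <- m[, hit[found], drop = FALSE]
  }
  X
}

#' Predict class labels with a C4.5 tree
#'
#' Deterministic root-to-leaf traversal; at each internal node the left
#' branch is taken when `value <= threshold`, the right branch otherwise.
#' A sample must provide a value for every gene its traversal visits;
#' hitting a missing value is a hard error naming the gene.
#'
#' @param object a `c45_tree`.
#' @param newdata an [expression_dataset], a matrix/data.frame with gene
#'   names as column names, or a named numeric vector for a single sample.
#' @param ... unused.
#' @return character vector of predicted class labels.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  X <- resolve_newdata(object, newdata)
  out <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    node <- 1L
    while (!is.na(object$gene[node])) {
      v <- X[i, object$gene[node]]
      if (is.na(v))
        stop_psodt("sample ", i, " lacks a value for gene ",
                   object$gene_names[object$gene[node]])
      node <- if (v <= object$threshold[node]) object$left[node]
              else object$right[node]
    }
    out[i] <- object$labels[object$pred[node]]
  }
  out
}

#' Classification accuracy of a tree on a labelled dataset
#'
#' @param tree a `c45_tree`.
#' @param dataset an [expression_dataset].
#' @return fraction of correctly classified samples, in \[0, 1\].
#' @export
classification_accuracy <- function(tree, dataset) {
  if (n_samples(dataset) == 0) stop_psodt("empty dataset")
  mean(predict(tree, dataset) == as.character(dataset$labels))
}

#' Format a tree as indented text
#'
#' One test per line (`gene <= thr` / `gene > thr`); leaves shown as
#' `class (n)` where `n` is the number of training samples at the leaf.
#'
#' @param tree a `c45_tree`.
#' @return character vector of lines.
#' @export
format_tree <- function(tree) {
  lines <- character(0)
  rec <- function(i, indent) {
    pad <- strrep("  ", indent)
    if (is_leaf_node(tree, i)) {
      lines[[length(lines) + 1]] <<- sprintf(
        "%s%s (%d)", pad, tree$labels[tree$pred[i]], sum(tree$counts[i, ]))
      return(invisible())
    }
    g <- tree$gene_names[tree$gene[i]]
    thr <- format(tree$threshold[i], digits = 15)
    lines[[length(lines) + 1]] <<- sprintf("%s%s <= %s", pad, g, thr)
    rec(tree$left[i], indent + 1)
    lines[[length(lines) + 1]] <<- sprintf("%s%s > %s", pad, g, thr)
    rec(tree$right[i], indent + 1)
  }
  rec(1L, 0)
  unlist(lines)
}

#' @export
print.c45_tree <- function(x, ...) {
  cat(sprintf("C4.5 tree: %d nodes, classes: %s\n", n_nodes(x),
              paste(x$labels, collapse = ", ")))
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

# Hand-build a c45_tree from a nested description, e.g. for fixture trees:
#   node: list(gene = "name", threshold = t, left = ..., right = ...)
#   leaf: list(label = "class")
# Counts are filled with zeros (structure-only trees for prediction tests).
build_tree <- function(node, gene_names, labels) {
  flat <- list(gene = integer(0), threshold = numeric(0), left = integer(0),
               right = integer(0), pred = integer(0))
  counts <- NULL
  rec <- function(nd) {
    id <- length(flat$gene) + 1L
    if (!is.null(nd$label)) {
      flat$gene[id] <<- NA_integer_; flat$threshold[id] <<- NA_real_
      flat$left[id] <<- NA_integer_; flat$right[id] <<- NA_integer_
      flat$pred[id] <<- match(nd$label, labels)
      counts <<- rbind(counts, rep(0L, length(labels)))
      return(id)
    }
    flat$gene[id] <<- match(nd$gene, gene_names)
    flat$threshold[id] <<- nd$threshold
    flat$left[id] <<- NA_integer_; flat$right[id] <<- NA_integer_
    flat$pred[id] <<- NA_integer_
    counts <<- rbind(counts, rep(0L, length(labels)))
    l <- rec(nd$left); flat$left[id] <<- l
    r <- rec(nd$right); flat$right[id] <<- r
    id
  }
  rec(node)
  colnames(counts) <- labels
  structure(c(flat, list(counts = counts, labels = labels,
                         gene_names = gene_names, params = c45_params())),
            class = "c45_tree")
}
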