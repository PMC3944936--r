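# Shared fixtures and independent oracles for the test suite.

# Small labelled dataset builder.
make_ds <- function(values, labels, gene_names = NULL) {
  m <- as.matrix(values)
  if (is.null(gene_names))
    gene_names <- if (ncol(m) > 0) paste0("g", seq_len(ncol(m))) else character(0)
  if (ncol(m) > 0) colnames(m) <- gene_names
  expression_dataset(m, gene_names = gene_names, labels = labels)
}

# ---- Independent brute-force gain-ratio oracle -----------------------------
# Recomputes entropy / gain / gain ratio from first principles, separate from
# the package's scoring path, for oracle-equivalence checks.
oracle_entropy <- function(y) {
  p <- as.numeric(table(y)) / length(y)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_best_split <- function(X, y, min_leaf = 1, eps = 1e-12) {
  best <- NULL
  n <- length(y)
  for (g in seq_len(ncol(X))) {
    v <- X[, g]
    s <- sort(unique(v))
    if (length(s) < 2) next
    for (thr in (s[-1] + s[-length(s)]) / 2) {
      L <- v <= thr
      nL <- sum(L); nR <- n - nL
      if (nL < min_leaf || nR < min_leaf) next
      gain <- oracle_entropy(y) -
        (nL / n) * oracle_entropy(y[L]) - (nR / n) * oracle_entropy(y[!L])
      if (gain <= eps) next
      si <- -(nL / n) * log2(nL / n) - (nR / n) * log2(nR / n)
      ratio <- gain / si
      if (is.null(best) || ratio > best$ratio + eps ||
          (abs(ratio - best$ratio) <= eps && gain > best$gain + eps))
        best <- list(gene = g, threshold = thr, gain = gain, ratio = ratio)
    }
  }
  best
}

random_tiny_case <- function() {
  n <- sample(2:6, 1)
  p <- sample(1:3, 1)
  X <- matrix(sample(1:3, n * p, replace = TRUE), n, p)
  y <- sample(c("A", "B"), n, replace = TRUE)
  list(X = X, y = y)
}

# ---- Three-gene female-cancer fixture tree ---------------------------------
# Root: 218934_s_at > 2.7133 -> uterus; else 206166_s_at > 2.5063 -> cervix
# uteri; else 212341_at <= 10.026 -> ovary, > 10.026 -> cervix uteri.
female_cancer_tree <- function() {
  genes <- c("218934_s_at", "206166_s_at", "212341_at")
  labels <- c("cervix uteri", "ovary", "uterus")
  psodt:::build_tree(
    list(gene = "218934_s_at", threshold = 2.7133,
         left = list(gene = "206166_s_at", threshold = 2.5063,
                     left = list(gene = "212341_at", threshold = 10.026,
                                 left = list(label = "ovary"),
                                 right = list(label = "cervix uteri")),
                     right = list(label = "cervix uteri")),
         right = list(label = "uterus")),
    genes, labels)
}

# Build a c45_tree directly from flat arrays (for pruning tests that need
# specific class-count configurations).
flat_tree <- function(gene, threshold, left, right, pred, counts, labels,
                      gene_names) {
  colnames(counts) <- labels
  structure(list(gene = as.integer(gene), threshold = as.numeric(threshold),
                 left = as.integer(left), right = as.integer(right),
                 pred = as.integer(pred), counts = counts,
                 labels = labels, gene_names = gene_names,
                 params = c45_params()),
            class = "c45_tree")
}

# Exact binomial pessimistic error count, computed here independently.
pess_errors <- function(counts, conf = 0.25) {
  n <- sum(counts); e <- n - max(counts)
  u <- if (e >= n) 1 else qbeta(1 - conf, e + 1, n - e)
  n * u
}
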