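test_that("entropy matches closed forms and rejects degenerate input", {
  expect_equal(entropy(c(2, 2)), 1.0)
  expect_equal(entropy(c(4, 0)), 0.0)
  expect_equal(entropy(c(9, 5)),
               -(9 / 14) * log2(9 / 14) - (5 / 14) * log2(5 / 14))
  expect_lte(entropy(c(3, 1, 2)), log2(3))
  expect_error(entropy(c(0, 0)), "all-zero")
})

test_that("candidate thresholds are midpoints of distinct sorted values", {
  expect_equal(candidate_thresholds(c(1, 2, 3)), c(1.5, 2.5))
  expect_equal(candidate_thresholds(c(5, 5, 5)), numeric(0))
  expect_equal(candidate_thresholds(c(2, 1)), 1.5)
})

test_that("split scoring: gain, split info and ratio on hand-computed cases", {
  s <- split_scores(c(1, 2, 3, 4), c("A", "A", "B", "B"), 2.5)
  expect_equal(s$information_gain, 1.0)
  expect_equal(s$split_info, 1.0)
  expect_equal(s$gain_ratio, 1.0)

  # children with the parent's class proportions carry no information
  s0 <- split_scores(c(1, 2, 3, 4), c("A", "B", "A", "B"), 2.5)
  expect_equal(s0$information_gain, 0, tolerance = 1e-12)

  expect_error(split_scores(c(1, 2), c("A", "B"), 5), "empty branch")
})

test_that("best_split picks the qualifying gain-ratio maximum with deterministic ties", {
  # one separating gene among constants
  ds <- make_ds(cbind(c(5, 5, 5, 5), c(1, 2, 3, 4)), c("A", "A", "B", "B"))
  bs <- best_split(ds, c45_params(min_samples_leaf = 1))
  expect_equal(bs$gene_index, 2)
  expect_equal(bs$threshold, 2.5)

  # all constant -> none
  expect_null(best_split(make_ds(cbind(c(1, 1), c(2, 2)), c("A", "B")),
                         c45_params(min_samples_leaf = 1)))

  # identical scores -> lower gene index wins
  ds2 <- make_ds(cbind(c(1, 2, 3, 4), c(1, 2, 3, 4)), c("A", "A", "B", "B"))
  expect_equal(best_split(ds2, c45_params(min_samples_leaf = 1))$gene_index, 1)

  # min_samples_leaf gates the only available (isolating) threshold
  ds3 <- make_ds(matrix(c(1, 1, 1, 10), 4, 1), c("A", "A", "A", "B"))
  expect_null(best_split(ds3, c45_params(min_samples_leaf = 2)))
})

test_that("best_split agrees with the brute-force oracle on random tiny cases", {
  set.seed(401)
  for (i in 1:300) {
    case <- random_tiny_case()
    ds <- make_ds(case$X, case$y)
    got <- best_split(ds, c45_params(min_samples_leaf = 1))
    want <- oracle_best_split(case$X, factor(case$y), min_leaf = 1)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$gene_index, want$gene)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$gain_ratio, want$ratio, tolerance = 1e-10)
    }
  }
})

test_that("tree growth: unique optimal split, pure leaf, zero-gene majority leaf", {
  ds <- make_ds(matrix(c(1, 2, 3, 4), 4, 1), c("A", "A", "B", "B"))
  tr <- grow_tree(ds, c45_params(min_samples_leaf = 1))
  expect_equal(psodt:::n_nodes(tr), 3)
  expect_equal(tr$threshold[1], 2.5)
  expect_equal(predict(tr, ds), c("A", "A", "B", "B"))

  pure <- grow_tree(make_ds(matrix(1:3, 3, 1), c("A", "A", "A")))
  expect_equal(psodt:::n_nodes(pure), 1)
  expect_equal(pure$labels[pure$pred[1]], "A")

  empty <- grow_tree(subset_genes(make_ds(matrix(1:3, 3, 1),
                                          c("A", "A", "B")), 0))
  expect_equal(psodt:::n_nodes(empty), 1)
  expect_equal(predict(empty, make_ds(matrix(0, 1, 0), "A")), "A")
})

test_that("leaf majority ties resolve to the earliest class level", {
  ds <- make_ds(matrix(c(1, 1, 1, 1), 4, 1), c("B", "A", "B", "A"))
  tr <- grow_tree(ds)
  expect_equal(predict(tr, ds), rep("A", 4))
})

test_that("internal-node class counts equal the sum of their children's", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(8:25, 1)
    ds <- make_ds(matrix(runif(n * 4), n, 4),
                  sample(c("A", "B", "C"), n, replace = TRUE))
    tr <- grow_tree(ds, c45_params(min_samples_leaf = 1))
    for (j in seq_along(tr$gene)) {
      if (!is.na(tr$gene[j])) {
        expect_equal(tr$counts[j, ],
                     tr$counts[tr$left[j], ] + tr$counts[tr$right[j], ])
        # non-degenerate test: both branches trained on >= 1 sample
        expect_gte(sum(tr$counts[tr$left[j], ]), 1)
        expect_gte(sum(tr$counts[tr$right[j], ]), 1)
      }
    }
  }
})

test_that("relabeling classes permutes predictions but not structure or accuracy", {
  set.seed(78)
  n <- 20
  X <- matrix(runif(n * 3), n, 3)
  y <- sample(c("A", "B", "C"), n, replace = TRUE)
  swap <- c(A = "C", B = "A", C = "B")
  ds1 <- make_ds(X, y)
  ds2 <- make_ds(X, unname(swap[y]))
  t1 <- grow_tree(ds1, c45_params(min_samples_leaf = 1))
  t2 <- grow_tree(ds2, c45_params(min_samples_leaf = 1))
  expect_equal(t1$gene, t2$gene)
  expect_equal(t1$threshold, t2$threshold)
  expect_equal(unname(swap[predict(t1, ds1)]), predict(t2, ds2))
  expect_equal(classification_accuracy(t1, ds1),
               classification_accuracy(t2, ds2))
})

test_that("strictly increasing transforms of one gene leave branching unchanged", {
  set.seed(79)
  n <- 24
  X <- matrix(runif(n * 3), n, 3)
  y <- sample(c("A", "B"), n, replace = TRUE)
  t1 <- grow_tree(make_ds(X, y), c45_params(min_samples_leaf = 1))
  X2 <- X
  X2[, 2] <- exp(3 * X2[, 2])   # strictly increasing
  t2 <- grow_tree(make_ds(X2, y), c45_params(min_samples_leaf = 1))
  expect_equal(t1$gene, t2$gene)
  expect_equal(predict(t1, make_ds(X, y)), predict(t2, make_ds(X2, y)))
})

test_that("prediction follows the <=/> convention and flags missing genes", {
  tr <- female_cancer_tree()
  # only the genes on the traversal path are needed
  expect_equal(predict(tr, c("218934_s_at" = 3.0)), "uterus")
  expect_error(predict(tr, c("218934_s_at" = 2.0)), "206166_s_at")
  # boundary value goes left (<=)
  expect_equal(predict(tr, c("218934_s_at" = 2.7133, "206166_s_at" = 3.0,
                             "212341_at" = 0)), "cervix uteri")
})

test_that("accuracy counts correct predictions over a dataset", {
  ds <- make_ds(matrix(c(1, 2, 3), 3, 1), c("A", "A", "B"))
  tr <- grow_tree(subset_genes(ds, 0))  # majority leaf "A"
  expect_equal(classification_accuracy(tr, ds), 2 / 3)
  other <- make_ds(matrix(c(1, 2), 2, 1), c("B", "B"))
  expect_equal(classification_accuracy(tr, other), 0)
  consistent <- make_ds(matrix(runif(10), 10, 1),
                        rep(c("A", "B"), each = 5))
  full <- grow_tree(consistent, c45_params(min_samples_leaf = 1))
  expect_equal(classification_accuracy(full, consistent), 1.0)
})

test_that("pessimistic bound decides subtree replacement, computed independently", {
  labels <- c("A", "B")
  # split with no error reduction: children repeat the parent majority
  same <- flat_tree(gene = c(1, NA, NA), threshold = c(0.5, NA, NA),
                    left = c(2, NA, NA), right = c(3, NA, NA),
                    pred = c(1, 1, 1),
                    counts = rbind(c(12, 2), c(6, 1), c(6, 1)),
                    labels = labels, gene_names = "g1")
  expect_lte(pess_errors(c(12, 2)),
             pess_errors(c(6, 1)) + pess_errors(c(6, 1)))
  pr <- prune_tree(same, c45_params(prune = TRUE))
  expect_equal(psodt:::n_nodes(pr), 1)
  expect_equal(pr$labels[pr$pred[1]], "A")

  # a perfect split isolating 1 of 21 samples reduces the pessimistic error
  # and is kept at confidence 0.25 (leaf bound 2.586 > subtree bound 2.089)
  iso <- flat_tree(gene = c(1, NA, NA), threshold = c(0.5, NA, NA),
                   left = c(2, NA, NA), right = c(3, NA, NA),
                   pred = c(1, 1, 2),
                   counts = rbind(c(20, 1), c(20, 0), c(0, 1)),
                   labels = labels, gene_names = "g1")
  expect_gt(pess_errors(c(20, 1)),
            pess_errors(c(20, 0)) + pess_errors(c(0, 1)))
  kept <- prune_tree(iso, c45_params(prune = TRUE))
  expect_equal(psodt:::n_nodes(kept), 3)

  # disabled pruning is the identity
  expect_identical(prune_tree(iso, c45_params(prune = FALSE)), iso)
})

test_that("pruning shrinks trees monotonically and preserves no-op predictions", {
  set.seed(80)
  n <- 40
  ds <- make_ds(matrix(runif(n * 5), n, 5),
                sample(c("A", "B"), n, replace = TRUE))
  grown <- grow_tree(ds, c45_params(min_samples_leaf = 1))
  pruned <- prune_tree(grown, c45_params(prune = TRUE))
  expect_lte(psodt:::n_nodes(pruned), psodt:::n_nodes(grown))
  if (identical(psodt:::n_nodes(pruned), psodt:::n_nodes(grown)))
    expect_equal(predict(pruned, ds), predict(grown, ds))
})
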