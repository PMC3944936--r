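test_that("stratified folds balance classes and totals deterministically", {
  lab <- rep(c("A", "B"), each = 5)
  f <- stratified_folds(lab, 5, seed = 1)
  for (k in 1:5) {
    expect_equal(sum(f == k & lab == "A"), 1)
    expect_equal(sum(f == k & lab == "B"), 1)
  }

  f7 <- stratified_folds(rep("A", 7), 5, seed = 2)
  expect_equal(sort(tabulate(f7, 5), decreasing = TRUE), c(2, 2, 1, 1, 1))

  expect_identical(stratified_folds(lab, 5, seed = 3),
                   stratified_folds(lab, 5, seed = 3))
  expect_error(stratified_folds(lab, 11), "k must be")

  # multi-class: per-class counts differ by at most one in every fold
  set.seed(4)
  lab3 <- sample(rep(c("A", "B", "C"), c(13, 9, 7)))
  f3 <- stratified_folds(lab3, 4, seed = 4)
  for (cl in c("A", "B", "C")) {
    per <- tabulate(f3[lab3 == cl], 4)
    expect_lte(diff(range(per)), 1)
  }
  expect_lte(diff(range(tabulate(f3, 4))), 1)
})

test_that("cv fitness: separable gene scores 1, empty mask scores the baseline", {
  set.seed(12)
  n <- 30
  x <- c(rnorm(n / 2, 0), rnorm(n / 2, 20))  # far-apart classes
  ds <- make_ds(cbind(x, rnorm(n)), rep(c("A", "B"), each = n / 2))
  expect_equal(cv_fitness(c(1, 0), ds, k = 3, seed = 1), 1.0)

  lab <- c(rep("A", 18), rep("B", 12))       # 60% majority
  ds2 <- make_ds(matrix(rnorm(60), 30, 2), lab)
  expect_equal(cv_fitness(c(0, 0), ds2), 0.6)
  expect_error(cv_fitness(c(1, 0, 0), ds2), "mask length")
})

test_that("cv fitness under permuted labels stays at the chance level", {
  set.seed(13)
  n <- 40
  ds <- make_ds(matrix(rnorm(n * 5), n, 5), rep(c("A", "B"), each = n / 2))
  fits <- vapply(1:20, function(i) {
    perm <- ds
    perm$labels <- sample(ds$labels)
    cv_fitness(c(1, 1, 0, 0, 0), perm, k = 3, seed = i)
  }, numeric(1))
  expect_true(all(fits >= 0 & fits <= 1))
  # 99% t-interval for the mean of the 20 permutation fitnesses around 0.5
  expect_lte(abs(mean(fits) - 0.5),
             qt(0.995, 19) * sd(fits) / sqrt(20))
})

test_that("nested protocol: per-fold masks come only from training data", {
  sdset <- synth_data(synth_spec(n_samples = 30, n_genes = 20,
                                 n_informative = 2, effect_size = 4),
                      seed = 7)
  res <- run_psodt(sdset$dataset, pso_params(n_particles = 5, max_iter = 5),
                   k = 3, inner_k = 3, seed = 7)
  for (f in seq_len(res$k)) {
    train <- subset_samples(sdset$dataset, res$fold_id != f)
    redo <- select_on_training(train, pso_params(n_particles = 5, max_iter = 5),
                               inner_k = 3, seed = res$fold_seeds[f])
    expect_identical(redo$mask, res$fold_masks[[f]])
  }
})

test_that("selection run is reproducible and degrades gracefully on constant genes", {
  sdset <- synth_data(synth_spec(n_samples = 24, n_genes = 10,
                                 n_informative = 2), seed = 3)
  p <- pso_params(n_particles = 4, max_iter = 4)
  a <- run_psodt(sdset$dataset, p, k = 3, inner_k = 3, seed = 17)
  b <- run_psodt(sdset$dataset, p, k = 3, inner_k = 3, seed = 17)
  expect_identical(a[setdiff(names(a), "trees")], b[setdiff(names(b), "trees")])
  expect_equal(a$mean_accuracy, mean(a$fold_accuracy))
  expect_true(all(a$fold_accuracy >= 0 & a$fold_accuracy <= 1))

  flat <- make_ds(matrix(1, 12, 1), rep(c("A", "A", "B"), 4))
  r <- run_psodt(flat, pso_params(n_particles = 3, max_iter = 3),
                 k = 3, inner_k = 3, seed = 2)
  expect_true(all(abs(r$fold_accuracy - 2 / 3) < 0.35))
})

test_that("naive mode reports the whole-data CV fitness of one PSO run", {
  sdset <- synth_data(synth_spec(n_samples = 24, n_genes = 10,
                                 n_informative = 2, effect_size = 4),
                      seed = 9)
  r <- run_psodt(sdset$dataset, pso_params(n_particles = 4, max_iter = 4),
                 k = 3, mode = "naive", seed = 9)
  expect_equal(r$k, 1)
  expect_length(r$fold_masks, 1)
  expect_equal(r$mean_accuracy, r$fold_accuracy)
})

test_that("run summaries: single-run sd convention and repeated-run shape", {
  s1 <- summarize_runs(97.5, 10)
  expect_equal(s1$sd_accuracy_pct, 0)

  # weak signal so the fitness trace does not saturate at 1 immediately
  sdset <- synth_data(synth_spec(n_samples = 24, n_genes = 20,
                                 n_informative = 2, effect_size = 1),
                      seed = 19)
  summ <- repeat_runs(sdset$dataset, pso_params(n_particles = 4, max_iter = 6),
                      k = 3, inner_k = 3, n_runs = 3, seed = 19)
  expect_equal(nrow(summ$runs), 3)
  expect_equal(summ$mean_accuracy_pct, mean(summ$runs$accuracy_pct))
  expect_equal(summ$sd_accuracy_pct, sd(summ$runs$accuracy_pct))
  expect_equal(summ$runs$n_selected_genes,
               vapply(summ$results, function(r) r$n_union, integer(1)))
  expect_length(unique(summ$run_seeds), 3)
  # distinct derived seeds: the runs' selections and traces differ somewhere
  expect_false(identical(
    list(summ$results[[1]]$histories, summ$results[[1]]$fold_masks),
    list(summ$results[[2]]$histories, summ$results[[2]]$fold_masks)))
})

test_that("gene frequencies count selection events and flag repeated genes", {
  genes <- paste0("g", 1:4)
  mk <- function(masks) structure(list(gene_names = genes, fold_masks = masks),
                                  class = "selection_result")
  r1 <- mk(list(c(TRUE, TRUE, FALSE, FALSE), c(TRUE, FALSE, TRUE, FALSE),
                c(TRUE, FALSE, FALSE, FALSE), c(TRUE, TRUE, FALSE, FALSE),
                c(TRUE, FALSE, TRUE, FALSE)))
  tab <- gene_selection_frequency(r1)
  expect_equal(tab$frequency[tab$gene == "g1"], 5)
  expect_true(tab$frequent[tab$gene == "g1"])
  expect_equal(tab$frequency[tab$gene == "g2"], 2)
  expect_false(tab$frequent[tab$gene == "g2"])
  expect_equal(tab$frequency[tab$gene == "g4"], 0)
  expect_equal(attr(tab, "n_events"), 5)
  # sorted by frequency, then name
  expect_equal(tab$gene[1], "g1")

  # adding a run can only keep or increase frequencies
  r2 <- mk(list(c(FALSE, TRUE, FALSE, TRUE)))
  tab2 <- gene_selection_frequency(list(r1, r2))
  m1 <- tab$frequency[order(tab$gene)]
  m2 <- tab2$frequency[order(tab2$gene)]
  expect_true(all(m2 >= m1))

  r3 <- mk(list(c(TRUE, TRUE, FALSE, FALSE)))
  r3$gene_names <- paste0("h", 1:4)
  expect_error(gene_selection_frequency(list(r1, r3)), "namespace")
})
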