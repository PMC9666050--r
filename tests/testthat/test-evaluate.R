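test_that("confusion metrics reproduce the hand-worked 2-class example", {
  cm <- matrix(c(3, 2, 1, 4), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m <- metrics_from_confusion(cm)
  expect_equal(m$recall[1], 0.75)
  expect_equal(m$precision[1], 0.6)
  expect_equal(m$accuracy[1], 0.7)
  expect_equal(m$F1[1], 2 * 0.75 * 0.6 / 1.35)
  expect_equal(attr(m, "overall_accuracy"), 0.7)
  perfect <- metrics_from_confusion(diag(5, 2))
  expect_true(all(perfect$accuracy == 1 & perfect$recall == 1 &
                  perfect$precision == 1 & perfect$F1 == 1))
  degen <- matrix(c(0, 3, 0, 7), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_warning(md <- metrics_from_confusion(degen), "no true instances")
  expect_equal(md$recall[1], 0)
  expect_equal(md$F1[1], 0)
  expect_error(metrics_from_confusion(matrix(0, 2, 2)), "empty")
})

test_that("confusion metrics agree with a brute-force per-sample counter", {
  set.seed(41)
  classes <- c("CY", "TI", "HO")
  for (i in 1:20) {
    n <- sample(10:100, 1)
    true <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    cm <- confusion_matrix(true, pred, classes)
    m <- suppressWarnings(metrics_from_confusion(cm))
    for (j in seq_along(classes)) {
      cl <- classes[j]
      tp <- sum(true == cl & pred == cl)
      fn <- sum(true == cl & pred != cl)
      fp <- sum(true != cl & pred == cl)
      tn <- sum(true != cl & pred != cl)
      expect_equal(m$TP[j], tp)
      expect_equal(m$accuracy[j], (tp + tn) / n)
      if (tp + fn > 0) expect_equal(m$recall[j], tp / (tp + fn))
      if (tp + fp > 0) expect_equal(m$precision[j], tp / (tp + fp))
    }
    expect_equal(sum(cm), n)
  }
})

test_that("the Kruskal-Wallis screen reproduces the two-group rank example", {
  X <- cbind(feature = c(1, 2, 3, 10, 11, 12))
  labels <- rep(c("a", "b"), each = 3)
  out <- kruskal_wallis_screen(X, labels)
  expect_equal(out$H, 3.857142857, tolerance = 1e-8)
  expect_equal(out$p, 0.04953461, tolerance = 1e-4)
  Xc <- cbind(rnorm(6), 5)
  expect_warning(out2 <- kruskal_wallis_screen(Xc, labels), "constant")
  expect_equal(out2$H[2], 0)
  expect_equal(out2$p[2], 1)
  # identical group distributions carry no between-group rank variation
  X0 <- cbind(rep(c(1, 2, 3), 2))
  expect_equal(kruskal_wallis_screen(X0, labels)$H, 0)
})

test_that("strongly separated classes give small screen p-values after PCA", {
  recs <- cached_recordings(delta = 2, trials = 6)
  fm <- feature_matrix(segment_recordings(recs, 400), basis = "db4")
  pca <- pca_fit(fm$values, k = 10, standardize = TRUE)
  scores <- pca_transform(pca, fm$values)
  out <- kruskal_wallis_screen(scores, fm$labels)
  expect_lt(median(out$p), 0.001)
})

test_that("cross-validation is deterministic, grouped, and accounts every window", {
  recs <- cached_recordings(delta = 2, trials = 6)
  ev1 <- cross_validate(recs, basis = "db4", k_pca = 10, n_folds = 3,
                        classifier = "knn", seed = 7)
  ev2 <- cross_validate(recs, basis = "db4", k_pca = 10, n_folds = 3,
                        classifier = "knn", seed = 7)
  expect_identical(ev1$confusion, ev2$confusion)
  expect_identical(ev1$overall_accuracy, ev2$overall_accuracy)
  expect_equal(sum(ev1$confusion), ev1$n_windows)
  expect_equal(ev1$n_windows, 36 * 7)  # 36 trials x 7 windows each
  # every trial's windows share one fold by construction
  expect_equal(length(ev1$fold_assignments), 36L)
  expect_true(all(table(ev1$fold_assignments) > 0))
  # per-class recall recomputable from the confusion
  m <- ev1$per_class
  expect_equal(m$recall, m$TP / (m$TP + m$FN), tolerance = 1e-12)
})

test_that("fold models use training windows only (manual refit agrees)", {
  recs <- cached_recordings(delta = 2, trials = 6)
  seed <- 7L
  n_folds <- 3L
  ev <- cross_validate(recs, basis = "db4", k_pca = 10, n_folds = n_folds,
                       classifier = "knn", seed = seed)
  # independent reimplementation of the fold loop from exported pieces
  windows <- segment_recordings(recs, 400)
  fm <- feature_matrix(windows, basis = "db4")
  gids <- paste(fm$subjects, fm$labels, fm$trials, sep = "|")
  fold_of <- ev$fold_assignments
  cm <- NULL
  for (f in seq_len(n_folds)) {
    tr <- fold_of[gids] != f
    pca <- pca_fit(fm$values[tr, ], k = 10, standardize = TRUE)
    clf <- train_classifier("knn", pca_transform(pca, fm$values[tr, ]),
                            fm$labels[tr], seed = seed + 97L * f)
    pred <- predict(clf, pca_transform(pca, fm$values[!tr, ]))
    cmf <- confusion_matrix(fm$labels[!tr], pred, movement_classes())
    cm <- if (is.null(cm)) unclass(cmf) else cm + unclass(cmf)
  }
  expect_equal(unclass(ev$confusion), cm)
})

test_that("noise evaluation is invariant to a common rescaling of data and reference", {
  recs <- cached_recordings(delta = 2, trials = 6)
  recs10 <- lapply(recs, function(r) { r$samples <- r$samples * 10; r })
  a1 <- cross_validate(recs, basis = "db4", k_pca = 10, n_folds = 3,
                       noise_level = 0.3, reference_magnitude = 0.01,
                       seed = 3)$overall_accuracy
  a2 <- cross_validate(recs10, basis = "db4", k_pca = 10, n_folds = 3,
                       noise_level = 0.3, reference_magnitude = 0.1,
                       seed = 3)$overall_accuracy
  expect_equal(a1, a2)
})

test_that("sweep tables have the swept parameter in rows and accuracies in [0, 1]", {
  recs <- cached_recordings(delta = 2, trials = 6)
  tab <- sweep_dimension(recs, dims = c(5L, 10L), classifiers = "knn",
                         basis = "db4", n_folds = 3, seed = 7)
  expect_equal(dim(tab), c(2L, 2L))
  expect_equal(tab$dimension, c(5L, 10L))
  expect_true(all(tab$knn >= 0 & tab$knn <= 1))
  tabb <- sweep_basis(recs, bases = c("db4", "sym3"), classifiers = "knn",
                      k_pca = 10, n_folds = 3, seed = 7)
  expect_equal(tabb$basis, c("db4", "sym3"))
  expect_true(all(tabb$knn >= 0 & tabb$knn <= 1))
})

test_that("cross-validation rejects impossible fold counts", {
  recs <- cached_recordings(delta = 2, trials = 6)
  expect_error(cross_validate(recs, basis = "db4", n_folds = 7),
               "at least")
})
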