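test_that("confusion-matrix metrics match direct substitution", {
  # binary: TP = 9, FN = 1 / FP = 1, TN = 9
  cm <- matrix(c(9, 1, 1, 9), 2, byrow = TRUE)
  m <- confusion_metrics(cm)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$macro_precision, 0.9)
  expect_equal(m$macro_recall, 0.9)
  expect_equal(m$macro_f1, 0.9)
  # perfect diagonal
  mp <- confusion_metrics(diag(c(4, 5, 6)))
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$macro_f1, 1)
  # 3-class worked example, one-vs-rest arithmetic done by hand:
  # precision = (1, 4/6, 3/4); recall = (1, 4/5, 3/5)
  m3 <- confusion_metrics(matrix(c(5, 0, 0, 0, 4, 1, 0, 2, 3), 3,
                                 byrow = TRUE))
  expect_equal(m3$accuracy, 12 / 15)
  expect_equal(m3$macro_precision, mean(c(1, 4 / 6, 3 / 4)))
  expect_equal(m3$macro_recall, mean(c(1, 4 / 5, 3 / 5)))
  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(m3$macro_f1,
               mean(c(f1(1, 1), f1(4 / 6, 4 / 5), f1(3 / 4, 3 / 5))))
  expect_error(confusion_metrics(matrix(numeric(0), 0, 0)), "square")
})

test_that("metrics agree with an independent oracle on random matrices", {
  oracle <- function(cm) {
    n <- nrow(cm); prec <- rec <- numeric(n)
    for (k in seq_len(n)) {
      tp <- cm[k, k]; fp <- sum(cm[, k]) - tp; fn <- sum(cm[k, ]) - tp
      prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
      rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    }
    list(acc = sum(diag(cm)) / sum(cm), prec = mean(prec), rec = mean(rec))
  }
  set.seed(99)
  for (r in 1:20) {
    cm <- matrix(rpois(9, 4), 3)
    if (sum(cm) == 0) next
    m <- confusion_metrics(cm)
    o <- oracle(cm)
    expect_equal(m$accuracy, o$acc)
    expect_equal(m$macro_precision, o$prec)
    expect_equal(m$macro_recall, o$rec)
  }
})

test_that("fold assignment is stratified to within one instance", {
  labels <- rep(c("Healthy", "Mild", "Severe"), times = c(54, 18, 18))
  for (seed in 1:5) {
    fold <- stratified_folds(labels, 5, seed)
    tab <- table(fold, labels)
    for (cl in colnames(tab))
      expect_lte(max(tab[, cl]) - min(tab[, cl]), 1)
  }
  expect_error(stratified_folds(c("a", "a", "b"), 2), "b")
})

test_that("zone staging reproduces the reference table and boundary rules", {
  sims <- c(0.91, 0.72, 0.54, 0.90, 0.73, 0.45, 0.93, 0.68, 0.42)
  expect_equal(classify_zone(sims),
               c("Healthy", "Mild Stress", "Severe Stress",
                 "Healthy", "Mild Stress", "Severe Stress",
                 "Healthy", "Mild Stress", "Severe Stress"))
  expect_equal(classify_zone(0.80), "Healthy")      # inclusive boundary
  expect_equal(classify_zone(0.60), "Mild Stress")  # inclusive boundary
  expect_error(classify_zone(0.5, c(0.6, 0.8)), "thresholds")
})

test_that("zone similarity is the mean off-diagonal kernel value", {
  g <- deviation_graph(healthy_anchor, epsilon = 0.05, owner_id = "x")
  expect_equal(zone_similarity(list(g, g, g)), 1.0)
  graphs <- build_graphs(random_intensities(4, 12), epsilon = 0.05)
  s <- zone_similarity(graphs, sigma = 0.7)
  # independent pairwise computation
  vals <- c()
  for (i in 1:3) for (j in (i + 1):4)
    vals <- c(vals, pgk_pair(phi_embedding(graphs[[i]]),
                             phi_embedding(graphs[[j]]), sigma = 0.7))
  expect_equal(s, mean(vals))
  expect_error(zone_similarity(graphs[1]), "2")
})

test_that("field report arranges zones into an acre grid and rejects duplicates", {
  zr <- data.frame(
    acre_id = rep(c("A1", "A2", "A3"), each = 3),
    zone_id = rep(c("Z1", "Z2", "Z3"), times = 3),
    similarity = c(0.91, 0.72, 0.54, 0.90, 0.73, 0.45, 0.93, 0.68, 0.42),
    stringsAsFactors = FALSE)
  zr$status <- classify_zone(zr$similarity)
  fr <- field_report(zr)
  expect_equal(fr$status["A1", "Z1"], "Healthy")
  expect_equal(fr$status["A3", "Z3"], "Severe Stress")
  expect_equal(fr$summary["A2", "Mild Stress"], 1)
  expect_error(field_report(rbind(zr, zr[1, ])), "duplicate")
  empty <- field_report(zr[0, ])
  expect_equal(nrow(empty$status), 0L)
})

test_that("the staging pipeline orders conditions on generated fields", {
  rec <- generate_field(seed = 5)
  zr <- zone_report(rec)
  by_cond <- tapply(zr$similarity, zr$condition, mean)
  expect_gt(by_cond["Healthy"], by_cond["Mild"])
  expect_gt(by_cond["Mild"], by_cond["Severe"])
  expect_true(all(zr$similarity >= 0 & zr$similarity <= 1))
})

test_that("method comparison flags identical runs, shifts and low power", {
  a <- c(0.9, 0.92, 0.88, 0.91, 0.9, 0.93, 0.89, 0.9)
  cmp <- compare_methods(list(m1 = a, m2 = a))
  expect_equal(cmp$p_values["m1", "m2"], 1)
  set.seed(8)
  b <- runif(20, 0.85, 0.95)
  cmp2 <- compare_methods(list(m1 = b + 0.05, m2 = b))
  expect_lt(cmp2$p_values["m1", "m2"], 0.05)
  cmp3 <- compare_methods(list(m1 = a[1:2], m2 = a[1:2] + 0.01))
  expect_true(cmp3$low_power)
  expect_error(compare_methods(list(m1 = a, m2 = a[1:3])), "mismatched")
})

test_that("grid search never sees held-out fold data", {
  rec <- generate_field(seed = 21)
  grids <- list(C_grid = c(1, 10), sigma_grid = list(0.25, 0.5, "median"))
  fit <- do.call(pgk_cv, c(list(rec, kernel = "pgk", seed = 21), grids))
  # corrupt ONLY the rows of fold 1's held-out set with a marker value
  test_rows <- which(fit$fold_assignment == 1)
  rec2 <- rec
  rec2$LC[test_rows] <- rec2$LC[test_rows] * 10 + 5
  fit2 <- do.call(pgk_cv, c(list(rec2, kernel = "pgk", seed = 21), grids))
  # fold 1 trains without those rows: its selected hyperparameters are
  # unchanged if (and only if) selection ignores held-out data
  expect_equal(fit2$selected[1, c("C", "param")],
               fit$selected[1, c("C", "param")])
})

test_that("cross-validation is deterministic given a seed", {
  rec <- generate_field(seed = 31)
  f1 <- pgk_cv(rec, kernel = "pgk", seed = 9,
               C_grid = c(1, 10), sigma_grid = list(0.5))
  f2 <- pgk_cv(rec, kernel = "pgk", seed = 9,
               C_grid = c(1, 10), sigma_grid = list(0.5))
  expect_identical(f1$fold_accuracy, f2$fold_accuracy)
  expect_identical(f1$selected, f2$selected)
  expect_error(pgk_cv(rec[1:10, ], kernel = "pgk"), "fewer members|folds")
})

test_that("baseline kernels also separate the default benchmark classes", {
  rec <- generate_field(seed = 2)
  for (k in c("wl", "sp", "pgk_linear", "linear")) {
    fit <- pgk_cv(rec, kernel = k, seed = 2, C_grid = c(1, 10),
                  h_grid = 0:2, bin_grid = c(0.1, 0.2))
    expect_gt(fit$mean_accuracy, 0.8)
    expect_true(all(fit$fold_accuracy >= 0 & fit$fold_accuracy <= 1))
  }
})
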