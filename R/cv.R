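#' Stratified fold assignment
#'
#' Shuffles each class independently and deals its members round-robin
#' over the folds, so per-fold class counts differ from perfect
#' proportionality by at most one instance.
#'
#' @param labels class label vector.
#' @param k number of folds.
#' @param seed RNG seed for the within-class shuffles.
#' @return Integer fold id (1..k) per observation.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  if (length(labels) < k) stop("fewer observations than folds")
  small <- names(which(table(labels) < k))
  if (length(small))
    stop("class(es) with fewer members than folds: ",
         paste(small, collapse = ", "))
  set.seed(seed)
  fold <- integer(length(labels))
  offset <- 0L
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    # stagger classes so small classes do not pile into the same folds
    offset <- offset + length(idx)
  }
  fold
}

# Per-split kernel stack: fits the normalisation (and any other
# data-dependent quantity) on `fit_idx` only, then returns one full n x n
# kernel matrix per kernel-parameter value.
.cv_kernels <- function(records, fit_idx, opts) {
  norm <- fit_normalization(records[fit_idx, , drop = FALSE], opts$traits)
  P <- predict(norm, records)
  if (opts$kernel == "linear")
    return(list(params = NA_real_, K = list(tcrossprod(P))))
  graphs <- build_graphs(P, epsilon = opts$epsilon,
                         thresholds = opts$thresholds)
  if (opts$kernel %in% c("pgk", "pgk_linear")) {
    phi <- phi_matrix(graphs, augmented = opts$augmented)
    if (opts$kernel == "pgk_linear")
      return(list(params = NA_real_,
                  K = list(normalize_kernel(tcrossprod(phi)))))
    sigmas <- vapply(opts$sigma_grid, function(s) {
      if (identical(s, "median")) median_heuristic(phi[fit_idx, , drop = FALSE])
      else as.numeric(s)
    }, numeric(1))
    d2 <- as.matrix(stats::dist(phi))^2
    return(list(params = sigmas,
                K = lapply(sigmas, function(s) exp(-d2 / (2 * s^2)))))
  }
  if (opts$kernel == "wl") {
    return(list(params = as.numeric(opts$h_grid),
                K = lapply(opts$h_grid, function(h)
                  normalize_kernel(tcrossprod(wl_features(graphs, h))))))
  }
  # shortest-path
  list(params = as.numeric(opts$bin_grid),
       K = lapply(opts$bin_grid, function(b)
         normalize_kernel(tcrossprod(sp_features(graphs, b)))))
}

.svm_accuracy <- function(K, train, test, y, C, tol = 0.05) {
  # coarse SMO tolerance: near-duplicate kernel rows (tight clusters,
  # zero-noise classes) make the default 1e-3 stopping rule cycle
  fit <- tryCatch(
    kernlab::ksvm(kernlab::as.kernelMatrix(K[train, train, drop = FALSE]),
                  y[train], kernel = "matrix", C = C, tol = tol),
    error = function(e) NULL)
  if (is.null(fit)) return(list(pred = NULL, accuracy = NA_real_))
  sv <- kernlab::SVindex(fit)
  pred <- kernlab::predict(fit, kernlab::as.kernelMatrix(
    K[test, train, drop = FALSE][, sv, drop = FALSE]))
  pred <- factor(as.character(pred), levels = levels(y))
  list(pred = pred, accuracy = mean(pred == y[test]))
}

#' Cross-validated kernel-SVM stress classification
#'
#' The package's central fitting routine: stratified outer k-fold
#' cross-validation of a precomputed-kernel support vector machine, with
#' all data-dependent quantities (trait normalisation, median-heuristic
#' bandwidth) refitted on training data at every level, and
#' hyperparameters (`C` and the kernel parameter) selected by grid search
#' over an inner stratified cross-validation of the training fold only.
#' Ties in the grid search are broken toward smaller `C`, then the
#' smaller kernel parameter.
#'
#' @param records labelled trait table (`condition` column required).
#' @param kernel `"pgk"` (Gaussian on the interaction embedding),
#'   `"pgk_linear"`, `"wl"` (Weisfeiler-Lehman on perceptual states),
#'   `"sp"` (shortest-path) or `"linear"` (linear kernel on the
#'   continuous intensity vectors, the flat-feature baseline).
#' @param folds outer folds (default 5).
#' @param seed RNG seed controlling fold assignment (outer and inner).
#' @param C_grid SVM cost grid.
#' @param sigma_grid RBF bandwidth grid; the string `"median"` resolves
#'   to the median heuristic on the training embeddings.
#' @param h_grid Weisfeiler-Lehman iteration grid.
#' @param bin_grid shortest-path bin-width grid.
#' @param epsilon edge-pruning threshold for graph construction.
#' @param thresholds perceptual-state cuts.
#' @param inner_folds folds of the inner model-selection loop.
#' @param augmented use the node-augmented embedding (pgk variants).
#'   Classification defaults to `TRUE`: the edges-only embedding is
#'   invariant to complementing every intensity, which makes uniformly
#'   high (healthy) and uniformly low (collapsed) trait profiles
#'   indistinguishable; appending the node intensities removes that
#'   blind spot.
#' @param traits trait registry.
#' @return Object of class `pgk_cv`: per-fold confusion matrices,
#'   metrics and selected hyperparameters, plus mean and sd of accuracy
#'   and macro precision/recall/F1 across folds.
#' @examples
#' \donttest{
#' rec <- generate_field(seed = 7)
#' fit <- pgk_cv(rec, kernel = "pgk", seed = 7,
#'               C_grid = c(1, 10), sigma_grid = list(0.5, "median"))
#' summary(fit)
#' }
#' @export
pgk_cv <- function(records,
                   kernel = c("pgk", "pgk_linear", "wl", "sp", "linear"),
                   folds = 5L, seed = 1L,
                   C_grid = c(0.1, 1, 10, 100),
                   sigma_grid = list(0.1, 0.25, 0.5, 1.0, "median"),
                   h_grid = c(0L, 1L, 2L, 3L),
                   bin_grid = c(0.05, 0.1, 0.2),
                   epsilon = 0.05, thresholds = c(1 / 3, 2 / 3),
                   inner_folds = 3L, augmented = TRUE,
                   traits = pgk_traits()) {
  kernel <- match.arg(kernel)
  validate_trait_records(records, traits, require_condition = TRUE)
  y <- factor(records$condition)
  if (nlevels(y) < 2L) stop("need at least two condition classes")
  opts <- list(kernel = kernel, epsilon = epsilon, thresholds = thresholds,
               augmented = augmented, sigma_grid = sigma_grid,
               h_grid = h_grid, bin_grid = bin_grid, traits = traits)
  fold <- stratified_folds(y, folds, seed)
  fold_out <- vector("list", folds)
  for (f in seq_len(folds)) {
    train <- which(fold != f)
    test <- which(fold == f)
    # --- inner grid search on the training fold only ---
    inner <- stratified_folds(y[train], inner_folds, seed + f)
    ks0 <- .cv_kernels(records, train, opts)  # param values for bookkeeping
    n_par <- length(ks0$params)
    score <- matrix(0, length(C_grid), n_par)
    cnt <- matrix(0L, length(C_grid), n_par)
    for (g in seq_len(inner_folds)) {
      itr <- train[inner != g]
      iva <- train[inner == g]
      ks <- .cv_kernels(records, itr, opts)
      for (pi in seq_len(n_par)) for (ci in seq_along(C_grid)) {
        a <- .svm_accuracy(ks$K[[pi]], itr, iva, y, C_grid[ci])$accuracy
        if (!is.na(a)) {
          score[ci, pi] <- score[ci, pi] + a
          cnt[ci, pi] <- cnt[ci, pi] + 1L
        }
      }
    }
    mean_score <- ifelse(cnt > 0, score / pmax(cnt, 1L), -Inf)
    # tie-break toward smaller C, then smaller kernel parameter
    ord <- order(rep(C_grid, times = n_par),
                 rep(ks0$params, each = length(C_grid)))
    flat <- as.vector(mean_score)[ord]
    best <- ord[which.max(flat)]
    ci <- (best - 1L) %% length(C_grid) + 1L
    pi <- (best - 1L) %/% length(C_grid) + 1L
    # --- final fit on the full training fold ---
    res <- .svm_accuracy(ks0$K[[pi]], train, test, y, C_grid[ci])
    if (is.null(res$pred))
      stop("SVM training failed on fold ", f)
    cm <- table(true = y[test], predicted = res$pred)
    met <- confusion_metrics(unclass(cm))
    fold_out[[f]] <- list(confusion = cm,
                          accuracy = met$accuracy,
                          macro_precision = met$macro_precision,
                          macro_recall = met$macro_recall,
                          macro_f1 = met$macro_f1,
                          C = C_grid[ci],
                          param = ks0$params[pi],
                          inner_score = mean_score[ci, pi])
  }
  pull <- function(fld) vapply(fold_out, `[[`, numeric(1), fld)
  acc <- pull("accuracy")
  out <- list(kernel = kernel, folds = folds, seed = seed, n = nrow(records),
              classes = levels(y), fold_results = fold_out,
              fold_accuracy = acc,
              mean_accuracy = mean(acc), sd_accuracy = stats::sd(acc),
              mean_macro_precision = mean(pull("macro_precision")),
              mean_macro_recall = mean(pull("macro_recall")),
              mean_macro_f1 = mean(pull("macro_f1")),
              selected = data.frame(fold = seq_len(folds),
                                    C = pull("C"), param = pull("param")),
              fold_assignment = fold)
  class(out) <- "pgk_cv"
  out
}

#' @export
print.pgk_cv <- function(x, ...) {
  cat(sprintf("Cross-validated kernel SVM [%s], %d-fold, n = %d, seed = %d\n",
              x$kernel, x$folds, x$n, x$seed))
  cat(sprintf("  accuracy: %.3f +/- %.3f   macro F1: %.3f\n",
              x$mean_accuracy, x$sd_accuracy, x$mean_macro_f1))
  invisible(x)
}

#' @export
summary.pgk_cv <- function(object, ...) {
  cat(sprintf("Cross-validated kernel SVM [%s], %d-fold, n = %d, seed = %d\n",
              object$kernel, object$folds, object$n, object$seed))
  cat(sprintf("  mean accuracy        %.4f +/- %.4f\n",
              object$mean_accuracy, object$sd_accuracy))
  cat(sprintf("  mean macro precision %.4f\n", object$mean_macro_precision))
  cat(sprintf("  mean macro recall    %.4f\n", object$mean_macro_recall))
  cat(sprintf("  mean macro F1        %.4f\n", object$mean_macro_f1))
  cat("  selected hyperparameters per fold:\n")
  print(object$selected, row.names = FALSE)
  invisible(object)
}

#' Paired comparison of classification methods
#'
#' Compares methods evaluated under identical data partitions (same
#' generator seeds / fold assignments), by a paired two-sided test on the
#' per-seed mean accuracies: Wilcoxon signed-rank by default, paired
#' t-test optionally.  With fewer than 6 paired observations the result
#' is flagged low-power.
#'
#' @param results named list of equal-length numeric vectors (per-seed
#'   mean accuracy per method), or a matrix with one column per method.
#' @param test `"wilcoxon"` or `"t"`.
#' @return Object of class `pgk_comparison`: per-method mean/sd table and
#'   a symmetric matrix of pairwise p-values.
#' @export
compare_methods <- function(results, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (is.matrix(results))
    results <- stats::setNames(lapply(seq_len(ncol(results)),
                                      function(j) results[, j]),
                               colnames(results))
  if (length(results) < 2L) stop("need at least two methods to compare")
  n <- unique(lengths(results))
  if (length(n) != 1L)
    stop("methods were evaluated on mismatched partitions (unequal lengths)")
  methods <- names(results)
  tab <- data.frame(method = methods,
                    mean = vapply(results, mean, numeric(1)),
                    sd = vapply(results, stats::sd, numeric(1)),
                    stringsAsFactors = FALSE)
  p <- matrix(NA_real_, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods)) for (j in seq_along(methods)) {
    if (i >= j) next
    d <- results[[i]] - results[[j]]
    p[i, j] <- p[j, i] <- if (all(d == 0)) 1 else if (test == "wilcoxon")
      suppressWarnings(stats::wilcox.test(d, exact = FALSE)$p.value)
    else stats::t.test(d)$p.value
  }
  structure(list(table = tab, p_values = p, test = test, n = n,
                 low_power = n < 6L),
            class = "pgk_comparison")
}

#' @export
print.pgk_comparison <- function(x, ...) {
  cat(sprintf("Method comparison (%s test over %d paired runs%s)\n",
              x$test, x$n, if (x$low_power) "; LOW POWER" else ""))
  print(x$table, row.names = FALSE)
  cat("pairwise p-values:\n")
  print(round(x$p_values, 4))
  invisible(x)
}
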