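#' Multi-seed synthetic benchmark of kernel classifiers
#'
#' Repeats the full pipeline — generate a synthetic field, encode,
#' build graphs, cross-validate a precomputed-kernel SVM — over a set of
#' generator seeds, for one or several kernels evaluated on identical
#' datasets and fold partitions, so the per-seed accuracies are directly
#' paired for [compare_methods()].
#'
#' @param kernels character vector of kernels (see [pgk_cv()]).
#' @param seeds integer vector of generator seeds (each seed also
#'   seeds the fold assignment).
#' @param design field design.
#' @param profiles condition profiles.
#' @param ... further arguments passed to [pgk_cv()] (grids, epsilon,
#'   folds, ...).
#' @return Object of class `pgk_benchmark`: matrix `accuracy` (seeds x
#'   kernels) of per-seed mean accuracies, the analogous `macro_f1`
#'   matrix, and the call parameters.
#' @export
pgk_benchmark <- function(kernels = "pgk", seeds = 1:20,
                          design = field_design(),
                          profiles = default_profiles(), ...) {
  acc <- matrix(NA_real_, length(seeds), length(kernels),
                dimnames = list(seeds, kernels))
  f1 <- acc
  for (si in seq_along(seeds)) {
    rec <- generate_field(design, profiles, seed = seeds[si])
    for (ki in seq_along(kernels)) {
      fit <- pgk_cv(rec, kernel = kernels[ki], seed = seeds[si], ...)
      acc[si, ki] <- fit$mean_accuracy
      f1[si, ki] <- fit$mean_macro_f1
    }
  }
  structure(list(accuracy = acc, macro_f1 = f1, seeds = seeds,
                 kernels = kernels),
            class = "pgk_benchmark")
}

#' @export
print.pgk_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic benchmark over %d seeds\n", length(x$seeds)))
  tab <- data.frame(
    kernel = x$kernels,
    mean_accuracy = colMeans(x$accuracy),
    sd_accuracy = apply(x$accuracy, 2L, stats::sd),
    mean_macro_f1 = colMeans(x$macro_f1))
  print(tab, row.names = FALSE)
  invisible(x)
}
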