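#' Fit a per-trait min-max normalisation model
#'
#' Learns per-trait extrema from a set of raw trait records so that raw,
#' unit-heterogeneous measurements can be mapped onto a common perceptual
#' intensity scale in \[0, 1\].  Traits that are constant over the fitting
#' records are flagged degenerate and later map to the neutral intensity
#' 0.5.  Inside cross-validation the model is always fitted on training
#' records only; held-out values are clamped into \[0, 1\].
#'
#' @param records data frame of raw trait records (see
#'   [validate_trait_records()]).
#' @param traits trait registry.
#' @return An object of class `pgk_norm` with a `table` of per-trait
#'   `min`, `max` and `degenerate` flags.
#' @examples
#' rec <- generate_field(seed = 1)
#' fit_normalization(rec)
#' @export
fit_normalization <- function(records, traits = pgk_traits()) {
  validate_trait_records(records, traits)
  tab <- data.frame(
    code = traits$code,
    min = vapply(traits$code, function(c) min(records[[c]]), numeric(1)),
    max = vapply(traits$code, function(c) max(records[[c]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  tab$degenerate <- tab$max == tab$min
  structure(list(table = tab, traits = traits, n = nrow(records)),
            class = "pgk_norm")
}

#' @export
print.pgk_norm <- function(x, ...) {
  cat("Perceptual normalisation model (fitted on", x$n, "records)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Map raw trait records to perceptual intensities
#'
#' Applies the fitted min-max normalisation `p = (x - min) / (max - min)`
#' per trait.  Values outside the fitted range are clamped to \[0, 1\];
#' degenerate traits (max equal to min over the fitting records) map to
#' 0.5.
#'
#' @method predict pgk_norm
#' @param object a `pgk_norm` model.
#' @param newdata data frame of raw trait records.
#' @param ... unused.
#' @return Numeric matrix of perceptual intensities, one row per plant
#'   (rownames are plant ids), one column per trait in canonical order.
#' @export
predict.pgk_norm <- function(object, newdata, ...) {
  validate_trait_records(newdata, object$traits)
  tab <- object$table
  p <- matrix(NA_real_, nrow(newdata), nrow(tab),
              dimnames = list(newdata$plant_id, tab$code))
  for (k in seq_len(nrow(tab))) {
    x <- newdata[[tab$code[k]]]
    if (tab$degenerate[k]) {
      p[, k] <- 0.5
    } else {
      p[, k] <- pmin(pmax((x - tab$min[k]) / (tab$max[k] - tab$min[k]), 0), 1)
    }
  }
  p
}

#' Serialise / restore a normalisation model
#'
#' Writes the per-trait min/max table as a small JSON file.
#'
#' @param model a `pgk_norm` object.
#' @param path destination / source file.
#' @return `write_normalization()` returns `path`; `read_normalization()`
#'   a `pgk_norm`.
#' @export
write_normalization <- function(model, path) {
  stopifnot(inherits(model, "pgk_norm"))
  jsonlite::write_json(
    list(n = model$n,
         traits = model$traits,
         table = model$table),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(table = as.data.frame(obj$table),
                 traits = as.data.frame(obj$traits),
                 n = obj$n),
            class = "pgk_norm")
}

validate_state_thresholds <- function(thresholds) {
  if (!is.numeric(thresholds) ||
      (is.matrix(thresholds) && nrow(thresholds) != 2L) ||
      (!is.matrix(thresholds) && length(thresholds) != 2L))
    stop("state thresholds must be a numeric pair (t_low, t_high) or a 2-row matrix")
  tl <- if (is.matrix(thresholds)) thresholds[1L, ] else thresholds[1L]
  th <- if (is.matrix(thresholds)) thresholds[2L, ] else thresholds[2L]
  if (any(!(tl > 0 & tl < th & th < 1)))
    stop("state thresholds must satisfy 0 < t_low < t_high < 1")
  invisible(thresholds)
}

#' Discretise perceptual intensities into low/medium/high states
#'
#' Intensities below `t_low` are "low", intensities in `[t_low, t_high)`
#' are "medium" and intensities at or above `t_high` are "high" (lower
#' bound inclusive).  The default cuts are the fixed tertiles (1/3, 2/3);
#' per-trait empirical tertiles can be supplied as a 2-row matrix (see
#' [tertile_thresholds()]).
#'
#' @param p numeric vector or matrix of intensities in \[0, 1\] (columns =
#'   traits when a matrix).
#' @param thresholds numeric pair `c(t_low, t_high)` or a 2 x m matrix of
#'   per-trait cuts.
#' @return Character vector/matrix of states over `{"low","medium","high"}`
#'   with attribute `thresholds`.
#' @examples
#' discretize(c(LC = 0.92, WI = 0.12))
#' @export
discretize <- function(p, thresholds = c(1 / 3, 2 / 3)) {
  validate_state_thresholds(thresholds)
  x <- if (is.matrix(p)) p else matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  if (is.matrix(thresholds)) {
    if (ncol(thresholds) != ncol(x))
      stop("per-trait thresholds must have one column per trait")
    tl <- matrix(thresholds[1L, ], nrow(x), ncol(x), byrow = TRUE)
    th <- matrix(thresholds[2L, ], nrow(x), ncol(x), byrow = TRUE)
  } else {
    tl <- thresholds[1L]; th <- thresholds[2L]
  }
  s <- matrix("medium", nrow(x), ncol(x), dimnames = dimnames(x))
  s[x < tl] <- "low"
  s[x >= th] <- "high"
  out <- if (is.matrix(p)) s else stats::setNames(s[1L, ], colnames(x))
  attr(out, "thresholds") <- thresholds
  out
}

#' Per-trait empirical tertile thresholds
#'
#' Computes per-trait (1/3, 2/3) sample quantiles from a training
#' intensity matrix, for the empirical-tertile discretisation mode.
#'
#' @param p intensity matrix (rows = plants).
#' @return 2 x m numeric matrix of per-trait `(t_low, t_high)` cuts.
#' @export
tertile_thresholds <- function(p) {
  stopifnot(is.matrix(p))
  q <- apply(p, 2L, stats::quantile, probs = c(1 / 3, 2 / 3), names = FALSE)
  # keep cuts strictly inside (0, 1) so the threshold contract holds
  q[1L, ] <- pmin(pmax(q[1L, ], 1e-6), 1 - 2e-6)
  q[2L, ] <- pmin(pmax(q[2L, ], q[1L, ] + 1e-6), 1 - 1e-6)
  q
}

#' Aggregate plant-level intensities to a zone-level vector
#'
#' Per-trait arithmetic mean over the plants of one zone.
#'
#' @param p intensity matrix with one row per plant of a single zone.
#' @param zones optional vector of zone ids for the rows; supplying rows
#'   from more than one zone is an error.
#' @return Named numeric vector of zone-level intensities.
#' @export
aggregate_zone <- function(p, zones = NULL) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L, dimnames = list(NULL, names(p)))
  if (nrow(p) == 0L) stop("cannot aggregate an empty set of plant vectors")
  if (!is.null(zones)) {
    if (length(zones) != nrow(p))
      stop("'zones' must have one entry per row of 'p'")
    if (length(unique(zones)) > 1L)
      stop("cannot aggregate plants from mixed zones: ",
           paste(unique(zones), collapse = ", "))
  }
  colMeans(p)
}

#' Aggregate a whole field of plant intensities to zone means
#'
#' @param p intensity matrix (rows = plants).
#' @param zones zone identifier per row (combine acre and zone ids when
#'   zone ids repeat across acres).
#' @return Matrix of per-zone mean intensities, rownames = zone ids.
#' @export
aggregate_zones <- function(p, zones) {
  stopifnot(is.matrix(p), length(zones) == nrow(p))
  g <- split(seq_len(nrow(p)), zones)
  out <- t(vapply(g, function(i) colMeans(p[i, , drop = FALSE]),
                  numeric(ncol(p))))
  colnames(out) <- colnames(p)
  out
}
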