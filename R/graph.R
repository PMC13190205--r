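#' Build a deviation-weighted perceptual trait interaction graph
#'
#' Nodes are the traits of one plant (or zone), carrying the perceptual
#' intensity and its discrete state; every unordered trait pair gets an
#' undirected edge weighted by the perceptual deviation
#' `w_ij = |p_i - p_j|`, and weak edges with `w_ij < epsilon` are pruned.
#' With `epsilon = 0` the graph is the fully connected trait-interaction
#' graph.
#'
#' @param p named numeric vector of perceptual intensities in \[0, 1\], in
#'   canonical trait order.
#' @param epsilon pruning threshold (>= 0); edges with weight strictly
#'   below `epsilon` are dropped.
#' @param states optional precomputed state vector; derived from
#'   `thresholds` when `NULL`.
#' @param owner_id plant or zone identifier carried by the graph.
#' @param thresholds state cuts passed to [discretize()].
#' @return An object of class `pgk_graph`: node codes, intensities,
#'   states, an edge table (`a`, `b`, `weight`), `epsilon` and
#'   `mode = "deviation"`.
#' @examples
#' healthy <- c(LC = 0.92, LA = 0.88, TU = 0.90, VP = 0.85, ES = 0.87, WI = 0.12)
#' deviation_graph(healthy, epsilon = 0.1)
#' @export
deviation_graph <- function(p, epsilon = 0.05, states = NULL,
                            owner_id = NA_character_,
                            thresholds = c(1 / 3, 2 / 3)) {
  if (epsilon < 0) stop("'epsilon' must be >= 0")
  if (is.null(names(p))) stop("'p' must be a named intensity vector")
  if (any(p < -1e-12 | p > 1 + 1e-12))
    stop("perceptual intensities must lie in [0, 1]")
  p <- pmin(pmax(p, 0), 1)
  if (is.null(states)) states <- c(discretize(p, thresholds))
  pairs <- trait_pairs(names(p))
  w <- abs(p[pairs$a] - p[pairs$b])
  keep <- w >= epsilon
  edges <- data.frame(a = pairs$a[keep], b = pairs$b[keep],
                      weight = unname(w[keep]), stringsAsFactors = FALSE)
  structure(list(owner_id = as.character(owner_id),
                 codes = names(p),
                 intensity = p,
                 state = states,
                 edges = edges,
                 epsilon = epsilon,
                 mode = "deviation"),
            class = "pgk_graph")
}

#' @export
print.pgk_graph <- function(x, ...) {
  cat(sprintf("Perceptual trait graph [%s mode] owner=%s\n", x$mode, x$owner_id))
  cat(sprintf("  %d nodes, %d/%d edges retained (epsilon = %g)\n",
              length(x$codes), nrow(x$edges),
              length(x$codes) * (length(x$codes) - 1L) / 2L, x$epsilon))
  cat("  nodes: ",
      paste(sprintf("%s=%.2f(%s)", x$codes, x$intensity,
                    substr(x$state, 1, 1)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Build graphs for every row of an intensity matrix
#'
#' @param p intensity matrix (rows = plants or zones, rownames used as
#'   owner ids).
#' @param epsilon pruning threshold.
#' @param thresholds state cuts.
#' @param mode `"deviation"` (default) or `"correlation"` (requires
#'   `template`).
#' @param template a [correlation_template()] when `mode = "correlation"`.
#' @return List of `pgk_graph` objects.
#' @export
build_graphs <- function(p, epsilon = 0.05, thresholds = c(1 / 3, 2 / 3),
                         mode = c("deviation", "correlation"),
                         template = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(p))
  owners <- rownames(p)
  if (is.null(owners)) owners <- as.character(seq_len(nrow(p)))
  lapply(seq_len(nrow(p)), function(i) {
    v <- p[i, ]
    if (mode == "deviation")
      deviation_graph(v, epsilon, owner_id = owners[i], thresholds = thresholds)
    else
      correlation_graph(v, template, owner_id = owners[i], thresholds = thresholds)
  })
}

#' Fit a correlation-based edge template over a training cohort
#'
#' The alternative graph construction: edges connect trait pairs whose
#' absolute Pearson correlation across the training cohort reaches
#' `r_min`, with edge weight `|r|`.  Trait pairs involving a
#' zero-variance trait are excluded.  A two-sided correlation-test mode
#' (`method = "pvalue"`, screen at `alpha`) is available; the magnitude
#' threshold is the deterministic default.
#'
#' @param p training intensity matrix (>= 3 rows).
#' @param r_min minimum absolute correlation for an edge.
#' @param method `"threshold"` (|r| screen) or `"pvalue"`.
#' @param alpha significance level for the p-value mode.
#' @return Object of class `pgk_corr_template` with the retained edge
#'   table.
#' @export
correlation_template <- function(p, r_min = 0.3,
                                 method = c("threshold", "pvalue"),
                                 alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(is.matrix(p))
  if (nrow(p) < 3L)
    stop("correlation template needs at least 3 training vectors")
  pairs <- trait_pairs(colnames(p))
  keep <- logical(nrow(pairs)); r <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    x <- p[, pairs$a[k]]; y <- p[, pairs$b[k]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next  # undefined correlation
    r[k] <- stats::cor(x, y)
    keep[k] <- if (method == "threshold") abs(r[k]) >= r_min
               else stats::cor.test(x, y)$p.value < alpha
  }
  structure(list(edges = data.frame(a = pairs$a[keep], b = pairs$b[keep],
                                    r = r[keep], weight = abs(r[keep]),
                                    stringsAsFactors = FALSE),
                 codes = colnames(p), r_min = r_min, method = method,
                 alpha = alpha, n = nrow(p)),
            class = "pgk_corr_template")
}

#' @export
print.pgk_corr_template <- function(x, ...) {
  cat(sprintf("Correlation edge template (%s mode, n = %d): %d edges\n",
              x$method, x$n, nrow(x$edges)))
  if (nrow(x$edges)) print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Build a correlation-mode trait graph for one plant
#'
#' Edge set and weights come from a training-cohort
#' [correlation_template()]; node intensities and states are the plant's
#' own.
#'
#' @inheritParams deviation_graph
#' @param template a `pgk_corr_template`.
#' @return A `pgk_graph` with `mode = "correlation"`.
#' @export
correlation_graph <- function(p, template, states = NULL,
                              owner_id = NA_character_,
                              thresholds = c(1 / 3, 2 / 3)) {
  stopifnot(inherits(template, "pgk_corr_template"))
  if (!identical(names(p), template$codes))
    stop("intensity vector traits do not match the template trait set")
  if (is.null(states)) states <- c(discretize(p, thresholds))
  structure(list(owner_id = as.character(owner_id),
                 codes = names(p),
                 intensity = pmin(pmax(p, 0), 1),
                 state = states,
                 edges = template$edges[, c("a", "b", "weight")],
                 epsilon = template$r_min,
                 mode = "correlation"),
            class = "pgk_graph")
}

#' Convert a trait graph to an igraph object
#'
#' @param g a `pgk_graph`.
#' @return An undirected `igraph` graph with vertex attributes `code`,
#'   `intensity`, `state` and edge attribute `weight`.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "pgk_graph"))
  ig <- igraph::make_empty_graph(n = length(g$codes), directed = FALSE)
  ig <- igraph::set_vertex_attr(ig, "name", value = g$codes)
  ig <- igraph::set_vertex_attr(ig, "intensity", value = unname(g$intensity))
  ig <- igraph::set_vertex_attr(ig, "state", value = unname(g$state))
  if (nrow(g$edges))
    ig <- igraph::add_edges(ig, rbind(g$edges$a, g$edges$b),
                            weight = g$edges$weight)
  ig
}

#' @method plot pgk_graph
#' @export
plot.pgk_graph <- function(x, ...) {
  ig <- as_igraph(x)
  igraph::plot.igraph(
    ig,
    vertex.size = 15 + 25 * igraph::V(ig)$intensity,
    edge.width = 1 + 6 * (if (igraph::ecount(ig)) igraph::E(ig)$weight else 1),
    main = paste0("Trait graph: ", x$owner_id), ...)
  invisible(x)
}

graphs_consistent <- function(graphs) {
  codes <- graphs[[1L]]$codes
  ok <- vapply(graphs, function(g) identical(g$codes, codes), logical(1))
  if (!all(ok))
    stop("graphs carry inconsistent trait sets; cannot compare")
  codes
}
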