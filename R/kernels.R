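#' Interaction embedding of a trait graph
#'
#' Maps a perceptual trait graph to its fixed-length interaction vector
#' Phi(G): the edge weights laid out in canonical pair order
#' (see [trait_pairs()]), with exact zeros at pruned coordinates.  In
#' augmented mode the six node intensities are appended, giving a
#' 21-dimensional embedding.  Because every graph over the same trait set
#' lands in the same coordinate system, the Gaussian kernel on this
#' embedding is a bona fide Mercer kernel.
#'
#' @param g a `pgk_graph`.
#' @param augmented append the node-intensity block.
#' @return Named numeric vector of length `m(m-1)/2` (or `+ m` when
#'   augmented).
#' @examples
#' g <- deviation_graph(c(LC = .92, LA = .88, TU = .9, VP = .85, ES = .87, WI = .12),
#'                      epsilon = 0)
#' phi_embedding(g)[["LC-WI"]]  # 0.80
#' @export
phi_embedding <- function(g, augmented = FALSE) {
  stopifnot(inherits(g, "pgk_graph"))
  pairs <- trait_pairs(g$codes)
  v <- stats::setNames(numeric(nrow(pairs)), pairs$label)
  if (nrow(g$edges)) {
    unknown <- setdiff(unique(c(g$edges$a, g$edges$b)), g$codes)
    if (length(unknown))
      stop("unknown trait code in graph edges: ", unknown[1L])
    lab <- ifelse(match(g$edges$a, g$codes) < match(g$edges$b, g$codes),
                  paste(g$edges$a, g$edges$b, sep = "-"),
                  paste(g$edges$b, g$edges$a, sep = "-"))
    v[lab] <- g$edges$weight
  }
  if (augmented) v <- c(v, g$intensity)
  v
}

#' Stack interaction embeddings of a graph collection
#'
#' @param graphs list of `pgk_graph` objects over a common trait set.
#' @param augmented append node intensities.
#' @return Numeric matrix, one row per graph (rownames = owner ids).
#' @export
phi_matrix <- function(graphs, augmented = FALSE) {
  graphs_consistent(graphs)
  x <- t(vapply(graphs, phi_embedding, augmented = augmented,
                FUN.VALUE = phi_embedding(graphs[[1L]], augmented)))
  rownames(x) <- vapply(graphs, function(g) g$owner_id, character(1))
  x
}

#' Median-heuristic kernel bandwidth
#'
#' The median of pairwise Euclidean distances between embeddings - the
#' standard data-driven bandwidth for Gaussian kernels.  Falls back to 1
#' when all embeddings coincide.
#'
#' @param phi embedding matrix (rows = graphs).
#' @return Positive scalar bandwidth.
#' @export
median_heuristic <- function(phi) {
  d <- stats::median(stats::dist(phi))
  if (!is.finite(d) || d <= 0) 1 else d
}

#' Perceptual graph kernel between two embeddings
#'
#' RBF variant: `exp(-||a - b||^2 / (2 sigma^2))`; linear variant: the
#' plain inner product `<a, b>`.
#'
#' @param a,b interaction vectors of equal length.
#' @param sigma bandwidth (> 0), RBF variant only.
#' @param variant `"rbf"` or `"linear"`.
#' @return Scalar similarity; the RBF value lies in (0, 1\] with
#'   `pgk_pair(a, a) = 1`.
#' @export
pgk_pair <- function(a, b, sigma = 1, variant = c("rbf", "linear")) {
  variant <- match.arg(variant)
  if (length(a) != length(b))
    stop("interaction vectors must have equal length")
  if (variant == "linear") return(sum(a * b))
  if (sigma <= 0) stop("'sigma' must be > 0 for the rbf variant")
  exp(-sum((a - b)^2) / (2 * sigma^2))
}

.rbf_gram <- function(phi, sigma) {
  d2 <- as.matrix(stats::dist(phi))^2
  exp(-d2 / (2 * sigma^2))
}

#' Cosine-normalise a kernel matrix
#'
#' `K_ij / sqrt(K_ii K_jj)`; the normalised kernel keeps a unit diagonal
#' and remains positive semi-definite.  Rows with a zero self-similarity
#' (e.g. fully pruned graphs under an inner-product kernel) get zero
#' off-diagonal similarity and a unit diagonal, which preserves positive
#' semi-definiteness.
#'
#' @param K square kernel matrix.
#' @return Normalised matrix of the same shape.
#' @export
normalize_kernel <- function(K) {
  d <- diag(K)
  s <- sqrt(pmax(d, 0))
  zero <- s <= 0
  s[zero] <- 1
  Kn <- K / outer(s, s)
  Kn[zero, ] <- 0
  Kn[, zero] <- 0
  diag(Kn)[zero] <- 1
  Kn
}

#' Gram matrix of a graph collection under a chosen kernel
#'
#' Computes the full similarity matrix for one of: the perceptual graph
#' kernel (`"pgk"`, Gaussian on the interaction embedding;
#' `"pgk_linear"`, inner product of embeddings), the Weisfeiler-Lehman
#' subtree kernel on perceptual-state labels (`"wl"`), or the
#' shortest-path kernel on state-labelled endpoints and binned weighted
#' distances (`"sp"`).  The smallest eigenvalue is recorded as a
#' positive-semi-definiteness certificate.
#'
#' @param graphs list of `pgk_graph` objects over a common trait set.
#' @param kernel kernel type.
#' @param sigma RBF bandwidth; `"median"` resolves to the median
#'   heuristic over the supplied graphs.
#' @param h Weisfeiler-Lehman refinement iterations (>= 0).
#' @param bin_width shortest-path distance bin width (> 0).
#' @param normalized cosine-normalise the matrix (default for `wl`, `sp`
#'   and `pgk_linear`; the RBF kernel already has a unit diagonal).
#' @param augmented use the node-augmented embedding (pgk variants).
#' @return An object of class `pgk_kernel_matrix`: the matrix `K`, owner
#'   `ids`, the resolved `spec`, and `psd_certificate` (smallest
#'   eigenvalue).
#' @export
gram_matrix <- function(graphs, kernel = c("pgk", "pgk_linear", "wl", "sp"),
                        sigma = "median", h = 2L, bin_width = 0.1,
                        normalized = NULL, augmented = FALSE) {
  kernel <- match.arg(kernel)
  if (length(graphs) < 1L) stop("need at least one graph")
  graphs_consistent(graphs)
  if (is.null(normalized)) normalized <- kernel %in% c("pgk_linear", "wl", "sp")
  spec <- list(type = kernel, normalized = normalized)
  if (kernel %in% c("pgk", "pgk_linear")) {
    phi <- phi_matrix(graphs, augmented = augmented)
    spec$augmented <- augmented
    if (kernel == "pgk") {
      if (identical(sigma, "median")) sigma <- median_heuristic(phi)
      if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be > 0")
      spec$sigma <- sigma
      K <- .rbf_gram(phi, sigma)
    } else {
      K <- tcrossprod(phi)
    }
  } else if (kernel == "wl") {
    if (h < 0) stop("'h' must be >= 0")
    spec$h <- h
    K <- tcrossprod(wl_features(graphs, h))
  } else {
    if (bin_width <= 0) stop("'bin_width' must be > 0")
    spec$bin_width <- bin_width
    K <- tcrossprod(sp_features(graphs, bin_width))
  }
  if (normalized) K <- normalize_kernel(K)
  K <- (K + t(K)) / 2
  ids <- vapply(graphs, function(g) g$owner_id, character(1))
  dimnames(K) <- list(ids, ids)
  structure(list(K = K, ids = ids, spec = spec,
                 psd_certificate = min(eigen(K, symmetric = TRUE,
                                             only.values = TRUE)$values)),
            class = "pgk_kernel_matrix")
}

#' @export
print.pgk_kernel_matrix <- function(x, ...) {
  cat(sprintf("%d x %d kernel matrix [%s%s]\n", nrow(x$K), ncol(x$K),
              x$spec$type, if (isTRUE(x$spec$normalized)) ", normalised" else ""))
  extra <- x$spec[setdiff(names(x$spec), c("type", "normalized"))]
  if (length(extra))
    cat("  ", paste(names(extra), unlist(extra), sep = " = ", collapse = ", "),
        "\n", sep = "")
  cat(sprintf("  smallest eigenvalue: %.3e\n", x$psd_certificate))
  invisible(x)
}

#' Weisfeiler-Lehman subtree features on perceptual-state labels
#'
#' Classic WL refinement over the pruned graph topology: the initial node
#' label is the perceptual state; at each iteration a node's label is
#' compressed from (own label, sorted multiset of neighbour labels).  The
#' feature vector concatenates compressed-label counts over iterations
#' `0..h`.  Note that on the unpruned complete graph every node sees the
#' same neighbour multiset up to its own removal, so WL adds little
#' beyond state histograms there; pruning is what gives it topology to
#' work with.
#'
#' @param graphs list of `pgk_graph`.
#' @param h number of refinement iterations (>= 0).
#' @return Numeric feature count matrix, one row per graph.
#' @export
wl_features <- function(graphs, h = 2L) {
  if (h < 0) stop("'h' must be >= 0")
  codes <- graphs_consistent(graphs)
  m <- length(codes)
  adj <- lapply(graphs, function(g) {
    nb <- rep(list(integer(0)), m)
    if (nrow(g$edges)) {
      ia <- match(g$edges$a, codes); ib <- match(g$edges$b, codes)
      for (k in seq_along(ia)) {
        nb[[ia[k]]] <- c(nb[[ia[k]]], ib[k])
        nb[[ib[k]]] <- c(nb[[ib[k]]], ia[k])
      }
    }
    nb
  })
  labels <- lapply(graphs, function(g) unname(g$state))
  blocks <- list(.label_counts(labels))
  if (h > 0) for (it in seq_len(h)) {
    labels <- lapply(seq_along(graphs), function(gi) {
      lab <- labels[[gi]]
      vapply(seq_len(m), function(v) {
        paste0(lab[v], "|", paste(sort(lab[adj[[gi]][[v]]]), collapse = ","))
      }, character(1))
    })
    # compress to a shared dictionary so counts align across graphs
    dict <- sort(unique(unlist(labels)))
    labels <- lapply(labels, function(lab)
      paste0("it", it, "_", match(lab, dict)))
    blocks[[it + 1L]] <- .label_counts(labels)
  }
  do.call(cbind, blocks)
}

.label_counts <- function(labels) {
  dict <- sort(unique(unlist(labels)))
  t(vapply(labels, function(lab)
    as.numeric(table(factor(lab, levels = dict))), numeric(length(dict))))
}

#' Shortest-path kernel features
#'
#' All-pairs shortest paths on the pruned, deviation-weighted graph; each
#' reachable node pair contributes one count to the feature indexed by
#' (unordered endpoint state pair, distance bin of width `bin_width`).
#' The kernel is the inner product of these counts (delta matching on
#' binned triples), hence an explicit and positive semi-definite feature
#' map.  Unreachable pairs are skipped; a totally pruned graph has an
#' empty feature set and zero similarity to everything.
#'
#' @param graphs list of `pgk_graph`.
#' @param bin_width distance bin width (> 0).
#' @return Numeric feature count matrix, one row per graph.
#' @export
sp_features <- function(graphs, bin_width = 0.1) {
  if (bin_width <= 0) stop("'bin_width' must be > 0")
  codes <- graphs_consistent(graphs)
  m <- length(codes)
  feats <- lapply(graphs, function(g) {
    D <- igraph::distances(as_igraph(g), weights = NULL, algorithm = "dijkstra")
    keys <- character(0)
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      if (!is.finite(D[i, j])) next
      st <- sort(c(g$state[i], g$state[j]))
      keys <- c(keys, paste0(st[1L], "|", st[2L], "|",
                             floor(D[i, j] / bin_width + 1e-9)))
    }
    keys
  })
  dict <- sort(unique(unlist(feats)))
  if (!length(dict)) return(matrix(0, length(graphs), 0L))
  t(vapply(feats, function(k)
    as.numeric(table(factor(k, levels = dict))), numeric(length(dict))))
}

#' Positive semi-definiteness check
#'
#' @param K square symmetric matrix, or a `pgk_kernel_matrix`.
#' @param tol eigenvalue tolerance; the verdict is
#'   `min(eigenvalues) >= -tol`.
#' @return List with `min_eigenvalue` and logical `psd`.
#' @export
check_psd <- function(K, tol = 1e-8) {
  if (inherits(K, "pgk_kernel_matrix")) K <- K$K
  if (!is.matrix(K) || nrow(K) != ncol(K))
    stop("'K' must be a square matrix")
  if (max(abs(K - t(K))) > 1e-10)
    stop("'K' is asymmetric beyond 1e-10")
  lam <- min(eigen((K + t(K)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  list(min_eigenvalue = lam, psd = lam >= -tol)
}

#' Write / read a kernel matrix as delimited text
#'
#' The matrix is written as tab-separated values with a header row of
#' owner ids; the kernel spec and PSD certificate go to a JSON sidecar
#' (`<path>.meta.json`).
#'
#' @param km a `pgk_kernel_matrix`.
#' @param path destination / source TSV file.
#' @return `path` / a `pgk_kernel_matrix`.
#' @export
write_kernel_matrix <- function(km, path) {
  stopifnot(inherits(km, "pgk_kernel_matrix"))
  utils::write.table(km$K, path, sep = "\t", col.names = NA, quote = FALSE)
  jsonlite::write_json(list(spec = km$spec, ids = km$ids,
                            psd_certificate = km$psd_certificate),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kernel_matrix
#' @export
read_kernel_matrix <- function(path) {
  K <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1L, check.names = FALSE))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  structure(list(K = K, ids = meta$ids, spec = as.list(meta$spec),
                 psd_certificate = meta$psd_certificate),
            class = "pgk_kernel_matrix")
}
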