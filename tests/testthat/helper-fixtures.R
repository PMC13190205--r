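# Reference trait anchors: healthy and stressed plants on the intensity scale
healthy_anchor <- c(LC = 0.92, LA = 0.88, TU = 0.90, VP = 0.85, ES = 0.87,
                    WI = 0.12)
stress_anchor <- c(LC = 0.45, LA = 0.41, TU = 0.39, VP = 0.72, ES = 0.36,
                   WI = 0.91)

# wrap an intensity matrix as a minimal trait table
records_from_matrix <- function(p, condition = NULL) {
  out <- data.frame(plant_id = paste0("p", seq_len(nrow(p))),
                    zone_id = "Z01", acre_id = "A1",
                    as.data.frame(p), stringsAsFactors = FALSE)
  if (!is.null(condition)) out$condition <- condition
  out
}

# random intensity matrix over the canonical traits
random_intensities <- function(n, seed) {
  set.seed(seed)
  p <- matrix(runif(n * 6), n, 6,
              dimnames = list(paste0("p", seq_len(n)), trait_codes()))
  p
}

# hand-built small graph over an arbitrary trait set, for kernel oracles
make_graph <- function(codes, states, edges, intensity = NULL,
                       owner = "g") {
  if (is.null(intensity))
    intensity <- stats::setNames(rep(0.5, length(codes)), codes)
  structure(list(owner_id = owner, codes = codes,
                 intensity = intensity,
                 state = stats::setNames(states, codes),
                 edges = edges, epsilon = 0, mode = "deviation"),
            class = "pgk_graph")
}

edge_df <- function(a = character(), b = character(), weight = numeric()) {
  data.frame(a = a, b = b, weight = weight, stringsAsFactors = FALSE)
}

# independent brute-force enumeration of retained deviation edges
brute_force_edges <- function(p, epsilon) {
  kept <- 0L
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i < j && abs(p[i] - p[j]) >= epsilon) kept <- kept + 1L
    }
  }
  kept
}

# independent naive WL refinement: uncompressed string labels all the way
naive_wl_features <- function(graphs, h) {
  codes <- graphs[[1]]$codes
  nb <- function(g, v) {
    out <- character(0)
    if (nrow(g$edges) == 0) return(out)
    for (k in seq_len(nrow(g$edges))) {
      if (g$edges$a[k] == v) out <- c(out, g$edges$b[k])
      if (g$edges$b[k] == v) out <- c(out, g$edges$a[k])
    }
    out
  }
  relabel <- function(g, lab) {
    vapply(codes, function(v) {
      paste0(lab[v], "(", paste(sort(lab[nb(g, v)]), collapse = ";"), ")")
    }, character(1))
  }
  all_feats <- lapply(graphs, function(g) {
    lab <- g$state
    feats <- paste0("h0:", unname(lab))
    if (h > 0) for (it in seq_len(h)) {
      lab <- relabel(g, lab)
      feats <- c(feats, paste0("h", it, ":", unname(lab)))
    }
    feats
  })
  dict <- sort(unique(unlist(all_feats)))
  t(vapply(all_feats, function(f)
    as.numeric(table(factor(f, levels = dict))), numeric(length(dict))))
}
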