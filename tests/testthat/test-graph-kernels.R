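test_that("the interaction embedding lays edge weights out in canonical pair order", {
  g <- deviation_graph(healthy_anchor, epsilon = 0)
  v <- phi_embedding(g)
  expect_equal(length(v), 15L)
  expect_equal(names(v), trait_pairs()$label)
  expect_equal(unname(v["LC-WI"]), 0.80)
  expect_equal(unname(v["LC-LA"]), abs(0.92 - 0.88))
  # pruned coordinates are exact zeros
  gp <- deviation_graph(healthy_anchor, epsilon = 0.1)
  vp <- phi_embedding(gp)
  expect_equal(sum(vp != 0), 5L)
  expect_equal(vp[vp != 0], v[vp != 0])
  # full pruning gives the zero vector
  u <- stats::setNames(rep(0.5, 6), trait_codes())
  expect_equal(unname(phi_embedding(deviation_graph(u, 0.01))), rep(0, 15))
  # augmented mode appends the six node intensities
  expect_equal(length(phi_embedding(g, augmented = TRUE)), 21L)
  expect_equal(unname(phi_embedding(g, augmented = TRUE)[16:21]),
               unname(healthy_anchor))
})

test_that("embedding is deterministic and rejects foreign trait codes", {
  g1 <- deviation_graph(stress_anchor, epsilon = 0.05)
  g2 <- deviation_graph(stress_anchor, epsilon = 0.05)
  expect_identical(phi_embedding(g1), phi_embedding(g2))
  bad <- g1
  bad$edges$a[1] <- "XX"
  expect_error(phi_embedding(bad), "XX")
})

test_that("pairwise kernel values match independent arithmetic", {
  a <- phi_embedding(deviation_graph(healthy_anchor, epsilon = 0))
  b <- phi_embedding(deviation_graph(stress_anchor, epsilon = 0))
  expect_equal(pgk_pair(a, a), 1.0)
  # ||a - b||^2 = 2 sigma^2  =>  exp(-1)
  d <- sqrt(sum((a - b)^2))
  expect_equal(pgk_pair(a, b, sigma = d / sqrt(2)), exp(-1))
  # brute-force oracle: explicit loop over the 15 coordinate differences
  ss <- 0
  for (k in 1:15) ss <- ss + (a[[k]] - b[[k]])^2
  expect_equal(pgk_pair(a, b, sigma = 1), exp(-ss / 2))
  expect_equal(pgk_pair(a, b, variant = "linear"), sum(a * b))
  expect_error(pgk_pair(a, b, sigma = 0), "sigma")
  expect_error(pgk_pair(a, b[1:3]), "length")
})

test_that("gram matrices have the advertised structure", {
  g <- deviation_graph(healthy_anchor, epsilon = 0.05, owner_id = "h")
  km <- gram_matrix(list(g, g, g), kernel = "pgk", sigma = 0.5)
  expect_equal(unname(km$K), matrix(1, 3, 3))
  graphs <- build_graphs(random_intensities(8, 31), epsilon = 0.05)
  lin <- gram_matrix(graphs, kernel = "pgk_linear", normalized = FALSE)
  phi <- phi_matrix(graphs)
  expect_equal(unname(lin$K), unname(tcrossprod(phi)))
  rbf <- gram_matrix(graphs, kernel = "pgk", sigma = 0.5)
  expect_equal(unname(diag(rbf$K)), rep(1, 8))
  expect_equal(rbf$spec$sigma, 0.5)
  expect_error(gram_matrix(graphs, kernel = "pgk", sigma = -1), "sigma")
})

test_that("median-heuristic bandwidth is the median pairwise distance", {
  phi <- matrix(c(0, 0, 3, 4, 6, 8), 3, 2, byrow = TRUE)
  # pairwise distances: 5, 10, 5 -> median 5
  expect_equal(median_heuristic(phi), 5)
  expect_equal(median_heuristic(matrix(1, 4, 2)), 1)  # degenerate fallback
})

test_that("WL at h = 0 is the state-histogram kernel", {
  graphs <- build_graphs(random_intensities(6, 17), epsilon = 0.05)
  f0 <- wl_features(graphs, 0)
  hist <- t(vapply(graphs, function(g)
    as.numeric(table(factor(g$state, levels = c("high", "low", "medium")))),
    numeric(3)))
  expect_equal(unname(tcrossprod(f0)), unname(tcrossprod(hist)))
})

test_that("WL separates a path from a triangle after one refinement", {
  path <- make_graph(c("A", "B", "C"), c("low", "high", "low"),
                     edge_df(c("A", "B"), c("B", "C"), c(1, 1)))
  tri <- make_graph(c("A", "B", "C"), c("low", "high", "low"),
                    edge_df(c("A", "B", "A"), c("B", "C", "C"), c(1, 1, 1)))
  f0 <- wl_features(list(path, tri), 0)
  expect_equal(f0[1, ], f0[2, ])  # identical state histograms
  K1 <- tcrossprod(wl_features(list(path, tri), 1))
  # hand refinement at h = 1:
  #   path: A -> low(high), B -> high(low,low), C -> low(high)
  #   tri:  A -> low(high,low), B -> high(low,low), C -> low(high,low)
  # h0 block: counts (high=1, low=2) in both -> 1*1 + 2*2 = 5
  # h1 block: only B's label is shared -> 1; so k12 = 5 + 1
  expect_equal(K1[1, 2], 6)
  # self products: h0 gives 1^2+2^2 = 5; h1 gives 2^2+1^2 = 5
  expect_equal(K1[1, 1], 10)
  expect_equal(K1[2, 2], 10)
})

test_that("label-isomorphic graphs are indistinguishable to WL", {
  g1 <- make_graph(c("A", "B", "C"), c("low", "high", "medium"),
                   edge_df(c("A", "B"), c("B", "C"), c(1, 1)))
  # same labelled structure, different trait naming/order
  g2 <- make_graph(c("A", "B", "C"), c("medium", "high", "low"),
                   edge_df(c("C", "A"), c("B", "B"), c(1, 1)))
  K <- tcrossprod(wl_features(list(g1, g2), 2))
  expect_equal(K[1, 1], K[1, 2])
  expect_equal(K[1, 1], K[2, 2])
  expect_error(wl_features(list(g1), -1), "h")
})

test_that("compressed WL features agree with a naive recursive oracle", {
  for (seed in 1:4) {
    graphs <- build_graphs(random_intensities(4, seed + 40),
                           epsilon = 0.15)
    for (h in 0:2) {
      K <- tcrossprod(wl_features(graphs, h))
      K_naive <- tcrossprod(naive_wl_features(graphs, h))
      expect_equal(unname(K), unname(K_naive))
    }
  }
})

test_that("shortest-path features match a hand-executed computation", {
  path <- make_graph(c("A", "B", "C"), c("low", "high", "low"),
                     edge_df(c("A", "B"), c("B", "C"), c(1, 1)))
  f <- sp_features(list(path), bin_width = 0.1)
  # shortest paths: A-B = 1 (low,high), B-C = 1 (high,low), A-C = 2 (low,low)
  expect_equal(sum(f), 3)
  expect_equal(unname(tcrossprod(f)[1, 1]), 2^2 + 1^2)  # {bin10:lh x2, bin20:ll x1}
  empty <- make_graph(c("A", "B", "C"), c("low", "high", "low"), edge_df())
  K <- tcrossprod(sp_features(list(path, empty), 0.1))
  expect_equal(K[1, 2], 0)
  expect_equal(K[2, 2], 0)
  expect_error(sp_features(list(path), bin_width = 0), "bin_width")
})

test_that("PSD checks give analytic eigenvalues and enforce symmetry", {
  r <- check_psd(diag(3))
  expect_equal(r$min_eigenvalue, 1)
  expect_true(r$psd)
  r2 <- check_psd(matrix(c(1, 2, 2, 1), 2))
  expect_equal(r2$min_eigenvalue, -1)
  expect_false(r2$psd)
  expect_error(check_psd(matrix(c(1, 2, 0, 1), 2)), "asymmetric")
  expect_error(check_psd(matrix(1, 2, 3)), "square")
})

test_that("kernel similarity decreases with embedding distance at fixed sigma", {
  base <- rep(0, 15)
  d <- seq(0.1, 1.5, by = 0.2)
  vals <- vapply(d, function(dd) {
    other <- base; other[1] <- dd
    pgk_pair(base, other, sigma = 0.5)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("kernel matrices round-trip through delimited text", {
  graphs <- build_graphs(random_intensities(5, 77), epsilon = 0.05)
  km <- gram_matrix(graphs, kernel = "pgk", sigma = 0.7)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_kernel_matrix(km, path)
  km2 <- read_kernel_matrix(path)
  expect_equal(km2$K, km$K, tolerance = 1e-12)
  expect_equal(km2$spec$sigma, 0.7)
  expect_equal(km2$ids, km$ids)
})

test_that("normalised kernels keep a unit diagonal and handle zero rows", {
  graphs <- build_graphs(random_intensities(10, 55), epsilon = 0.05)
  K <- tcrossprod(phi_matrix(graphs))
  Kn <- normalize_kernel(K)
  expect_equal(unname(diag(Kn)), rep(1, 10))
  expect_true(check_psd(Kn, 1e-8)$psd)
  # a fully pruned graph: zero self-similarity handled without NaN
  u <- stats::setNames(rep(0.5, 6), trait_codes())
  gz <- deviation_graph(u, epsilon = 0.01)
  K2 <- tcrossprod(phi_matrix(c(graphs, list(gz))))
  Kn2 <- normalize_kernel(K2)
  expect_false(anyNA(Kn2))
  expect_equal(Kn2[11, 11], 1)
  expect_equal(sum(abs(Kn2[11, -11])), 0)
})
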