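test_that("deviation graphs on the reference anchors retain 5 and 9 edges", {
  gh <- deviation_graph(healthy_anchor, epsilon = 0.1)
  gs <- deviation_graph(stress_anchor, epsilon = 0.1)
  expect_equal(nrow(gh$edges), brute_force_edges(healthy_anchor, 0.1))
  expect_equal(nrow(gs$edges), brute_force_edges(stress_anchor, 0.1))
  expect_equal(nrow(gh$edges), 5L)
  expect_equal(nrow(gs$edges), 9L)
  # all retained healthy edges touch the wilting index
  expect_true(all(gh$edges$a == "WI" | gh$edges$b == "WI"))
})

test_that("edge weights are exact absolute deviations above the threshold", {
  for (seed in 1:10) {
    p <- random_intensities(1, seed)[1, ]
    eps <- runif(1, 0, 0.3)
    g <- deviation_graph(p, epsilon = eps)
    expect_true(all(g$edges$weight >= eps))
    expect_equal(g$edges$weight, abs(p[g$edges$a] - p[g$edges$b]),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_lte(nrow(g$edges), 15L)
  }
})

test_that("epsilon = 0 gives the complete graph, uniform vectors the empty one", {
  p <- random_intensities(1, 2)[1, ]
  expect_equal(nrow(deviation_graph(p, epsilon = 0)$edges), 15L)
  u <- stats::setNames(rep(0.4, 6), trait_codes())
  expect_equal(nrow(deviation_graph(u, epsilon = 0.01)$edges), 0L)
  expect_error(deviation_graph(p, epsilon = -0.1), "epsilon")
})

test_that("edge count is non-increasing in epsilon", {
  p <- random_intensities(1, 6)[1, ]
  eps <- seq(0, 1, by = 0.05)
  counts <- vapply(eps, function(e) nrow(deviation_graph(p, e)$edges),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("absolute-deviation weights satisfy the triangle inequality", {
  for (seed in 1:5) {
    p <- random_intensities(1, seed + 20)[1, ]
    for (i in 1:5) for (j in (i + 1):6) for (k in seq_len(6)[-c(i, j)]) {
      wij <- abs(p[i] - p[j]); wik <- abs(p[i] - p[k]); wkj <- abs(p[k] - p[j])
      expect_lte(wij, wik + wkj + 1e-12)
    }
  }
})

test_that("graph construction is equivariant under trait permutation", {
  p <- random_intensities(1, 8)[1, ]
  g <- deviation_graph(p, epsilon = 0.05)
  set.seed(1)
  perm <- sample(6)
  gp <- deviation_graph(p[perm], epsilon = 0.05)
  canon <- function(g) {
    e <- g$edges
    ab <- t(apply(e[, c("a", "b")], 1, sort))
    o <- order(ab[, 1], ab[, 2])
    data.frame(a = ab[o, 1], b = ab[o, 2], w = e$weight[o],
               row.names = NULL)
  }
  expect_equal(canon(gp), canon(g), tolerance = 1e-12)
  expect_equal(sort(names(gp$intensity)), sort(names(g$intensity)))
})

test_that("correlation templates keep strong pairs and drop flat traits", {
  set.seed(42)
  n <- 500
  x <- runif(n)
  p <- cbind(LC = x, LA = 1 - 0.5 * x,           # perfectly linear pair
             TU = runif(n), VP = runif(n),       # independent pair
             ES = runif(n), WI = rep(0.3, n))    # constant trait
  tpl <- correlation_template(p, r_min = 0.3)
  lab <- paste(tpl$edges$a, tpl$edges$b, sep = "-")
  expect_true("LC-LA" %in% lab)
  expect_equal(tpl$edges$weight[lab == "LC-LA"], 1.0, tolerance = 1e-12)
  expect_false("TU-VP" %in% lab)                 # |r| ~ 0 at n = 500
  expect_false(any(tpl$edges$a == "WI" | tpl$edges$b == "WI"))
  expect_error(correlation_template(p[1:2, ]), "3")
})

test_that("correlation-mode graphs share the template edges with own node data", {
  p <- random_intensities(20, 13)
  tpl <- correlation_template(p, r_min = 0.1)
  g <- correlation_graph(p[1, ], tpl, owner_id = "p1")
  expect_equal(g$mode, "correlation")
  expect_equal(g$edges$weight, tpl$edges$weight)
  expect_equal(unname(g$intensity), unname(p[1, ]))
})

test_that("graph serialisation round-trips losslessly in both formats", {
  g <- deviation_graph(healthy_anchor, epsilon = 0.1, owner_id = "plant-1")
  for (ext in c(".graphml", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_graph_file(g, path)
    g2 <- read_graph_file(path)
    expect_equal(g2$codes, g$codes)
    expect_equal(g2$intensity, g$intensity, tolerance = 1e-12)
    expect_equal(g2$state, g$state)
    expect_equal(g2$edges$weight, g$edges$weight, tolerance = 1e-12)
    expect_equal(g2$edges$a, g$edges$a)
    expect_equal(g2$epsilon, g$epsilon)
    expect_equal(g2$mode, g$mode)
    expect_equal(g2$owner_id, g$owner_id)
  }
})

test_that("an edgeless graph survives serialisation", {
  u <- stats::setNames(rep(0.4, 6), trait_codes())
  g <- deviation_graph(u, epsilon = 0.2)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, path)
  g2 <- read_graph_file(path)
  expect_equal(length(g2$codes), 6L)
  expect_equal(nrow(g2$edges), 0L)
})

test_that("a graph file missing a node entry fails naming the trait", {
  g <- deviation_graph(healthy_anchor, epsilon = 0.1)
  path <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  node <- xml2::xml_find_first(doc, ".//g:node[@id='VP']", ns)
  xml2::xml_remove(node)
  xml2::write_xml(doc, path)
  expect_error(read_graph_file(path), "VP")
})
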