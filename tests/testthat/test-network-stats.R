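test_that("network construction filters, deduplicates and labels nodes", {
  edges <- data.frame(a = c("A", "A", "B", "C", "C", "D"),
                      b = c("B", "B", "C", "A", "C", "E"),
                      score = c(899, 950, 900, 920, 999, 800))
  g <- build_network(edges)
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 3)  # A-B (dedup, max 950), B-C, C-A; D-E dropped
  expect_equal(sort(el$score), c(900, 920, 950))
  expect_false(any(el$a == el$b))  # self-loop C-C dropped
  # any-domain-discontinuous labels the protein discontinuous
  nc <- data.frame(protein = c("A", "A", "B"),
                   domain_class = c("continuous", "discontinuous", "continuous"))
  g2 <- build_network(edges, node_class = nc)
  expect_identical(igraph::vertex_attr(g2, "continuity",
                                       igraph::V(g2)[name == "A"]),
                   "discontinuous")
  expect_warning(build_network(data.frame(a = "A", b = "B", score = NA)),
                 "malformed")
})

test_that("centralities match closed forms on canonical graphs", {
  p3 <- build_network(data.frame(a = c("L", "C"), b = c("C", "R"),
                                 score = c(900, 900)))
  ct <- centralities(p3)
  ctr <- ct[ct$node == "C", ]
  expect_equal(ctr$degree_centrality, 1)
  expect_equal(ctr$betweenness_centrality, 1)
  k4 <- build_network(data.frame(a = c("A","A","A","B","B","C"),
                                 b = c("B","C","D","C","D","D"),
                                 score = 900))
  expect_true(all(centralities(k4)$betweenness == 0))
  expect_error(centralities(igraph::make_empty_graph(0)), "empty")
})

test_that("betweenness equals the brute-force path-count oracle", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(5:9, 1)
    repeat {
      adj <- matrix(0, n, n)
      adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, 0.45)
      adj <- adj + t(adj)
      if (any(adj > 0)) break
    }
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    igraph::V(g)$name <- as.character(1:n)
    got <- centralities(g)$betweenness
    expect_equal(got, betweenness_bruteforce(adj), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney matches its exact small-sample distribution", {
  # identical samples: U = n1 n2 / 2 by midranks
  r <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$U, 9 / 2)
  # complete separation
  expect_equal(mann_whitney(1:4, 11:14)$U, 0)
  expect_equal(mann_whitney(11:14, 1:4)$U, 16)
  # n1 = n2 = 4: exact p equals enumeration over all 70 splits
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.4, 2.8, 6.0, 0.9)
  r <- mann_whitney(x, y)
  pool <- c(x, y)
  us <- apply(utils::combn(8, 4), 2, function(ix) {
    xx <- pool[ix]; yy <- pool[-ix]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  })
  u_obs <- r$U
  p_exact <- mean(abs(us - 8) >= abs(u_obs - 8))  # two-sided around n1n2/2
  expect_equal(r$p_value, p_exact, tolerance = 1e-10)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("chi-square on 2x2 tables reproduces hand computations", {
  r <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  expect_equal(r$cramers_v, 1)
  r2 <- chi_square_2x2(matrix(c(25, 25, 25, 25), 2))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$cramers_v, 0)
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "zero margin")
  # Yates correction is available but off by default
  t3 <- matrix(c(12, 5, 7, 14), 2)
  expect_gt(chi_square_2x2(t3)$statistic,
            chi_square_2x2(t3, correct = TRUE)$statistic)
})

test_that("Spearman matches the exhaustive rank-permutation oracle", {
  expect_equal(spearman(1:6, c(2, 4, 5, 7, 9, 20))$rho, 1)
  expect_equal(spearman(1:6, -(1:6))$rho, -1)
  x <- c(0.3, 1.2, 0.7, 2.5, 1.9, 0.1)
  y <- c(5.1, 2.2, 4.4, 0.9, 3.3, 6.6)
  r <- spearman(x, y)
  rx <- rank(x)
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  rhos <- apply(perms, 1, function(p) cor(rx, p))
  expect_equal(r$p_value, mean(abs(rhos) >= abs(r$rho) - 1e-12),
               tolerance = 1e-10)
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("Wald intervals reproduce printed consistency CIs", {
  expect_equal(round(wald_ci(3407, 3423), 4), c(0.9930, 0.9976))
  expect_equal(round(wald_ci(3461, 3478), 4), c(0.9928, 0.9974))
  expect_equal(wald_ci(10, 10), c(1, 1))
  expect_equal(wald_ci(0, 10)[1], 0)
  # Wilson stays inside [0,1] and differs from Wald at the extremes
  w <- wilson_ci(10, 10)
  expect_lt(w[1], 1); expect_equal(w[2], 1)
})

test_that("log-log regression recovers exact power laws with coverage", {
  x <- c(1, 2, 5, 10, 20, 50)
  f <- suppressWarnings(loglog_powerlaw_fit(x, 3 * x^(-2)))
  expect_equal(f$slope, -2, tolerance = 1e-10)
  expect_equal(f$intercept, log10(3), tolerance = 1e-10)
  expect_error(loglog_powerlaw_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
  # minimal n = 3 input still yields a defined, wide band
  f3 <- loglog_powerlaw_fit(c(1, 2, 4), c(2, 3.9, 8.2))
  expect_true(all(is.finite(f3$band$fit)))
  expect_true(all(f3$band$hi >= f3$band$lo))
  # slope CI covers the truth at about the nominal rate
  set.seed(9)
  cover <- logical(400)
  for (i in seq_along(cover)) {
    xx <- 10^runif(15, 0, 2)
    yy <- 5 * xx^(-1.5) * 10^rnorm(15, 0, 0.1)
    ci <- loglog_powerlaw_fit(xx, yy)$slope_ci
    cover[i] <- ci[1] <= -1.5 && -1.5 <= ci[2]
  }
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("Ward clustering keeps planted blocks contiguous", {
  set.seed(10)
  m <- matrix(10^rnorm(64, -2, 0.1), 8, 8)
  m[1:4, 1:4] <- 10^rnorm(16, 1, 0.1)
  m[5:8, 5:8] <- 10^rnorm(16, 1, 0.1)
  cl <- cluster_interaction_matrix(m)
  blk <- (cl$row_order <= 4)
  expect_true(all(diff(which(blk)) == 1) || all(diff(which(!blk)) == 1))
  # permutation invariance of the dendrogram heights
  perm <- sample(8)
  cl2 <- cluster_interaction_matrix(m[perm, ])
  expect_equal(sort(cl2$row_hclust$height), sort(cl$row_hclust$height),
               tolerance = 1e-10)
  # zeros get a pseudocount rather than -Inf
  m0 <- m; m0[1, 1] <- 0
  expect_silent(cluster_interaction_matrix(m0))
  expect_error(cluster_interaction_matrix(matrix(1, 3, 3)), "all-equal")
  expect_error(cluster_interaction_matrix(m[1, , drop = FALSE]), ">= 2")
})
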