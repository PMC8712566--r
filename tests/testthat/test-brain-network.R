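# band filtering, VAR fitting, Granger causality, spanning trees, metrics

test_that("bandpass keeps in-band tones and rejects out-of-band ones", {
  fs <- 512
  t <- seq(0, 8, length.out = 4096)
  x6 <- sin(2 * pi * 6 * t)
  x20 <- sin(2 * pi * 20 * t)
  y6 <- bandpass(x6, fs, 4, 8)
  y20 <- bandpass(x20, fs, 4, 8)
  a6 <- fft_peak_amplitude(y6, fs, 6)
  a20 <- fft_peak_amplitude(y20, fs, 20)
  expect_gt(a6, 0.95)
  expect_lt(a6, 1.05)
  expect_lt(20 * log10(a20 / 1), -40)   # >= 40 dB down
  expect_equal(bandpass(rep(0, 1024), 128, 4, 8), rep(0, 1024))
  expect_error(bandpass(x6, fs, 200, 300), "Nyquist")
  # matrix input filters row-wise and keeps shape/names
  m <- rbind(a = x6, b = x20)
  fm <- bandpass(m, fs, 4, 8)
  expect_identical(dim(fm), dim(m))
  expect_identical(rownames(fm), c("a", "b"))
  expect_equal(fm[1, ], y6)
})

test_that("VAR order selection recovers the generating order", {
  hits <- 0
  for (rep in 1:20) {
    set.seed(300 + rep)
    A <- list(matrix(c(0.5, 0.1, 0.2, 0.4), 2, 2),
              matrix(c(-0.3, 0.05, 0, -0.25), 2, 2))
    x <- choqfuse:::.simulate_var(A, 2000)
    fit <- fit_var(x, max_order = 6)
    if (fit$order == 2) hits <- hits + 1
  }
  expect_gte(hits, 18)  # >= 90% of replicates
})

test_that("white noise yields near-zero coefficients; constants error", {
  set.seed(310)
  x <- matrix(rnorm(2 * 3000), 2)
  fit <- fit_var(x, max_order = 3)
  # OLS bound: |coef| within ~4 standard errors of zero
  expect_lt(max(abs(fit$coefficients)), 4 / sqrt(3000) * 2)
  expect_error(fit_var(matrix(1, 2, 1000), max_order = 2), "zero variance")
  expect_error(fit_var(matrix(rnorm(100), 2), max_order = 20), "too short")
})

test_that("pairwise GC finds the coupling direction", {
  set.seed(320)
  n <- 4096
  y <- rnorm(n)
  x <- c(0, 0.5 * y[-n]) + rnorm(n)
  f_yx <- pairwise_gc(x, y, order = 2)
  f_xy <- pairwise_gc(y, x, order = 2)
  expect_gt(f_yx, 0.05)
  expect_gt(f_yx, f_xy)
  # lagged copy: strong forward GC, weak reverse
  z <- c(0, x[-n]) + 1e-3 * rnorm(n)
  expect_gt(pairwise_gc(z, x, order = 1), 1)
  expect_lt(pairwise_gc(x, z, order = 1), pairwise_gc(z, x, order = 1))
  # independent white noise: F below the permutation null quantile
  a <- rnorm(n); b <- rnorm(n)
  f0 <- pairwise_gc(a, b, order = 2)
  null_f <- vapply(1:100, function(i) {
    set.seed(5000 + i)
    pairwise_gc(a, sample(b), order = 2)
  }, numeric(1))
  expect_lt(f0, quantile(null_f, 0.99))
  # non-negativity of nested least squares
  expect_gte(f0, -1e-12)
})

test_that("connectivity localizes a single coupling and is equivariant", {
  set.seed(330)
  A <- list(diag(0.4, 3), diag(-0.2, 3))
  A[[1]][2, 1] <- 0.6   # channel 1 drives channel 2
  ep <- choqfuse:::.simulate_var(A, 2048)
  rownames(ep) <- c("c1", "c2", "c3")
  band <- tibble::tibble(band = "broad", lo = 1, hi = 45)
  W <- connectivity(ep, fs = 128, bands = band, max_order = 4)$broad
  expect_equal(unname(diag(W)), c(0, 0, 0))
  expect_equal(max(W), W["c2", "c1"])   # the planted 1 -> 2 coupling
  others <- W
  others["c2", "c1"] <- 0
  expect_gt(W["c2", "c1"], 2 * max(others))
  # permuting channels permutes the matrix consistently
  perm <- c(3, 1, 2)
  W2 <- connectivity(ep[perm, ], fs = 128, bands = band, max_order = 4)$broad
  expect_equal(W2, W[perm, perm], tolerance = 1e-10)
  # averaging identical epochs changes nothing
  W3 <- connectivity(list(ep, ep), fs = 128, bands = band, max_order = 4)$broad
  expect_equal(W3, W, tolerance = 1e-10)
})

test_that("Kruskal maximum spanning tree: worked example and oracle checks", {
  # 4-node example: weights AB=4, AC=3, AD=2, BC=BD=CD=1 -> star at A
  W <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  W["A", "B"] <- W["B", "A"] <- 4
  W["A", "C"] <- W["C", "A"] <- 3
  W["A", "D"] <- W["D", "A"] <- 2
  W["B", "C"] <- W["C", "B"] <- 1
  W["B", "D"] <- W["D", "B"] <- 1
  W["C", "D"] <- W["D", "C"] <- 1
  tr <- max_spanning_tree(W)
  el <- igraph::as_edgelist(tr)
  expect_equal(igraph::ecount(tr), 3)
  expect_setequal(paste(el[, 1], el[, 2]), c("A B", "A C", "A D"))
  expect_equal(sum(igraph::E(tr)$weight), 9)

  # random complete graphs: total weight matches igraph's MST of negated
  # weights, and the tree has n - 1 edges
  set.seed(340)
  for (rep in 1:10) {
    n <- sample(5:19, 1)
    S <- matrix(0, n, n)
    S[upper.tri(S)] <- runif(n * (n - 1) / 2)
    S <- S + t(S)
    tr <- max_spanning_tree(S)
    expect_equal(igraph::ecount(tr), n - 1)
    g <- igraph::graph_from_adjacency_matrix(-S, weighted = TRUE,
                                             mode = "undirected")
    ref <- igraph::mst(g)
    expect_equal(sum(igraph::E(tr)$weight), -sum(igraph::E(ref)$weight),
                 tolerance = 1e-10)
  }

  # a tree input is its own spanning tree
  S <- matrix(0, 5, 5)
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(3, 5))) {
    S[e[1], e[2]] <- S[e[2], e[1]] <- runif(1, 0.5, 1)
  }
  tr <- max_spanning_tree(S)
  el <- igraph::as_edgelist(tr)
  expect_setequal(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])),
                  c("1 2", "2 3", "3 4", "3 5"))

  # disconnected input errors
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- 1
  expect_error(max_spanning_tree(S), "disconnected")
})

test_that("tree metrics: closed forms for stars and paths", {
  star <- igraph::make_star(19, mode = "undirected")
  ms <- mst_metrics(star)
  expect_equal(ms$max_degree, 18L)
  expect_equal(ms$leaf_fraction, 18 / 19)
  expect_equal(ms$diameter, 2L)
  expect_equal(ms$max_bc, 1)           # all pairs cross the hub
  expect_equal(ms$hierarchy, 18 / (2 * 18 * 1))

  path <- igraph::make_ring(19, circular = FALSE)
  mp <- mst_metrics(path)
  expect_equal(mp$max_degree, 2L)
  expect_equal(mp$leaf_fraction, 2 / 19)
  expect_equal(mp$diameter, 18L)
  expect_equal(mp$max_bc_raw, 81)      # centre node: 9 * 9 pairs
  expect_error(mst_metrics(igraph::make_ring(5)), "not a spanning tree")
})

test_that("metrics equal the brute-force oracle on enumerated trees", {
  # exhaustive over all labelled trees for n = 3..5; sampled for n = 6..8
  check_tree <- function(edges, n) {
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    got <- mst_metrics(g)
    want <- oracle_tree_metrics(edges, n)
    expect_equal(got$max_degree, as.integer(want$max_degree))
    expect_equal(got$max_bc, want$max_bc, tolerance = 1e-12)
    expect_equal(got$max_bc_raw, want$max_bc_raw)
    expect_equal(got$leaf_fraction, want$leaf_fraction)
    expect_equal(got$diameter, as.integer(want$diameter))
    expect_equal(got$hierarchy, want$hierarchy, tolerance = 1e-12)
  }
  for (n in 3:5) {
    seqs <- expand.grid(rep(list(seq_len(n)), n - 2))
    for (r in seq_len(nrow(seqs))) {
      check_tree(prufer_decode(as.integer(seqs[r, ]), n), n)
    }
  }
  set.seed(350)
  for (n in 6:8) {
    for (rep in 1:60) {
      check_tree(prufer_decode(sample(n, n - 2, replace = TRUE), n), n)
    }
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(360)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    edges <- prufer_decode(sample(n, n - 2, replace = TRUE), n)
    perm <- sample(n)
    edges2 <- matrix(perm[edges], ncol = 2)
    g1 <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g2 <- igraph::graph_from_edgelist(edges2, directed = FALSE)
    expect_equal(mst_metrics(g1), mst_metrics(g2))
  }
})
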