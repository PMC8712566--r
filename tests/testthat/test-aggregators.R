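# Choquet integral, its generalizations, OWA and baselines

test_that("classic Choquet examples", {
  m_add <- sugeno_measure(c(0.5, 0.3, 0.2), lambda = 0)
  # additive measure reduces to the weighted mean
  expect_equal(choquet(c(0.9, 0.6, 0.3), m_add),
               0.9 * 0.5 + 0.6 * 0.3 + 0.3 * 0.2)
  # idempotency via telescoping with g(X) = 1
  m <- sugeno_measure(c(0.3, 0.3, 0.3))
  expect_equal(choquet(rep(0.42, 3), m), 0.42)
  # against the independent summation oracle
  h <- c(0.9, 0.6, 0.3)
  expect_equal(choquet(h, m), oracle_integral("choquet", h, c(0.3, 0.3, 0.3)),
               tolerance = 1e-12)
})

test_that("the classic integral is internal and monotone", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    h <- runif(n)
    g <- rand_densities(n)
    m <- sugeno_measure(g)
    v <- choquet(h, m)
    expect_gte(v, min(h) - 1e-12)
    expect_lte(v, max(h) + 1e-12)
    i <- sample(n, 1)
    h2 <- h
    h2[i] <- min(1, h[i] + runif(1, 0, 1 - h[i]))
    expect_gte(choquet(h2, m), v - 1e-12)
  }
})

test_that("CM with the product t-norm recovers the classic integral", {
  set.seed(44)
  prod_spec <- tnorm_spec("product")
  for (rep in 1:100) {
    n <- sample(2:8, 1)
    h <- runif(n)
    m <- sugeno_measure(rand_densities(n))
    expect_equal(choquet_generalized(h, m, prod_spec, operator = "CM"),
                 choquet(h, m), tolerance = 1e-12)
  }
})

test_that("CFM clamps at one and equals CM below it", {
  set.seed(55)
  sp <- tnorm_spec(8, 0.5)
  for (rep in 1:50) {
    n <- sample(2:6, 1)
    h <- runif(n)
    m <- sugeno_measure(rand_densities(n))
    cm <- choquet_generalized(h, m, sp, operator = "CM")
    cfm <- choquet_generalized(h, m, sp, operator = "CFM")
    expect_lte(cfm, 1)
    if (cm <= 1) expect_identical(cfm, cm)
  }
})

test_that("CD2 with family 8 matches a term-by-term oracle", {
  h <- c(0.9, 0.6, 0.3)
  g <- c(0.5, 0.4, 0.3)
  m <- sugeno_measure(g)
  sp <- tnorm_spec(8, 0.1)
  expect_equal(
    choquet_generalized(h, m, sp, operator = "CD2"),
    oracle_integral("CD2", h, g, oracle_tnorm("family8", 0.1)),
    tolerance = 1e-10
  )
  # alternative boundary h_(0) = h_(1)
  expect_equal(
    choquet_generalized(h, m, sp, operator = "CD2", h0 = "first"),
    oracle_integral("CD2", h, g, oracle_tnorm("family8", 0.1), h0 = "first"),
    tolerance = 1e-10
  )
})

test_that("every operator matches its naive oracle on random instances", {
  set.seed(77)
  ops <- c("choquet", "CM", "CFM", "CCM", "CMC", "CMMin", "CMMin2",
           "CMinM", "CD1", "CD2", "CD3")
  tn_pool <- list(list("product", NA), list("minimum", NA),
                  list("lukasiewicz", NA), list("family8", 0.1),
                  list("family8", 2), list("family12", 0.2),
                  list("family12", 1.5))
  for (rep in 1:250) {
    n <- sample(2:8, 1)
    h <- runif(n)
    if (rep %% 7 == 0) h[sample(n, 1)] <- 0   # exercise the CD3 guard
    g <- rand_densities(n)
    m <- sugeno_measure(g)
    tn <- tn_pool[[sample(length(tn_pool), 1)]]
    sp <- if (is.na(tn[[2]])) tnorm_spec(tn[[1]]) else tnorm_spec(tn[[1]], tn[[2]])
    M <- oracle_tnorm(tn[[1]], tn[[2]])
    for (op in ops) {
      got <- suppressWarnings(choquet_generalized(h, m, sp, operator = op))
      want <- oracle_integral(op, h, g, M)
      expect_equal(got, want, tolerance = 1e-10,
                   label = paste(op, tn[[1]], "rep", rep))
    }
  }
})

test_that("CD3 precedence switch changes the integrand as documented", {
  h <- c(0.8, 0.5, 0.2)
  g <- c(0.4, 0.4, 0.4)
  m <- sugeno_measure(g)
  sp <- tnorm_spec("product")
  M <- oracle_tnorm("product")
  expect_equal(choquet_generalized(h, m, sp, operator = "CD3"),
               oracle_integral("CD3", h, g, M, cd3_ratio = TRUE),
               tolerance = 1e-12)
  expect_equal(choquet_generalized(h, m, sp, operator = "CD3",
                                   cd3_ratio = "sum"),
               oracle_integral("CD3", h, g, M, cd3_ratio = FALSE),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(
    choquet_generalized(h, m, sp, operator = "CD3"),
    choquet_generalized(h, m, sp, operator = "CD3", cd3_ratio = "sum"))))
})

test_that("OWA with linear weights", {
  expect_equal(owa(c(0.6, 0.9, 0.3)), 0.9 * 0.5 + 0.6 * (1 / 3) + 0.3 * (1 / 6))
  expect_equal(owa(rep(0.37, 5)), 0.37)
  expect_equal(owa(0.8), 0.8)
  expect_equal(owa(0.8, normalize = FALSE), 0.8)
  set.seed(88)
  for (rep in 1:30) {
    x <- runif(sample(1:8, 1))
    expect_equal(owa(x), oracle_owa(x), tolerance = 1e-12)
    expect_equal(owa(x, normalize = FALSE), oracle_owa(x, FALSE),
                 tolerance = 1e-12)
  }
})

test_that("elementary baselines", {
  expect_equal(simple_aggregate(c(0.2, 0.8, 0.5), "median"), 0.5)
  expect_equal(simple_aggregate(c(0.2, 0.8), "mean"), 0.5)
  expect_equal(simple_aggregate(c(0.6, 0.7, 0.2), "majority_vote"), 2 / 3)
  expect_equal(simple_aggregate(c(0.2, 0.8), "min"), 0.2)
  expect_equal(simple_aggregate(c(0.2, 0.8), "max"), 0.8)
})

test_that("score sorting is stable under ties and rejects bad input", {
  s <- sort_scores(c(0.5, 0.9, 0.5))
  expect_equal(s$permutation, c(2, 1, 3))
  expect_equal(s$h_next, c(0.9, 0.5, 0.5, 0))
  expect_error(sort_scores(c(0.5, 1.2)), "\\[0, 1\\]")
  m <- sugeno_measure(c(0.4, 0.4))
  expect_error(choquet(c(0.2, 0.3, 0.4), m), "different lengths")
})

test_that("the tidy score-table interface matches direct evaluation", {
  set.seed(99)
  dens <- c(a = 0.6, b = 0.5, c = 0.4)
  tab <- tidyr::expand_grid(sample = 1:4, class = 1:2,
                            classifier = c("a", "b", "c"))
  tab$score <- runif(nrow(tab))
  out <- aggregate_scores(tab, dens, operator = "choquet")
  expect_equal(nrow(out), 8)
  m <- sugeno_measure(dens)
  one <- tab[tab$sample == 2 & tab$class == 1, ]
  expect_equal(out$fused[out$sample == 2 & out$class == 1],
               choquet(one$score[match(names(dens), one$classifier)], m))
})
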