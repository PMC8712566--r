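# fusion harness: splitting, densities, per-sample fusion, the experiment

test_that("stratified holdout reproduces the 80:20 protocol", {
  tbl <- gen_feature_table(seed = 1)
  sp <- split_holdout(tbl, 0.2, seed = 5)
  expect_equal(nrow(sp$test), 8)
  expect_equal(as.integer(table(sp$test$label)), c(4L, 4L))
  expect_equal(nrow(sp$train), 32)
  expect_length(intersect(sp$train$subject, sp$test$subject), 0)
  # determinism
  sp2 <- split_holdout(tbl, 0.2, seed = 5)
  expect_identical(sp$test$subject, sp2$test$subject)
  # tiny balanced case
  tiny <- tibble::tibble(label = c("a", "a", "b", "b"), f = rnorm(4))
  sp3 <- split_holdout(tiny, 0.5, seed = 1)
  expect_equal(as.integer(table(sp3$test$label)), c(1L, 1L))
  expect_error(split_holdout(tibble::tibble(label = c("a", "b", "b"),
                                            f = 1:3), 0.2),
               "at least 2")
})

test_that("cross-validated densities behave like accuracies", {
  # strongly separated single feature: near-perfect densities
  set.seed(60)
  strong <- tibble::tibble(
    label = rep(c("HC", "SZ"), each = 20),
    f1 = c(rnorm(20, 0), rnorm(20, 6)),
    f2 = rnorm(40)
  )
  d <- estimate_densities(strong, c("decision_tree", "knn", "logistic"),
                          folds = 5, seed = 2)
  expect_true(all(d > 0.85))
  expect_true(all(d <= 1 - 1e-6))   # flooring keeps the measure valid
  # pure-noise features: near-chance densities
  noise <- tibble::tibble(label = rep(c("HC", "SZ"), each = 20),
                          f1 = rnorm(40), f2 = rnorm(40))
  dn <- estimate_densities(noise, "knn", folds = 5, seed = 3)
  expect_gt(dn, 0.5 - 0.35)
  expect_lt(dn, 0.5 + 0.35)
  # same call, same folds -> identical densities
  expect_identical(d, estimate_densities(strong,
                                         c("decision_tree", "knn", "logistic"),
                                         folds = 5, seed = 2))
  expect_error(estimate_densities(strong, "knn", folds = 25), "minority")
})

test_that("fuse_sample: dominance, single classifier, oracle agreement", {
  dens <- c(a = 0.8, b = 0.7, c = 0.6)
  probs <- rbind(c(0.9, 0.1), c(0.9, 0.1), c(0.9, 0.1))
  for (op in c("choquet", "CM", "CD2")) {
    sp <- if (op == "choquet") NULL else tnorm_spec(12, 0.5)
    expect_equal(fuse_sample(probs, dens, op, sp)$class, 1)
  }
  # n = 1: argmax of that classifier's own probabilities
  expect_equal(fuse_sample(rbind(c(0.3, 0.7)), c(x = 1), "choquet")$class, 2)
  # 3-classifier case against explicit per-class integrals
  probs <- rbind(c(0.8, 0.2), c(0.7, 0.3), c(0.2, 0.8))
  dens <- c(a = 0.9, b = 0.9, c = 0.2)
  out <- fuse_sample(probs, dens, "choquet")
  v1 <- oracle_integral("choquet", probs[, 1], dens)
  v2 <- oracle_integral("choquet", probs[, 2], dens)
  expect_equal(out$fused, c(v1, v2), tolerance = 1e-10)
  expect_equal(out$class, which.max(c(v1, v2)))
})

test_that("ties resolve by mean raw score, then lower class index", {
  dens <- c(a = 0.5, b = 0.5)
  # identical fused values for both classes, class 2 has larger mean score
  probs <- rbind(c(0.4, 0.6), c(0.6, 0.4))
  out <- fuse_sample(probs, dens, "min")
  expect_true(out$tie)
  expect_equal(out$class, 1)  # equal means too -> lower index
  # all-zero scores fall back to the tie rule
  out0 <- fuse_sample(rbind(c(0, 0), c(0, 0)), dens, "mean")
  expect_equal(out0$class, 1)
})

test_that("equal additive densities make the classic integral the mean", {
  set.seed(61)
  for (rep in 1:20) {
    n <- sample(2:6, 1)
    probs <- matrix(runif(2 * n), n, 2)
    dens <- rep(1 / n, n)
    out <- fuse_sample(probs, dens, "choquet")
    expect_equal(out$fused, colMeans(probs), tolerance = 1e-10)
    mean_pred <- fuse_sample(probs, dens, "mean")
    expect_equal(out$class, mean_pred$class)
  }
})

test_that("the repeated experiment pools exactly and is deterministic", {
  tbl <- gen_feature_table(seed = 17)
  grid <- dplyr::bind_rows(
    tibble::tibble(operator = "choquet", family = NA_character_,
                   alpha = NA_real_),
    tibble::tibble(operator = "CM", family = "12", alpha = 0.2),
    tibble::tibble(operator = "mean", family = NA_character_,
                   alpha = NA_real_)
  )
  cfg <- fusion_config(n_repetitions = 4, cv_folds = 5,
                       classifiers = c("decision_tree", "knn", "logistic"),
                       operator_grid = grid, seed = 99)
  ex <- run_fusion_experiment(tbl, cfg)
  expect_s3_class(ex, "fusion_experiment")
  expect_equal(unique(ex$grid$n), 4 * 8)    # reps x test size, exactly
  expect_equal(nrow(ex$grid), 3)
  expect_true(all(ex$grid$accuracy >= 0 & ex$grid$accuracy <= 1))
  ex2 <- run_fusion_experiment(tbl, cfg)
  expect_identical(ex$grid, ex2$grid)
  expect_identical(ex$individual, ex2$individual)
  # glance/tidy/autoplot surfaces
  g <- glance(ex)
  expect_equal(g$n_pooled, 32)
  expect_identical(tidy(ex), ex$grid)
  expect_s3_class(ggplot2::autoplot(ex), "ggplot")
  expect_s3_class(plot_alpha_profile(ex, "CM", 12), "ggplot")
})

test_that("summarize_grid ranks by accuracy and keeps ties", {
  grid <- tibble::tibble(operator = c("a", "b", "c"),
                         family = NA_character_, alpha = NA_real_,
                         accuracy = c(0.7, 0.9, 0.9))
  out <- summarize_grid(grid)
  expect_equal(out$accuracy, c(0.9, 0.9, 0.7))
  expect_equal(nrow(out), 3)
  # best row matches an exhaustive scan
  expect_equal(out$operator[1], grid$operator[which.max(grid$accuracy)])
})

test_that("two master seeds differ only within Monte-Carlo noise", {
  sc1 <- gen_classifier_scores(n_samples = 800, rho = 0.1, seed = 101)
  sc2 <- gen_classifier_scores(n_samples = 800, rho = 0.1, seed = 202)
  acc <- function(sc) {
    sc |>
      dplyr::filter(.data$class == .data$truth) |>
      dplyr::summarise(a = mean(.data$score > 0.5)) |>
      dplyr::pull(a)
  }
  # binomial s.e. at n = 800 x 5 classifiers
  se <- sqrt(0.85 * 0.15 / 4000)
  expect_lt(abs(acc(sc1) - acc(sc2)), 6 * se)
})
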