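#' The fusion experiment harness
#'
#' Reproduces the ensemble-fusion protocol on a subjects-by-features table
#' with binary labels: an 80:20 stratified holdout is drawn; the base
#' classifiers are fitted on the training part; each classifier's fuzzy
#' density is its mean five-fold cross-validated accuracy on that training
#' part; the fitted models score the held-out subjects, and for every grid
#' cell (operator, t-norm family, alpha) the per-class score vectors are
#' fused and the argmax taken as the prediction. The whole procedure is
#' repeated (200 repetitions by default) with fresh splits, models and
#' densities each run, and accuracies are pooled over all repetitions
#' (e.g. 200 runs x 8 held-out subjects = 1,600 pooled predictions per
#' cell). A per-run macro average is reported alongside.
#'
#' @name fusion_pipeline
NULL

#' Experiment configuration
#'
#' @param holdout_fraction Test fraction of the stratified split (default
#'   0.2, i.e. the 80:20 protocol).
#' @param n_repetitions Number of independent split-fit-fuse runs.
#' @param cv_folds Folds for the density-estimating cross-validation.
#' @param classifiers Character vector naming base classifiers (see
#'   [classifier_roster()]).
#' @param operator_grid Tibble with columns `operator`, `family`, `alpha`
#'   (family/alpha `NA` for t-norm-free operators); default
#'   [default_operator_grid()].
#' @param h0,cd3_ratio Passed to the difference-type integrals; see
#'   [choquet_generalized()].
#' @param seed Master seed; per-repetition seeds are derived from it.
#' @return A list of class `fusion_config`.
#' @export
fusion_config <- function(holdout_fraction = 0.2, n_repetitions = 200,
                          cv_folds = 5,
                          classifiers = names(classifier_roster()),
                          operator_grid = default_operator_grid(),
                          h0 = "one", cd3_ratio = "ratio", seed = 1L) {
  stopifnot(holdout_fraction > 0, holdout_fraction < 1,
            n_repetitions >= 1, cv_folds >= 2)
  structure(list(holdout_fraction = holdout_fraction,
                 n_repetitions = as.integer(n_repetitions),
                 cv_folds = as.integer(cv_folds),
                 classifiers = classifiers,
                 operator_grid = operator_grid,
                 h0 = h0, cd3_ratio = cd3_ratio,
                 seed = as.integer(seed)),
            class = "fusion_config")
}

#' Default operator-by-t-norm search grid
#'
#' Classical Choquet plus the `CM`, `CFM` and `CD2` pre-aggregations over
#' the two headline families (8 and 12) at a short alpha ladder, with the
#' OWA, mean and majority-vote baselines.
#'
#' @param operators Generalized operators to sweep.
#' @param families T-norm families (ids or names).
#' @param alphas Alpha values; intersected with each family's range.
#' @param baselines Parameter-free rows to append.
#' @return Tibble with columns `operator`, `family`, `alpha`.
#' @export
default_operator_grid <- function(operators = c("CM", "CFM", "CD2"),
                                  families = c(8, 12),
                                  alphas = c(0.1, 0.2, 0.5, 1, 2),
                                  baselines = c("choquet", "owa", "mean",
                                                "majority_vote")) {
  cells <- tidyr::expand_grid(operator = operators,
                              family = as.character(families),
                              alpha = alphas)
  keep <- purrr::map_lgl(seq_len(nrow(cells)), function(i) {
    !inherits(try(tnorm_spec(cells$family[i], cells$alpha[i]), silent = TRUE),
              "try-error")
  })
  dplyr::bind_rows(
    cells[keep, ],
    tibble::tibble(operator = baselines, family = NA_character_,
                   alpha = NA_real_)
  )
}

#' Stratified holdout split
#'
#' @param data Data frame with a `label` column (two classes).
#' @param fraction Test fraction; test size per class is
#'   `round(fraction * class size)`.
#' @param seed RNG seed (split is reproducible under it).
#' @return List with `train` and `test` tibbles (disjoint, stratified).
#' @examples
#' tbl <- gen_feature_table(n_per_class = 20, seed = 1)
#' sp <- split_holdout(tbl, 0.2, seed = 1)
#' table(sp$test$label)  # 4 and 4
#' @export
split_holdout <- function(data, fraction = 0.2, seed = 1L) {
  stopifnot("label" %in% names(data), fraction > 0, fraction < 1)
  counts <- table(data$label)
  if (any(counts < 2)) stop("every class needs at least 2 samples",
                            call. = FALSE)
  idx_test <- withr::with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      rows <- which(data$label == cl)
      sample(rows, max(1, round(fraction * length(rows))))
    }))
  })
  list(train = dplyr::as_tibble(data[-idx_test, , drop = FALSE]),
       test = dplyr::as_tibble(data[idx_test, , drop = FALSE]))
}

.feature_matrix <- function(data) {
  drop <- intersect(c("label", "subject", "sample"), names(data))
  as.matrix(data[, setdiff(names(data), drop), drop = FALSE])
}

.stratified_folds <- function(y, folds, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(y))
    for (cl in levels(y)) {
      rows <- which(y == cl)
      fold[rows] <- sample(rep_len(seq_len(folds), length(rows)))
    }
    fold
  })
}

#' Estimate fuzzy densities by cross-validated accuracy
#'
#' Each classifier's density is its mean accuracy over stratified
#' cross-validation folds of the training data -- the "degree of trust"
#' assigned to that model inside the fuzzy measure. Densities are clamped
#' into `[1e-6, 1 - 1e-6]` so the Sugeno measure stays well defined.
#'
#' @param train Training tibble with a `label` column.
#' @param classifiers Character vector of roster names.
#' @param folds Number of CV folds (must not exceed the minority class
#'   count).
#' @param seed RNG seed for fold assignment and stochastic learners.
#' @return Named numeric vector of densities.
#' @export
estimate_densities <- function(train, classifiers = names(classifier_roster()),
                               folds = 5, seed = 1L) {
  y <- factor(train$label)
  if (min(table(y)) < folds) {
    stop("cv folds (", folds, ") exceed the minority class count (",
         min(table(y)), ")", call. = FALSE)
  }
  X <- .feature_matrix(train)
  roster <- classifier_roster(classifiers)
  fold <- .stratified_folds(y, folds, seed)
  acc <- vapply(names(roster), function(nm) {
    entry <- roster[[nm]]
    fold_acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      model <- withr::with_seed(seed + f, entry$fit(X[tr, , drop = FALSE], y[tr]))
      pr <- entry$prob(model, X[!tr, , drop = FALSE])
      pred <- levels(y)[max.col(pr, ties.method = "first")]
      mean(pred == as.character(y[!tr]))
    }, numeric(1))
    mean(fold_acc)
  }, numeric(1))
  pmin(pmax(acc, 1e-6), 1 - 1e-6)
}

#' Fuse one sample's classifier probabilities into a prediction
#'
#' Aggregates each class's score vector independently (the measure chain is
#' rebuilt for each class's score ordering) and predicts the argmax of the
#' fused class values. Exact ties go to the class with the larger mean raw
#' score, then to the lower class index.
#'
#' @param probs Classifiers-by-classes probability matrix (rows in the
#'   density order).
#' @param densities Named densities (one per classifier row).
#' @param operator Operator id; integrals, `"owa"`, or a
#'   [simple_aggregate()] kind.
#' @param tnorm Optional [tnorm_spec()].
#' @param ... Passed to [choquet_generalized()].
#' @return List with `class` (predicted column index), `fused` (per-class
#'   fused values), and `tie` (logical).
#' @export
fuse_sample <- function(probs, densities, operator = "choquet", tnorm = NULL,
                        ...) {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == length(densities))
  lambda <- if (operator %in% .AGGREGATOR_IDS) solve_lambda(densities) else NA
  fused <- vapply(seq_len(ncol(probs)), function(cl) {
    .fuse_vector(probs[, cl], densities, lambda, operator, tnorm, ...)
  }, numeric(1))
  .argmax_with_ties(fused, colMeans(probs))
}

.argmax_with_ties <- function(fused, mean_scores) {
  top <- which(fused == max(fused))
  tie <- length(top) > 1
  if (tie) {
    best_mean <- top[mean_scores[top] == max(mean_scores[top])]
    top <- min(best_mean)
  }
  list(class = top[1], fused = fused, tie = tie)
}

#' Run the repeated fusion experiment
#'
#' @param data Feature table with a binary `label` column (any other
#'   non-feature columns named `subject` or `sample` are ignored as
#'   features).
#' @param config A [fusion_config()].
#' @return Object of class `fusion_experiment`: `grid` (per-cell pooled and
#'   macro accuracy), `individual` (pooled accuracy per base classifier),
#'   `runs` (per-repetition records: densities, test indices, per-cell
#'   correct counts), and the `config`.
#' @seealso [summarize_grid()], [tidy.fusion_experiment()],
#'   [autoplot.fusion_experiment()]
#' @export
run_fusion_experiment <- function(data, config = fusion_config()) {
  stopifnot(inherits(config, "fusion_config"))
  y_all <- factor(data$label)
  stopifnot(nlevels(y_all) == 2)
  grid <- config$operator_grid
  specs <- .grid_specs(grid)
  rep_seeds <- withr::with_seed(config$seed,
                                sample.int(2^30, config$n_repetitions))
  roster <- classifier_roster(config$classifiers)

  n_cells <- nrow(grid)
  correct <- matrix(0, config$n_repetitions, n_cells)
  totals <- integer(config$n_repetitions)
  indiv_correct <- matrix(0, config$n_repetitions, length(roster),
                          dimnames = list(NULL, names(roster)))
  runs <- vector("list", config$n_repetitions)

  for (r in seq_len(config$n_repetitions)) {
    rs <- rep_seeds[r]
    sp <- split_holdout(data, config$holdout_fraction, seed = rs)
    ytr <- factor(sp$train$label, levels = levels(y_all))
    yte <- factor(sp$test$label, levels = levels(y_all))
    Xtr <- .feature_matrix(sp$train)
    Xte <- .feature_matrix(sp$test)
    dens <- estimate_densities(sp$train, config$classifiers,
                               folds = config$cv_folds, seed = rs)
    models <- lapply(names(roster), function(nm) {
      withr::with_seed(rs + 1L, roster[[nm]]$fit(Xtr, ytr))
    })
    probs <- lapply(seq_along(models), function(i) {
      pr <- roster[[i]]$prob(models[[i]], Xte)
      pr <- as.matrix(pr)
      if (!is.null(colnames(pr))) pr <- pr[, levels(y_all), drop = FALSE]
      # renormalize against rounding in the learners
      pr / pmax(rowSums(pr), 1e-12)
    })
    names(probs) <- names(roster)
    for (i in seq_along(probs)) {
      pred <- levels(y_all)[max.col(probs[[i]], ties.method = "first")]
      indiv_correct[r, i] <- sum(pred == as.character(yte))
    }
    lambda <- solve_lambda(dens)
    n_test <- length(yte)
    totals[r] <- n_test
    for (s in seq_len(n_test)) {
      pm <- do.call(rbind, lapply(probs, function(p) p[s, ]))
      pred_cells <- .fuse_cells(pm, dens, lambda, grid, specs,
                                h0 = config$h0, cd3_ratio = config$cd3_ratio)
      truth <- as.integer(yte[s])
      correct[r, ] <- correct[r, ] + as.numeric(pred_cells == truth)
    }
    runs[[r]] <- list(seed = rs, densities = dens,
                      test_subjects = if ("subject" %in% names(sp$test))
                        sp$test$subject else NULL,
                      correct = correct[r, ], n_test = n_test)
  }

  grid_out <- grid |>
    dplyr::mutate(
      n = sum(totals),
      accuracy = colSums(correct) / sum(totals),
      macro_accuracy = colMeans(correct / totals)
    )
  indiv <- tibble::tibble(
    classifier = colnames(indiv_correct),
    n = sum(totals),
    accuracy = colSums(indiv_correct) / sum(totals)
  )
  structure(list(grid = grid_out, individual = indiv, runs = runs,
                 config = config, levels = levels(y_all)),
            class = "fusion_experiment")
}

# Pre-resolve tnorm specs for every grid row (NA family -> NULL).
.grid_specs <- function(grid) {
  lapply(seq_len(nrow(grid)), function(i) {
    if (is.na(grid$family[i])) return(NULL)
    fam <- grid$family[i]
    fam_num <- suppressWarnings(as.numeric(fam))
    tnorm_spec(if (!is.na(fam_num)) fam_num else fam, grid$alpha[i])
  })
}

# Fuse one sample's classifier-by-class matrix under every grid cell.
# The sorted scores and measure chains per class are computed once.
.fuse_cells <- function(pm, densities, lambda, grid, specs,
                        h0 = "one", cd3_ratio = "ratio") {
  n_class <- ncol(pm)
  prep <- lapply(seq_len(n_class), function(cl) {
    s <- sort_scores(pm[, cl])
    chain <- sugeno_measure(densities[s$permutation], lambda = lambda)$cumulative
    list(hs = s$sorted, hnext = c(s$sorted[-1], 0), gU = chain)
  })
  mean_scores <- colMeans(pm)
  vapply(seq_len(nrow(grid)), function(i) {
    op <- grid$operator[i]
    fused <- if (op %in% .AGGREGATOR_IDS) {
      vapply(prep, function(p)
        .integral_value(p$hs, p$hnext, p$gU, op, specs[[i]],
                        h0 = h0, cd3_ratio = cd3_ratio, warn_cd3 = FALSE),
        numeric(1))
    } else if (op == "owa") {
      apply(pm, 2, owa)
    } else {
      apply(pm, 2, simple_aggregate, kind = op)
    }
    .argmax_with_ties(fused, mean_scores)$class
  }, numeric(1))
}

#' Evaluate an operator grid on a table of classifier scores
#'
#' Fuses every sample of a long score table (as produced by
#' [gen_classifier_scores()], or read from CSV) under every grid cell and
#' reports the resulting accuracy per cell, together with the individual
#' classifiers' thresholded accuracies. This is the score-level counterpart
#' of [run_fusion_experiment()] for the case where base-classifier outputs
#' already exist.
#'
#' @param scores Tibble with columns `sample`, `truth`, `classifier`,
#'   `class`, `score`.
#' @param densities Named densities, one per classifier.
#' @param grid Tibble with `operator`, `family`, `alpha` rows (see
#'   [default_operator_grid()]).
#' @param h0,cd3_ratio Passed to the difference-type integrals.
#' @return List with `grid` (input grid plus `accuracy`, `n`) and
#'   `individual` (per-classifier accuracy).
#' @export
fuse_score_table <- function(scores, densities, grid,
                             h0 = "one", cd3_ratio = "ratio") {
  stopifnot(all(c("sample", "truth", "classifier", "class", "score") %in%
                  names(scores)))
  cls <- names(densities)
  classes <- sort(unique(scores$class))
  wide <- scores |>
    dplyr::arrange(.data$sample, .data$classifier, .data$class)
  samples <- unique(wide$sample)
  n_s <- length(samples)
  # scores as an array: sample x classifier x class
  arr <- array(NA_real_, c(n_s, length(cls), length(classes)))
  i <- match(wide$sample, samples)
  j <- match(wide$classifier, cls)
  k <- match(wide$class, classes)
  arr[cbind(i, j, k)] <- wide$score
  if (anyNA(arr)) stop("score table is missing (sample, classifier, class) ",
                       "combinations", call. = FALSE)
  truth <- wide$truth[match(samples, wide$sample)]
  specs <- .grid_specs(grid)
  lambda <- solve_lambda(densities)
  correct <- matrix(0, n_s, nrow(grid))
  for (s in seq_len(n_s)) {
    pm <- matrix(arr[s, , ], length(cls), length(classes))
    pred <- .fuse_cells(pm, densities, lambda, grid, specs,
                        h0 = h0, cd3_ratio = cd3_ratio)
    correct[s, ] <- as.numeric(classes[pred] == truth[s])
  }
  indiv <- scores |>
    dplyr::filter(.data$class == .data$truth) |>
    dplyr::group_by(.data$classifier) |>
    dplyr::summarise(accuracy = mean(.data$score > 0.5), .groups = "drop")
  list(
    grid = grid |> dplyr::mutate(n = n_s, accuracy = colMeans(correct)),
    individual = indiv
  )
}

#' Rank grid cells of a fusion experiment
#'
#' @param experiment A `fusion_experiment` (or its `grid` tibble).
#' @param by Accuracy column to rank on.
#' @return Tibble sorted by decreasing accuracy; ties keep all rows, in
#'   grid order.
#' @export
summarize_grid <- function(experiment, by = "accuracy") {
  grid <- if (inherits(experiment, "fusion_experiment")) experiment$grid
          else dplyr::as_tibble(experiment)
  stopifnot(nrow(grid) > 0)
  grid |> dplyr::arrange(dplyr::desc(.data[[by]]))
}

#' @export
print.fusion_experiment <- function(x, ...) {
  best <- summarize_grid(x)[1, ]
  cat("<fusion_experiment>", x$config$n_repetitions, "repetitions,",
      nrow(x$grid), "grid cells,", x$grid$n[1], "pooled predictions/cell\n")
  cat("  best cell:", best$operator,
      if (!is.na(best$family)) paste0("(family ", best$family,
                                      ", alpha ", best$alpha, ")") else "",
      "accuracy", signif(best$accuracy, 4), "\n")
  cat("  best individual:",
      x$individual$classifier[which.max(x$individual$accuracy)],
      signif(max(x$individual$accuracy), 4), "\n")
  invisible(x)
}

#' Tidy and summarize fusion experiments
#'
#' `tidy()` returns the per-cell accuracy grid; `glance()` a one-row
#' summary with the best fused and best individual accuracies and the lift
#' between them.
#'
#' @param x A `fusion_experiment`.
#' @param ... Unused.
#' @export
tidy.fusion_experiment <- function(x, ...) {
  x$grid
}

#' @rdname tidy.fusion_experiment
#' @export
glance.fusion_experiment <- function(x, ...) {
  best <- summarize_grid(x)[1, ]
  tibble::tibble(
    n_repetitions = x$config$n_repetitions,
    n_pooled = best$n,
    best_operator = best$operator,
    best_family = best$family,
    best_alpha = best$alpha,
    best_accuracy = best$accuracy,
    best_individual = max(x$individual$accuracy),
    lift = best$accuracy - max(x$individual$accuracy)
  )
}
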