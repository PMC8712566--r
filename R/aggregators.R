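#' Choquet integrals and pre-aggregation operators
#'
#' The classical (discrete) Choquet integral of a score vector
#' \eqn{h(x_1),\ldots,h(x_n)} with respect to a fuzzy measure \eqn{g} sorts
#' the scores non-increasingly, sets \eqn{h(x_{n+1}) = 0}, and computes
#' \deqn{C = \sum_{i=1}^n \big(h(x_{(i)}) - h(x_{(i+1)})\big)\, g(U_i),}
#' where \eqn{U_i} collects the classifiers holding the \eqn{i} largest
#' scores. The generalized forms replace the product between increment and
#' measure by a t-norm \eqn{M}, giving pre-aggregation operators: they keep
#' directional monotonicity but may lose idempotency and internality. The
#' eleven operators implemented here (ids in parentheses):
#'
#' * `choquet`: classical integral.
#' * `CM`: \eqn{\sum M(h_{(i)} - h_{(i+1)},\, g(U_i))}.
#' * `CFM`: the `CM` sum clamped at 1.
#' * `CCM`: \eqn{\sum M(h_{(i)}, g(U_i)) - M(h_{(i+1)}, g(U_i))}.
#' * `CMC`: \eqn{\sum M(h_{(i)}, g(U_i)) - M(h_{(i+1)}, g(U_i)) +
#'   M(h_{(i)} - h_{(i+1)}, g(U_i))}.
#' * `CMMin`: \eqn{\sum M(\min(h_{(i)}, g(U_i)) - \min(h_{(i+1)}, g(U_i)),\, g(U_i))}.
#' * `CMMin2`: \eqn{\sum M(\min(h_{(i)}, g(U_i)),\, \min(h_{(i+1)}, g(U_i)))}.
#' * `CMinM`: \eqn{\sum \min(M(h_{(i)}, g(U_i)),\, M(h_{(i+1)}, g(U_i)))}.
#' * `CD1`: \eqn{\sum M(h_{(i-1)} - h_{(i+1)},\, g(U_i))}.
#' * `CD2`: \eqn{\sum M(h_{(i-1)} + h_{(i+1)} - h_{(i)},\, g(U_i))}.
#' * `CD3`: \eqn{\sum M\big((h_{(i-1)} + h_{(i+1)}) / h_{(i)},\, g(U_i)\big)}.
#'
#' The difference-type operators CD1-CD3 reference \eqn{h_{(0)}}, one slot
#' above the largest score; since scores are probabilities the default is
#' \eqn{h_{(0)} = 1} (configurable to \eqn{h_{(0)} = h_{(1)}}). First
#' arguments passed to \eqn{M} are clipped into \eqn{[0,1]}, the t-norm's
#' domain. In `CD3`, terms with \eqn{h_{(i)} = 0} contribute 0 (all later
#' sorted scores are 0 as well).
#'
#' @name aggregators
NULL

.AGGREGATOR_IDS <- c("choquet", "CM", "CFM", "CCM", "CMC", "CMMin",
                     "CMMin2", "CMinM", "CD1", "CD2", "CD3")

#' Sort a score vector for integration
#'
#' Orders scores non-increasingly with stable ties (original classifier index
#' breaks ties), recording the permutation so the measure densities can be
#' aligned to the same ordering.
#'
#' @param h Numeric vector of scores in \eqn{[0,1]}.
#' @return List with `sorted` scores, the `permutation`, and `h_next`
#'   (the sorted vector extended by the boundary value \eqn{h_{(n+1)} = 0}).
#' @export
sort_scores <- function(h) {
  if (any(!is.finite(h)) || any(h < 0 | h > 1)) {
    stop("scores must be finite and in [0, 1]", call. = FALSE)
  }
  perm <- order(-h, seq_along(h))  # stable: ties by original index
  list(sorted = h[perm], permutation = perm, h_next = c(h[perm], 0))
}

#' Classical Choquet integral
#'
#' @param h Score vector (unsorted; sorted internally).
#' @param measure A [sugeno_measure()] whose densities are in the *original*
#'   classifier order; the measure chain is rebuilt on the score ordering.
#'   Alternatively a plain numeric vector of densities.
#' @return Single numeric value in \eqn{[\min h, \max h]}.
#' @examples
#' m <- sugeno_measure(c(0.5, 0.3, 0.2), lambda = 0)
#' choquet(c(0.9, 0.6, 0.3), m)  # additive measure: weighted mean 0.69
#' @export
choquet <- function(h, measure) {
  agg <- .prepare_integral(h, measure)
  sum((agg$hs - agg$hnext) * agg$gU)
}

# Align measure chain to the score ordering: re-solve the chain with the
# densities permuted like the sorted scores (lambda is order-invariant).
.prepare_integral <- function(h, measure) {
  if (inherits(measure, "sugeno_measure")) {
    g <- measure$densities
    lambda <- measure$lambda
  } else {
    g <- .check_densities(measure)
    lambda <- solve_lambda(g)
  }
  if (length(g) != length(h)) {
    stop("score vector and measure densities have different lengths (",
         length(h), " vs ", length(g), ")", call. = FALSE)
  }
  s <- sort_scores(h)
  chain <- sugeno_measure(g[s$permutation], lambda = lambda)$cumulative
  list(hs = s$sorted, hnext = c(s$sorted[-1], 0), gU = chain)
}

#' Generalized (pre-aggregation) Choquet integrals
#'
#' Evaluates one of the operators listed in [aggregators] with a t-norm as
#' the integrand function; `operator = "choquet"` ignores the t-norm and
#' falls back to the classical integral. `CM` with the product t-norm
#' reproduces the classical Choquet integral exactly.
#'
#' @inheritParams choquet
#' @param tnorm A [tnorm_spec()]; required for all operators except
#'   `"choquet"`.
#' @param operator Operator id, one of `"choquet"`, `"CM"`, `"CFM"`, `"CCM"`,
#'   `"CMC"`, `"CMMin"`, `"CMMin2"`, `"CMinM"`, `"CD1"`, `"CD2"`, `"CD3"`.
#' @param h0 Boundary value \eqn{h_{(0)}} used by CD1/CD2/CD3: `"one"`
#'   (default, \eqn{h_{(0)} = 1}) or `"first"` (\eqn{h_{(0)} = h_{(1)}}).
#' @param cd3_ratio How CD3's integrand is parsed: `"ratio"` (default,
#'   \eqn{(h_{(i-1)} + h_{(i+1)})/h_{(i)}}) or `"sum"`
#'   (\eqn{h_{(i-1)} + h_{(i+1)}/h_{(i)}}).
#' @return Single numeric value.
#' @examples
#' m <- sugeno_measure(c(0.4, 0.4, 0.4))
#' sp <- tnorm_spec("family8", alpha = 0.1)
#' choquet_generalized(c(0.9, 0.6, 0.3), m, sp, operator = "CD2")
#' @export
choquet_generalized <- function(h, measure, tnorm = NULL,
                                operator = "CM",
                                h0 = c("one", "first"),
                                cd3_ratio = c("ratio", "sum")) {
  operator <- match.arg(operator, .AGGREGATOR_IDS)
  if (operator == "choquet") return(choquet(h, measure))
  if (is.null(tnorm)) stop("operator '", operator, "' needs a tnorm_spec",
                           call. = FALSE)
  h0 <- match.arg(h0)
  cd3_ratio <- match.arg(cd3_ratio)
  agg <- .prepare_integral(h, measure)
  .integral_value(agg$hs, agg$hnext, agg$gU, operator, tnorm,
                  h0 = h0, cd3_ratio = cd3_ratio)
}

# Core operator evaluation on an already sorted score vector and aligned
# measure chain; shared by choquet_generalized() and the fusion harness.
.integral_value <- function(hs, hnext, gU, operator, tnorm,
                            h0 = "one", cd3_ratio = "ratio",
                            warn_cd3 = TRUE) {
  n <- length(hs)
  gU <- .clip01(gU)  # chain terminal is 1 only to solver tolerance
  M <- function(a, b) tnorm_evaluate(tnorm, .clip01(a), b)
  hprev <- c(if (h0 == "one") 1 else hs[1], hs[-n])

  switch(operator,
    choquet = sum((hs - hnext) * gU),
    CM = sum(M(hs - hnext, gU)),
    CFM = min(sum(M(hs - hnext, gU)), 1),
    CCM = sum(M(hs, gU) - M(hnext, gU)),
    CMC = sum(M(hs, gU) - M(hnext, gU) + M(hs - hnext, gU)),
    CMMin = sum(M(pmin(hs, gU) - pmin(hnext, gU), gU)),
    CMMin2 = sum(M(pmin(hs, gU), pmin(hnext, gU))),
    CMinM = sum(pmin(M(hs, gU), M(hnext, gU))),
    CD1 = sum(M(hprev - hnext, gU)),
    CD2 = sum(M(hprev + hnext - hs, gU)),
    CD3 = {
      keep <- hs > 0
      if (!all(keep) && warn_cd3) {
        warning("CD3: ", sum(!keep), " term(s) with h_(i) = 0 skipped")
      }
      arg <- if (cd3_ratio == "ratio") {
        (hprev[keep] + hnext[keep]) / hs[keep]
      } else {
        hprev[keep] + hnext[keep] / hs[keep]
      }
      if (any(keep)) sum(M(arg, gU[keep])) else 0
    }
  )
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Ordered weighted averaging (OWA)
#'
#' \deqn{\mathrm{OWA}(x_1,\ldots,x_n) = \sum_j \omega_j y_j,} where
#' \eqn{y_j} is the j-th largest input and the weight profile is the linearly
#' decaying \eqn{\omega_1 = 1,\ \omega_2 = 1 - 1/n,\ \ldots,\ \omega_n = 1/n},
#' used with or without normalization to unit sum.
#'
#' @param x Numeric vector.
#' @param weights Optional weight vector (applied to the sorted values);
#'   defaults to the linear profile above.
#' @param normalize Divide the weights by their sum (then the result is a
#'   weighted mean, internal in \eqn{[\min x, \max x]}).
#' @return Single numeric value.
#' @examples
#' owa(c(0.6, 0.9, 0.3))                # normalized linear weights: 0.70
#' owa(c(0.6, 0.9, 0.3), normalize = FALSE)
#' @export
owa <- function(x, weights = NULL, normalize = TRUE) {
  stopifnot(is.numeric(x), length(x) >= 1, all(is.finite(x)))
  n <- length(x)
  if (is.null(weights)) weights <- 1 - (seq_len(n) - 1) / n
  stopifnot(length(weights) == n)
  if (normalize) weights <- weights / sum(weights)
  sum(weights * sort(x, decreasing = TRUE))
}

#' Elementary aggregation baselines
#'
#' Minimum, maximum, median, mean, and majority vote (inputs thresholded at
#' 0.5; the vote returns the fraction of votes for the positive class, so a
#' value > 0.5 means the ensemble votes positive).
#'
#' @param x Numeric score vector.
#' @param kind One of `"min"`, `"max"`, `"median"`, `"mean"`,
#'   `"majority_vote"`.
#' @param threshold Vote threshold (majority vote only).
#' @return Single numeric value.
#' @examples
#' simple_aggregate(c(0.2, 0.8, 0.5), "median")
#' simple_aggregate(c(0.6, 0.7, 0.2), "majority_vote")  # 2/3
#' @export
simple_aggregate <- function(x, kind = c("min", "max", "median", "mean",
                                         "majority_vote"),
                             threshold = 0.5) {
  kind <- match.arg(kind)
  switch(kind,
    min = min(x),
    max = max(x),
    median = stats::median(x),
    mean = mean(x),
    majority_vote = mean(x > threshold)
  )
}

#' Aggregate a tidy table of classifier scores
#'
#' Data-frame-first interface over the integral operators: takes a long table
#' with one row per (sample, class, classifier) score, aggregates each
#' (sample, class) score vector under the given measure and operator, and
#' returns one fused value per sample and class.
#'
#' @param scores A data frame with columns `sample`, `class`, `classifier`,
#'   `score` (additional columns are ignored).
#' @param densities Named numeric vector of fuzzy densities; names must match
#'   the `classifier` values.
#' @param operator Operator id (see [aggregators]), or `"owa"` or one of the
#'   [simple_aggregate()] kinds.
#' @param tnorm Optional [tnorm_spec()] for generalized operators.
#' @param ... Passed on to [choquet_generalized()].
#' @return A tibble with columns `sample`, `class`, `fused`.
#' @export
aggregate_scores <- function(scores, densities, operator = "choquet",
                             tnorm = NULL, ...) {
  stopifnot(all(c("sample", "class", "classifier", "score") %in% names(scores)))
  cls_names <- names(densities)
  lambda <- if (operator %in% .AGGREGATOR_IDS) solve_lambda(densities) else NA
  scores |>
    dplyr::group_by(.data$sample, .data$class) |>
    dplyr::summarise(
      fused = {
        h <- .data$score[match(cls_names, .data$classifier)]
        if (anyNA(h)) stop("scores table is missing classifiers named in ",
                           "the densities", call. = FALSE)
        .fuse_vector(h, densities, lambda, operator, tnorm, ...)
      },
      .groups = "drop"
    )
}

.fuse_vector <- function(h, densities, lambda, operator, tnorm, ...) {
  if (operator %in% .AGGREGATOR_IDS) {
    m <- sugeno_measure(densities, lambda = lambda)
    choquet_generalized(h, m, tnorm, operator = operator, ...)
  } else if (operator == "owa") {
    owa(h)
  } else {
    simple_aggregate(h, kind = operator)
  }
}
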