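#' Sugeno lambda-fuzzy measures from classifier densities
#'
#' A fuzzy measure (capacity) on a finite set of classifiers is a monotone
#' set function with \eqn{g(\emptyset) = 0} and \eqn{g(X) = 1}. The Sugeno
#' lambda-measure is the one-parameter family satisfying, on disjoint sets,
#' \deqn{g(U \cup W) = g(U) + g(W) + \lambda\, g(U)\, g(W), \qquad \lambda > -1.}
#' Given per-classifier densities \eqn{g_i = g(\{x_i\})} -- here the
#' cross-validated accuracy of each base classifier -- the normalization
#' \eqn{g(X) = 1} pins lambda down as the unique root of
#' \deqn{1 + \lambda = \prod_{i=1}^n (1 + \lambda g_i)}
#' with \eqn{\lambda > -1}, \eqn{\lambda \neq 0} (lambda = 0 exactly when the
#' densities sum to 1, in which case the measure is additive).
#'
#' @name sugeno
NULL

.check_densities <- function(g) {
  if (!is.numeric(g) || length(g) < 1 || any(!is.finite(g))) {
    stop("densities must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(g < 0) || any(g > 1)) {
    stop("densities must lie in [0, 1]", call. = FALSE)
  }
  if (any(g == 0)) {
    warning("zero densities floored at 1e-6 (a zero-importance classifier ",
            "would degenerate the measure chain)")
    g[g == 0] <- 1e-6
  }
  g
}

#' Solve for the Sugeno measure parameter lambda
#'
#' Finds the unique admissible root of
#' \eqn{f(\lambda) = \prod_i (1 + \lambda g_i) - (1 + \lambda)}.
#' The sign of \eqn{\sum g_i - 1} decides the bracket: densities summing
#' below 1 give \eqn{\lambda > 0} (super-additive measure), above 1 give
#' \eqn{\lambda \in (-1, 0)} (sub-additive), and exactly 1 gives the additive
#' measure \eqn{\lambda = 0}. Root finding is bisection on the bracket
#' (expanded geometrically on the positive side) to width 1e-12, followed by
#' a Newton polish.
#'
#' @param densities Numeric vector of per-classifier densities in (0, 1);
#'   exact zeros are floored at 1e-6 with a warning. With a single
#'   classifier the density must be 1 and lambda is 0 by convention.
#' @return The solved lambda (a single number, > -1).
#' @examples
#' solve_lambda(c(0.5, 0.5))   # additive: 0
#' solve_lambda(c(0.3, 0.3))   # (1 - 0.6) / 0.09 = 4.444...
#' @export
solve_lambda <- function(densities) {
  g <- .check_densities(densities)
  n <- length(g)
  if (n == 1) {
    if (abs(g - 1) > 1e-5) {
      stop("with a single classifier the density must equal 1 (g(X) = 1)",
           call. = FALSE)
    }
    return(0)
  }
  if (any(g >= 1)) {
    stop("densities must be strictly below 1 when n >= 2 ",
         "(a unit density leaves no admissible lambda)", call. = FALSE)
  }
  s <- sum(g)
  if (abs(s - 1) <= 1e-12) return(0)

  f <- function(lam) prod(1 + lam * g) - (1 + lam)

  if (s > 1) {
    lo <- -1 + 1e-12
    hi <- -1e-12
  } else {
    lo <- 1e-12
    hi <- 1
    while (f(hi) <= 0 && hi < 1e12) hi <- hi * 2
    if (f(hi) <= 0) stop("lambda root bracketing failed (f never positive); ",
                         "densities: ", paste(signif(g, 4), collapse = ", "),
                         call. = FALSE)
  }
  flo <- f(lo); fhi <- f(hi)
  if (sign(flo) == sign(fhi)) {
    stop("no sign change on the lambda bracket [", lo, ", ", hi, "]; ",
         "f(lo) = ", flo, ", f(hi) = ", fhi, call. = FALSE)
  }
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else { hi <- mid; fhi <- fm }
    if (hi - lo < 1e-12) break
  }
  lam <- (lo + hi) / 2
  # Newton polish: f'(lam) = sum_i g_i prod_{j!=i}(1+lam g_j) - 1
  for (k in 1:3) {
    p <- 1 + lam * g
    fp <- sum(g * prod(p) / p) - 1
    if (abs(fp) < 1e-15) break
    step <- f(lam) / fp
    cand <- lam - step
    if (cand > -1 && is.finite(cand)) lam <- cand
  }
  if (abs(f(lam)) > 1e-10) {
    stop("lambda solve did not converge: residual ", abs(f(lam)), call. = FALSE)
  }
  lam
}

#' Build the cumulative Sugeno measure chain
#'
#' Given densities already arranged in the score-sorted order
#' \eqn{g_{(1)}, \ldots, g_{(n)}} and the solved lambda, recurses
#' \deqn{g(U_1) = g_{(1)}, \qquad
#'       g(U_{i+1}) = g(U_i) + g_{(i+1)} + \lambda\, g_{(i+1)}\, g(U_i),}
#' the measure of the nested level sets \eqn{U_i = \{x_{(1)},\ldots,x_{(i)}\}}.
#' By construction of lambda the chain is non-decreasing and terminates at
#' \eqn{g(X) = 1} (to 1e-9).
#'
#' @param densities Densities in the ordering of the sorted score vector.
#' @param lambda The parameter from [solve_lambda()] (solved on the same
#'   densities; ordering does not affect it).
#' @return An object of class `sugeno_measure`: list with `lambda`,
#'   `densities`, and the `cumulative` chain \eqn{g(U_1), \ldots, g(U_n)}.
#' @examples
#' sugeno_measure(c(0.5, 0.3, 0.2), lambda = 0)$cumulative  # 0.5 0.8 1.0
#' @export
sugeno_measure <- function(densities, lambda = solve_lambda(densities)) {
  g <- .check_densities(densities)
  if (!is.finite(lambda) || lambda <= -1) {
    stop("lambda must be a finite number > -1", call. = FALSE)
  }
  n <- length(g)
  cum <- numeric(n)
  cum[1] <- g[1]
  if (n > 1) {
    for (i in 1:(n - 1)) {
      cum[i + 1] <- cum[i] + g[i + 1] + lambda * g[i + 1] * cum[i]
    }
  }
  if (abs(cum[n] - 1) > 1e-6 && !(n == 1 && abs(g[1] - 1) < 1e-5)) {
    # lambda inconsistent with the densities is allowed for exploratory use,
    # but a chain far from g(X)=1 is usually a usage error
    warning("measure chain ends at ", signif(cum[n], 8),
            ", not 1; lambda and densities are inconsistent")
  } else {
    # the normalization axiom fixes g(X) = 1 exactly; snapping removes the
    # solver's terminal residual, to which boundary-steep t-norms such as
    # Yager with alpha < 1 are acutely sensitive
    cum[n] <- 1
  }
  structure(
    list(lambda = lambda, densities = g, cumulative = cum),
    class = "sugeno_measure"
  )
}

#' @export
print.sugeno_measure <- function(x, ...) {
  cat("<sugeno_measure> n =", length(x$densities),
      " lambda =", signif(x$lambda, 6), "\n")
  cat("  g(U_i):", paste(signif(x$cumulative, 4), collapse = " "), "\n")
  invisible(x)
}

#' @rdname sugeno_measure
#' @param x A `sugeno_measure` object.
#' @param ... Unused.
#' @return `tidy()` returns a tibble with one row per ordered classifier:
#'   its density \eqn{g_{(i)}} and the cumulative \eqn{g(U_i)}.
#' @export
tidy.sugeno_measure <- function(x, ...) {
  tibble::tibble(
    position = seq_along(x$densities),
    density = x$densities,
    cumulative = x$cumulative
  )
}

#' Read / write fuzzy densities
#'
#' Densities interchange as JSON (`{"classifier": density, ...}`) or
#' two-column CSV (`classifier,density`).
#'
#' @param path File path; format inferred from the extension.
#' @param densities Named numeric vector.
#' @return `read_densities()` returns a named numeric vector.
#' @export
read_densities <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- as.numeric(unlist(x))
    names(out) <- names(unlist(x))
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    out <- df[[2]]
    names(out) <- as.character(df[[1]])
  }
  .check_densities(out)
}

#' @rdname read_densities
#' @export
write_densities <- function(densities, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(densities), path, auto_unbox = TRUE, digits = NA)
  } else {
    readr::write_csv(
      tibble::tibble(classifier = names(densities), density = unname(densities)),
      path
    )
  }
  invisible(path)
}
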