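#' Triangular-norm families for generalized Choquet integrals
#'
#' A t-norm is a commutative, associative, monotone binary operation on
#' \eqn{[0,1]^2} with identity 1. Inside a generalized Choquet integral the
#' t-norm \eqn{M(\cdot,\cdot)} replaces the product between the score
#' increment and the measure of the level set, turning the classical integral
#' into a pre-aggregation operator. This registry holds the two parametric
#' families used as headline integrands in schizophrenia-vs-control EEG
#' fusion work -- registered under their monograph indices 8 and 12 -- plus
#' the classical and the commonly used named parametric families.
#'
#' Family 8 is
#' \deqn{M(x,y) = \frac{\max(\alpha^2 xy - (1-x)(1-y),\, 0)}
#'                     {\alpha^2 - (\alpha-1)^2 (1-x)(1-y)}, \quad \alpha > 0,}
#' and family 12 is the Yager t-norm
#' \deqn{M(x,y) = \max\!\big(1 - ((1-x)^\alpha + (1-y)^\alpha)^{1/\alpha},\, 0\big),
#'       \quad \alpha > 0.}
#'
#' @name tnorms
NULL

# Internal registry. Each entry: fn(x, y, alpha), alpha range (open interval
# bounds; NA = no parameter), and excluded interior points.
.tnorm_registry <- local({
  fam8 <- function(x, y, alpha) {
    # grouped so that swapping x and y is bit-identical
    num <- alpha^2 * (x * y) - (1 - x) * (1 - y)
    out <- numeric(length(num))
    pos <- num > 0
    if (any(pos)) {
      den <- alpha^2 - (alpha - 1)^2 * ((1 - x[pos]) * (1 - y[pos]))
      out[pos] <- num[pos] / den
    }
    out
  }
  yager <- function(x, y, alpha) {
    pmax(1 - ((1 - x)^alpha + (1 - y)^alpha)^(1 / alpha), 0)
  }
  list(
    family8 = list(
      id = 8L, fn = fam8,
      alpha_lo = 0, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      description = "rational family no. 8 (alpha > 0)"
    ),
    family12 = list(
      id = 12L, fn = yager,
      alpha_lo = 0, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      description = "Yager family, monograph no. 12 (alpha > 0)"
    ),
    product = list(
      id = NA_integer_, fn = function(x, y, alpha) x * y,
      alpha_lo = NA_real_, alpha_hi = NA_real_, lo_open = NA, hi_open = NA,
      description = "product t-norm (classical Choquet integrand)"
    ),
    minimum = list(
      id = NA_integer_, fn = function(x, y, alpha) pmin(x, y),
      alpha_lo = NA_real_, alpha_hi = NA_real_, lo_open = NA, hi_open = NA,
      description = "minimum t-norm"
    ),
    lukasiewicz = list(
      id = NA_integer_, fn = function(x, y, alpha) pmax(x + y - 1, 0),
      alpha_lo = NA_real_, alpha_hi = NA_real_, lo_open = NA, hi_open = NA,
      description = "Lukasiewicz t-norm"
    ),
    hamacher = list(
      id = NA_integer_,
      fn = function(x, y, alpha) {
        den <- alpha + (1 - alpha) * (x + y - x * y)
        out <- ifelse(den > 0, x * y / den, 0)
        out[x == 0 | y == 0] <- 0
        out
      },
      alpha_lo = 0, alpha_hi = Inf, lo_open = FALSE, hi_open = TRUE,
      description = "Hamacher family (alpha >= 0)"
    ),
    frank = list(
      id = NA_integer_,
      fn = function(x, y, alpha) {
        if (abs(alpha - 1) < 1e-12) return(x * y)
        log1p((alpha^x - 1) * (alpha^y - 1) / (alpha - 1)) / log(alpha)
      },
      alpha_lo = 0, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      description = "Frank family (alpha > 0; alpha = 1 is the product limit)"
    ),
    yager = list(
      id = NA_integer_,
      fn = yager,
      alpha_lo = 0, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      description = "Yager family (alpha > 0); same formula as family 12"
    ),
    dombi = list(
      id = NA_integer_,
      fn = function(x, y, alpha) {
        out <- numeric(length(x))
        pos <- x > 0 & y > 0
        if (any(pos)) {
          a <- (1 / x[pos] - 1)^alpha + (1 / y[pos] - 1)^alpha
          out[pos] <- 1 / (1 + a^(1 / alpha))
        }
        out
      },
      alpha_lo = 0, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      description = "Dombi family (alpha > 0)"
    ),
    schweizer_sklar = list(
      id = NA_integer_,
      fn = function(x, y, alpha) {
        if (alpha > 0) {
          pmax(x^alpha + y^alpha - 1, 0)^(1 / alpha)
        } else {
          out <- numeric(length(x))
          pos <- x > 0 & y > 0
          out[pos] <- (x[pos]^alpha + y[pos]^alpha - 1)^(1 / alpha)
          out
        }
      },
      alpha_lo = -Inf, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      alpha_exclude = 0,
      description = "Schweizer-Sklar family (alpha != 0)"
    ),
    aczel_alsina = list(
      id = NA_integer_,
      fn = function(x, y, alpha) {
        out <- numeric(length(x))
        pos <- x > 0 & y > 0
        if (any(pos)) {
          a <- (-log(x[pos]))^alpha + (-log(y[pos]))^alpha
          out[pos] <- exp(-a^(1 / alpha))
        }
        out[x == 1 & y > 0] <- y[x == 1 & y > 0]
        out[y == 1 & x > 0] <- x[y == 1 & x > 0]
        out
      },
      alpha_lo = 0, alpha_hi = Inf, lo_open = TRUE, hi_open = TRUE,
      description = "Aczel-Alsina family (alpha > 0)"
    )
  )
})

.tnorm_resolve_name <- function(family, numbering = NULL) {
  if (is.numeric(family)) {
    id <- as.integer(family)
    if (!is.null(numbering)) {
      hit <- names(numbering)[match(id, unlist(numbering))]
      if (length(hit) == 1 && !is.na(hit)) return(.tnorm_resolve_name(hit))
    }
    ids <- vapply(.tnorm_registry, function(e) e$id, integer(1))
    hit <- names(.tnorm_registry)[which(ids == id)]
    if (length(hit) == 0) {
      stop("Unknown t-norm family id: ", id,
           " (only monograph numbers 8 and 12 are registered by index;",
           " pass a `numbering` map for others)", call. = FALSE)
    }
    return(hit[[1]])
  }
  nm <- gsub("[- ]", "_", tolower(as.character(family)))
  if (nm %in% c("family_8", "8")) nm <- "family8"
  if (nm %in% c("family_12", "12")) nm <- "family12"
  if (!nm %in% names(.tnorm_registry)) {
    stop("Unknown t-norm family: '", family, "'. See tnorm_families().",
         call. = FALSE)
  }
  nm
}

#' Construct a t-norm specification
#'
#' @param family Family name (e.g. `"family8"`, `"family12"`, `"product"`,
#'   `"hamacher"`, `"yager"`) or a monograph index (8 or 12 are built in).
#' @param alpha Real parameter for parametric families; ignored (must be
#'   omitted or NA) for parameter-free families.
#' @param numbering Optional named list mapping family names to user-chosen
#'   integer indices, extending the built-in numbering.
#'
#' @return An object of class `tnorm_spec` with elements `family`, `alpha`
#'   and the admissible parameter range.
#' @examples
#' tnorm_spec("family12", alpha = 0.2)
#' tnorm_spec(8, alpha = 0.1)
#' tnorm_spec("product")
#' @export
tnorm_spec <- function(family, alpha = NA_real_, numbering = NULL) {
  nm <- .tnorm_resolve_name(family, numbering)
  entry <- .tnorm_registry[[nm]]
  has_alpha <- !is.na(entry$alpha_lo)
  if (has_alpha) {
    if (is.na(alpha)) {
      stop("Family '", nm, "' requires a parameter alpha in ",
           .range_label(entry), call. = FALSE)
    }
    if (!.alpha_valid(entry, alpha)) {
      stop("alpha = ", alpha, " is outside the admissible range ",
           .range_label(entry), " for family '", nm, "'", call. = FALSE)
    }
  } else if (!is.na(alpha)) {
    stop("Family '", nm, "' takes no parameter", call. = FALSE)
  }
  structure(
    list(family = nm, id = entry$id, alpha = if (has_alpha) alpha else NA_real_,
         alpha_lo = entry$alpha_lo, alpha_hi = entry$alpha_hi,
         lo_open = entry$lo_open, hi_open = entry$hi_open),
    class = "tnorm_spec"
  )
}

#' @export
print.tnorm_spec <- function(x, ...) {
  cat("<tnorm_spec> family:", x$family,
      if (!is.na(x$id)) paste0("(no. ", x$id, ")") else "",
      if (!is.na(x$alpha)) paste0("alpha = ", x$alpha) else "(no parameter)",
      "\n")
  invisible(x)
}

.alpha_valid <- function(entry, alpha) {
  if (is.na(entry$alpha_lo)) return(is.na(alpha))
  lo_ok <- if (entry$lo_open) alpha > entry$alpha_lo else alpha >= entry$alpha_lo
  hi_ok <- if (entry$hi_open) alpha < entry$alpha_hi else alpha <= entry$alpha_hi
  excl <- entry$alpha_exclude
  lo_ok && hi_ok && (is.null(excl) || !any(abs(alpha - excl) < 1e-12))
}

.range_label <- function(entry) {
  if (is.na(entry$alpha_lo)) return("(none)")
  paste0(if (entry$lo_open) "(" else "[", entry$alpha_lo, ", ",
         entry$alpha_hi, if (entry$hi_open) ")" else "]",
         if (!is.null(entry$alpha_exclude))
           paste0(" \\ {", paste(entry$alpha_exclude, collapse = ","), "}") else "")
}

#' Evaluate a t-norm on the unit square
#'
#' Vectorized over `x` and `y` (recycled to a common length). Raw formula
#' values that stray outside \eqn{[0,1]} by floating-point rounding (within
#' 1e-12) are clipped back in; larger excursions raise an error because they
#' indicate an invalid family implementation, not rounding.
#'
#' @param spec A [tnorm_spec()].
#' @param x,y Numeric vectors in \eqn{[0,1]}.
#' @return Numeric vector of \eqn{M(x,y)} values in \eqn{[0,1]}.
#' @examples
#' sp <- tnorm_spec("family12", alpha = 1)
#' tnorm_evaluate(sp, 0.7, 0.6)  # Lukasiewicz: max(0.7 + 0.6 - 1, 0) = 0.3
#' @export
tnorm_evaluate <- function(spec, x, y) {
  stopifnot(inherits(spec, "tnorm_spec"))
  if (any(!is.finite(x)) || any(!is.finite(y)) ||
      any(x < 0 | x > 1) || any(y < 0 | y > 1)) {
    stop("t-norm arguments must lie in [0, 1]", call. = FALSE)
  }
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  out <- .tnorm_registry[[spec$family]]$fn(x, y, spec$alpha)
  bad <- out < -1e-12 | out > 1 + 1e-12
  if (any(bad)) {
    stop("t-norm '", spec$family, "' produced values outside [0,1] beyond ",
         "rounding tolerance", call. = FALSE)
  }
  pmin(pmax(out, 0), 1)
}

#' Parameter grid for a t-norm family
#'
#' Builds the arithmetic grid `lo, lo+step, ..., hi` and keeps the points that
#' are admissible for the family. The defaults reproduce the sweep
#' \eqn{-10, -9.9, \ldots, 9.9, 10} used when searching pre-aggregation
#' operators; for a family with \eqn{\alpha > 0} this leaves the 100 values
#' \eqn{0.1, 0.2, \ldots, 10}.
#'
#' @param family Family name or index (see [tnorm_spec()]).
#' @param lo,hi,step Grid limits and spacing.
#' @param numbering Optional numbering map, as in [tnorm_spec()].
#' @return Increasing numeric vector of admissible parameter values; for a
#'   parameter-free family, `NA` (a single spec with no alpha).
#' @examples
#' length(alpha_grid("family12"))  # 100
#' @export
alpha_grid <- function(family, lo = -10, hi = 10, step = 0.1, numbering = NULL) {
  stopifnot(lo <= hi, step > 0)
  nm <- .tnorm_resolve_name(family, numbering)
  entry <- .tnorm_registry[[nm]]
  if (is.na(entry$alpha_lo)) return(NA_real_)
  # round to the grid's decimal precision so 0.1 increments land exactly
  k <- max(0, ceiling(-log10(step)) + 1)
  grid <- round(seq(lo, hi, by = step), k)
  grid[vapply(grid, function(a) .alpha_valid(entry, a), logical(1))]
}

#' Catalogue of registered t-norm families
#'
#' @return A tibble with one row per family: `family`, `id` (monograph index
#'   where one is registered), `has_alpha`, the admissible range, and a short
#'   description.
#' @examples
#' tnorm_families()
#' @export
tnorm_families <- function() {
  tibble::tibble(
    family = names(.tnorm_registry),
    id = unname(vapply(.tnorm_registry, function(e) e$id, integer(1))),
    has_alpha = unname(vapply(.tnorm_registry,
                              function(e) !is.na(e$alpha_lo), logical(1))),
    alpha_lo = unname(vapply(.tnorm_registry, function(e) e$alpha_lo,
                             numeric(1))),
    alpha_hi = unname(vapply(.tnorm_registry, function(e) e$alpha_hi,
                             numeric(1))),
    range = unname(vapply(.tnorm_registry, .range_label, character(1))),
    description = unname(vapply(.tnorm_registry, function(e) e$description,
                                character(1)))
  )
}
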