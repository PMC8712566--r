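#' EEG band-wise connectivity and spanning-tree metrics
#'
#' The feature pipeline turns a multichannel resting-state epoch into one
#' row of global network descriptors per frequency band: (1) zero-phase FIR
#' band-pass filtering into canonical EEG bands, (2) directed connectivity
#' from pairwise linear Granger causality (GC) on vector-autoregressive
#' fits with AIC order selection, (3) a maximum spanning tree (MST) over the
#' symmetrized connectivity network (Kruskal on descending weights), and
#' (4) five global tree metrics: maximal degree, maximal betweenness
#' centrality, leaf fraction, diameter, and tree hierarchy.
#'
#' @name brain_network
NULL

#' Canonical EEG frequency bands
#'
#' @return Tibble of the six bands used throughout: delta (0.5-4 Hz), theta
#'   (4-8), low alpha (8-10), high alpha (10-12), beta (13-30), gamma
#'   (30-45).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "low_alpha", "high_alpha", "beta", "gamma"),
    lo = c(0.5, 4, 8, 10, 13, 30),
    hi = c(4, 8, 10, 12, 30, 45)
  )
}

#' The 19 scalp electrodes of the 10-20 system
#' @return Character vector of electrode labels.
#' @export
electrode_names <- function() {
  c("Fp1", "Fp2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "Fz", "Pz", "Cz")
}

#' Zero-phase FIR band-pass filter
#'
#' Designs a linear-phase FIR band-pass (Hamming-windowed, via
#' [signal::fir1()]) and applies it forward-backward ([signal::filtfilt()])
#' so the output has zero phase distortion. The default filter order scales
#' with the sampling rate (1.5 s of taps) but is capped so the forward-
#' backward pass remains well conditioned on short epochs.
#'
#' @param x Numeric vector, or channels-by-samples matrix (filtered row-wise).
#' @param fs Sampling rate, Hz.
#' @param lo,hi Band edges, Hz; must satisfy `0 < lo < hi < fs/2`.
#' @param order FIR order (number of taps minus one); even. Default
#'   `min(floor((n - 1)/3), round(1.5 * fs))`.
#' @return Filtered signal, same shape as `x`.
#' @examples
#' fs <- 256; t <- seq(0, 4, by = 1/fs)
#' x <- sin(2 * pi * 6 * t) + sin(2 * pi * 40 * t)
#' y <- bandpass(x, fs, 4, 8)  # keeps the 6 Hz component
#' @export
bandpass <- function(x, fs, lo, hi, order = NULL) {
  stopifnot(is.numeric(fs), fs > 0)
  if (!(lo > 0 && hi > lo && hi < fs / 2)) {
    stop("band edges must satisfy 0 < lo < hi < fs/2 (Nyquist ", fs / 2, " Hz)",
         call. = FALSE)
  }
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (is.null(order)) order <- min(floor((n - 1) / 3), round(1.5 * fs))
  order <- max(16, 2 * floor(order / 2))  # even, not degenerate
  flt <- signal::fir1(order, c(lo, hi) / (fs / 2), type = "pass")
  apply_filter <- function(v) as.numeric(signal::filtfilt(flt, v))
  if (is.matrix(x)) {
    out <- t(apply(x, 1, apply_filter))
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply_filter(x)
  }
}

# Lag-embed a multichannel series: returns response matrix (T-p) x k and the
# stacked lag design (T-p) x (k*p), lag-major ordering.
.var_embed <- function(X, p) {
  # X: T x k (time in rows)
  Tn <- nrow(X); k <- ncol(X)
  E <- stats::embed(X, p + 1)
  resp <- E[, seq_len(k), drop = FALSE]
  design <- E[, -seq_len(k), drop = FALSE]
  list(resp = resp, design = design, n = Tn - p, k = k)
}

#' Fit a vector-autoregressive model with AIC order selection
#'
#' Ordinary least squares per channel equation; the order is chosen by
#' minimizing \eqn{\mathrm{AIC}(p) = \log\det\hat\Sigma_p + 2 k^2 p / T}
#' over `1..max_order` on the common sample (first `max_order` observations
#' dropped for every candidate, so likelihoods are comparable).
#'
#' @param x Channels-by-samples numeric matrix (or samples vector for a
#'   univariate AR).
#' @param max_order Largest candidate lag order.
#' @return List with `order`, `coefficients` (k x (k*p) matrix, lag-major),
#'   `sigma` (residual covariance), `resid_var` (per-equation residual
#'   variances), and the `aic` profile.
#' @export
fit_var <- function(x, max_order = 20) {
  X <- if (is.matrix(x)) t(x) else matrix(as.numeric(x), ncol = 1)  # T x k
  Tn <- nrow(X); k <- ncol(X)
  stopifnot(max_order >= 1)
  if (Tn < 10 * k * max_order) {
    stop("series too short for max_order = ", max_order,
         " (need >= ", 10 * k * max_order, " samples, have ", Tn, ")",
         call. = FALSE)
  }
  if (any(apply(X, 2, stats::sd) < 1e-12)) {
    stop("degenerate (constant) channel: zero variance", call. = FALSE)
  }
  Xc <- scale(X, center = TRUE, scale = FALSE)
  emb <- .var_embed(Xc, max_order)
  n_common <- emb$n
  aic <- numeric(max_order)
  fits <- vector("list", max_order)
  for (p in seq_len(max_order)) {
    D <- emb$design[, seq_len(k * p), drop = FALSE]
    fit <- .lm.fit(D, emb$resp)
    res <- matrix(fit$residuals, nrow = n_common)
    Sig <- crossprod(res) / n_common
    det_sig <- det(as.matrix(Sig))
    if (det_sig <= 0) det_sig <- .Machine$double.xmin
    aic[p] <- log(det_sig) + 2 * k^2 * p / n_common
    fits[[p]] <- fit
  }
  p_star <- which.min(aic)
  fit <- fits[[p_star]]
  res <- matrix(fit$residuals, nrow = n_common)
  coefs <- t(matrix(fit$coefficients, ncol = k))  # k x (k*p)
  kappa_d <- tryCatch(
    kappa(emb$design[, seq_len(k * p_star), drop = FALSE], exact = FALSE),
    error = function(e) NA_real_)
  if (is.finite(kappa_d) && kappa_d > 1e10) {
    stop("ill-conditioned VAR regression (condition number ",
         format(kappa_d, digits = 3), ")", call. = FALSE)
  }
  list(order = p_star, coefficients = coefs,
       sigma = crossprod(res) / n_common,
       resid_var = colMeans(res^2), aic = aic)
}

# Residual variance of a least-squares fit; ML convention (divide by n).
.ols_resvar <- function(design, resp) {
  fit <- .lm.fit(design, resp)
  mean(fit$residuals^2)
}

#' Pairwise linear Granger causality
#'
#' Time-domain GC from `y` to `x`:
#' \deqn{F_{y \to x} = \ln\big(\sigma^2_{restricted} / \sigma^2_{full}\big),}
#' where the restricted model regresses \eqn{x_t} on its own `order` lags and
#' the full model adds the lags of `y`. Nested least squares guarantees
#' \eqn{F \ge 0} up to rounding. If `order` is `NULL`, the lag order is
#' chosen by bivariate VAR AIC (see [fit_var()]).
#'
#' @param x,y Numeric series of common length. The direction measured is
#'   `y` driving `x`.
#' @param order Lag order; `NULL` for AIC selection up to `max_order`.
#' @param max_order AIC search bound when `order` is `NULL`.
#' @return Single non-negative number \eqn{F_{y\to x}}.
#' @export
pairwise_gc <- function(x, y, order = NULL, max_order = 20) {
  stopifnot(length(x) == length(y))
  if (is.null(order)) {
    order <- fit_var(rbind(x, y), max_order = max_order)$order
  }
  stopifnot(order >= 1)
  x <- x - mean(x); y <- y - mean(y)
  emb <- .var_embed(cbind(x, y), order)
  xlags <- emb$design[, seq(1, 2 * order, by = 2), drop = FALSE]
  v_full <- .ols_resvar(emb$design, emb$resp[, 1])
  v_restr <- .ols_resvar(xlags, emb$resp[, 1])
  if (v_full <= 0) stop("zero full-model residual variance", call. = FALSE)
  log(v_restr / v_full)
}

#' Band-wise directed connectivity matrix
#'
#' For each frequency band, band-pass filters every epoch and evaluates
#' pairwise GC over all ordered channel pairs; `W[i, j]` holds the causal
#' influence of channel `j` on channel `i` (\eqn{F_{j \to i}}), averaged over
#' the subject's epochs. The lag order is selected once per channel pair and
#' band (bivariate AIC on the first epoch) and reused across epochs.
#'
#' @param epochs A channels-by-samples matrix, or a list of such matrices
#'   (one per epoch; averaged).
#' @param fs Sampling rate, Hz.
#' @param bands Tibble with columns `band`, `lo`, `hi`; default [eeg_bands()].
#' @param max_order AIC search bound per pair.
#' @return Named list (one entry per band) of directed weight matrices with
#'   zero diagonal; channel names carried over from row names.
#' @export
connectivity <- function(epochs, fs, bands = eeg_bands(), max_order = 20) {
  if (is.matrix(epochs)) epochs <- list(epochs)
  stopifnot(length(epochs) >= 1, nrow(bands) >= 1)
  k <- nrow(epochs[[1]])
  ch <- rownames(epochs[[1]])
  if (is.null(ch)) ch <- paste0("ch", seq_len(k))
  out <- vector("list", nrow(bands))
  names(out) <- bands$band
  for (b in seq_len(nrow(bands))) {
    filtered <- lapply(epochs, bandpass, fs = fs, lo = bands$lo[b],
                       hi = bands$hi[b])
    W <- matrix(0, k, k, dimnames = list(ch, ch))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        p_ij <- tryCatch(
          fit_var(filtered[[1]][c(i, j), , drop = FALSE],
                  max_order = max_order)$order,
          error = function(e) NA_integer_)
        if (is.na(p_ij)) next  # degenerate pair: leave 0, move on
        f_j_to_i <- f_i_to_j <- 0
        for (ep in filtered) {
          xi <- ep[i, ]; xj <- ep[j, ]
          f_j_to_i <- f_j_to_i + max(0, pairwise_gc(xi, xj, order = p_ij))
          f_i_to_j <- f_i_to_j + max(0, pairwise_gc(xj, xi, order = p_ij))
        }
        W[i, j] <- f_j_to_i / length(filtered)  # column drives row
        W[j, i] <- f_i_to_j / length(filtered)
      }
    }
    out[[b]] <- W
  }
  out
}

#' Maximum spanning tree by Kruskal's algorithm
#'
#' Symmetrizes a directed connectivity matrix (mean of the two directions by
#' default, elementwise max optionally), sorts all edges by decreasing
#' weight, and adds the strongest edges that do not close a loop until the
#' tree spans all nodes (n - 1 edges). Equal weights are broken
#' lexicographically by node pair, so the tree is deterministic.
#'
#' @param W Square non-negative weight matrix (directed or symmetric).
#' @param rule How to symmetrize a directed matrix: `"mean"` or `"max"`.
#' @return An [igraph] undirected tree with edge attribute `weight`.
#' @examples
#' W <- matrix(c(0, 4, 3, 2, 4, 0, 1, 1, 3, 1, 0, 1, 2, 1, 1, 0), 4, 4)
#' igraph::as_edgelist(max_spanning_tree(W))  # edges 1-2, 1-3, 1-4
#' @export
max_spanning_tree <- function(W, rule = c("mean", "max")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
  n <- nrow(W)
  S <- if (rule == "mean") (W + t(W)) / 2 else pmax(W, t(W))
  idx <- which(upper.tri(S) & S > 0, arr.ind = TRUE)  # zero weight = no edge
  ew <- S[idx]
  ord <- order(-ew, idx[, 1], idx[, 2])  # weight desc, then lexicographic
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  chosen <- matrix(0L, n - 1, 2)
  wts <- numeric(n - 1)
  m <- 0L
  for (e in ord) {
    ra <- find(idx[e, 1]); rb <- find(idx[e, 2])
    if (ra != rb) {
      parent[ra] <- rb
      m <- m + 1L
      chosen[m, ] <- c(idx[e, 1], idx[e, 2])
      wts[m] <- ew[e]
      if (m == n - 1L) break
    }
  }
  if (m < n - 1L) {
    stop("connectivity graph is disconnected: spanning tree has only ",
         m, " edges for ", n, " nodes", call. = FALSE)
  }
  g <- igraph::graph_from_edgelist(chosen, directed = FALSE)
  igraph::E(g)$weight <- wts
  if (!is.null(rownames(W))) igraph::V(g)$name <- rownames(W)
  g
}

#' Global metrics of a spanning tree
#'
#' For a tree on m nodes: maximal degree; maximal betweenness centrality
#' (`max_bc` as the fraction of the \eqn{(m-1)(m-2)/2} node pairs whose path
#' crosses the node, `max_bc_raw` as the raw pair count); leaf fraction
#' \eqn{L/m}; diameter in edges; and tree hierarchy
#' \deqn{T_h = \frac{L}{2\, m_{edges}\, BC_{max}},}
#' with \eqn{BC_{max}} the normalized fraction -- the balance between
#' integration (few crossings) and overload of the most central node.
#'
#' @param tree An igraph tree (from [max_spanning_tree()]).
#' @return One-row tibble: `max_degree`, `max_bc`, `max_bc_raw`,
#'   `leaf_fraction`, `diameter`, `hierarchy`.
#' @export
mst_metrics <- function(tree) {
  m <- igraph::vcount(tree)
  if (igraph::ecount(tree) != m - 1 || !igraph::is_connected(tree)) {
    stop("input is not a spanning tree (need m nodes, m-1 edges, connected)",
         call. = FALSE)
  }
  deg <- igraph::degree(tree)
  bc_raw <- igraph::betweenness(tree, weights = NA)
  pairs <- if (m > 2) (m - 1) * (m - 2) / 2 else 1
  bc_norm <- bc_raw / pairs
  L <- sum(deg == 1)
  bmax <- max(bc_norm)
  tibble::tibble(
    max_degree = as.integer(max(deg)),
    max_bc = bmax,
    max_bc_raw = max(bc_raw),
    leaf_fraction = L / m,
    diameter = as.integer(igraph::diameter(tree, weights = NA)),
    hierarchy = if (bmax > 0) L / (2 * (m - 1) * bmax) else NA_real_
  )
}

#' Extract the band-wise MST feature vector for a cohort
#'
#' Runs the full pipeline -- band filtering, pairwise GC, maximum spanning
#' tree, tree metrics -- for every subject and band, and assembles the
#' subjects-by-features table used for classification (5 metrics per band).
#'
#' @param cohort List of subjects; each a list with `epochs` (list of
#'   channels-by-samples matrices) and `label`. [gen_var_cohort()] produces
#'   this structure.
#' @param fs Sampling rate, Hz.
#' @param bands Band table (default [eeg_bands()]).
#' @param max_order AIC bound for the GC fits.
#' @param mst_rule Symmetrization rule passed to [max_spanning_tree()].
#' @return Tibble: `subject`, `label`, then `<band>_<metric>` columns.
#' @export
extract_features <- function(cohort, fs, bands = eeg_bands(), max_order = 20,
                             mst_rule = "mean") {
  rows <- purrr::imap(cohort, function(subj, sid) {
    conn <- connectivity(subj$epochs, fs = fs, bands = bands,
                         max_order = max_order)
    feats <- purrr::imap(conn, function(W, band) {
      met <- mst_metrics(max_spanning_tree(W, rule = mst_rule))
      met <- met[, c("max_degree", "max_bc", "leaf_fraction", "diameter",
                     "hierarchy")]
      names(met) <- paste0(band, "_", names(met))
      met
    })
    dplyr::bind_cols(
      tibble::tibble(subject = as.character(sid), label = subj$label),
      dplyr::bind_cols(feats)
    )
  })
  dplyr::bind_rows(rows)
}
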