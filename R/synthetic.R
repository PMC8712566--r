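#' Synthetic cohorts, feature tables, and classifier-score ensembles
#'
#' Generators that emulate the shapes and statistical structure of a
#' resting-state EEG case-control study -- two classes of 20 subjects with
#' 19-channel recordings at 512 Hz, 25 artifact-free 8-s epochs each --
#' without any clinical data: (1) multichannel signals from stable VAR(2)
#' processes whose directed coupling topology differs between classes, so
#' Granger-causality connectivity separates them; (2) subjects-by-features
#' tables of spanning-tree metrics with controllable per-feature effect
#' sizes; (3) ensembles of classifier probability outputs with controllable
#' marginal accuracy and error correlation (Gaussian copula on latent
#' correctness). All generators are deterministic under their seed.
#'
#' @name synthetic_data
NULL

# Companion-matrix spectral radius of a VAR(p) given list of k x k lag
# matrices; stability requires < 1.
.var_spectral_radius <- function(A) {
  k <- nrow(A[[1]]); p <- length(A)
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p)) comp[1:k, ((l - 1) * k + 1):(l * k)] <- A[[l]]
  if (p > 1) comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

.simulate_var <- function(A, n, burn = 200, sd_noise = 1) {
  k <- nrow(A[[1]]); p <- length(A)
  x <- matrix(0, k, n + burn + p)
  for (t in (p + 1):(n + burn + p)) {
    xt <- stats::rnorm(k, sd = sd_noise)
    for (l in seq_len(p)) xt <- xt + A[[l]] %*% x[, t - l]
    x[, t] <- xt
  }
  x[, (burn + p + 1):(n + burn + p), drop = FALSE]
}

# Class coupling template: diagonal AR(2) dynamics plus directed lag-1
# couplings on the given edges.
.coupling_var <- function(n_channels, edges, strength) {
  A1 <- diag(0.5, n_channels)
  A2 <- diag(-0.3, n_channels)
  if (length(edges)) {
    for (e in edges) A1[e[2], e[1]] <- A1[e[2], e[1]] + strength
  }
  list(A1, A2)
}

#' Generate a two-class cohort of VAR-coupled multichannel signals
#'
#' Both classes share the same within-channel dynamics; they differ in the
#' set of directed lag-1 couplings (class 1 is more densely coupled by
#' default), which is the property the Granger-causality pipeline is meant
#' to recover. Subject-level variability comes from a multiplicative jitter
#' on the coupling strengths and independent innovation noise.
#'
#' @param n_per_class Subjects per class (default 20, the 40-subject
#'   cohort).
#' @param n_channels Channels (default 19; named after the 10-20
#'   electrodes when 19).
#' @param fs Sampling rate, Hz (default 512).
#' @param n_epochs Epochs per subject (default 25).
#' @param epoch_len Samples per epoch (default 4096, i.e. 8 s at 512 Hz).
#' @param coupling_strength Base off-diagonal coupling (default 0.35).
#' @param n_couplings Integer vector of length 2: number of directed
#'   couplings in class HC and class SZ (default `c(4, 12)`).
#' @param seed RNG seed.
#' @return Named list of subjects, each `list(epochs = <list of
#'   channels-by-samples matrices>, label = "HC"|"SZ")`, with attributes
#'   `fs` and the generating spec.
#' @export
gen_var_cohort <- function(n_per_class = 20, n_channels = 19, fs = 512,
                           n_epochs = 25, epoch_len = 4096,
                           coupling_strength = 0.35,
                           n_couplings = c(4, 12), seed = 1L) {
  stopifnot(n_per_class >= 1, n_channels >= 2, n_epochs >= 1, epoch_len >= 64)
  ch <- if (n_channels == 19) electrode_names() else
    paste0("ch", seq_len(n_channels))
  withr::with_seed(seed, {
    all_pairs <- utils::combn(n_channels, 2, simplify = FALSE)
    # directed edges: sample ordered pairs, class SZ gets a superset
    dirpairs <- unlist(lapply(all_pairs, function(p) list(p, rev(p))),
                       recursive = FALSE)
    picks <- sample(length(dirpairs), max(n_couplings))
    edges_hc <- dirpairs[picks[seq_len(n_couplings[1])]]
    edges_sz <- dirpairs[picks[seq_len(n_couplings[2])]]
    subjects <- list()
    for (cls in c("HC", "SZ")) {
      edges <- if (cls == "HC") edges_hc else edges_sz
      for (s in seq_len(n_per_class)) {
        jitter <- stats::runif(1, 0.85, 1.15)
        A <- .coupling_var(n_channels, edges, coupling_strength * jitter)
        rho <- .var_spectral_radius(A)
        if (rho >= 1) {
          stop("unstable VAR for subject ", cls, s,
               ": companion spectral radius ", signif(rho, 5), call. = FALSE)
        }
        epochs <- lapply(seq_len(n_epochs), function(e) {
          x <- .simulate_var(A, epoch_len)
          rownames(x) <- ch
          x
        })
        subjects[[paste0(cls, "_", s)]] <- list(epochs = epochs, label = cls)
      }
    }
    attr(subjects, "fs") <- fs
    attr(subjects, "spec") <- list(
      n_per_class = n_per_class, n_channels = n_channels, fs = fs,
      n_epochs = n_epochs, epoch_len = epoch_len,
      coupling_strength = coupling_strength, n_couplings = n_couplings,
      seed = seed)
    subjects
  })
}

# Plausible locations/scales for the five tree metrics at 19 nodes.
.metric_profiles <- function() {
  tibble::tibble(
    metric = c("max_degree", "max_bc", "leaf_fraction", "diameter",
               "hierarchy"),
    mean = c(4.5, 0.62, 0.58, 8.5, 0.42),
    sd = c(1.2, 0.09, 0.07, 1.8, 0.08),
    integer = c(TRUE, FALSE, FALSE, TRUE, FALSE)
  )
}

#' Generate a subjects-by-features table of tree metrics
#'
#' Emulates the 5-metrics-by-6-bands feature table (30 features, 40
#' subjects by default). Class differences are injected as shifts of the
#' class-SZ mean by `effect` standard deviations on selected features;
#' within-class noise is Gaussian. The default places an effect of 0.8 sd
#' on leaf fraction and diameter in every band -- a moderate global
#' reorganization of the tree backbone, the kind of shift reported for
#' schizophrenia MST studies -- leaving the other metrics at chance.
#' Metric-range constraints are respected (integer rounding for degree and
#' diameter, leaf fraction clipped into (0, 1]).
#'
#' @param n_per_class Subjects per class (default 20).
#' @param bands Band names (default the six of [eeg_bands()]).
#' @param effect Named numeric vector of per-feature effect sizes in sd
#'   units (names `<band>_<metric>`); unnamed scalar applies everywhere;
#'   `NULL` for the default pattern.
#' @param seed RNG seed.
#' @return Tibble: `subject`, `label`, and one column per feature.
#' @examples
#' dim(gen_feature_table(seed = 1))  # 40 x 32
#' @export
gen_feature_table <- function(n_per_class = 20, bands = eeg_bands()$band,
                              effect = NULL, seed = 1L) {
  prof <- .metric_profiles()
  feats <- tidyr::expand_grid(band = bands, metric = prof$metric) |>
    dplyr::left_join(prof, by = "metric") |>
    dplyr::mutate(feature = paste0(.data$band, "_", .data$metric))
  eff <- stats::setNames(rep(0, nrow(feats)), feats$feature)
  if (is.null(effect)) {
    eff[grepl("_(leaf_fraction|diameter)$", names(eff))] <- 0.8
  } else if (is.null(names(effect))) {
    eff[] <- effect
  } else {
    unknown <- setdiff(names(effect), names(eff))
    if (length(unknown)) stop("unknown feature(s) in effect: ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    eff[names(effect)] <- effect
  }
  n <- 2 * n_per_class
  label <- rep(c("HC", "SZ"), each = n_per_class)
  withr::with_seed(seed, {
    cols <- purrr::map(seq_len(nrow(feats)), function(j) {
      mu <- feats$mean[j] + ifelse(label == "SZ", eff[j] * feats$sd[j], 0)
      v <- stats::rnorm(n, mu, feats$sd[j])
      if (feats$integer[j]) v <- pmax(2, round(v))
      if (feats$metric[j] == "leaf_fraction") v <- pmin(pmax(v, 0.05), 1)
      if (feats$metric[j] %in% c("max_bc", "hierarchy")) v <- pmin(pmax(v, 0.01), 1)
      v
    })
    names(cols) <- feats$feature
    dplyr::bind_cols(
      tibble::tibble(subject = paste0("S", seq_len(n)), label = label),
      tibble::as_tibble(cols)
    )
  })
}

#' Generate correlated classifier-score ensembles
#'
#' Latent Gaussian-copula correctness model: each sample draws a latent
#' normal vector with the given correlation; classifier i is correct when
#' its latent coordinate falls below the `accuracy[i]` quantile, so marginal
#' accuracies are matched exactly in expectation and error co-occurrence is
#' governed by the copula correlation. Probabilities are then drawn so that
#' thresholding at 0.5 reproduces correctness: a correct classifier's
#' true-class probability is `0.5 + B/2` with `B ~ Beta(5, 2)` (confident
#' but imperfect), an erring classifier puts `0.5 + B'/2` on the wrong
#' class with `B' ~ Beta(2, 5)` (weakly wrong).
#'
#' @param n_samples Number of samples (default 1600, matching 200
#'   repetitions of 8 held-out subjects).
#' @param n_classifiers Ensemble size (default 5).
#' @param accuracies Marginal accuracy per classifier, recycled (default
#'   0.85).
#' @param rho Error correlation: a scalar for an exchangeable structure or
#'   a full correlation matrix (must be positive semi-definite).
#' @param seed RNG seed.
#' @return Tibble in long form: `sample`, `truth` (1 or 2), `classifier`,
#'   `class`, `score`; per sample and classifier the two class scores sum
#'   to 1.
#' @export
gen_classifier_scores <- function(n_samples = 1600, n_classifiers = 5,
                                  accuracies = 0.85, rho = 0.2, seed = 1L) {
  acc <- rep_len(accuracies, n_classifiers)
  stopifnot(all(acc > 0), all(acc < 1))
  R <- if (is.matrix(rho)) rho else {
    m <- matrix(rho, n_classifiers, n_classifiers); diag(m) <- 1; m
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < -1e-8) {
    stop("correlation structure is not positive semi-definite ",
         "(min eigenvalue ", signif(min(ev$values), 4), ")", call. = FALSE)
  }
  Rhalf <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  withr::with_seed(seed, {
    truth <- rep_len(c(1L, 2L), n_samples)
    Z <- matrix(stats::rnorm(n_samples * n_classifiers), n_samples) %*% Rhalf
    correct <- sweep(stats::pnorm(Z), 2, acc, "<")
    conf_ok <- matrix(stats::rbeta(n_samples * n_classifiers, 5, 2), n_samples)
    conf_bad <- matrix(stats::rbeta(n_samples * n_classifiers, 2, 5), n_samples)
    p_true <- ifelse(correct, 0.5 + conf_ok / 2, 0.5 - conf_bad / 2)
    long <- tidyr::expand_grid(sample = seq_len(n_samples),
                               classifier = paste0("clf", seq_len(n_classifiers)))
    i <- long$sample
    j <- match(long$classifier, paste0("clf", seq_len(n_classifiers)))
    pt <- p_true[cbind(i, j)]
    tr <- truth[i]
    dplyr::bind_rows(
      long |> dplyr::mutate(truth = tr, class = tr, score = pt),
      long |> dplyr::mutate(truth = tr, class = 3L - tr, score = 1 - pt)
    ) |>
      dplyr::arrange(.data$sample, .data$classifier, .data$class) |>
      dplyr::select("sample", "truth", "classifier", "class", "score")
  })
}
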