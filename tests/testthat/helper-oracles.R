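# Independent oracle implementations used to cross-check the package.
# Everything here is written from the defining formulas with plain loops,
# deliberately sharing no code with the package internals.

# ---- t-norm formulas (scalar) -----------------------------------------

oracle_tnorm <- function(family, alpha = NA) {
  switch(family,
    product = function(x, y) x * y,
    minimum = function(x, y) min(x, y),
    lukasiewicz = function(x, y) max(x + y - 1, 0),
    family8 = function(x, y) {
      num <- alpha^2 * x * y - (1 - x) * (1 - y)
      if (num <= 0) return(0)
      num / (alpha^2 - (alpha - 1)^2 * (1 - x) * (1 - y))
    },
    family12 = function(x, y) {
      max(1 - ((1 - x)^alpha + (1 - y)^alpha)^(1 / alpha), 0)
    },
    stop("no oracle for family ", family)
  )
}

# ---- Sugeno lambda by dense scan + bisection --------------------------

oracle_lambda <- function(g) {
  if (abs(sum(g) - 1) <= 1e-12) return(0)
  f <- function(lam) prod(1 + lam * g) - (1 + lam)
  lo_grid <- if (sum(g) > 1) seq(-1 + 1e-9, -1e-9, length.out = 4001)
             else exp(seq(log(1e-9), log(1e6), length.out = 4001))
  vals <- vapply(lo_grid, f, numeric(1))
  k <- which(diff(sign(vals)) != 0)[1]
  stopifnot(!is.na(k))
  lo <- lo_grid[k]; hi <- lo_grid[k + 1]
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (sign(f(mid)) == sign(f(lo))) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

oracle_chain <- function(g_ordered, lam, snap_terminal = TRUE) {
  cum <- numeric(length(g_ordered))
  cum[1] <- g_ordered[1]
  for (i in seq_len(length(g_ordered) - 1)) {
    cum[i + 1] <- cum[i] + g_ordered[i + 1] + lam * g_ordered[i + 1] * cum[i]
  }
  # g(X) = 1 holds exactly by the measure's normalization axiom
  if (snap_terminal) cum[length(cum)] <- 1
  cum
}

# ---- naive integral summations ----------------------------------------
# h: raw scores; g: densities in the same (original) order; M: scalar fn.
# Every operator re-sorts and rebuilds the chain itself, with plain loops.

oracle_integral <- function(operator, h, g, M = NULL, h0 = 1,
                            cd3_ratio = TRUE) {
  ord <- order(-h, seq_along(h))
  hs <- h[ord]
  gs <- g[ord]
  lam <- oracle_lambda(g)
  gU <- oracle_chain(gs, lam)
  n <- length(hs)
  hn <- c(hs, 0)                      # hn[i+1] = h_(i+1), hn[n+1] = 0
  hp <- c(if (identical(h0, "first")) hs[1] else 1, hs)  # hp[i] = h_(i-1)
  clip <- function(v) min(max(v, 0), 1)
  Mc <- function(a, b) M(clip(a), clip(b))
  gU <- vapply(gU, clip, numeric(1))
  tot <- 0
  for (i in seq_len(n)) {
    term <- switch(operator,
      choquet = (hs[i] - hn[i + 1]) * gU[i],
      CM = ,
      CFM = Mc(hs[i] - hn[i + 1], gU[i]),
      CCM = Mc(hs[i], gU[i]) - Mc(hn[i + 1], gU[i]),
      CMC = Mc(hs[i], gU[i]) - Mc(hn[i + 1], gU[i]) +
            Mc(hs[i] - hn[i + 1], gU[i]),
      CMMin = Mc(min(hs[i], gU[i]) - min(hn[i + 1], gU[i]), gU[i]),
      CMMin2 = Mc(min(hs[i], gU[i]), min(hn[i + 1], gU[i])),
      CMinM = min(Mc(hs[i], gU[i]), Mc(hn[i + 1], gU[i])),
      CD1 = Mc(hp[i] - hn[i + 1], gU[i]),
      CD2 = Mc(hp[i] + hn[i + 1] - hs[i], gU[i]),
      CD3 = {
        if (hs[i] == 0) 0
        else if (cd3_ratio) Mc((hp[i] + hn[i + 1]) / hs[i], gU[i])
        else Mc(hp[i] + hn[i + 1] / hs[i], gU[i])
      },
      stop("unknown operator ", operator)
    )
    tot <- tot + term
  }
  if (operator == "CFM") min(tot, 1) else tot
}

oracle_owa <- function(x, normalize = TRUE) {
  n <- length(x)
  w <- 1 - (seq_len(n) - 1) / n
  if (normalize) w <- w / sum(w)
  sum(w * sort(x, decreasing = TRUE))
}

# ---- trees: Prufer decoding and brute-force metrics -------------------

prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  m <- 0L
  for (s in seq) {
    leaf <- which(degree == 1L)[1]
    m <- m + 1L
    edges[m, ] <- c(leaf, s)
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

# All-pairs metrics by explicit path walking on the (unique) tree paths.
oracle_tree_metrics <- function(edges, n) {
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    a <- edges[r, 1]; b <- edges[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  deg <- lengths(adj)
  # BFS from every node: distances + parents
  bc_raw <- numeric(n)
  diam <- 0L
  for (s in seq_len(n)) {
    dist <- rep(-1L, n); parent <- rep(0L, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) if (dist[w] < 0) {
        dist[w] <- dist[v] + 1L
        parent[w] <- v
        queue <- c(queue, w)
      }
    }
    diam <- max(diam, max(dist))
    for (t in seq_len(n)) {
      if (t <= s) next
      v <- t
      while (parent[v] != 0 && parent[v] != s) {
        bc_raw[parent[v]] <- bc_raw[parent[v]] + 1
        v <- parent[v]
      }
    }
  }
  pairs <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  L <- sum(deg == 1)
  bmax <- max(bc_raw) / pairs
  list(max_degree = max(deg), max_bc = bmax, max_bc_raw = max(bc_raw),
       leaf_fraction = L / n, diameter = diam,
       hierarchy = if (bmax > 0) L / (2 * (n - 1) * bmax) else NA_real_)
}

# Amplitude of the dominant spectral line, via FFT.
fft_peak_amplitude <- function(x, fs, freq) {
  n <- length(x)
  sp <- abs(stats::fft(x)) / n * 2
  bin <- round(freq * n / fs) + 1
  max(sp[max(1, bin - 2):min(n, bin + 2)])
}

# random sugeno-admissible densities
rand_densities <- function(n) stats::runif(n, 0.05, 0.95)
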