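# Shared fixtures and independent oracles, built in code.

# Small study configuration for fast end-to-end tests.
tiny_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(
      n_mice = 2,
      geometry = lobule_geometry(c(20, 20)),
      n_background = c(positive = 80, negative = 40),
      seed = seed
    ),
    list(...)
  )
  do.call(synthetic_config, args)
}

# Noise-free configuration: exact intensities, exact m/z.
noiseless_config <- function(seed = 1, ...) {
  tiny_config(
    seed = seed,
    mouse_sd = 0, noise_sd = 0, tic_sd = 0, mass_error_ppm = 0,
    n_background = c(positive = 0, negative = 0),
    ...
  )
}

# Gaussian profile-mode peak on a regular m/z axis.
gaussian_spectrum <- function(center = 500, sigma = 0.01, height = 100,
                              from = center - 1, to = center + 1,
                              step = 0.002, baseline = 0) {
  mz <- seq(from, to, by = step)
  tibble::tibble(
    mz = mz,
    intensity = baseline + height * exp(-(mz - center)^2 / (2 * sigma^2))
  )
}

# Brute-force Benjamini-Hochberg step-up: literal evaluation of
# q_(i) = min_{j >= i} (p_(j) * m / j), returned in input order.
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Brute-force relative betweenness by explicit geodesic enumeration over all
# simple paths (graphs with <= 8 nodes).
betweenness_brute <- function(graph) {
  n <- igraph::vcount(graph)
  vs <- seq_len(n)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  # all simple paths between s and t via depth-first enumeration
  all_paths <- function(s, t) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1L]] <<- path
        return()
      }
      for (nb in vs[A[last, ]]) {
        if (!(nb %in% path)) walk(c(path, nb))
      }
    }
    walk(s)
    out
  }
  bc <- numeric(n)
  comp <- igraph::components(graph)$membership
  for (s in vs) {
    for (t in vs) {
      if (s >= t || comp[s] != comp[t]) next
      paths <- all_paths(s, t)
      lens <- vapply(paths, length, integer(1))
      geod <- paths[lens == min(lens)]
      for (v in vs) {
        if (v == s || v == t) next
        through <- vapply(geod, function(p) v %in% p, logical(1))
        bc[v] <- bc[v] + mean(through)
      }
    }
  }
  out <- numeric(n)
  for (ci in unique(comp)) {
    nc <- sum(comp == ci)
    norm <- (nc - 1) * (nc - 2) / 2
    idx <- comp == ci
    out[idx] <- if (norm > 0) bc[idx] / norm else 0
  }
  stats::setNames(out, igraph::V(graph)$name)
}

# Exhaustive hypergeometric upper tail by enumerating all draws of size n
# from a background of N compounds, K of which are in the pathway.
hyper_brute <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # first K elements are the pathway members
  mean(hits >= k)
}

# Single-linkage clustering of centroids at a ppm tolerance (oracle for the
# alignment binning on well-separated cases).
single_linkage_bins <- function(mz, tol_ppm) {
  n <- length(mz)
  if (n == 1) return(1L)
  d <- as.dist(abs(outer(mz, mz, "-")) / outer(mz, mz, pmin) * 1e6)
  hc <- stats::hclust(d, method = "single")
  stats::cutree(hc, h = tol_ppm)
}

# Balanced zonal long table simulated directly from the random-intercept
# model (bypassing the imaging stages).
simulate_zonal_rows <- function(n_mice = 5, zone_effects = c(0, 0, 0),
                                mouse_sd = 0.3, resid_sd = 0.16, mu = 5) {
  d <- expand.grid(mouse = seq_len(n_mice), zone = c("Z1", "Z2", "Z3"),
    roi = 1:3, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  zi <- match(d$zone, c("Z1", "Z2", "Z3"))
  b <- stats::rnorm(n_mice, 0, mouse_sd)
  d$median_intensity <- exp(
    mu + zone_effects[zi] + b[d$mouse] + stats::rnorm(nrow(d), 0, resid_sd)
  )
  tibble::as_tibble(d)
}
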