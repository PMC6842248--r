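# Independent oracles and shared fixtures.

# Spearman via the classical formula 1 - 6 * sum(d^2) / (n (n^2 - 1));
# exact for tie-free vectors.
spearman_formula <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Brute-force caliper oracle: project a point set onto many directions and
# take the extreme widths. Independent of the convex-hull implementation.
feret_oracle <- function(points, n_angles = 3600) {
  angles <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  widths <- vapply(angles, function(a) {
    proj <- points[, 1] * cos(a) + points[, 2] * sin(a)
    max(proj) - min(proj)
  }, numeric(1))
  list(feret_max = max(widths), feret_min = min(widths))
}

# corner cloud of a pixel set, for feeding the caliper oracle
corner_points <- function(pixels) {
  x <- pixels[, 2]; y <- pixels[, 1]
  cbind(c(x - 0.5, x + 0.5, x + 0.5, x - 0.5),
        c(y - 0.5, y - 0.5, y + 0.5, y + 0.5))
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # genes 1..K carry the term
  mean(hits >= k)
}

# Hand step-up BH: q_(i) = min_{j >= i} p_(j) * m / j, input order restored.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  pmin(q_sorted, 1)[order(o)]
}

# small binary image with the given foreground pixel coordinates
image_from_pixels <- function(pixels, nrow, ncol, value = 255L) {
  img <- matrix(0L, nrow, ncol)
  img[pixels] <- value
  img
}

# standard planted-nexus fixture: one 50-gene module (6 queries inside)
# over a 1000-gene background, compendium-scale condition count
nexus_fixture <- function(seed, n_conditions = 155, latent_correlation = 0.9,
                          noise_sd = 0.3, n_background = 1000,
                          module_size = 50) {
  genes <- sprintf("nx_%02d", seq_len(module_size))
  mod <- module_spec("nexus", genes, latent_correlation, "GO:NEXUS")
  list(matrix = generate_expression_matrix(n_background + module_size,
                                           n_conditions, list(mod),
                                           noise_sd = noise_sd, seed = seed),
       module = mod,
       queries = genes[1:6],
       planted = genes[-(1:6)])
}
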