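# Shared fixtures: everything is built in code at test time.

# Spectrum made of Gaussian peaks on a uniform grid (+ optional offset/noise).
gaussian_spectrum <- function(centers, areas, sigma, mz = seq(900, 1100, 0.1),
                              offset = 0, noise_sd = 0, seed = NULL,
                              sample_id = "fix") {
  y <- rep(offset, length(mz))
  for (i in seq_along(centers))
    y <- y + areas[i] * stats::dnorm(mz, centers[i], sigma)
  if (noise_sd > 0)
    y <- y + pepclass:::with_seed(seed, stats::rnorm(length(mz), 0, noise_sd))
  mass_spectrum(mz, pmax(y, 0), sample_id)
}

# Tiny two-class area matrix: two well-separated Gaussian clusters.
separable_matrix <- function(n_per = 10, p = 4, sep = 100, sd = 1, seed = 1) {
  pepclass:::with_seed(seed, {
    x <- rbind(matrix(stats::rnorm(n_per * p, 0, sd), n_per),
               matrix(stats::rnorm(n_per * p, sep, sd), n_per))
    list(x = x, labels = rep(c("response", "progression"), each = n_per))
  })
}

# Brute-force morphological opening oracle: sliding min then sliding max.
opening_bruteforce <- function(x, width) {
  n <- length(x)
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  win <- function(v, i, pad) {
    idx <- (i - half_l):(i + half_r)
    c(v[idx[idx >= 1 & idx <= n]], rep(pad, sum(idx < 1 | idx > n)))
  }
  er <- vapply(seq_len(n), function(i) min(win(x, i, Inf)), 0)
  vapply(seq_len(n), function(i) max(win(er, i, -Inf)), 0)
}

# Exhaustive pair-counting AUC oracle.
auc_bruteforce <- function(x, group) {
  xp <- x[group == "progression"]; xr <- x[group == "response"]
  conc <- 0
  for (a in xp) for (b in xr) conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(xp) * length(xr))
}
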