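# Internal numeric helpers shared across the pipeline.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so generators are pure functions of
#' their configuration (including the seed) and never disturb the caller's
#' RNG stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Running minimum / maximum over a centred window of `width` points,
# van Herk style: O(n) via block prefix/suffix cumulative extremes.
# Edges are handled by padding with +Inf (min) / -Inf (max), which makes the
# morphological opening anti-extensive right up to the boundary.
running_extreme <- function(x, width, op = c("min", "max")) {
  op <- match.arg(op)
  n <- length(x)
  width <- as.integer(width)
  if (width <= 1L) return(x)
  if (width > n) stop("window wider than the signal")
  pad <- if (op == "min") Inf else -Inf
  half_l <- (width - 1L) %/% 2L
  half_r <- width - 1L - half_l
  xp <- c(rep(pad, half_l), x, rep(pad, half_r))
  np <- length(xp)
  nblocks <- ceiling(np / width)
  xp <- c(xp, rep(pad, nblocks * width - np))
  m <- matrix(xp, nrow = width)
  cumf <- if (op == "min") cummin else cummax
  pref <- apply(m, 2, cumf)
  suff <- apply(m[width:1, , drop = FALSE], 2, cumf)[width:1, , drop = FALSE]
  out <- numeric(np)
  # window [i, i + width - 1] on the padded signal spans at most two blocks
  idx <- seq_len(np - width + 1L)
  j_end <- idx + width - 1L
  comb <- if (op == "min") pmin else pmax
  out <- comb(suff[cbind((idx - 1L) %% width + 1L, (idx - 1L) %/% width + 1L)],
              pref[cbind((j_end - 1L) %% width + 1L, (j_end - 1L) %/% width + 1L)])
  out[seq_len(n)]
}

# Savitzky-Golay convolution weights for smoothing (0th derivative) by
# polynomial least squares on a symmetric window.
sgolay_coef <- function(window, polyorder) {
  stopifnot(window %% 2L == 1L, polyorder < window)
  half <- (window - 1L) %/% 2L
  z <- (-half):half
  A <- outer(z, 0:polyorder, `^`)
  # first row of (A'A)^-1 A' gives the smoothing weights
  (solve(crossprod(A), t(A)))[1L, ]
}

# Inverse-CDF draw from a normal truncated below at `lower` (vectorised over
# mean/sd). Keeps seeded determinism: consumes exactly length(mean) uniforms.
rtruncnorm_lower <- function(n, mean, sd, lower = 0) {
  plo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, plo, 1)
  stats::qnorm(u, mean, sd)
}

round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
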