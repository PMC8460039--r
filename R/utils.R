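# Small shared helpers.

#' Draw from a von Mises distribution
#'
#' Best–Fisher (1979) rejection sampler.  `kappa = Inf` returns the mean
#' direction exactly; `kappa = 0` is uniform on the circle.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration, `>= 0` (may be `Inf`).
#' @return angles in `(-pi, pi]`.
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  stopifnot(kappa >= 0)
  if (is.infinite(kappa)) return(rep(wrap_angle(mu), n))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- sign(u[3] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  wrap_angle(out + mu)
}

#' Wrap angles to (-pi, pi]
#' @keywords internal
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Centered rolling mean
#'
#' @param x numeric vector.
#' @param width window length in samples (forced odd by extending by 1).
#' @keywords internal
rolling_mean <- function(x, width) {
  width <- as.integer(width)
  if (width <= 1) return(x)
  if (width %% 2 == 0) width <- width + 1L
  half <- width %/% 2
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Derive a child seed from a parent seed and a stage label
#'
#' Keeps all stage-level randomness reproducible from one user seed while
#' decorrelating stages.  Result is kept below 2^31.
#' @keywords internal
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 2654435L + h * 97L) %% .Machine$integer.max
}

#' Geometric band centers
#' @keywords internal
geom_centers <- function(f_lo, f_hi, n) {
  exp(seq(log(f_lo), log(f_hi), length.out = n))
}

# internal: stratified fold assignment, seeded, balanced within class
stratified_folds <- function(labels, k, seed) {
  set.seed(child_seed(seed, "folds"))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}
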