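# Principal spectral components: eigen-decomposition of the
# between-frequency covariance of normalised log power spectra,
# cosine-similarity templates, and d-prime sensitivity with a
# permutation null.

#' Principal spectral component decomposition of a PSD ensemble
#'
#' Each trial PSD is divided elementwise by the ensemble mean at each
#' frequency and logged, centering the data around the log of the mean
#' spectrum; the between-frequency covariance of these normalised
#' log-spectra (the plain cross-product over trials, not divided by the
#' trial count: eigenvectors are scale invariant) is eigen-decomposed.
#' The eigenvectors are the principal spectral components (PSCs): sets of
#' frequencies whose power co-varies across trials.
#'
#' @param ens a `psd_ensemble` from [multitaper_trials()], or a plain
#'   matrix `P[freq, trial]` of strictly positive power values.
#' @return the ensemble with fields added: `Pbar` (normalised
#'   log-spectra), `C` (covariance), `lambda` (eigenvalues, descending),
#'   `psc` (unit-norm eigenvector matrix, one PSC per column) and
#'   `projections[k, trial]` (trial projections onto each PSC).
#' @export
psc_decompose <- function(ens) {
  P <- if (inherits(ens, "psd_ensemble")) ens$P else ens
  if (any(!is.finite(P)) || any(P <= 0))
    stop("power values must be finite and positive (log is taken)")
  mu <- rowMeans(P)
  Pbar <- log(P) - log(mu)
  C <- Pbar %*% t(Pbar)
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lambda <- e$values
  psc <- e$vectors
  proj <- t(psc) %*% Pbar
  out <- if (inherits(ens, "psd_ensemble")) ens else list(P = P)
  out$Pbar <- Pbar
  out$C <- C
  out$lambda <- lambda
  out$psc <- psc
  out$projections <- proj
  class(out) <- unique(c("psc_result", class(out)))
  out
}

#' @export
print.psc_result <- function(x, ...) {
  cat(sprintf("<psc_result> %d frequencies, %d trials; top eigenvalues: %s\n",
              nrow(x$P), ncol(x$P),
              paste(signif(utils::head(x$lambda, 3), 3), collapse = ", ")))
  invisible(x)
}

#' Cosine similarity between two vectors
#'
#' The inner product of the two unit-normalised vectors: 1 for the exact
#' same orientation, 0 for orthogonal vectors.  The sign of an
#' eigenvector is arbitrary, so comparisons of PSCs usually report the
#' absolute value.
#'
#' @param a,b non-zero numeric vectors of equal length.
#' @param absolute return `|cos|` (default `FALSE`).
#' @return scalar in `[-1, 1]` (or `[0, 1]`).
#' @export
cosine_similarity <- function(a, b, absolute = FALSE) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  v <- sum(a * b) / (na * nb)
  if (absolute) abs(v) else v
}

#' Cross-channel PSC template
#'
#' Aligns the signs of one PSC across channels (flipping each channel's
#' copy to agree with the first channel) and returns the unit-normalised
#' mean: the template against which per-channel PSCs are scored with
#' [cosine_similarity()].
#'
#' @param psc_list list of numeric vectors: the k-th PSC from each good
#'   channel.
#' @return unit-norm template vector.
#' @export
psc_template <- function(psc_list) {
  ref <- psc_list[[1]]
  aligned <- lapply(psc_list, function(v) if (sum(v * ref) < 0) -v else v)
  tmpl <- Reduce(`+`, aligned) / length(aligned)
  tmpl / sqrt(sum(tmpl^2))
}

#' d-prime sensitivity index
#'
#' `|mean_a - mean_b| / sqrt((var_a + var_b)/2)`.  A zero pooled
#' variance is guarded to a capped sentinel.
#'
#' @param a,b numeric samples for the two conditions.
#' @param cap sentinel returned when the pooled variance is zero but the
#'   means differ (default 1e6).
#' @return non-negative scalar.
#' @export
dprime <- function(a, b, cap = 1e6) {
  s <- sqrt((stats::var(a) + stats::var(b)) / 2)
  d <- abs(mean(a) - mean(b))
  if (s == 0) return(if (d == 0) 0 else cap)
  d / s
}

#' PSC sensitivity between behavioral states with a permutation null
#'
#' For each PSC (given its trial projections), computes d-prime between
#' the two condition labels and a permutation p-value: the fraction of
#' label shuffles whose d-prime meets or exceeds the observed one, with
#' the `(b + 1) / (m + 1)` correction.  BH correction is applied across
#' all rows.
#'
#' @param projections matrix `psc x trial` (or vector for a single PSC).
#' @param condition factor/character of length `n_trial` with two
#'   levels.
#' @param n_perm number of label shuffles (default 20000).
#' @param seed seed for the shuffles.
#' @param channel optional channel id recorded in the output table.
#' @return data.frame: psc, dprime, p, q, significant.
#' @export
psc_sensitivity <- function(projections, condition, n_perm = 20000,
                            seed = 1, channel = NA) {
  if (is.null(dim(projections))) projections <- matrix(projections, nrow = 1)
  condition <- as.factor(condition)
  stopifnot(nlevels(condition) == 2,
            length(condition) == ncol(projections))
  set.seed(child_seed(seed, "psc-perm"))
  ia <- condition == levels(condition)[1]
  K <- nrow(projections)
  n <- length(condition)
  perm_idx <- replicate(n_perm, sample.int(n))
  out <- data.frame(channel = channel, psc = seq_len(K), dprime = NA_real_,
                    p = NA_real_)
  for (k in seq_len(K)) {
    x <- projections[k, ]
    d0 <- dprime(x[ia], x[!ia])
    dperm <- apply(perm_idx, 2, function(ix) {
      pa <- ia[ix]
      dprime(x[pa], x[!pa])
    })
    out$dprime[k] <- d0
    out$p[k] <- (sum(dperm >= d0) + 1) / (n_perm + 1)
  }
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p < 0.05 & out$q < 0.05
  out
}
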