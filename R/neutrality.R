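#' Tajima's D
#'
#' D = (d - S/a1) / sqrt(e1 S + e2 S(S-1)) with the canonical constants
#' a1, a2, b1, b2, c1, c2, e1, e2 of the neutral-equilibrium variance.
#' Significance is assessed by coalescent simulation under neutrality at
#' theta = S/a1 (Watterson), with p the lower-tail proportion of
#' simulated D values <= the observed one ((b+1)/(B+1) convention) --
#' small p flags the negative departures expected under recent expansion.
#'
#' @param aln An `aln` with >= 4 sequences recommended.
#' @param n_null Number of neutral simulations for the p-value (default
#'   1000; 0 skips it).
#' @param seed Optional seed for the null simulations.
#' @return A list with `D`, `p` (lower tail, or `NULL`), `n`, `S`, `d`;
#'   `D` is `NA` (flagged undefined) when S = 0.
#' @export
tajimas_d <- function(aln, n_null = 1000, seed = NULL) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  S <- segregating_sites(aln)
  d <- mean_pairwise_differences(aln)
  if (S == 0)
    return(list(D = NA_real_, p = NULL, n = n, S = 0L, d = d,
                undefined = TRUE))
  D <- tajima_d_stat(n, S, d)
  p <- NULL
  if (n_null > 0) {
    theta_w <- S / harmonic(n - 1L)
    p <- with_seed(seed, {
      b <- 0L
      for (i in seq_len(n_null)) {
        st <- coalescent_sample_stats(n, theta = theta_w)
        if (st$S == 0) next
        if (tajima_d_stat(n, st$S, st$d) <= D + 1e-12) b <- b + 1L
      }
      (b + 1) / (n_null + 1)
    })
  }
  list(D = D, p = p, n = n, S = S, d = d, undefined = FALSE)
}

harmonic <- function(k) sum(1 / seq_len(k))

tajima_d_stat <- function(n, S, d) {
  a1 <- harmonic(n - 1L)
  a2 <- sum(1 / seq_len(n - 1L)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (d - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# log unsigned Stirling numbers of the first kind, rows 0..n
# (recurrence in log space so n in the hundreds stays finite)
log_stirling_first <- function(n) {
  ls <- matrix(-Inf, n + 1L, n + 1L)
  ls[1L, 1L] <- 0
  for (m in seq_len(n)) {
    for (k in seq_len(m)) {
      a <- ls[m, k]                      # |S(m-1, k-1)|
      b <- log(m - 1) + ls[m, k + 1L]    # (m-1) |S(m-1, k)|
      ls[m + 1L, k + 1L] <- if (a == -Inf) b else if (b == -Inf) a else
        max(a, b) + log1p(exp(-abs(a - b)))
    }
  }
  ls
}

# log P(K = k | theta, n) under the Ewens sampling distribution
log_ewens_k <- function(n, theta, ls = log_stirling_first(n)) {
  k <- seq_len(n)
  log_rising <- sum(log(theta + 0:(n - 1L)))
  ls[n + 1L, k + 1L] + k * log(theta) - log_rising
}

#' Fu's Fs
#'
#' Fs = ln(S' / (1 - S')) where S' is the probability of observing at
#' least the sampled number of haplotypes under the Ewens sampling
#' distribution with theta set to the mean pairwise difference d.  The
#' Ewens probabilities use unsigned Stirling numbers of the first kind
#' over the rising factorial, evaluated in log space so samples of
#' several hundred sequences stay numerically exact.  Significance is
#' assessed by neutral coalescent simulation at theta = d, p being the
#' proportion of simulated Fs <= the observed value (Fu's convention: the
#' test is significant at the 5% level when p < 0.02).
#'
#' @param aln An `aln` with >= 2 sequences.
#' @param n_null Number of neutral simulations for the p-value (default
#'   1000; 0 skips it).
#' @param seed Optional seed.
#' @return A list with `Fs`, `p` (or `NULL`), `n`, `k` (haplotype count),
#'   `theta` (= d); `Fs` is `NA`-flagged when d = 0, and `+/-Inf`-flagged
#'   when S' underflows to 0 or 1.
#' @export
fus_fs <- function(aln, n_null = 1000, seed = NULL) {
  n <- nrow(aln)
  if (n < 2L) stop("need at least 2 sequences")
  d <- mean_pairwise_differences(aln)
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  k_obs <- length(unique(seqs))
  if (d == 0)
    return(list(Fs = NA_real_, p = NULL, n = n, k = k_obs, theta = d,
                undefined = TRUE))
  ls <- log_stirling_first(n)
  Fs <- fu_fs_stat(n, k_obs, d, ls)
  p <- NULL
  if (n_null > 0 && is.finite(Fs)) {
    p <- with_seed(seed, {
      b <- 0L
      for (i in seq_len(n_null)) {
        st <- coalescent_sample_stats(n, theta = d)
        if (st$d == 0) next
        fs_i <- fu_fs_stat(n, st$k, st$d, ls)
        if (is.finite(fs_i) && fs_i <= Fs + 1e-12) b <- b + 1L
      }
      (b + 1) / (n_null + 1)
    })
  }
  list(Fs = Fs, p = p, n = n, k = k_obs, theta = d, undefined = FALSE)
}

fu_fs_stat <- function(n, k_obs, theta, ls = log_stirling_first(n)) {
  lp <- log_ewens_k(n, theta, ls)
  log_sp <- logsumexp(lp[k_obs:n])             # log P(K >= k_obs)
  if (log_sp >= 0) return(Inf)                 # S' numerically 1
  log_1msp <- log1p(-exp(log_sp))              # log(1 - S')
  if (!is.finite(log_1msp)) return(Inf)
  log_sp - log_1msp
}
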