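#' Observed mismatch distribution
#'
#' Histogram of the number of differing sites over all unordered sequence
#' pairs.  Element `i + 1` of the returned vector is the number of pairs
#' at `i` differences; the total is n(n-1)/2.
#'
#' @param aln An `aln` with >= 2 sequences.
#' @return Integer vector of pair counts indexed from 0 differences.
#' @export
mismatch_observed <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  d <- pairwise_diff_matrix(aln)
  v <- d[upper.tri(d)]
  tabulate(v + 1L, nbins = max(v) + 1L)
}

# equilibrium probability of i differences between two lineages at scaled
# population size theta
geom_equilibrium <- function(i, theta) {
  if (theta == 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under the sudden-expansion model
#'
#' Probability of observing i pairwise differences when a population at
#' scaled size theta0 expanded instantaneously to theta1 a time tau (in
#' mutational units, tau = 2ut) ago:
#' \deqn{F_i = \hat F_i(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{j=0}^{i} \frac{\tau^j}{j!}
#'   [\hat F_{i-j}(\theta_0) - \hat F_{i-j}(\theta_1)]}
#' with the equilibrium law \eqn{\hat F_i(\theta) = \theta^i /
#' (1+\theta)^{i+1}}.  At tau = 0 this is the equilibrium geometric form;
#' at theta0 = 0 with theta1 large it approaches Poisson(tau).
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param theta0 Pre-expansion scaled size (>= 0).
#' @param theta1 Post-expansion scaled size (>= 0).
#' @param support_max Largest difference count evaluated.
#' @param fold_tail If `TRUE` (default) the probability mass beyond
#'   `support_max` is folded into the last bin so the vector sums to 1;
#'   otherwise raw probabilities are returned.
#' @return Numeric vector of probabilities for 0..`support_max`
#'   differences.
#' @export
mismatch_expected <- function(tau, theta0, theta1, support_max,
                              fold_tail = TRUE) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0, support_max >= 0)
  i <- 0:support_max
  f1 <- geom_equilibrium(i, theta1)
  f0 <- geom_equilibrium(i, theta0)
  ex <- if (tau == 0) 1 else if (theta1 == 0) 0 else
    exp(-tau * (theta1 + 1) / theta1)
  # Poisson weights tau^j / j!
  pw <- if (tau == 0) c(1, rep(0, support_max)) else
    exp(i * log(tau) - lfactorial(i))
  # conv[k] = sum_j pw[j] (f0 - f1)[k - j]
  dd <- f0 - f1
  conv <- if (support_max == 0) pw[1] * dd else
    stats::convolve(pw, rev(dd), type = "open")[seq_along(i)]
  p <- f1 + ex * conv
  p <- pmax(p, 0)
  if (fold_tail) p[length(p)] <- p[length(p)] + max(0, 1 - sum(p))
  p
}

# SSD between observed relative frequencies and raw model probabilities,
# evaluated on the observed support trimmed of trailing zeros (so padding
# the histogram with zeros never changes the value)
mismatch_ssd <- function(obs_counts, tau, theta0, theta1) {
  k <- max(which(obs_counts > 0))
  o <- obs_counts[1:k] / sum(obs_counts)
  e <- mismatch_expected(tau, theta0, theta1, k - 1L, fold_tail = FALSE)
  sum((o - e)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares estimation of (tau, theta0, theta1): the sum of squared
#' deviations (SSD) between the observed relative mismatch frequencies
#' and the model's expected probabilities is minimised by bounded
#' Nelder-Mead search from multiple scattered start points.  Bounds are
#' tau in \[0, 4 max_diff\] and theta in \[0, 10 d\] where d is the mean
#' observed difference count.
#'
#' @param observed Mismatch histogram (counts indexed from 0 differences,
#'   as from [mismatch_observed()]).
#' @param n Sample size behind the histogram (stored for resampling).
#' @param restarts Number of scattered restarts (default 20).
#' @param seed Optional seed for the restart points.
#' @param start Optional list of additional start points
#'   `c(tau, theta0, theta1)` (tried first).
#' @param maxit,reltol Nelder-Mead iteration cap and relative
#'   convergence tolerance.
#' @return A `mismatch_fit`: list with `tau`, `theta0`, `theta1`, `ssd`,
#'   `observed`, `observed_freq`, `expected` (folded, on the observed
#'   support), `n`, and `converged`.
#' @export
fit_sudden_expansion <- function(observed, n = NULL, restarts = 20,
                                 seed = NULL, start = NULL,
                                 maxit = 1000, reltol = 1e-10) {
  if (!length(observed) || sum(observed) == 0)
    stop("empty mismatch histogram")
  tot <- sum(observed)
  diffs <- seq_along(observed) - 1L
  dbar <- sum(diffs * observed) / tot
  max_diff <- max(diffs[observed > 0])
  lo <- c(0, 0, 0)
  hi <- c(max(4 * max_diff, 1), max(10 * dbar, 1), max(10 * dbar, 1))
  clamp <- function(p) pmin(pmax(p, lo), hi)
  obj <- function(p) {
    p <- clamp(p)
    mismatch_ssd(observed, p[1], p[2], p[3])
  }
  starts <- list(c(dbar, 0.01, max(10 * dbar, 1) / 2),
                 c(max_diff / 2, dbar / 10, 5 * dbar),
                 c(0, dbar, dbar))
  if (!is.null(start)) starts <- c(start, starts)
  if (length(starts) > max(restarts, 1))
    starts <- starts[seq_len(max(restarts, 1))]
  rand <- with_seed(seed, replicate(max(restarts - length(starts), 0),
                                    stats::runif(3, lo, hi),
                                    simplify = FALSE))
  starts <- c(starts, rand)
  best <- NULL
  converged <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(clamp(s), obj, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) {
      best <- fit
      converged <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("sudden-expansion fit failed from every start")
  p <- clamp(best$par)
  k <- max(which(observed > 0))
  structure(list(
    tau = p[1], theta0 = p[2], theta1 = p[3], ssd = best$value,
    observed = observed, observed_freq = observed / tot,
    expected = mismatch_expected(p[1], p[2], p[3], k - 1L),
    n = n, converged = converged), class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "Sudden-expansion fit: tau = %.3f, theta0 = %.3f, theta1 = %.3f, SSD = %.5f\n",
    x$tau, x$theta0, x$theta1, x$ssd))
  if (!is.null(x$tau_ci))
    cat(sprintf("tau 95%% CI: %.3f-%.3f\n", x$tau_ci[1], x$tau_ci[2]))
  if (!is.null(x$ssd_p)) cat(sprintf("SSD p = %.4f\n", x$ssd_p))
  invisible(x)
}

# simulate one coalescent sample under the fitted expansion model and
# refit; returns c(tau, ssd)
boot_replicate <- function(n, tau, theta0, theta1, restarts) {
  st <- coalescent_sample_stats(n, theta = theta1,
                                expansion = if (tau > 0 || theta0 != theta1)
                                  list(tau = tau, theta0 = theta0) else NULL)
  h <- st$mismatch
  if (sum(h) == 0 || all(h[-1] == 0)) {
    # monomorphic sample: the model degenerates to tau = 0
    return(c(tau = 0, ssd = 0))
  }
  # refits warm-start at the generating parameters; lighter optimiser
  # effort suffices for resampling quantiles
  f <- fit_sudden_expansion(h, n = n, restarts = restarts,
                            start = list(c(tau, theta0, theta1)),
                            maxit = 400, reltol = 1e-8)
  c(tau = f$tau, ssd = f$ssd)
}

parametric_bootstrap <- function(fit, n = NULL, B = 1000, seed = NULL,
                                 restarts = 5) {
  n <- n %||% fit$n
  if (is.null(n)) stop("sample size n required for parametric resampling")
  with_seed(seed, {
    out <- vapply(seq_len(B), function(b)
      boot_replicate(n, fit$tau, fit$theta0, fit$theta1, restarts),
      numeric(2))
    data.frame(tau = out[1, ], ssd = out[2, ])
  })
}

#' Goodness-of-fit p-value for the sudden-expansion model
#'
#' Parametric Monte-Carlo test: B coalescent samples of size n are
#' simulated under the fitted model, each is refitted, and the p-value is
#' the proportion of simulated SSD values at least as large as the
#' observed one, with the (b+1)/(B+1) convention.
#'
#' @param fit A `mismatch_fit`.
#' @param n Sample size (defaults to the size stored in the fit).
#' @param B Number of simulated samples (default 10000).
#' @param seed Optional seed.
#' @param restarts Restarts per refit (default 5; each refit also warm
#'   starts from the observed fit).
#' @return p-value in (0, 1].
#' @export
ssd_pvalue <- function(fit, n = NULL, B = 10000, seed = NULL, restarts = 5) {
  stopifnot(B >= 1)
  bs <- parametric_bootstrap(fit, n, B, seed, restarts)
  (sum(bs$ssd >= fit$ssd - 1e-15) + 1) / (B + 1)
}

#' Parametric bootstrap confidence interval for tau
#'
#' Percentile interval of the refitted expansion time across B coalescent
#' samples simulated under the fitted model.
#'
#' @inheritParams ssd_pvalue
#' @param level Confidence level (default 0.95).
#' @return Numeric vector `c(low, high)`.
#' @export
tau_confidence_interval <- function(fit, n = NULL, B = 10000, level = 0.95,
                                    seed = NULL, restarts = 5) {
  stopifnot(B >= 1, level > 0, level < 1)
  bs <- parametric_bootstrap(fit, n, B, seed, restarts)
  a <- (1 - level) / 2
  ci <- unname(stats::quantile(bs$tau, c(a, 1 - a), type = 7))
  if (fit$tau < ci[1] || fit$tau > ci[2])
    attr(ci, "recentring_flag") <- TRUE
  ci
}

#' Time since expansion from tau
#'
#' Converts the mutational-units expansion time tau to generations and
#' years via t = tau / (2u), where u is the mutation rate of the whole
#' fragment per generation, u = mu * s.  The per-nucleotide rate mu is
#' derived from an interspecific divergence rate quoted in percent per
#' site per million years: mu = rate/100/1e6 * generation_time, halved
#' first when `halve_rate = TRUE` (divergence accumulates along two
#' lineages; both conventions are supported and flagged in the result).
#'
#' @param tau Expansion time in mutational units (>= 0).
#' @param tau_ci Optional `c(low, high)` CI for tau, transformed
#'   identically.
#' @param s Fragment length in sites.
#' @param generation_time Generation time in years (default 2).
#' @param divergence_rate Divergence rate in % per site per Myr (default
#'   0.52).
#' @param halve_rate Halve the divergence rate to a per-lineage mutation
#'   rate (default `FALSE`).
#' @return An `expansion_dating` list with `t_generations`, `t_years`,
#'   `ci_years`, `u`, `mu`, and the settings used.
#' @export
time_since_expansion <- function(tau, tau_ci = NULL, s,
                                 generation_time = 2,
                                 divergence_rate = 0.52,
                                 halve_rate = FALSE) {
  stopifnot(tau >= 0, s > 0, divergence_rate > 0, generation_time > 0)
  rate_site_year <- divergence_rate / 100 / 1e6
  if (halve_rate) rate_site_year <- rate_site_year / 2
  mu <- rate_site_year * generation_time
  u <- mu * s
  t_gen <- tau / (2 * u)
  out <- list(t_generations = t_gen,
              t_years = t_gen * generation_time,
              ci_years = if (!is.null(tau_ci))
                tau_ci / (2 * u) * generation_time,
              u = u, mu = mu, s = s,
              generation_time = generation_time,
              divergence_rate = divergence_rate,
              halve_rate = halve_rate)
  class(out) <- "expansion_dating"
  out
}

#' @export
print.expansion_dating <- function(x, ...) {
  cat(sprintf("Time since expansion: %.0f generations = %.3f Myr\n",
              x$t_generations, x$t_years / 1e6))
  if (!is.null(x$ci_years))
    cat(sprintf("95%% CI: %.3f-%.3f Myr\n", x$ci_years[1] / 1e6,
                x$ci_years[2] / 1e6))
  cat(sprintf("u = %.4g per fragment per generation (%s divergence rate)\n",
              x$u, if (x$halve_rate) "halved" else "un-halved"))
  invisible(x)
}
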