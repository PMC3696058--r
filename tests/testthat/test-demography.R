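test_that("observed mismatch histograms match brute force", {
  a <- mk_aln(rep("ACGTACGT", 3))
  expect_equal(mismatch_observed(a), 3L)   # all 3 pairs at zero differences

  b <- mk_aln(c("AAAA", "AAAT", "AATT", "ATTT"))
  h <- mismatch_observed(b)
  expect_equal(sum(h), choose(4, 2))
  expect_equal(h, c(0L, 3L, 2L, 1L))

  for (seed in 1:3) {
    r <- related_aln(7, 60, seed, mut = 0.1)
    m <- unclass(r)
    diffs <- c()
    for (i in 1:6) for (j in (i + 1):7) diffs <- c(diffs, sum(m[i, ] != m[j, ]))
    expect_equal(mismatch_observed(r),
                 tabulate(diffs + 1L, nbins = max(diffs) + 1L))
  }
})

test_that("expected mismatch law hits its equilibrium and Poisson limits", {
  # tau = 0: geometric equilibrium form theta^i / (1+theta)^(i+1)
  th <- 3
  e <- mismatch_expected(0, th, 7, 25, fold_tail = FALSE)
  expect_equal(e, th^(0:25) / (1 + th)^(1:26), tolerance = 1e-9)

  # theta0 = 0, theta1 -> infinity: Poisson(tau)
  p <- mismatch_expected(3, 0, 1e9, 30, fold_tail = FALSE)
  expect_equal(p, dpois(0:30, 3), tolerance = 1e-3)

  # normalisation over wide support
  for (pars in list(c(4, 1, 50), c(0.5, 0.2, 2), c(10, 0, 30))) {
    s <- sum(mismatch_expected(pars[1], pars[2], pars[3],
                               ceiling(10 * (pars[1] + pars[3])),
                               fold_tail = FALSE))
    expect_equal(s, 1, tolerance = 1e-6)
    expect_equal(sum(mismatch_expected(pars[1], pars[2], pars[3], 15)), 1,
                 tolerance = 1e-12)
  }
})

test_that("SSD is invariant to zero padding and zero at self-consistency", {
  obs <- c(1, 4, 8, 6, 3, 1)
  f1 <- fit_sudden_expansion(obs, n = 8, restarts = 10, seed = 1)
  f2 <- fit_sudden_expansion(c(obs, 0, 0, 0), n = 8, restarts = 10, seed = 1)
  expect_equal(f1$ssd, f2$ssd, tolerance = 1e-9)
  expect_equal(f1$tau, f2$tau, tolerance = 1e-6)

  # histogram exactly equal to a model curve: SSD ~ 0 at the generator
  probs <- mismatch_expected(4, 0.5, 20, 40, fold_tail = FALSE)
  fit <- fit_sudden_expansion(probs * 1e4, n = 50, restarts = 25, seed = 2)
  expect_lt(fit$ssd, 1e-7)
})

test_that("SSD p-value and tau CI behave at the boundaries", {
  fit <- structure(list(tau = 3, theta0 = 0.2, theta1 = 15, ssd = 0,
                        n = 20), class = "mismatch_fit")
  expect_equal(ssd_pvalue(fit, B = 30, seed = 3), 1)

  set.seed(4)
  st <- haplostruct:::coalescent_sample_stats(40, 15,
                                              expansion = list(tau = 5,
                                                               theta0 = 0.3))
  f <- fit_sudden_expansion(st$mismatch, n = 40, seed = 5)
  ci <- tau_confidence_interval(f, B = 60, seed = 6)
  expect_lte(ci[1], ci[2])
  expect_gte(ci[1], 0)
})

test_that("expansion dating follows t = tau / 2u with u = mu * s", {
  expect_equal(time_since_expansion(0, s = 338)$t_years, 0)

  # tau = 5, s = 338, 0.52%/Myr un-halved, 2-year generations
  d <- time_since_expansion(5, s = 338)
  expect_equal(d$u, 0.52 / 100 / 1e6 * 2 * 338, tolerance = 1e-12)
  expect_equal(d$u, 3.5152e-6, tolerance = 1e-6)
  expect_equal(d$t_generations, 5 / (2 * 3.5152e-6), tolerance = 1e-6)
  expect_equal(d$t_years / 1e6, 1.4224, tolerance = 1e-4)

  # doubling s halves t; halving the rate doubles t
  expect_equal(time_since_expansion(5, s = 676)$t_years, d$t_years / 2)
  expect_equal(time_since_expansion(5, s = 338, halve_rate = TRUE)$t_years,
               d$t_years * 2)

  # CI endpoints transform identically
  d2 <- time_since_expansion(5, tau_ci = c(2, 8), s = 338)
  expect_equal(d2$ci_years / d2$t_years, c(2, 8) / 5, tolerance = 1e-12)
})

test_that("expansion simulations give unimodal, equilibrium gives flat fits", {
  set.seed(11)
  # strong recent expansion: fitted tau positive, SSD small
  st <- haplostruct:::coalescent_sample_stats(60, 20,
                                              expansion = list(tau = 6,
                                                               theta0 = 0.2))
  f <- fit_sudden_expansion(st$mismatch, n = 60, seed = 7)
  expect_gt(f$tau, 0.5)
  expect_lt(f$ssd, 0.05)
})
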