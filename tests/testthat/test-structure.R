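two_pop_fixed <- function() {
  # two populations fixed for different haplotypes
  a <- mk_aln(c(rep("AAAAAAAAAA", 5), rep("AAAAATTTTT", 5)))
  pm <- mk_pm(rownames(a), rep(c("P1", "P2"), each = 5))
  list(aln = a, pm = pm,
       d = pairwise_distance_matrix(a, subst_model_config("p")))
}

test_that("fixation indices follow the variance-component identities", {
  idx <- phi_indices(0.5, 0.3, 1.2)
  tot <- 2.0
  expect_equal(unname(idx["phi_CT"]), 0.5 / tot)
  expect_equal(unname(idx["phi_SC"]), 0.3 / 1.5)
  expect_equal(unname(idx["phi_ST"]), 0.8 / tot)
  expect_equal((1 - idx[["phi_ST"]]),
               (1 - idx[["phi_CT"]]) * (1 - idx[["phi_SC"]]), tolerance = 1e-12)
})

test_that("fixed different haplotypes give Phi_ST = 1, identical give ~0", {
  fx <- two_pop_fixed()
  am <- amova(fx$d, fx$pm, n_perm = 99, seed = 1)
  expect_equal(unname(am$indices["phi_ST"]), 1)
  expect_lt(am$p_values[["phi_ST"]], 0.05)
  expect_equal(sum(am$table$df[1:2]), nrow(fx$aln) - 1L)
  expect_equal(sum(am$table$SSD[1:2]), am$table$SSD[3], tolerance = 1e-9)
  expect_equal(am$table$percent[3], 100, tolerance = 1e-9)

  pp <- pairwise_phi_st(fx$d, fx$pm, n_perm = 99, seed = 2)
  expect_equal(pp$phi_st["P1", "P2"], 1)
  # two-population amova equals the pairwise entry exactly
  expect_equal(unname(am$indices["phi_ST"]), pp$phi_st["P1", "P2"])
})

test_that("three-level AMOVA satisfies the index identity and df/SSD sums", {
  set.seed(5)
  ds <- simulate_coalescent(sim_config(demes = 4, sample_sizes = 6,
                                       theta = 4, migration = 1,
                                       sequence_length = 300))
  d <- pairwise_distance_matrix(ds$aln, subst_model_config("p"))
  sch <- grouping_scheme("ab_cd", c(D1 = "G1", D2 = "G1",
                                    D3 = "G2", D4 = "G2"))
  am <- amova(d, ds$pm, sch, n_perm = 50, seed = 3)
  i <- am$indices
  expect_equal(1 - i[["phi_ST"]],
               (1 - i[["phi_CT"]]) * (1 - i[["phi_SC"]]), tolerance = 1e-9)
  expect_equal(sum(am$table$df[1:3]), nrow(ds$aln) - 1L)
  expect_equal(sum(am$table$SSD[1:3]), am$table$SSD[4], tolerance = 1e-9)
  expect_equal(am$table$percent[4], 100, tolerance = 1e-6)
  # two-level phi_ST from an independent transcription of the formulas
  d2 <- unclass(d)
  pop <- ds$pm$locality[match(rownames(d), ds$pm$individual)]
  am2 <- amova(d, ds$pm, n_perm = 0)
  expect_equal(unname(am2$indices["phi_ST"]), oracle_phi_st(d2, pop),
               tolerance = 1e-12)
})

test_that("random splits of one panmictic deme give Phi_CT near zero", {
  set.seed(7)
  ds <- simulate_coalescent(sim_config(demes = 1, sample_sizes = 24,
                                       theta = 5, sequence_length = 400))
  # assign individuals arbitrarily to 4 pseudo-populations in 2 groups
  pm <- mk_pm(rownames(ds$aln), rep(c("A", "B", "C", "D"), each = 6))
  d <- pairwise_distance_matrix(ds$aln, subst_model_config("p"))
  sch <- grouping_scheme("null", c(A = "G1", B = "G1", C = "G2", D = "G2"))
  phis <- replicate(20, {
    perm <- sample(nrow(ds$aln))
    pmx <- mk_pm(rownames(ds$aln)[perm], rep(c("A", "B", "C", "D"), each = 6))
    amova(d, pmx, sch, n_perm = 0)$indices[["phi_CT"]]
  })
  expect_lt(abs(mean(phis)), 0.05)
})

test_that("permutation p-values respect the (b+1)/(B+1) convention bounds", {
  fx <- two_pop_fixed()
  pop <- factor(rep(c("P1", "P2"), each = 5))
  # observed Phi_ST = 1 beats every permutation: minimal p
  out <- permutation_test(fx$d, pop, n_perm = 199, seed = 4)
  expect_equal(out$statistic, 1)
  expect_lt(out$p, 0.05)
  expect_gte(out$p, 1 / 200)
})

test_that("exact permutation enumeration matches a brute-force oracle", {
  set.seed(9)
  a <- related_aln(6, 60, seed = 13, mut = 0.15)
  pm <- mk_pm(rownames(a), rep(c("P1", "P2", "P3"), each = 2))
  d <- pairwise_distance_matrix(a, subst_model_config("p"))
  pop <- factor(rep(c("P1", "P2", "P3"), each = 2))
  out <- permutation_test(d, pop, exact = TRUE)
  expect_true(out$exact)
  expect_equal(out$n_perm, factorial(6) / 8)  # 6!/(2!2!2!) arrangements
  # independent enumeration: all permutations of the 6 individuals
  d2 <- unclass(d)
  all_perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  all_perms <- all_perms[apply(all_perms, 1, function(x)
    length(unique(x)) == 6), ]
  stats <- apply(all_perms, 1, function(ix)
    oracle_phi_st(d2, as.character(pop)[order(ix)]))
  # label arrangements repeat across permutations; tail proportion is
  # unchanged by the repetition factor
  obs <- oracle_phi_st(d2, as.character(pop))
  oracle_p <- mean(stats >= obs - 1e-12)
  expect_equal(out$p, oracle_p, tolerance = 1e-12)
})

test_that("BH-FDR matches the brute-force step-up rule", {
  expect_equal(bh_fdr(0.03)$p_adjusted, 0.03)
  r <- bh_fdr(c(0.01, 0.02, 0.04), q = 0.05)
  expect_true(all(r$rejected))

  brute_force_bh <- function(p, q) {
    m <- length(p)
    ord <- order(p)
    ps <- p[ord]
    k <- suppressWarnings(max(which(ps <= q * seq_len(m) / m)))
    rej <- rep(FALSE, m)
    if (is.finite(k)) rej[ord[seq_len(k)]] <- TRUE
    adj <- rev(cummin(rev(ps * m / seq_len(m))))
    adj <- pmin(adj, 1)
    list(adj = adj[order(ord)], rej = rej)
  }
  set.seed(21)
  for (i in 1:20) {
    p <- round(runif(sample(1:10, 1))^2, 4)
    got <- bh_fdr(p, q = 0.05)
    want <- brute_force_bh(p, q = 0.05)
    expect_equal(got$p_adjusted, want$adj, tolerance = 1e-12)
    expect_equal(got$rejected, want$rej)
  }
  expect_equal(bh_fdr(numeric())$p_adjusted, numeric())
  expect_error(bh_fdr(c(0.2, 1.4)), "0, 1")
})

test_that("permutation p distributions are seed-stable on a null design", {
  set.seed(31)
  ds <- simulate_coalescent(sim_config(demes = 1, sample_sizes = 12,
                                       theta = 4, sequence_length = 300))
  d <- pairwise_distance_matrix(ds$aln, subst_model_config("p"))
  pop <- factor(rep(c("A", "B"), each = 6))
  p1 <- permutation_test(d, pop, n_perm = 300, seed = 11)$p
  p2 <- permutation_test(d, pop, n_perm = 300, seed = 11)$p
  p3 <- permutation_test(d, pop, n_perm = 300, seed = 12)$p
  expect_identical(p1, p2)           # same seed, same p
  expect_lt(abs(p1 - p3), 0.25)      # different seed, same distribution
})
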