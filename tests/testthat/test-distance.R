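aln_to_dnabin <- function(aln) {
  ape::as.DNAbin(tolower(unclass(aln)))
}

test_that("TN93 distance basics", {
  cfg <- subst_model_config("TN93")
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT", cfg), 0)
  # p-distance: 1 difference in 338 sites
  x <- paste(rep("A", 338), collapse = "")
  y <- paste(c(rep("A", 337), "C"), collapse = "")
  expect_equal(tn93_distance(x, y, subst_model_config("p")), 1 / 338)
  expect_error(tn93_distance("ACG", "ACGT", cfg), "length mismatch")
  # very large gamma shape converges to the no-gamma distance
  f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  a <- related_aln(2, 400, seed = 8, mut = 0.06)
  s <- unclass(a)
  d0 <- tn93_distance(s[1, ], s[2, ], subst_model_config("TN93",
                                                         base_freqs = f))
  dg <- tn93_distance(s[1, ], s[2, ],
                      subst_model_config("TN93", gamma_shape = 1e6,
                                         base_freqs = f))
  expect_equal(dg, d0, tolerance = 1e-6)
})

test_that("TN93 agrees with the ape reference implementation", {
  for (seed in 1:4) {
    a <- related_aln(6, 500, seed, mut = 0.05)
    d_ours <- pairwise_distance_matrix(a, subst_model_config("TN93"))
    d_ape <- as.matrix(ape::dist.dna(aln_to_dnabin(a), model = "TN93"))
    expect_equal(unclass(d_ours)[, ], d_ape[rownames(d_ours), colnames(d_ours)],
                 tolerance = 1e-9, ignore_attr = TRUE)
    dg_ours <- pairwise_distance_matrix(
      a, subst_model_config("TN93", gamma_shape = 0.5))
    dg_ape <- as.matrix(ape::dist.dna(aln_to_dnabin(a), model = "TN93",
                                      gamma = 0.5))
    expect_equal(unclass(dg_ours)[, ], dg_ape[rownames(dg_ours),
                                              colnames(dg_ours)],
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("TN93 correction inflates and gamma deflates with larger alpha", {
  for (seed in 5:8) {
    a <- related_aln(4, 300, seed, mut = 0.08)
    m <- unclass(a)
    f <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
    p_cfg <- subst_model_config("p")
    for (i in 1:3) for (j in (i + 1):4) {
      dp <- tn93_distance(m[i, ], m[j, ], p_cfg)
      dt <- tn93_distance(m[i, ], m[j, ],
                          subst_model_config("TN93", base_freqs = f))
      if (is.finite(dt)) {
        expect_gte(dt, dp - 1e-12)
        # non-increasing in alpha
        alphas <- c(0.2, 0.5, 1, 5, 100)
        dg <- vapply(alphas, function(al)
          tn93_distance(m[i, ], m[j, ],
                        subst_model_config("TN93", gamma_shape = al,
                                           base_freqs = f)), numeric(1))
        expect_true(all(diff(dg) <= 1e-12))
      }
    }
  }
})

test_that("distance matrices are symmetric, labelled, and saturation-safe", {
  a <- mk_aln(rep("ACGTACGT", 3))
  d <- pairwise_distance_matrix(a, subst_model_config("p"))
  expect_true(all(d == 0))
  expect_equal(rownames(d), rownames(a))

  r <- related_aln(6, 200, seed = 11, mut = 0.1)
  d2 <- pairwise_distance_matrix(r, subst_model_config("p"))
  expect_equal(unclass(d2)[, ], t(unclass(d2))[, ])
  # elementwise re-computation
  m <- unclass(r)
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(d2[i, j], sum(m[i, ] != m[j, ]) / 200)

  # label permutation follows input order
  perm <- c(3, 1, 2, 6, 5, 4)
  rp <- mk_aln(seq_strings(r)[perm], ids = rownames(r)[perm])
  dp <- pairwise_distance_matrix(rp, subst_model_config("p"))
  expect_equal(unclass(dp)[, ], unclass(d2)[perm, perm])

  # saturated pairs: two maximally divergent sequences
  sat <- mk_aln(c(paste(rep("AC", 50), collapse = ""),
                  paste(rep("CA", 50), collapse = "")))
  expect_error(pairwise_distance_matrix(sat, subst_model_config("TN93")),
               "saturated")
  dfall <- pairwise_distance_matrix(sat, subst_model_config("TN93"),
                                    on_saturation = "p_fallback")
  expect_equal(dfall[1, 2], 1)
})
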