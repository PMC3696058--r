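# Shared fixture builders and independent oracles for the test suite.

mk_aln <- function(seqs, ids = paste0("i", seq_along(seqs))) {
  as_aln(stats::setNames(seqs, ids))
}

mk_pm <- function(ids, localities) {
  as_popmap(data.frame(individual = ids, locality = localities,
                       stringsAsFactors = FALSE))
}

mk_ht <- function(seqs, localities = rep("L1", length(seqs))) {
  a <- mk_aln(seqs)
  collapse_haplotypes(a, mk_pm(rownames(a), localities))
}

random_aln <- function(n, L, seed, bases = c("A", "C", "G", "T")) {
  set.seed(seed)
  mk_aln(replicate(n, paste(sample(bases, L, replace = TRUE), collapse = "")))
}

# alignment of sequences derived from one root by sprinkling mutations,
# so pairwise distances stay in the estimable range
related_aln <- function(n, L, seed, mut = 0.04,
                        bases = c("A", "C", "G", "T")) {
  set.seed(seed)
  root <- sample(bases, L, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    s <- root
    k <- stats::rbinom(1, L, mut)
    if (k > 0) {
      sites <- sample(L, k)
      s[sites] <- vapply(s[sites], function(b)
        sample(setdiff(bases, b), 1), character(1))
    }
    paste(s, collapse = "")
  }, character(1))
  mk_aln(seqs)
}

# brute-force nucleotide diversity: O(n^2 L) double loop
oracle_pi <- function(aln) {
  m <- unclass(aln)
  n <- nrow(m)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(m[i, ] != m[j, ]) / ncol(m)
  tot / choose(n, 2)
}

# direct transcription of the two-level AMOVA Phi_ST (independent of the
# package's amova_components)
oracle_phi_st <- function(d2, pop) {
  pop <- as.character(pop)
  N <- length(pop)
  pops <- unique(pop)
  P <- length(pops)
  ssd_tot <- sum(d2) / (2 * N)
  ssd_wp <- 0
  for (p in pops) {
    idx <- which(pop == p)
    ssd_wp <- ssd_wp + sum(d2[idx, idx]) / (2 * length(idx))
  }
  ssd_ap <- ssd_tot - ssd_wp
  n_p <- as.numeric(table(pop))
  nc <- (N - sum(n_p^2) / N) / (P - 1)
  s_c <- ssd_wp / (N - P)
  s_b <- (ssd_ap / (P - 1) - s_c) / nc
  s_b / (s_b + s_c)
}

# direct transcription of Tajima's D from the textbook constants
oracle_tajima_d <- function(n, S, d) {
  a1 <- sum(1 / (1:(n - 1)))
  a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (d - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact Ewens haplotype-number distribution for small n: unsigned
# Stirling numbers of the first kind by integer recurrence (exact in
# doubles for n <= 8), P(K = k) = |S(n,k)| theta^k / theta^(n rising)
oracle_ewens_sprime <- function(n, k_obs, theta) {
  st <- matrix(0, n + 1, n + 1)
  st[1, 1] <- 1
  for (m in 1:n) for (k in 1:m)
    st[m + 1, k + 1] <- st[m, k] + (m - 1) * st[m, k + 1]
  rising <- prod(theta + 0:(n - 1))
  pk <- st[n + 1, 2:(n + 1)] * theta^(1:n) / rising
  sum(pk[k_obs:n])
}

# adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  nc2 <- choose(sum(tab), 2)
  expected <- sum_a * sum_b / nc2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# weighted Hamming distance between two character vectors
oracle_whamming <- function(x, y, w) sum(w[x != y])

# exhaustive Steiner-point search: minimum MST cost over the observed
# haplotypes plus any subset (up to max_extra) of candidate sequences.
# The pool distance matrix is computed once; Prim runs on index subsets.
oracle_steiner_optimum <- function(m_obs, w, candidates, max_extra = 3) {
  pool <- rbind(m_obs, candidates)
  np <- nrow(pool)
  Dp <- matrix(0, np, np)
  for (i in seq_len(np - 1)) for (j in (i + 1):np)
    Dp[i, j] <- Dp[j, i] <- oracle_whamming(pool[i, ], pool[j, ], w)
  mst_cost_idx <- function(idx) {
    n <- length(idx)
    if (n == 1) return(0)
    D <- Dp[idx, idx]
    used <- rep(FALSE, n)
    used[1] <- TRUE
    cost <- 0
    dmin <- D[1, ]
    for (step in seq_len(n - 1)) {
      k <- which.min(replace(dmin, used, Inf))
      cost <- cost + dmin[k]
      used[k] <- TRUE
      dmin <- pmin(dmin, D[k, ])
    }
    cost
  }
  n_obs <- nrow(m_obs)
  best <- mst_cost_idx(seq_len(n_obs))
  nc <- nrow(candidates)
  for (size in seq_len(min(max_extra, nc))) {
    subsets <- utils::combn(nc, size)
    for (ci in seq_len(ncol(subsets))) {
      best <- min(best,
                  mst_cost_idx(c(seq_len(n_obs), n_obs + subsets[, ci])))
    }
  }
  best
}

# all sequences over the per-site observed state sets (Steiner candidate
# grid), excluding the observed haplotypes themselves
steiner_candidate_grid <- function(m_obs) {
  states <- lapply(seq_len(ncol(m_obs)), function(s) unique(m_obs[, s]))
  grid <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  obs_key <- apply(m_obs, 1, paste, collapse = "")
  grid[!apply(grid, 1, paste, collapse = "") %in% obs_key, , drop = FALSE]
}

aln_to_charmat <- function(aln) unclass(aln)

seq_strings <- function(aln) apply(unclass(aln), 1, paste, collapse = "")
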