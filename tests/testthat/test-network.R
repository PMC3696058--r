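test_that("simple pair and star topologies come out as expected", {
  # two haplotypes one mutation apart: single edge, no medians
  n2 <- median_joining_network(mk_ht(c("AAAA", "AATA")))
  expect_equal(nrow(n2$edges), 1L)
  expect_equal(sum(n2$nodes$type == "median"), 0L)
  expect_equal(n2$edges$n_mutations, 1L)

  # star: central haplotype plus k singletons one mutation away
  star <- mk_ht(c("AAAAA", "TAAAA", "ATAAA", "AATAA", "AAATA"))
  ns <- median_joining_network(star)
  expect_equal(sum(ns$nodes$type == "median"), 0L)
  expect_equal(nrow(ns$edges), 4L)
  ctr <- ns$nodes$id[ns$nodes$sequence == "AAAAA"]
  expect_true(all(ns$edges$from == ctr | ns$edges$to == ctr))

  # unobserved central intermediate is reconstructed as a median vector
  tri <- mk_ht(c("TAA", "ATA", "AAT"))
  nt <- median_joining_network(tri)
  expect_equal(sum(nt$nodes$type == "median"), 1L)
  expect_equal(nt$nodes$sequence[nt$nodes$type == "median"], "AAA")
  expect_equal(nrow(nt$edges), 3L)
  expect_true(all(nt$edges$n_mutations == 1L))

  dup <- mk_ht(c("AA", "AT"))
  dup$haplotypes$sequence[2] <- "AA"
  expect_error(median_joining_network(dup), "duplicate")
})

test_that("every observed haplotype is a connected network node", {
  set.seed(17)
  ds <- simulate_coalescent(sim_config(demes = 1, sample_sizes = 15,
                                       theta = 4, sequence_length = 200))
  ht <- collapse_haplotypes(ds$aln, ds$pm)
  net <- median_joining_network(ht)
  expect_true(all(ht$haplotypes$haplotype_id %in% net$nodes$id))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  expect_equal(igraph::components(g)$no, 1L)
})

test_that("epsilon = 0 network is a subgraph of epsilon > 0 networks", {
  set.seed(23)
  ds <- simulate_coalescent(sim_config(demes = 1, sample_sizes = 12,
                                       theta = 5, sequence_length = 150))
  ht <- collapse_haplotypes(ds$aln, ds$pm)
  n0 <- median_joining_network(ht, epsilon = 0)
  n1 <- median_joining_network(ht, epsilon = 90)
  key <- function(net) paste(pmin(net$edges$from, net$edges$to),
                             pmax(net$edges$from, net$edges$to))
  expect_true(all(key(n0) %in% key(n1)))
  expect_gte(nrow(n1$edges), nrow(n0$edges))
})

test_that("inverse-origin reweighting assigns 90, 45, 30 for 1-3 origins", {
  # the 2x2 haplotype square: both sites mutate on two parallel edges
  sq <- median_joining_network(mk_ht(c("AA", "AT", "TA", "TT")))
  w <- reweight_sites(sq)
  expect_equal(w$weights, c(45, 45))

  # single-origin sites keep the base weight
  chain <- median_joining_network(mk_ht(c("AAA", "TAA", "TTA")))
  expect_equal(reweight_sites(chain)$weights, c(90, 90, 90))

  # a site on three edges gets 90/3 = 30
  fake <- chain
  fake$edges <- data.frame(from = c("a", "b", "c"), to = c("b", "c", "d"),
                           n_mutations = 1L, sites = c("2", "2", "2"),
                           weight = 90)
  expect_equal(reweight_sites(fake)$weights[2], 30)
})

test_that("reweighted rebuild is a fixed point without homoplasy", {
  ht <- mk_ht(c("AAAAA", "TAAAA", "TTAAA", "TTTAA"))
  net <- build_network_with_reweighting(ht, passes = 2)
  first <- attr(net, "first_pass")
  expect_equal(net$edges[, c("from", "to", "n_mutations", "sites")],
               first$edges[, c("from", "to", "n_mutations", "sites")])
  expect_equal(net$weights$weights, rep(90, 5))

  # a pair is unchanged by reweighting
  np <- build_network_with_reweighting(mk_ht(c("AAAA", "AATA")))
  expect_equal(nrow(np$edges), 1L)
})

test_that("reweighting steers paths away from homoplasic sites", {
  # site 1 mutates on two edges of the uniform-weight network; after
  # reweighting (w1 = 45) ties involving site 1 are broken against it
  ht <- mk_ht(c("AAAA", "TAAA", "TTAA", "ATAA"))
  n1 <- median_joining_network(ht)
  w <- reweight_sites(n1)
  origins <- table(unlist(strsplit(n1$edges$sites, ";")))
  for (s in names(origins)) {
    expect_equal(w$weights[as.integer(s)],
                 if (origins[[s]] >= 2) 90 / origins[[s]] else 90)
  }
  n2 <- median_joining_network(ht, weights = w)
  # the down-weighted network cost can only stay equal or drop relative
  # to evaluating pass-1 edges under the new weights
  cost_under <- function(net, wts) {
    sum(vapply(strsplit(net$edges$sites, ";"), function(s)
      sum(wts[as.integer(s)]), numeric(1)))
  }
  expect_lte(n2$cost, cost_under(n1, w$weights) + 1e-9)
})

test_that("network cost equals the exhaustive Steiner optimum (small cases)", {
  fixtures <- list(
    c("TAA", "ATA", "AAT"),
    c("AA", "AT", "TA", "TT"),
    c("AAAAA", "TAAAA", "ATAAA", "AATTT", "AATTA"),
    c("AAAAAA", "TTAAAA", "AATTAA", "AAAATT")
  )
  set.seed(41)
  for (i in 1:3) {
    # random binary fixtures: <= 6 haplotypes over <= 6 sites
    L <- sample(5:6, 1)
    seqs <- unique(replicate(sample(4:6, 1),
      paste(sample(c("A", "T"), L, TRUE), collapse = "")))
    if (length(seqs) >= 3) fixtures[[length(fixtures) + 1]] <- seqs
  }
  for (fx in fixtures) {
    ht <- mk_ht(fx)
    net <- median_joining_network(ht)
    m_obs <- do.call(rbind, strsplit(ht$haplotypes$sequence, ""))
    w <- rep(90, ncol(m_obs))
    cands <- steiner_candidate_grid(m_obs)
    opt <- oracle_steiner_optimum(m_obs, w, cands,
                                  max_extra = min(3, nrow(m_obs) - 2))
    expect_equal(net$cost, opt, tolerance = 1e-9)
  }
})
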