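#' Configuration for the structured-coalescent simulator
#'
#' Time is scaled in units of N generations (haploid demes of equal size
#' N), so `theta = 2 N mu_locus` is the scaled mutation rate per locus
#' and `migration = 2 N m` the scaled symmetric island-model rate; with
#' this convention the expected pairwise Phi_ST between two demes is
#' 1/(1 + 2Nm).  An optional sudden expansion multiplies the (ancestral)
#' deme size by `theta0 / theta` before time `tau / theta` (tau in
#' mutational units, so tau = 2 u t round-trips with the demographic
#' dating formula).
#'
#' @param demes Number of demes.
#' @param sample_sizes Integer vector of per-deme sample sizes (recycled
#'   to `demes`; names become locality codes, default `D1`, `D2`, ...).
#' @param theta Scaled mutation rate per locus (present-day; plays the
#'   role of theta1 under an expansion).
#' @param migration Scaled migration rate M = 2Nm (symmetric island
#'   model).
#' @param expansion Optional `list(tau =, theta0 =)` sudden-expansion
#'   history.
#' @param sequence_length Number of sites (finite-sites mutation, so
#'   homoplasy can arise).
#' @param model Substitution model for mutations: `"JC"` (uniform) or
#'   `"TN93"` (transition bias `ts_tv`).
#' @param ts_tv Transition/transversion weight for `model = "TN93"`
#'   (default 4).
#' @param merge_time With `migration = 0` and several demes, the scaled
#'   time at which all demes merge into one ancestral deme (otherwise no
#'   common ancestor exists and the config is rejected).
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(demes = 1, sample_sizes = 20, theta = 5,
                       migration = 0, expansion = NULL,
                       sequence_length = 600, model = c("JC", "TN93"),
                       ts_tv = 4, merge_time = NULL, seed = NULL) {
  model <- match.arg(model)
  sample_sizes <- rep_len(as.integer(sample_sizes), demes)
  if (is.null(names(sample_sizes)))
    names(sample_sizes) <- paste0("D", seq_len(demes))
  stopifnot(all(sample_sizes >= 1), theta >= 0, migration >= 0,
            sequence_length > 0)
  if (!is.null(expansion)) {
    stopifnot(expansion$tau >= 0, expansion$theta0 >= 0)
    if (theta <= 0) stop("expansion requires theta > 0")
  }
  if (demes > 1 && migration == 0 && is.null(merge_time))
    stop("migration = 0 with > 1 deme has no common ancestor; ",
         "set merge_time")
  structure(list(demes = demes, sample_sizes = sample_sizes, theta = theta,
                 migration = migration, expansion = expansion,
                 sequence_length = sequence_length, model = model,
                 ts_tv = ts_tv, merge_time = merge_time, seed = seed),
            class = "sim_config")
}

# structured-coalescent genealogy: continuous time, exponential races.
# Returns parent/branch-length arrays over nodes 1..(2n-1), leaf demes,
# and the tree height.
simulate_genealogy <- function(sample_sizes, migration = 0,
                               size_change = NULL, merge_time = NULL) {
  n <- sum(sample_sizes)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  blen <- numeric(n_nodes)
  node_time <- numeric(n_nodes)
  deme_of_leaf <- rep(seq_along(sample_sizes), sample_sizes)
  active <- seq_len(n)
  deme <- deme_of_leaf
  t <- 0
  nxt <- n + 1L
  relsize <- function(t) {
    if (!is.null(size_change) && t >= size_change$time)
      max(size_change$relsize, 1e-9)  # theta0 = 0: near-instant ancestral coalescence
    else 1
  }
  merged <- FALSE
  repeat {
    if (length(active) == 1L) break
    if (!merged && !is.null(merge_time) && t >= merge_time) {
      deme[] <- 1L
      merged <- TRUE
    }
    k_d <- tabulate(deme, nbins = max(deme))
    r <- relsize(t)
    rate_coal_d <- k_d * (k_d - 1) / 2 / r
    rate_coal <- sum(rate_coal_d)
    n_demes_now <- if (merged) 1L else length(sample_sizes)
    # per-lineage rate M/2 with the finite-island correction (d-1)/d, so
    # the classical expectation Phi_ST = 1/(1 + 2Nm) is exact for any
    # number of demes, not only in the many-deme limit
    rate_mig <- if (n_demes_now > 1L)
      length(active) * migration / 2 * (n_demes_now - 1) / n_demes_now
    else 0
    total <- rate_coal + rate_mig
    # piecewise-constant rates: stop at epoch boundaries and re-draw
    boundary <- Inf
    if (!is.null(size_change) && t < size_change$time)
      boundary <- min(boundary, size_change$time)
    if (!merged && !is.null(merge_time) && t < merge_time)
      boundary <- min(boundary, merge_time)
    if (total == 0) {
      if (!is.finite(boundary))
        stop("coalescent stalled: no events possible")
      t <- boundary
      next
    }
    dt <- stats::rexp(1, total)
    if (t + dt > boundary) {
      t <- boundary
      next
    }
    t <- t + dt
    if (stats::runif(1) < rate_coal / total) {
      d <- sample.int(length(rate_coal_d), 1L, prob = rate_coal_d)
      in_d <- which(deme == d)
      pair <- sample(in_d, 2L)
      a <- active[pair[1]]; b <- active[pair[2]]
      parent[c(a, b)] <- nxt
      blen[a] <- t - node_time[a]
      blen[b] <- t - node_time[b]
      node_time[nxt] <- t
      active <- c(active[-pair], nxt)
      deme <- c(deme[-pair], d)
      nxt <- nxt + 1L
    } else {
      i <- sample.int(length(active), 1L)
      others <- setdiff(seq_along(sample_sizes), deme[i])
      deme[i] <- if (length(others) == 1L) others else sample(others, 1L)
    }
  }
  list(parent = parent, blen = blen, node_time = node_time,
       n = n, deme_of_leaf = deme_of_leaf, height = t)
}

# leaves below every node (list of integer vectors)
descendant_leaves <- function(gen) {
  n_nodes <- 2L * gen$n - 1L
  below <- vector("list", n_nodes)
  for (i in seq_len(gen$n)) below[[i]] <- i
  ord <- order(gen$node_time[(gen$n + 1L):n_nodes])
  for (v in ((gen$n + 1L):n_nodes)[ord]) {
    kids <- which(gen$parent == v)
    below[[v]] <- sort(unlist(below[kids]))
  }
  below
}

# infinite-sites summary statistics for one single-deme (or expansion)
# coalescent sample: S, mean pairwise differences, haplotype count, and
# the mismatch histogram.  theta is the present-day scaled mutation rate;
# expansion = list(tau, theta0) as in sim_config().
coalescent_sample_stats <- function(n, theta, expansion = NULL) {
  size_change <- NULL
  if (!is.null(expansion) && theta > 0)
    size_change <- list(time = expansion$tau / theta,
                        relsize = expansion$theta0 / theta)
  gen <- simulate_genealogy(n, size_change = size_change)
  below <- descendant_leaves(gen)
  D <- matrix(0L, n, n)
  S <- 0L
  root <- 2L * n - 1L
  for (v in seq_len(root - 1L)) {
    m <- stats::rpois(1, theta / 2 * gen$blen[v])
    if (m == 0L) next
    S <- S + m
    s <- below[[v]]
    D[s, -s] <- D[s, -s] + m
    D[-s, s] <- D[-s, s] + m
  }
  v <- D[upper.tri(D)]
  # haplotype classes: leaves at zero distance share a haplotype
  k <- length(unique(apply(D, 1L, paste, collapse = ",")))
  list(S = S, d = mean(v), k = k,
       mismatch = tabulate(v + 1L, nbins = max(v) + 1L))
}

# drop mutations onto a genealogy over a finite-sites sequence
mutate_on_tree <- function(gen, theta, L, model = "JC", ts_tv = 4) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  root <- 2L * gen$n - 1L
  seqs <- matrix(NA_character_, root, L)
  seqs[root, ] <- sample(bases, L, replace = TRUE)
  # visit nodes from the root downwards (decreasing node time)
  ord <- order(gen$node_time[seq_len(root - 1L)], decreasing = TRUE)
  for (v in ord) {
    s <- seqs[gen$parent[v], ]
    m <- stats::rpois(1, theta / 2 * gen$blen[v])
    if (m > 0L) for (j in seq_len(m)) {
      site <- sample.int(L, 1L)
      cur <- s[site]
      if (model == "TN93") {
        cand <- c(transition[[cur]], setdiff(bases, c(cur, transition[[cur]])))
        s[site] <- sample(cand, 1L, prob = c(ts_tv, 1, 1))
      } else {
        s[site] <- sample(setdiff(bases, cur), 1L)
      }
    }
    seqs[v, ] <- s
  }
  seqs[seq_len(gen$n), , drop = FALSE]
}

#' Simulate a structured-coalescent dataset
#'
#' Draws a haploid structured-coalescent genealogy (island-model
#' migration, optional sudden size change), drops Poisson mutations on
#' its branches under a finite-sites substitution model, and returns the
#' resulting alignment, population map, and the generating truth.
#'
#' @param cfg A [sim_config()].
#' @return A `synthetic_dataset`: list with `aln` (class `aln`), `pm`
#'   (class `popmap`), and `truth` (tree height, deme labels, generating
#'   parameters).
#' @export
simulate_coalescent <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(cfg$seed, {
    size_change <- NULL
    if (!is.null(cfg$expansion))
      size_change <- list(time = cfg$expansion$tau / cfg$theta,
                          relsize = cfg$expansion$theta0 / cfg$theta)
    gen <- simulate_genealogy(cfg$sample_sizes, migration = cfg$migration,
                              size_change = size_change,
                              merge_time = cfg$merge_time)
    seqs <- mutate_on_tree(gen, cfg$theta, cfg$sequence_length,
                           model = cfg$model, ts_tv = cfg$ts_tv)
    n <- gen$n
    ids <- sprintf("ind%03d", seq_len(n))
    rownames(seqs) <- ids
    aln <- structure(seqs, class = "aln", locus = "sim")
    loc <- names(cfg$sample_sizes)[gen$deme_of_leaf]
    pm <- as_popmap(data.frame(individual = ids, locality = loc,
                               stringsAsFactors = FALSE))
    truth <- list(tree_height = gen$height,
                  deme_of_individual = stats::setNames(loc, ids),
                  theta = cfg$theta, migration = cfg$migration,
                  expansion = cfg$expansion,
                  sequence_length = cfg$sequence_length,
                  model = cfg$model, seed = cfg$seed)
    structure(list(aln = aln, pm = pm, truth = truth),
              class = "synthetic_dataset")
  })
}

#' Write a synthetic dataset to disk
#'
#' Emits `alignment.fasta`, `popmap.tsv` and `truth.json` under `out_dir`
#' so the dataset round-trips exactly through [read_fasta_alignment()]
#' and [read_population_map()].
#'
#' @param ds A `synthetic_dataset`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_synthetic_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "alignment.fasta")
  pmap <- file.path(out_dir, "popmap.tsv")
  truth <- file.path(out_dir, "truth.json")
  write_fasta_alignment(ds$aln, fa)
  utils::write.table(ds$pm, pmap, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  jsonlite::write_json(ds$truth, truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(alignment = fa, popmap = pmap, truth = truth))
}
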