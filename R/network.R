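#' Site weights for network construction
#'
#' Positive per-site weights used in the weighted Hamming distance of the
#' median-joining construction.  The inverse-origin rule assigns
#' `base_weight` to sites that mutate on a single network edge and
#' `base_weight / r` to sites with `r >= 2` inferred origins.
#'
#' @param weights Numeric vector of per-site weights (all > 0).
#' @param base_weight The single-origin weight (default 90).
#' @return A `site_weights` object.
#' @export
site_weights <- function(weights, base_weight = 90) {
  if (any(weights <= 0)) stop("site weights must be positive")
  structure(list(weights = as.numeric(weights), base_weight = base_weight),
            class = "site_weights")
}

uniform_weights <- function(n_sites, base_weight = 90) {
  site_weights(rep(base_weight, n_sites), base_weight)
}

# weighted Hamming distance matrix between rows of a character matrix:
# total weight minus the weighted match count, via one-hot cross products
weighted_hamming <- function(m, w) {
  n <- nrow(m)
  matches <- matrix(0, n, n)
  for (b in unique(as.vector(m))) {
    ind <- (m == b) * 1
    matches <- matches + ind %*% (w * t(ind))
  }
  D <- sum(w) - matches
  dimnames(D) <- list(rownames(m), rownames(m))
  diag(D) <- 0
  pmax(D, 0)
}

# deterministic MST (Kruskal; ties by edge order = (i, j) lexicographic).
# Returns list(edges = 2-col index matrix, cost).
mst_tree <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(list(edges = matrix(integer(), 0, 2), cost = 0))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[upper.tri(D)], pairs[, 1], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  comp <- seq_len(n)
  edges <- matrix(integer(), 0, 2)
  cost <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (comp[i] != comp[j]) {
      edges <- rbind(edges, c(i, j))
      cost <- cost + D[i, j]
      comp[comp == comp[j]] <- comp[i]
      if (nrow(edges) == n - 1L) break
    }
  }
  list(edges = edges, cost = cost)
}

# minimax (bottleneck) distance between all node pairs along the MST
minimax_matrix <- function(D, mst_edges) {
  n <- nrow(D)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mst_edges))) {
    i <- mst_edges[k, 1]; j <- mst_edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  mm <- matrix(Inf, n, n); diag(mm) <- 0
  for (root in seq_len(n)) {
    # DFS from root carrying the running path maximum
    stack <- list(c(root, 0))
    seen <- logical(n); seen[root] <- TRUE
    while (length(stack)) {
      top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- top[1]; mx <- top[2]
      for (u in adj[[v]]) if (!seen[u]) {
        seen[u] <- TRUE
        m2 <- max(mx, D[v, u])
        mm[root, u] <- m2
        stack[[length(stack) + 1L]] <- c(u, m2)
      }
    }
  }
  mm
}

# epsilon-relaxed minimum spanning network: all edges with
# d(u,v) <= minimax(u,v) + epsilon (epsilon = 0 gives the union of MSTs)
msn_edges <- function(D, epsilon = 0) {
  t <- mst_tree(D)
  mm <- minimax_matrix(D, t$edges)
  keep <- which(upper.tri(D) & D <= mm + epsilon + 1e-9, arr.ind = TRUE)
  keep
}

# quasi-median sequences of a triplet: per-site majority state where one
# exists, otherwise all three states are enumerated (finite product).
quasi_medians <- function(a, b, c, max_products = 729) {
  maj <- ifelse(a == b | a == c, a, ifelse(b == c, b, NA))
  open <- which(is.na(maj))
  if (!length(open)) return(matrix(maj, nrow = 1L))
  if (3^length(open) > max_products) return(NULL)
  states <- lapply(open, function(s) c(a[s], b[s], c[s]))
  grid <- as.matrix(expand.grid(states, stringsAsFactors = FALSE))
  out <- matrix(rep(maj, each = nrow(grid)), nrow = nrow(grid))
  out[, open] <- grid
  out
}

#' Median-joining haplotype network
#'
#' Builds a haplotype network by the median-joining principle: starting
#' from the observed haplotypes, quasi-median (Steiner) candidate
#' sequences generated from node triplets are added greedily whenever they
#' reduce the total weighted cost of the spanning tree, median vectors
#' that no longer reduce the cost are pruned, and the final network is the
#' epsilon-relaxed minimum spanning network over the remaining nodes under
#' the weighted Hamming distance.
#'
#' @param ht A `haplotype_table` (sequences must be distinct; collapse
#'   first).
#' @param weights A [site_weights()] or `NULL` for uniform `base_weight`.
#' @param epsilon Relaxation parameter of the spanning network (default
#'   0).
#' @param base_weight Default per-site weight (default 90).
#' @return A `haplotype_network`: list with `nodes` (data frame: id,
#'   sequence, type `"observed"`/`"median"`, frequency), `edges` (data
#'   frame: from, to, n_mutations, sites, weight), `weights`, `epsilon`,
#'   and `cost` (weighted MST cost over all nodes).
#' @export
median_joining_network <- function(ht, weights = NULL, epsilon = 0,
                                   base_weight = 90) {
  seqs <- ht$haplotypes$sequence
  if (length(seqs) < 2L) stop("need at least 2 haplotypes")
  if (anyDuplicated(seqs)) stop("duplicate sequences; collapse haplotypes first")
  L <- nchar(seqs[1])
  if (any(nchar(seqs) != L)) stop("haplotype sequences of unequal length")
  w <- if (is.null(weights)) uniform_weights(L, base_weight) else weights
  if (length(w$weights) != L) stop("weight vector length != sequence length")
  m_full <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = L,
                   byrow = TRUE)
  rownames(m_full) <- ht$haplotypes$haplotype_id
  n_obs <- nrow(m_full)
  # constant columns never mutate and carry zero distance: the whole
  # construction runs on the polymorphic sites only
  poly <- which(apply(m_full, 2L, function(col) length(unique(col)) > 1L))
  if (!length(poly)) stop("all haplotype sequences identical")
  m <- m_full[, poly, drop = FALSE]
  wp <- w$weights[poly]
  seq_key <- function(mm) apply(mm, 1L, paste, collapse = "")

  # greedy Steiner insertion: add the quasi-median that most reduces the
  # weighted MST cost; repeat until no candidate improves
  repeat {
    D <- weighted_hamming(m, wp)
    cur <- mst_tree(D)$cost
    known <- seq_key(m)
    best_gain <- 1e-9; best_seq <- NULL
    nb <- nrow(m)
    if (nb >= 3L) {
      combs <- utils::combn(nb, 3L)
      cand_pool <- character()
      for (ci in seq_len(ncol(combs))) {
        tri <- combs[, ci]
        qm <- quasi_medians(m[tri[1], ], m[tri[2], ], m[tri[3], ])
        if (is.null(qm)) next
        cand_pool <- c(cand_pool, setdiff(seq_key(qm), known))
      }
      cand_pool <- unique(cand_pool)
      for (cs in cand_pool) {
        cand <- strsplit(cs, "")[[1]]
        m2 <- rbind(m, cand)
        c2 <- mst_tree(weighted_hamming(m2, wp))$cost
        gain <- cur - c2
        if (gain > best_gain ||
            (abs(gain - best_gain) <= 1e-9 && !is.null(best_seq) &&
             cs < paste(best_seq, collapse = ""))) {
          best_gain <- gain; best_seq <- cand
        }
      }
    }
    if (is.null(best_seq)) break
    m <- rbind(m, best_seq)
    rownames(m)[nrow(m)] <- paste0("mv", nrow(m) - n_obs)
  }

  # prune median vectors whose removal leaves the MST cost unchanged
  repeat {
    if (nrow(m) == n_obs) break
    D <- weighted_hamming(m, wp)
    cur <- mst_tree(D)$cost
    removed <- FALSE
    for (i in rev(seq(n_obs + 1L, nrow(m)))) {
      c2 <- mst_tree(weighted_hamming(m[-i, , drop = FALSE], wp))$cost
      if (c2 <= cur + 1e-9) {
        m <- m[-i, , drop = FALSE]
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }
  if (nrow(m) > n_obs)
    rownames(m)[(n_obs + 1L):nrow(m)] <- paste0("mv", seq_len(nrow(m) - n_obs))

  D <- weighted_hamming(m, wp)
  cost <- mst_tree(D)$cost
  ed <- msn_edges(D, epsilon)
  sites <- lapply(seq_len(nrow(ed)), function(k)
    poly[which(m[ed[k, 1], ] != m[ed[k, 2], ])])
  # rebuild full-length sequences (constant sites shared by every node)
  m_out <- matrix(rep(m_full[1L, ], each = nrow(m)), nrow = nrow(m))
  m_out[, poly] <- m
  rownames(m_out) <- rownames(m)
  m <- m_out
  edges <- data.frame(
    from = rownames(m)[ed[, 1]], to = rownames(m)[ed[, 2]],
    n_mutations = lengths(sites),
    sites = vapply(sites, paste, character(1), collapse = ";"),
    weight = D[ed], stringsAsFactors = FALSE)
  freq <- c(ht$haplotypes$total, rep(0L, nrow(m) - n_obs))
  nodes <- data.frame(
    id = rownames(m), sequence = seq_key(m),
    type = c(rep("observed", n_obs), rep("median", nrow(m) - n_obs)),
    frequency = freq, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, weights = w,
                 epsilon = epsilon, cost = cost,
                 counts = ht$counts),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  nmv <- sum(x$nodes$type == "median")
  cat("Haplotype network: ", sum(x$nodes$type == "observed"),
      " observed haplotypes, ", nmv, " median vector(s), ",
      nrow(x$edges), " edges (epsilon = ", x$epsilon, ")\n", sep = "")
  invisible(x)
}

#' Inverse-origin site weights from a built network
#'
#' Counts, for every site, the number of distinct network edges on which
#' that site mutates (its inferred origins r) and assigns weight
#' `base_weight` when r <= 1 and `base_weight / r` when r >= 2.
#'
#' @param net A `haplotype_network`.
#' @param base_weight Single-origin weight (default 90).
#' @return A [site_weights()] covering every site of the alignment.
#' @export
reweight_sites <- function(net, base_weight = 90) {
  L <- nchar(net$nodes$sequence[1])
  origins <- integer(L)
  for (s in net$edges$sites) {
    idx <- as.integer(strsplit(s, ";", fixed = TRUE)[[1]])
    origins[idx] <- origins[idx] + 1L
  }
  w <- ifelse(origins >= 2L, base_weight / origins, base_weight)
  site_weights(w, base_weight)
}

#' Median-joining network with inverse-origin reweighting
#'
#' Two-pass construction: pass 1 builds the network under uniform weights,
#' the per-site origin counts of that network define the inverse-origin
#' weights (`base_weight` for single origins, `base_weight / r` for r
#' repeated origins), and pass 2 rebuilds the network under those weights.
#' Additional passes repeat the reweight/rebuild cycle.
#'
#' @param ht A `haplotype_table`.
#' @param epsilon Relaxation parameter (default 0).
#' @param base_weight Single-origin weight (default 90).
#' @param passes Number of build passes (default 2).
#' @return The final `haplotype_network`, with the pass-1 network in
#'   attribute `first_pass` and the final weights in `$weights`.
#' @export
build_network_with_reweighting <- function(ht, epsilon = 0, base_weight = 90,
                                           passes = 2) {
  stopifnot(passes >= 1)
  net <- median_joining_network(ht, weights = NULL, epsilon = epsilon,
                                base_weight = base_weight)
  first <- net
  for (p in seq_len(passes - 1L)) {
    w <- reweight_sites(net, base_weight)
    net <- median_joining_network(ht, weights = w, epsilon = epsilon,
                                  base_weight = base_weight)
  }
  attr(net, "first_pass") <- first
  net
}

#' Export a haplotype network
#'
#' Writes the network as GraphML (via igraph) and/or a plain edge list
#' with per-edge mutated sites; node attributes carry frequencies and
#' per-locality counts for overlaying haplogroup/locality compositions.
#'
#' @param net A `haplotype_network`.
#' @param graphml Optional GraphML output path.
#' @param edgelist Optional TSV edge-list output path.
#' @return Invisibly, the igraph object.
#' @export
write_network <- function(net, graphml = NULL, edgelist = NULL) {
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = net$nodes)
  if (!is.null(net$counts)) {
    cnt <- net$counts
    for (loc in colnames(cnt)) {
      v <- stats::setNames(cnt[, loc], rownames(cnt))
      igraph::V(g)$name -> nm
      attr_vals <- ifelse(nm %in% names(v), v[nm], 0L)
      g <- igraph::set_vertex_attr(g, paste0("n_", loc), value = attr_vals)
    }
  }
  if (!is.null(graphml)) igraph::write_graph(g, graphml, format = "graphml")
  if (!is.null(edgelist))
    utils::write.table(net$edges, edgelist, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(g)
}
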