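#' Model-based clustering of haplotypes into haplogroups
#'
#' Partitions haplotypes (weighted by their individual counts) by
#' maximising an independent-sites Dirichlet-multinomial marginal
#' likelihood over the polymorphic-site nucleotide counts, with a
#' symmetric Dirichlet prior (`alpha` per nucleotide).  The search is a
#' randomised greedy reassignment with restarts: for each number of
#' clusters K from 1 to `k_max`, `runs x replicates` random starts are
#' polished by single-haplotype moves until no move improves the score,
#' and the best partition over all K and restarts is returned.  Model
#' complexity is penalised only by the marginal likelihood's own Occam
#' factor.
#'
#' @param ht A `haplotype_table` (or an `aln`, collapsed internally with
#'   one locality).
#' @param k_max Largest number of clusters tried (default 22).
#' @param runs,replicates Restart schedule: `runs * replicates` random
#'   starts per K (defaults 10 and 6).
#' @param seed Optional seed making the search deterministic.
#' @param alpha Symmetric Dirichlet hyperparameter per nucleotide
#'   (default 0.25).
#' @return A `cluster_model`: list with `K`, `assignment` (haplotype_id
#'   -> cluster label, sizes decreasing), `log_marginal_likelihood`, and
#'   the search settings.
#' @export
cluster_haplotypes <- function(ht, k_max = 22, runs = 10, replicates = 6,
                               seed = NULL, alpha = 0.25) {
  if (inherits(ht, "aln")) {
    pm <- as_popmap(data.frame(individual = rownames(ht), locality = "all"))
    ht <- collapse_haplotypes(ht, pm)
  }
  hap_aln <- haplotype_alignment(ht)
  weights <- ht$haplotypes$total
  H <- nrow(hap_aln)
  m <- unclass(hap_aln)
  poly <- apply(m, 2L, function(col) length(unique(col)) >= 2L)
  settings <- list(k_max = k_max, runs = runs, replicates = replicates,
                   seed = seed, alpha = alpha)
  if (!any(poly) || H == 1L || k_max == 1L) {
    asg <- stats::setNames(rep(1L, H), ht$haplotypes$haplotype_id)
    ll <- if (any(poly))
      dm_partition_score(one_hot_counts(m[, poly, drop = FALSE], weights),
                         asg, alpha)
    else 0
    return(structure(c(list(K = 1L, assignment = asg,
                            log_marginal_likelihood = ll), settings),
                     class = "cluster_model"))
  }
  X <- one_hot_counts(m[, poly, drop = FALSE], weights)
  best <- NULL
  with_seed(seed, {
    for (K in seq_len(min(k_max, H))) {
      for (r in seq_len(runs * replicates)) {
        asg <- greedy_dm_partition(X, K, alpha)
        sc <- dm_partition_score(X, asg, alpha)
        if (is.null(best) || sc > best$score + 1e-9)
          best <- list(score = sc, assignment = asg)
      }
    }
  })
  # contiguous labels ordered by decreasing cluster weight
  asg <- best$assignment
  w_by <- tapply(weights, asg, sum)
  relab <- stats::setNames(seq_along(w_by),
                           names(sort(w_by, decreasing = TRUE)))
  asg <- unname(relab[as.character(asg)])
  names(asg) <- ht$haplotypes$haplotype_id
  structure(c(list(K = max(asg), assignment = asg,
                   log_marginal_likelihood = best$score), settings),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Haplogroup clustering: K =", x$K, "clusters, log marginal likelihood",
      sprintf("%.3f\n", x$log_marginal_likelihood))
  print(table(x$assignment))
  invisible(x)
}

# haplotype x (site * base) count matrix, rows scaled by haplotype counts
one_hot_counts <- function(m, weights) {
  bases <- c("A", "C", "G", "T")
  out <- matrix(0, nrow(m), ncol(m) * 4L)
  for (b in seq_along(bases)) {
    out[, (seq_len(ncol(m)) - 1L) * 4L + b] <- (m == bases[b]) * weights
  }
  attr(out, "n_sites") <- ncol(m)
  out
}

# Dirichlet-multinomial log marginal likelihood of a partition
dm_partition_score <- function(X, assignment, alpha) {
  S <- attr(X, "n_sites")
  score <- 0
  for (c in unique(assignment)) {
    rows <- which(assignment == c)
    cnt <- if (length(rows) == 1L) X[rows, ] else colSums(X[rows, , drop = FALSE])
    W <- sum(cnt) / S
    score <- score + S * (lgamma(4 * alpha) - lgamma(4 * alpha + W)) +
      sum(lgamma(alpha + cnt)) - 4 * S * lgamma(alpha)
  }
  score
}

greedy_dm_partition <- function(X, K, alpha, max_sweeps = 50) {
  H <- nrow(X)
  asg <- sample.int(K, H, replace = TRUE)
  score_move <- function(asg) dm_partition_score(X, asg, alpha)
  repeat {
    changed <- FALSE
    for (h in sample.int(H)) {
      cur <- asg[h]
      sc <- vapply(seq_len(K), function(k) {
        a2 <- asg; a2[h] <- k
        score_move(a2)
      }, numeric(1))
      k_best <- which.max(sc)
      if (k_best != cur && sc[k_best] > sc[cur] + 1e-9) {
        asg[h] <- k_best
        changed <- TRUE
      }
    }
    max_sweeps <- max_sweeps - 1L
    if (!changed || max_sweeps <= 0L) break
  }
  asg
}

#' Propagate haplogroup labels to individuals
#'
#' Each individual inherits the cluster label of its haplotype.  No
#' out-of-sample assignment: a haplotype absent from the model is an
#' error.
#'
#' @param model A `cluster_model`.
#' @param ht The `haplotype_table` the model was fitted to (its
#'   `assignment` maps individuals to haplotypes).
#' @return Named integer vector individual id -> cluster label.
#' @export
assign_haplogroups <- function(model, ht) {
  miss <- setdiff(unique(ht$assignment), names(model$assignment))
  if (length(miss))
    stop("haplotype(s) not covered by the cluster model: ",
         paste(miss, collapse = ", "))
  stats::setNames(model$assignment[ht$assignment], names(ht$assignment))
}

#' Haplogroup frequencies per locality
#'
#' Relative frequency of each haplogroup in every locality, plus a pooled
#' `total` row; each row sums to 1.
#'
#' @param labels Named vector individual id -> haplogroup label (from
#'   [assign_haplogroups()]).
#' @param pm A `popmap` covering the individuals.
#' @return Matrix of relative frequencies, localities (and `total`) in
#'   rows, haplogroups in columns.
#' @export
haplogroup_frequencies <- function(labels, pm) {
  loc <- popmap_localities(pm, names(labels))
  tab <- table(factor(loc), factor(labels))
  tab <- rbind(tab, total = colSums(tab))
  freq <- tab / rowSums(tab)
  freq[rowSums(tab) == 0, ] <- NA_real_
  as.matrix(freq)
}
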