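#' Number of segregating (polymorphic) sites
#'
#' Counts alignment columns with at least two distinct observed
#' nucleotides.  Gap/N columns are expected to have been removed already
#' (see [drop_gap_sites()]); any remaining `-`/`N` characters are ignored
#' when deciding whether a column is polymorphic.
#'
#' @param aln An `aln` object with >= 2 sequences.
#' @return Integer count S.
#' @export
segregating_sites <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  m <- unclass(aln)
  sum(apply(m, 2L, function(col) {
    length(unique(col[col %in% c("A", "C", "G", "T")])) >= 2L
  }))
}

#' Haplotype (gene) diversity
#'
#' Nei's unbiased estimator h = n/(n-1) * (1 - sum((c_i/n)^2)) from
#' haplotype counts.
#'
#' @param counts Integer vector of haplotype counts (sum n >= 2).
#' @return h in \[0, 1\].
#' @export
haplotype_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) stop("need at least 2 sequences")
  n / (n - 1) * (1 - sum((counts / n)^2))
}

# pairwise difference matrix via one-hot cross products: O(n^2 L) in BLAS
pairwise_diff_matrix <- function(aln) {
  m <- unclass(aln)
  match_counts <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    match_counts <- match_counts + tcrossprod(ind)
  }
  # comparable sites per pair: both in {A,C,G,T}
  obs <- (m %in% c("A", "C", "G", "T")) * 1
  dim(obs) <- dim(m)
  comp <- tcrossprod(obs)
  d <- comp - match_counts
  dimnames(d) <- list(rownames(m), rownames(m))
  diag(d) <- 0
  d
}

#' Mean number of pairwise differences
#'
#' Arithmetic mean, over all unordered sequence pairs, of the number of
#' differing sites.
#'
#' @param aln An `aln` with >= 2 sequences.
#' @return d (in sites).
#' @export
mean_pairwise_differences <- function(aln) {
  if (nrow(aln) < 2L) stop("need at least 2 sequences")
  d <- pairwise_diff_matrix(aln)
  sum(d[upper.tri(d)]) / choose(nrow(aln), 2)
}

#' Nucleotide diversity
#'
#' Mean proportion of differing sites over all unordered pairs; equals
#' [mean_pairwise_differences()] divided by the analysed length.
#'
#' @param aln An `aln` with >= 2 sequences.
#' @return pi (per site).
#' @export
nucleotide_diversity <- function(aln) {
  mean_pairwise_differences(aln) / ncol(aln)
}

#' Per-locality and pooled diversity summary
#'
#' One row per locality plus a pooled `total` row, with sample size (N),
#' polymorphic sites (S), haplotype count (H), haplotype diversity (h),
#' nucleotide diversity (pi) and mean pairwise differences (d).
#' Localities with a single individual get `NA` statistics rather than
#' zeros so they cannot silently deflate regional means.
#'
#' @param aln An `aln`.
#' @param pm A `popmap` covering the alignment.
#' @param per_locality Emit per-locality rows (default `TRUE`).
#' @param pooled One of `"pooled"` (statistics on the pooled sample,
#'   default) or `"mean"` (unweighted average of per-locality values).
#' @return Data frame with columns locality, N, S, H, h, pi, d.
#' @export
diversity_summary <- function(aln, pm, per_locality = TRUE,
                              pooled = c("pooled", "mean")) {
  pooled <- match.arg(pooled)
  loc <- popmap_localities(pm, rownames(aln))
  one <- function(sub, label) {
    n <- nrow(sub)
    if (n < 2L)
      return(data.frame(locality = label, N = n, S = NA_integer_,
                        H = NA_integer_, h = NA_real_, pi = NA_real_,
                        d = NA_real_, stringsAsFactors = FALSE))
    seqs <- apply(unclass(sub), 1L, paste, collapse = "")
    cnt <- as.integer(table(seqs))
    data.frame(locality = label, N = n, S = segregating_sites(sub),
               H = length(cnt), h = haplotype_diversity(cnt),
               pi = nucleotide_diversity(sub),
               d = mean_pairwise_differences(sub), stringsAsFactors = FALSE)
  }
  rows <- list()
  if (per_locality) {
    for (l in sort(unique(loc))) {
      sub <- structure(unclass(aln)[names(loc)[loc == l], , drop = FALSE],
                       class = "aln")
      rows[[l]] <- one(sub, l)
    }
  }
  if (pooled == "pooled" || !per_locality) {
    rows[["total"]] <- one(aln, "total")
  } else {
    per <- do.call(rbind, rows)
    rows[["total"]] <- data.frame(
      locality = "total", N = sum(per$N),
      S = NA_integer_, H = NA_integer_,
      h = mean(per$h, na.rm = TRUE), pi = mean(per$pi, na.rm = TRUE),
      d = mean(per$d, na.rm = TRUE), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
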