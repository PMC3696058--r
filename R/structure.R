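#' Grouping scheme for hierarchical AMOVA
#'
#' @param name Scheme label (e.g. `"west_vs_east"`).
#' @param assignment Named character vector mapping locality code to group
#'   label.
#' @return A `grouping_scheme` object.
#' @export
grouping_scheme <- function(name, assignment) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be named by locality code")
  structure(list(name = name, assignment = assignment),
            class = "grouping_scheme")
}

#' Fixation indices from AMOVA variance components
#'
#' Computes Phi_CT = sigma_a / sigma_T, Phi_SC = sigma_b / (sigma_b +
#' sigma_c) and Phi_ST = (sigma_a + sigma_b) / sigma_T from the three
#' hierarchical variance components (among groups, among populations
#' within groups, within populations).  With `sigma_a = NULL` the
#' two-level Phi_ST = sigma_b / (sigma_b + sigma_c) is returned.
#'
#' @param sigma_a Among-group variance component (or `NULL` for a
#'   two-level design).
#' @param sigma_b Among-populations(-within-groups) component.
#' @param sigma_c Within-population component.
#' @return Named numeric vector of fixation indices.
#' @export
phi_indices <- function(sigma_a = NULL, sigma_b, sigma_c) {
  if (is.null(sigma_a)) {
    return(c(phi_ST = sigma_b / (sigma_b + sigma_c)))
  }
  tot <- sigma_a + sigma_b + sigma_c
  c(phi_CT = sigma_a / tot,
    phi_SC = sigma_b / (sigma_b + sigma_c),
    phi_ST = (sigma_a + sigma_b) / tot)
}

# sum of squared distances within each level of f, divided by level size
ssd_within <- function(d2, f) {
  lv <- levels(f)
  s <- 0
  for (l in lv) {
    idx <- which(f == l)
    if (length(idx) > 1L)
      s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    # sum(d2[idx, idx]) counts each unordered pair twice
  }
  s
}

# AMOVA sums of squares, variance components and indices for a fixed design
amova_components <- function(d2, pop, grp = NULL) {
  N <- length(pop)
  pop <- factor(pop)
  n_p <- table(pop)
  P <- nlevels(pop)
  ssd_total <- sum(d2) / (2 * N)
  ssd_wp <- ssd_within(d2, pop)
  if (is.null(grp)) {
    ssd_ap <- ssd_total - ssd_wp
    df <- c(ap = P - 1L, wp = N - P)
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    sigma_c <- ssd_wp / df[["wp"]]
    sigma_b <- (ssd_ap / df[["ap"]] - sigma_c) / n_c
    list(ssd = c(among_populations = ssd_ap, within_populations = ssd_wp,
                 total = ssd_total),
         df = c(among_populations = P - 1L, within_populations = N - P,
                total = N - 1L),
         sigma = c(b = sigma_b, c = sigma_c),
         indices = phi_indices(NULL, sigma_b, sigma_c))
  } else {
    grp <- factor(grp)
    G <- nlevels(grp)
    if (G < 2L) stop("grouped AMOVA needs at least 2 groups")
    N_g <- tapply(seq_len(N), grp, length)
    ssd_wg <- ssd_within(d2, grp)
    ssd_ag <- ssd_total - ssd_wg
    ssd_ap <- ssd_wg - ssd_wp
    # unbalanced-design coefficients (Excoffier-style n, n', n'')
    pop_of <- tapply(as.character(grp), pop, unique)
    sum_np2_by_g <- tapply(as.numeric(n_p), factor(pop_of, levels(grp)),
                           function(x) sum(x^2))
    n1 <- (N - sum(sum_np2_by_g / N_g)) / (P - G)
    n2 <- (sum(sum_np2_by_g / N_g) - sum(n_p^2) / N) / (G - 1)
    n3 <- (N - sum(N_g^2) / N) / (G - 1)
    sigma_c <- ssd_wp / (N - P)
    sigma_b <- (ssd_ap / (P - G) - sigma_c) / n1
    sigma_a <- (ssd_ag / (G - 1) - sigma_c - n2 * sigma_b) / n3
    list(ssd = c(among_groups = ssd_ag, among_populations = ssd_ap,
                 within_populations = ssd_wp, total = ssd_total),
         df = c(among_groups = G - 1L, among_populations = P - G,
                within_populations = N - P, total = N - 1L),
         sigma = c(a = sigma_a, b = sigma_b, c = sigma_c),
         indices = phi_indices(sigma_a, sigma_b, sigma_c))
  }
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical partition of squared molecular distances into among-group,
#' among-population-within-group and within-population components, with
#' fixation indices and permutation p-values.  Without a grouping scheme a
#' two-level (among/within populations) analysis is performed.
#'
#' Permutation schemes follow the standard convention: Phi_ST permutes
#' individuals among populations (ignoring groups), Phi_SC permutes
#' individuals among populations within their group, and Phi_CT permutes
#' whole populations among groups.  p = (b + 1) / (n_perm + 1) where b is
#' the number of permuted statistics >= the observed one.  Negative
#' variance components are reported as computed (flagged), not truncated.
#'
#' @param d Molecular distance matrix over individuals (labels =
#'   individual ids).  The AMOVA sum of squares is built from squared
#'   Euclidean distances; for DNA sequences the number of differing sites
#'   (or its substitution-model-corrected analogue) is itself that
#'   squared distance, so the matrix is used as-is by default.  Set
#'   `squared = FALSE` when supplying a linear distance that must be
#'   squared first.
#' @param pm A `popmap` covering the individuals.
#' @param grouping Optional [grouping_scheme()] over the localities.
#' @param n_perm Number of permutation replicates (default 10000; 0 skips
#'   the significance test).
#' @param seed Optional integer seed for the permutations.
#' @param squared Whether `d` already is the squared-distance metric
#'   (default `TRUE`).
#' @return An `amova_result` with elements `table` (source, df, SSD,
#'   variance component, percent variation), `indices`, `p_values`,
#'   `negative_components` flag, and the design sizes.
#' @export
amova <- function(d, pm, grouping = NULL, n_perm = 10000, seed = NULL,
                  squared = TRUE) {
  ids <- rownames(d)
  pop <- factor(popmap_localities(pm, ids))
  if (nlevels(pop) < 2L) stop("AMOVA needs at least 2 populations")
  if (all(d == 0)) {
    warning("all distances are zero; fixation indices undefined")
  }
  d2 <- if (squared) unclass(d) else unclass(d)^2
  grp <- NULL
  if (!is.null(grouping)) {
    miss <- setdiff(levels(pop), names(grouping$assignment))
    if (length(miss))
      stop("grouping scheme lacks localit(ies): ", paste(miss, collapse = ", "))
    grp <- factor(grouping$assignment[as.character(pop)])
  }
  obs <- amova_components(d2, pop, grp)
  singletons <- names(which(table(pop) == 1L))
  if (length(singletons))
    warning("singleton population(s) in design: ",
            paste(singletons, collapse = ", "))
  p_values <- NULL
  if (n_perm > 0) {
    p_values <- with_seed(seed, {
      if (is.null(grp)) {
        c(phi_ST = perm_p(obs$indices[["phi_ST"]], n_perm, function() {
          amova_components(d2, sample(pop))$indices[["phi_ST"]]
        }))
      } else {
        pops <- levels(pop)
        grp_of_pop <- obs_grp_of_pop <- vapply(
          pops, function(p) as.character(grp[match(p, pop)]), character(1))
        c(phi_CT = perm_p(obs$indices[["phi_CT"]], n_perm, function() {
            g2 <- sample(grp_of_pop)
            names(g2) <- pops
            amova_components(d2, pop, factor(g2[as.character(pop)]))$indices[["phi_CT"]]
          }),
          phi_SC = perm_p(obs$indices[["phi_SC"]], n_perm, function() {
            pop2 <- pop
            for (g in levels(grp)) {
              idx <- which(grp == g)
              pop2[idx] <- sample(pop[idx])
            }
            amova_components(d2, pop2, grp)$indices[["phi_SC"]]
          }),
          phi_ST = perm_p(obs$indices[["phi_ST"]], n_perm, function() {
            i <- sample(length(pop))
            amova_components(d2, pop[i], grp[i])$indices[["phi_ST"]]
          }))
      }
    })
  }
  src <- names(obs$ssd)
  tab <- data.frame(
    source = sub("_", " ", src),
    df = as.integer(obs$df[src]),
    SSD = as.numeric(obs$ssd[src]),
    variance = c(as.numeric(obs$sigma), sum(obs$sigma)),
    percent = 100 * c(as.numeric(obs$sigma), sum(obs$sigma)) / sum(obs$sigma),
    stringsAsFactors = FALSE)
  structure(list(table = tab, indices = obs$indices, p_values = p_values,
                 sigma = obs$sigma,
                 negative_components = any(obs$sigma < 0),
                 n_perm = n_perm,
                 grouping = if (!is.null(grouping)) grouping$name,
                 n = length(pop), n_populations = nlevels(pop),
                 n_groups = if (!is.null(grp)) nlevels(grp)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA", if (!is.null(x$grouping)) paste0("(grouping: ", x$grouping, ")"),
      "\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Fixation indices:\n")
  print(round(x$indices, 5))
  if (!is.null(x$p_values)) {
    cat("Permutation p-values (", x$n_perm, " replicates):\n", sep = "")
    print(signif(x$p_values, 4))
  }
  if (x$negative_components)
    cat("Note: negative variance component(s) reported as computed.\n")
  invisible(x)
}

perm_p <- function(observed, n_perm, draw) {
  b <- 0L
  for (i in seq_len(n_perm)) if (draw() >= observed - 1e-12) b <- b + 1L
  (b + 1) / (n_perm + 1)
}

#' Permutation significance test for a fixation index
#'
#' Generic permutation machinery: given the distance matrix and design,
#' permutes according to the requested scheme and returns
#' p = (b + 1)/(n_perm + 1).  For the individuals-among-populations scheme
#' on tiny designs, `exact = TRUE` enumerates every distinct assignment of
#' individuals to population slots and returns the exact tail proportion
#' (the identity arrangement included).
#'
#' @param d Distance matrix over individuals.
#' @param pop Factor of population labels, one per individual.
#' @param grp Factor of group labels (required for the within/among-group
#'   schemes).
#' @param scheme One of `"permute_individuals_among_populations"`
#'   (tests Phi_ST), `"permute_individuals_within_groups"` (Phi_SC),
#'   `"permute_populations_among_groups"` (Phi_CT).
#' @param n_perm Number of random permutations.
#' @param seed Optional seed.
#' @param exact Exhaustive enumeration (only for
#'   `permute_individuals_among_populations`).
#' @param squared Whether `d` already is the squared-distance metric
#'   (default `TRUE`).
#' @return List with `statistic` (observed index), `p`, and `n_perm` (or
#'   the enumeration size when exact).
#' @export
permutation_test <- function(d, pop, grp = NULL,
                             scheme = c("permute_individuals_among_populations",
                                        "permute_individuals_within_groups",
                                        "permute_populations_among_groups"),
                             n_perm = 10000, seed = NULL, exact = FALSE,
                             squared = TRUE) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1 || exact)
  d2 <- if (squared) unclass(d) else unclass(d)^2
  pop <- factor(pop)
  if (scheme != "permute_individuals_among_populations") {
    if (is.null(grp)) stop("scheme ", scheme, " requires group labels")
    grp <- factor(grp)
    if (nlevels(grp) < 2L)
      stop("scheme ", scheme, " requires at least 2 groups")
  }
  if (scheme == "permute_individuals_among_populations") {
    stat <- function(p) amova_components(d2, p)$indices[["phi_ST"]]
    observed <- stat(pop)
    if (exact) {
      perms <- multiset_permutations(as.integer(pop))
      vals <- vapply(perms, function(idx)
        stat(factor(levels(pop)[idx], levels = levels(pop))), numeric(1))
      return(list(statistic = observed,
                  p = sum(vals >= observed - 1e-12) / length(vals),
                  n_perm = length(vals), exact = TRUE))
    }
    p <- with_seed(seed, perm_p(observed, n_perm, function() stat(sample(pop))))
    return(list(statistic = observed, p = p, n_perm = n_perm, exact = FALSE))
  }
  if (exact) stop("exact enumeration only for the among-populations scheme")
  if (scheme == "permute_individuals_within_groups") {
    observed <- amova_components(d2, pop, grp)$indices[["phi_SC"]]
    p <- with_seed(seed, perm_p(observed, n_perm, function() {
      pop2 <- pop
      for (g in levels(grp)) {
        idx <- which(grp == g)
        pop2[idx] <- sample(pop[idx])
      }
      amova_components(d2, pop2, grp)$indices[["phi_SC"]]
    }))
    return(list(statistic = observed, p = p, n_perm = n_perm, exact = FALSE))
  }
  # populations among groups
  observed <- amova_components(d2, pop, grp)$indices[["phi_CT"]]
  pops <- levels(pop)
  grp_of_pop <- vapply(pops, function(p) as.character(grp[match(p, pop)]),
                       character(1))
  p <- with_seed(seed, perm_p(observed, n_perm, function() {
    g2 <- stats::setNames(sample(grp_of_pop), pops)
    amova_components(d2, pop, factor(g2[as.character(pop)]))$indices[["phi_CT"]]
  }))
  list(statistic = observed, p = p, n_perm = n_perm, exact = FALSE)
}

# all distinct orderings of a label multiset, as lists of integer codes
multiset_permutations <- function(x) {
  n <- length(x)
  out <- list()
  rec <- function(prefix, remaining) {
    if (!length(remaining)) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in unique(remaining)) {
      i <- match(v, remaining)
      rec(c(prefix, v), remaining[-i])
    }
  }
  rec(integer(), sort(x))
  out
}

#' Pairwise Phi_ST between sampling localities
#'
#' Two-population AMOVA Phi_ST for every pair of retained localities, with
#' permutation p-values and Benjamini-Hochberg FDR adjustment across all
#' pairs.
#'
#' @param d Distance matrix over individuals.
#' @param pm A `popmap`.
#' @param n_perm Permutation replicates per pair (default 10000).
#' @param seed Optional seed.
#' @param min_n Minimum individuals per locality; smaller localities are
#'   excluded (default 5).
#' @param squared Whether `d` already is the squared-distance metric
#'   (default `TRUE`).
#' @return A `phi_st_matrix`: list with symmetric `phi_st`, `p`, and
#'   `p_adj` matrices over retained localities.
#' @export
pairwise_phi_st <- function(d, pm, n_perm = 10000, seed = NULL, min_n = 5,
                            squared = TRUE) {
  ids <- rownames(d)
  pop <- popmap_localities(pm, ids)
  sizes <- table(pop)
  keep <- names(sizes)[sizes >= min_n]
  if (length(keep) < 2L) stop("fewer than 2 localities with >= ", min_n,
                              " individuals")
  locs <- sort(keep)
  k <- length(locs)
  phi <- p <- matrix(NA_real_, k, k, dimnames = list(locs, locs))
  diag(phi) <- 0
  pair_seed <- 0L
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    idx <- which(pop %in% c(locs[i], locs[j]))
    d2 <- if (squared) unclass(d)[idx, idx] else unclass(d)[idx, idx]^2
    f <- factor(pop[idx])
    obs <- amova_components(d2, f)$indices[["phi_ST"]]
    pair_seed <- pair_seed + 1L
    pv <- if (n_perm > 0)
      with_seed(if (is.null(seed)) NULL else seed + pair_seed,
                perm_p(obs, n_perm, function()
                  amova_components(d2, sample(f))$indices[["phi_ST"]]))
    else NA_real_
    phi[i, j] <- phi[j, i] <- obs
    p[i, j] <- p[j, i] <- pv
  }
  pv_vec <- p[upper.tri(p)]
  adj <- bh_fdr(pv_vec)$p_adjusted
  p_adj <- matrix(NA_real_, k, k, dimnames = list(locs, locs))
  p_adj[upper.tri(p_adj)] <- adj
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  structure(list(phi_st = phi, p = p, p_adj = p_adj, n_perm = n_perm,
                 excluded = setdiff(names(sizes), keep)),
            class = "phi_st_matrix")
}

#' @export
print.phi_st_matrix <- function(x, ...) {
  cat("Pairwise Phi_ST over", nrow(x$phi_st), "localities",
      sprintf("(%d permutations)\n", x$n_perm))
  print(round(x$phi_st, 4))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment of a set of p-values, with rejection flags at
#' level `q`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @param q Target FDR level (default 0.05).
#' @return List with `p_adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(list(p_adjusted = numeric(), rejected = logical()))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  m <- sum(!is.na(pvalues))
  ord <- order(pvalues)
  rejected <- rep(FALSE, length(pvalues))
  below <- which(sort(pvalues) <= q * seq_len(length(pvalues)) / m)
  if (length(below)) rejected[ord[seq_len(max(below))]] <- TRUE
  list(p_adjusted = adj, rejected = rejected)
}

#' Write an AMOVA result as CSV
#'
#' Column layout mirrors the conventional AMOVA table: source of
#' variation, d.f., SSD, variance component, percent of variation, then
#' the fixation indices and their p-values.
#'
#' @param x An `amova_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_amova_csv <- function(x, path) {
  tab <- x$table
  idx <- c(x$indices, rep(NA_real_, nrow(tab) - length(x$indices)))
  pv <- if (!is.null(x$p_values))
    c(x$p_values, rep(NA_real_, nrow(tab) - length(x$p_values)))
  else rep(NA_real_, nrow(tab))
  out <- cbind(tab, fixation_index = idx, p_value = pv)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
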