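#' Substitution model configuration
#'
#' Configuration for pairwise genetic distances: the model (`"TN93"` or
#' `"p"`), an optional gamma shape for among-site rate heterogeneity, and
#' optional base frequencies (estimated from the pooled alignment when
#' `NULL`).
#'
#' @param model `"TN93"` (Tamura-Nei 1993) or `"p"` (raw proportion of
#'   differing sites).
#' @param gamma_shape Positive shape parameter alpha of the gamma
#'   distribution of site rates, or `NULL` for no rate heterogeneity.
#' @param base_freqs Named numeric vector `c(A=, C=, G=, T=)` summing to 1,
#'   or `NULL`.
#' @return An object of class `subst_model_config`.
#' @export
subst_model_config <- function(model = c("TN93", "p"), gamma_shape = NULL,
                               base_freqs = NULL) {
  model <- match.arg(model)
  if (!is.null(gamma_shape) && gamma_shape <= 0)
    stop("gamma_shape must be positive")
  if (!is.null(base_freqs)) {
    base_freqs <- base_freqs[c("A", "C", "G", "T")]
    if (anyNA(base_freqs) || abs(sum(base_freqs) - 1) > 1e-9)
      stop("base_freqs must be named A,C,G,T and sum to 1")
  }
  structure(list(model = model, gamma_shape = gamma_shape,
                 base_freqs = base_freqs), class = "subst_model_config")
}

base_frequencies <- function(aln) {
  m <- unclass(aln)
  tab <- table(factor(m[m %in% c("A", "C", "G", "T")],
                      levels = c("A", "C", "G", "T")))
  f <- as.numeric(tab) / sum(tab)
  names(f) <- c("A", "C", "G", "T")
  f
}

# gamma-corrected replacement for -log(w): alpha * (w^(-1/alpha) - 1)
neg_log_gamma <- function(w, alpha) {
  if (is.null(alpha)) -log(w) else alpha * (w^(-1 / alpha) - 1)
}

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Closed-form TN93 distance with optional gamma correction, in which each
#' logarithmic term `-log(w)` is replaced by `alpha * (w^(-1/alpha) - 1)`.
#' Sites where either sequence is not in `{A,C,G,T}` are skipped.  When a
#' logarithm/power argument is non-positive the pair is saturated: the
#' distance cannot be estimated under the model, and `NaN` flagged with
#' attribute `saturated = TRUE` is returned rather than a clamped value.
#'
#' @param x,y DNA strings (or single-row character vectors) of equal
#'   length.
#' @param cfg A [subst_model_config()]; base frequencies must be supplied
#'   in the config or via `base_freqs`.
#' @param base_freqs Base frequencies overriding the config (used when the
#'   pooled estimate lives outside the pair).
#' @return Non-negative distance per site, or `NaN` with
#'   `attr(, "saturated")` on saturation.
#' @export
tn93_distance <- function(x, y, cfg = subst_model_config(),
                          base_freqs = NULL) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "")[[1]]
  if (is.character(y) && length(y) == 1L) y <- strsplit(y, "")[[1]]
  if (length(x) != length(y)) stop("sequence length mismatch")
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable sites")
  x <- x[ok]; y <- y[ok]
  L <- length(x)
  if (cfg$model == "p") return(sum(x != y) / L)
  f <- base_freqs %||% cfg$base_freqs
  if (is.null(f)) {
    tab <- table(factor(c(x, y), levels = c("A", "C", "G", "T")))
    f <- as.numeric(tab) / sum(tab); names(f) <- c("A", "C", "G", "T")
  }
  pur <- c("A", "G")
  P1 <- sum((x %in% pur) & (y %in% pur) & x != y) / L   # A<->G transitions
  P2 <- sum(!(x %in% pur) & !(y %in% pur) & x != y) / L # C<->T transitions
  Q <- sum((x %in% pur) != (y %in% pur)) / L            # transversions
  gR <- f[["A"]] + f[["G"]]; gY <- f[["C"]] + f[["T"]]
  k1 <- 2 * f[["A"]] * f[["G"]] / gR
  k2 <- 2 * f[["C"]] * f[["T"]] / gY
  k3 <- 2 * (gR * gY - f[["A"]] * f[["G"]] * gY / gR -
               f[["C"]] * f[["T"]] * gR / gY)
  a <- cfg$gamma_shape
  d <- 0
  # degenerate frequency classes (k = 0) drop their term, but observed
  # changes of an impossible class mean the model cannot fit: saturation
  if (k1 > 0) {
    w1 <- 1 - P1 / k1 - Q / (2 * gR)
    if (w1 <= 0) return(structure(NaN, saturated = TRUE))
    d <- d + k1 * neg_log_gamma(w1, a)
  } else if (P1 > 0) return(structure(NaN, saturated = TRUE))
  if (k2 > 0) {
    w2 <- 1 - P2 / k2 - Q / (2 * gY)
    if (w2 <= 0) return(structure(NaN, saturated = TRUE))
    d <- d + k2 * neg_log_gamma(w2, a)
  } else if (P2 > 0) return(structure(NaN, saturated = TRUE))
  if (k3 > 0) {
    w3 <- 1 - Q / (2 * gR * gY)
    if (w3 <= 0) return(structure(NaN, saturated = TRUE))
    d <- d + k3 * neg_log_gamma(w3, a)
  } else if (Q > 0) return(structure(NaN, saturated = TRUE))
  unname(max(d, 0))
}

#' Pairwise distance matrix
#'
#' Symmetric matrix of model distances between all rows of an alignment
#' (or the unique haplotypes of a `haplotype_table`).  Base frequencies
#' are estimated once from the pooled alignment unless supplied in `cfg`.
#' Saturated pairs (non-positive logarithm arguments) raise an error
#' listing the pairs, unless `on_saturation = "p_fallback"` substitutes
#' the raw p-distance for those pairs.
#'
#' @param x An `aln` or `haplotype_table`.
#' @param cfg A [subst_model_config()].
#' @param on_saturation `"error"` (default) or `"p_fallback"`.
#' @return A `dist_matrix`: symmetric numeric matrix with zero diagonal
#'   and sequence labels.
#' @export
pairwise_distance_matrix <- function(x, cfg = subst_model_config(),
                                     on_saturation = c("error", "p_fallback")) {
  on_saturation <- match.arg(on_saturation)
  if (inherits(x, "haplotype_table")) x <- haplotype_alignment(x)
  if (nrow(x) < 2L) stop("need at least 2 sequences")
  m <- unclass(x)
  f <- cfg$base_freqs %||% base_frequencies(x)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  sat <- character()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    v <- tn93_distance(m[i, ], m[j, ], cfg, base_freqs = f)
    if (isTRUE(attr(v, "saturated"))) {
      if (on_saturation == "p_fallback") {
        v <- tn93_distance(m[i, ], m[j, ], subst_model_config("p"))
      } else {
        sat <- c(sat, paste(rownames(m)[i], rownames(m)[j], sep = "/"))
        v <- NaN
      }
    }
    d[i, j] <- d[j, i] <- v
  }
  if (length(sat))
    stop("saturated pair(s) under the substitution model: ",
         paste(sat, collapse = ", "),
         " (use on_saturation = \"p_fallback\")")
  structure(d, class = c("dist_matrix", "matrix"))
}

#' Write a distance matrix in square PHYLIP format
#'
#' @param d A distance matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_distances <- function(d, path) {
  n <- nrow(d)
  lines <- c(format(n), vapply(seq_len(n), function(i) {
    paste(c(formatC(rownames(d)[i], width = -10),
            formatC(d[i, ], format = "f", digits = 6)), collapse = " ")
  }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
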