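#' Read an aligned FASTA file
#'
#' Reads a FASTA file of aligned DNA sequences into an `aln` object (a
#' character matrix, one row per individual, one column per site).
#' Sequences are upper-cased and `U` is mapped to `T`.  IUPAC ambiguity
#' codes other than `N` are either rejected (default) or mapped to `N`.
#' The identifier of a record is the FASTA header up to the first
#' whitespace; any description after it is ignored.
#'
#' @param path Path to a FASTA file.
#' @param locus Optional locus label attached to the alignment.
#' @param ambiguity Either `"reject"` (error on R, Y, S, W, ... codes) or
#'   `"as_n"` (silently convert them to `N`).
#' @return An object of class `aln`: a character matrix with row names set
#'   to the individual identifiers and a `locus` attribute.
#' @export
read_fasta_alignment <- function(path, locus = NULL,
                                 ambiguity = c("reject", "as_n")) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA records in ", path)
  idx <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  if (length(seqs) != length(ids)) stop("FASTA record without sequence in ", path)
  as_aln(stats::setNames(seqs, ids), locus = locus, ambiguity = ambiguity)
}

#' Build an alignment object from named sequence strings
#'
#' @param x Named character vector of equal-length DNA strings.
#' @inheritParams read_fasta_alignment
#' @return An `aln` object.
#' @export
as_aln <- function(x, locus = NULL, ambiguity = c("reject", "as_n")) {
  ambiguity <- match.arg(ambiguity)
  if (is.null(names(x)) || anyNA(names(x)) || any(!nzchar(names(x))))
    stop("sequences must be named by individual id")
  if (anyDuplicated(names(x)))
    stop("duplicated individual ids: ",
         paste(unique(names(x)[duplicated(names(x))]), collapse = ", "))
  x <- toupper(x)
  x <- chartr("U", "T", x)
  len <- nchar(x)
  if (length(unique(len)) > 1L) {
    bad <- names(x)[len != len[1L]]
    stop("alignment length mismatch: record(s) ",
         paste(bad, collapse = ", "), " differ from ", len[1L], " sites")
  }
  if (len[1L] == 0L) stop("alignment has zero length")
  mat <- matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
                nrow = length(x), byrow = TRUE,
                dimnames = list(names(x), NULL))
  ok <- mat %in% c("A", "C", "G", "T", "N", "-")
  if (!all(ok)) {
    if (ambiguity == "reject") {
      bad <- unique(mat[!ok])
      stop("ambiguity codes present (use ambiguity = \"as_n\" to mask): ",
           paste(bad, collapse = ", "))
    }
    mat[!ok] <- "N"
  }
  structure(mat, class = "aln", locus = locus)
}

#' @export
print.aln <- function(x, ...) {
  cat("Aligned sequence set: ", nrow(x), " individuals x ", ncol(x),
      " sites", if (!is.null(attr(x, "locus")))
        paste0(" [", attr(x, "locus"), "]"), "\n", sep = "")
  invisible(x)
}

aln_ids <- function(aln) rownames(aln)

#' Write an alignment to FASTA
#'
#' @param aln An `aln` object.
#' @param path Output path.
#' @param width Line-wrap width (default 70 columns).
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path, width = 70) {
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  out <- unlist(lapply(seq_along(seqs), function(i) {
    s <- seqs[i]
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1L, nchar(s)))
    c(paste0(">", names(seqs)[i]), chunks)
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a population map
#'
#' Reads a delimited table (TSV or CSV, autodetected from the header line)
#' mapping individuals to sampling localities, with optional regional group
#' and coordinates.  Expected columns: `individual`, `locality`, and
#' optionally `group`, `lat`, `lon`; any further columns are kept as-is.
#'
#' @param path Path to the table.
#' @return A data frame of class `popmap`.
#' @export
read_population_map <- function(path) {
  if (!file.exists(path)) stop("population map not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  as_popmap(df)
}

#' Build a population map from a data frame
#'
#' @param df Data frame with at least `individual` and `locality` columns.
#' @return A `popmap` data frame.
#' @export
as_popmap <- function(df) {
  need <- c("individual", "locality")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("population map lacks column(s): ", paste(miss, collapse = ", "))
  df$individual <- as.character(df$individual)
  df$locality <- as.character(df$locality)
  if (any(!nzchar(df$locality))) stop("empty locality codes in population map")
  if (anyDuplicated(df$individual))
    stop("duplicated individual id(s) in population map: ",
         paste(unique(df$individual[duplicated(df$individual)]), collapse = ", "))
  if (!"group" %in% names(df)) df$group <- NA_character_
  class(df) <- c("popmap", "data.frame")
  df
}

popmap_localities <- function(pm, ids = NULL) {
  loc <- stats::setNames(pm$locality, pm$individual)
  if (is.null(ids)) return(loc)
  miss <- setdiff(ids, names(loc))
  if (length(miss))
    stop("individual(s) missing from population map: ",
         paste(miss, collapse = ", "))
  loc[ids]
}

#' Remove alignment columns containing gaps or Ns
#'
#' Complete-deletion gap handling: any column in which at least one
#' sequence carries `-` or `N` is removed, so every downstream statistic is
#' computed on one consistent site set.  A pairwise-deletion alternative is
#' not applied here; it can be emulated by masking before collapsing.
#'
#' @param aln An `aln` object.
#' @return The filtered `aln`; the retained original site indices are in
#'   attribute `kept_sites`.
#' @export
drop_gap_sites <- function(aln) {
  m <- unclass(aln)
  bad <- apply(m == "-" | m == "N", 2L, any)
  if (all(bad)) stop("all alignment columns contain gaps or Ns")
  out <- m[, !bad, drop = FALSE]
  structure(out, class = "aln", locus = attr(aln, "locus"),
            kept_sites = which(!bad))
}

#' Concatenate two locus alignments
#'
#' Inner join on individual id; individuals present in only one locus are
#' dropped and reported in the `dropped` attribute.
#'
#' @param a,b `aln` objects for the two loci.
#' @return Concatenated `aln` of length `ncol(a) + ncol(b)`.
#' @export
concatenate_loci <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (!length(common)) stop("no shared individuals between the two loci")
  dropped <- setdiff(union(rownames(a), rownames(b)), common)
  if (length(dropped))
    message(length(dropped), " individual(s) missing from one locus dropped: ",
            paste(dropped, collapse = ", "))
  out <- cbind(unclass(a)[common, , drop = FALSE],
               unclass(b)[common, , drop = FALSE])
  locus <- paste(c(attr(a, "locus"), attr(b, "locus")), collapse = "+")
  structure(out, class = "aln", locus = if (nzchar(locus)) locus else NULL,
            dropped = dropped)
}

#' Collapse identical sequences into haplotypes
#'
#' Identical sequences (exact string equality) are merged into haplotypes
#' with per-locality counts.  Haplotypes are ordered by decreasing total
#' count, ties broken by first occurrence, and labelled `H01`, `H02`, ...
#'
#' @param aln An `aln` object.
#' @param pm A `popmap` covering every individual in `aln`.
#' @return A `haplotype_table`: list with `haplotypes` (data frame of
#'   `haplotype_id`, `sequence`, `total`), `counts` (haplotype x locality
#'   count matrix), and `assignment` (individual id -> haplotype id).
#' @export
collapse_haplotypes <- function(aln, pm) {
  loc <- popmap_localities(pm, rownames(aln))
  seqs <- apply(unclass(aln), 1L, paste, collapse = "")
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  idx <- match(seqs, uniq)
  tot <- tabulate(idx, nbins = length(uniq))
  ord <- order(-tot, seq_along(uniq))
  uniq <- uniq[ord]
  tot <- tot[ord]
  idx <- match(seqs, uniq)
  hid <- sprintf("H%0*d", max(2L, nchar(length(uniq))), seq_along(uniq))
  locs <- sort(unique(loc))
  counts <- table(factor(hid[idx], levels = hid),
                  factor(loc, levels = locs))
  counts <- matrix(as.integer(counts), nrow = length(hid),
                   dimnames = list(hid, locs))
  structure(list(
    haplotypes = data.frame(haplotype_id = hid, sequence = uniq,
                            total = tot, stringsAsFactors = FALSE),
    counts = counts,
    assignment = stats::setNames(hid[idx], rownames(aln))
  ), class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table: ", nrow(x$haplotypes), " haplotypes, ",
      sum(x$haplotypes$total), " individuals, ",
      ncol(x$counts), " localities\n", sep = "")
  invisible(x)
}

#' Alignment of unique haplotype sequences
#'
#' @param ht A `haplotype_table`.
#' @return An `aln` whose rows are the haplotype sequences, named by
#'   haplotype id.
#' @export
haplotype_alignment <- function(ht) {
  as_aln(stats::setNames(ht$haplotypes$sequence, ht$haplotypes$haplotype_id))
}

#' Write a haplotype table as CSV
#'
#' Emits one row per haplotype with its sequence, total count and one
#' count column per locality.
#'
#' @param ht A `haplotype_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(ht, path) {
  df <- cbind(ht$haplotypes, as.data.frame(ht$counts))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Exclude under-sampled localities
#'
#' Localities with fewer than `min_n` sequenced individuals are removed
#' from both the population map and the alignment, for population-level
#' statistics where small samples lack power.
#'
#' @param pm A `popmap`.
#' @param aln An `aln`.
#' @param min_n Minimum number of individuals per locality (default 5).
#' @param require_two Error if fewer than 2 localities remain (default
#'   `TRUE`, since population-level statistics need at least two).
#' @return List with filtered `pm`, `aln`, and `removed` (named integer
#'   vector of excluded localities with their sample sizes).
#' @export
filter_min_sample_size <- function(pm, aln, min_n = 5, require_two = TRUE) {
  stopifnot(min_n >= 1)
  pm2 <- pm[pm$individual %in% rownames(aln), , drop = FALSE]
  sizes <- table(pm2$locality)
  drop <- names(sizes)[sizes < min_n]
  keep_ids <- pm2$individual[!pm2$locality %in% drop]
  if (require_two && length(setdiff(names(sizes), drop)) < 2L)
    stop("fewer than 2 localities remain after the min-", min_n, " filter")
  removed <- stats::setNames(as.integer(sizes[drop]), drop)
  if (length(drop))
    message("excluded ", length(drop), " localit(ies) with < ", min_n,
            " individuals: ",
            paste(sprintf("%s(%d)", drop, removed), collapse = ", "))
  list(pm = pm[pm$individual %in% keep_ids, , drop = FALSE],
       aln = structure(unclass(aln)[keep_ids, , drop = FALSE],
                       class = "aln", locus = attr(aln, "locus")),
       removed = removed)
}
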