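test_that("FASTA reading validates records and normalises characters", {
  tf <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc text", "acgu", ">b", "ACGT"), tf)
  a <- read_fasta_alignment(tf)
  expect_s3_class(a, "aln")
  expect_equal(nrow(a), 2L)
  expect_equal(ncol(a), 4L)
  expect_equal(rownames(a), c("a", "b"))
  expect_equal(unname(seq_strings(a)), c("ACGT", "ACGT"))

  writeLines(c(">a", "ACGT", ">b", "ACGTT"), tf)
  expect_error(read_fasta_alignment(tf), "length mismatch")

  writeLines(character(), tf)
  expect_error(read_fasta_alignment(tf), "no FASTA records")

  writeLines(c(">a", "ACRT"), tf)
  expect_error(read_fasta_alignment(tf), "ambiguity")
  expect_equal(unname(seq_strings(read_fasta_alignment(tf, ambiguity = "as_n"))),
               "ACNT")
})

test_that("FASTA write/read round-trips alignments exactly", {
  for (seed in 1:3) {
    a <- random_aln(7, 123, seed)
    tf <- withr::local_tempfile(fileext = ".fasta")
    write_fasta_alignment(a, tf)
    b <- read_fasta_alignment(tf)
    expect_identical(unclass(a)[, ], unclass(b)[, ])
  }
})

test_that("population maps reject duplicates and accept arbitrary codes", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("individual\tlocality", "a\tBPC", "b\tVEN", "c\tBPC"), tf)
  pm <- read_population_map(tf)
  expect_equal(nrow(pm), 3L)
  expect_setequal(unique(pm$locality), c("BPC", "VEN"))

  writeLines(c("individual,locality", "a,BPC", "a,VEN"), tf)
  expect_error(read_population_map(tf), "duplicated")
  expect_error(as_popmap(data.frame(individual = "a")), "lacks column")
})

test_that("gap/N columns are removed by complete deletion", {
  a <- mk_aln(c("ACGTACGTAC", "ACGTACGTAC"))
  expect_identical(unclass(drop_gap_sites(a))[, ], unclass(a)[, ])

  b <- mk_aln(c("ACGTACGTAC", "AC-TACGTAC"))
  expect_equal(ncol(drop_gap_sites(b)), 9L)
  expect_equal(attr(drop_gap_sites(b), "kept_sites"), c(1:2, 4:10))

  # planted gap columns vs an independent per-column scan
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(sample(c("A", "C", "G", "T"), 8 * 30, replace = TRUE), 8, 30)
    gap_cols <- sample(30, 6)
    for (g in gap_cols) m[sample(8, 1), g] <- sample(c("-", "N"), 1)
    a <- mk_aln(apply(m, 1, paste, collapse = ""))
    keep_oracle <- which(apply(m, 2, function(col) !any(col %in% c("-", "N"))))
    out <- drop_gap_sites(a)
    expect_equal(attr(out, "kept_sites"), keep_oracle)
    # idempotence
    out2 <- drop_gap_sites(out)
    expect_identical(unclass(out2)[, ], unclass(out)[, ])
  }

  expect_error(drop_gap_sites(mk_aln(c("-A", "A-"))), "all alignment columns")
})

test_that("locus concatenation inner-joins individuals and adds lengths", {
  a <- mk_aln(c(x = "ACGT", y = "ACGA", z = "ACGG"), ids = c("x", "y", "z"))
  b <- mk_aln(c(x = "TTTTTT", y = "TTTTTA", z = "TTTTTC"), ids = c("x", "y", "z"))
  ab <- concatenate_loci(a, b)
  expect_equal(ncol(ab), 10L)
  expect_equal(nrow(ab), 3L)

  b2 <- mk_aln(c("TTTTTT", "AAAAAA"), ids = c("y", "q"))
  expect_message(ab2 <- concatenate_loci(a, b2), "dropped")
  expect_equal(rownames(ab2), "y")
  expect_setequal(attr(ab2, "dropped"), c("x", "z", "q"))
  expect_error(concatenate_loci(a, mk_aln("GG", ids = "w")), "no shared")

  # order symmetry: same individuals, same per-individual characters
  ba <- concatenate_loci(b, a)
  expect_setequal(rownames(ab), rownames(ba))
  for (id in rownames(ab))
    expect_equal(sort(unclass(ab)[id, ]), sort(unclass(ba)[id, ]))
})

test_that("haplotype collapsing merges identical sequences with counts", {
  ht <- mk_ht(rep("ACGT", 4), localities = c("L1", "L1", "L2", "L2"))
  expect_equal(nrow(ht$haplotypes), 1L)
  expect_equal(unname(ht$counts[1, ]), c(2L, 2L))

  ht2 <- mk_ht(c("AAAA", "CCCC", "GGGG"))
  expect_equal(ht2$haplotypes$total, c(1L, 1L, 1L))

  # planted duplicates against a dictionary-count oracle
  set.seed(42)
  pool <- c("ACGT", "ACGA", "TCGA", "ACGT", "ACGT", "ACGA", "TTTT")
  locs <- sample(c("L1", "L2", "L3"), length(pool), replace = TRUE)
  ht3 <- mk_ht(pool, localities = locs)
  oracle <- sort(table(pool), decreasing = TRUE)
  expect_equal(sum(ht3$haplotypes$total), length(pool))
  expect_equal(ht3$haplotypes$total, as.integer(oracle))
  expect_equal(ht3$haplotypes$sequence, names(oracle))
  for (h in seq_len(nrow(ht3$haplotypes))) {
    s <- ht3$haplotypes$sequence[h]
    expect_equal(unname(ht3$counts[h, ]),
                 as.integer(table(factor(locs[pool == s],
                                         levels = colnames(ht3$counts)))))
  }
})

test_that("under-sampled localities are excluded by the min-n rule", {
  locs <- rep(c("A", "B", "C"), c(6, 5, 4))
  a <- random_aln(15, 20, seed = 3)
  pm <- mk_pm(rownames(a), locs)
  out <- filter_min_sample_size(pm, a, min_n = 5)
  expect_equal(out$removed, c(C = 4L))
  expect_setequal(unique(out$pm$locality), c("A", "B"))
  expect_equal(nrow(out$aln), 11L)

  out1 <- filter_min_sample_size(pm, a, min_n = 1)
  expect_equal(nrow(out1$aln), 15L)
  expect_length(out1$removed, 0L)

  expect_error(filter_min_sample_size(pm, a, min_n = 6), "fewer than 2")
})
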