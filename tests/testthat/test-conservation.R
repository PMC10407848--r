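toy_fasta <- ">s1\nAC-DE\n>s2\nACFDE\n"

test_that("FASTA and Clustal alignments parse identically", {
  m <- read_msa(text = toy_fasta, format = "fasta")
  expect_equal(m$ncol, 5L)
  expect_length(m$seqs, 2L)
  clustal <- paste(
    "CLUSTAL W multiple sequence alignment",
    "",
    "",
    "s1   AC-DE",
    "s2   ACFDE",
    "", sep = "\n")
  m2 <- read_msa(text = clustal, format = "clustal")
  expect_equal(m2$seqs, m$seqs)
  expect_equal(m2$ids, m$ids)
  # case normalisation and '.' gaps
  m3 <- read_msa(text = ">s1\nac.de\n>s2\nACFDE\n", format = "fasta")
  expect_equal(m3$seqs[1], "AC-DE")
})

test_that("ragged or undersized alignments are rejected", {
  expect_error(read_msa(text = ">s1\nACDE\n>s2\nAC\n", format = "fasta"))
  expect_error(protonpath:::new_msa("s1", "ACDE", "g"), "at least 2")
})

test_that("synthetic group alignments have the specified sequence counts", {
  gm <- generate_group_msas(group_msa_spec(seed = 3))
  expect_equal(unname(vapply(gm$msas, function(m) length(m$seqs),
                             integer(1))), rep(50L, 4))
  # FASTA round trip through the standard writer/reader is the identity
  f <- tempfile(fileext = ".fasta")
  write_msa_fasta(gm$msas$D, f)
  back <- read_msa(file = f, format = "fasta", group_label = "D")
  expect_identical(back$seqs, gm$msas$D$seqs)
  expect_identical(back$ids, gm$msas$D$ids)
})

test_that("reference mapping follows non-gap reference columns", {
  m <- read_msa(text = ">ref\nA-CD\n>s2\nAACD\n", format = "fasta")
  rm <- map_columns_to_reference(m, "ref")
  expect_equal(rm$col, c(1L, 3L, 4L))
  expect_equal(rm$refpos, 1:3)
  # strictly increasing partial bijection; inverse composition is identity
  expect_true(all(diff(rm$col) > 0))
  expect_equal(rm$refpos[match(rm$col, rm$col)], rm$refpos)
  # gapless reference -> identity map
  m2 <- read_msa(text = ">ref\nACDE\n>s2\nACDE\n", format = "fasta")
  rm2 <- map_columns_to_reference(m2, "ref")
  expect_equal(rm2$col, 1:4)
  expect_error(map_columns_to_reference(m, "nope"), "not present")
  # planted columns land on their planted reference positions (gapless)
  gm <- generate_group_msas(group_msa_spec(seed = 5))
  rmD <- map_columns_to_reference(gm$msas$D, "REFSEQ")
  planted_cols <- gm$ground_truth$planted$column
  expect_equal(rmD$refpos[match(planted_cols, rmD$col)], planted_cols)
})

test_that("column frequencies exclude gaps and X from the denominator", {
  m <- read_msa(text = ">a\nE\n>b\nE\n>c\nE\n>d\nE\n", format = "fasta")
  cf <- column_frequencies(m, 1)
  expect_equal(unname(cf$freq["E"]), 1.0)
  expect_equal(cf$gap_fraction, 0.0)
  expect_equal(sum(cf$freq), 1.0)

  m2 <- read_msa(text = ">a\nE\n>b\nE\n>c\n-\n>d\n-\n", format = "fasta")
  cf2 <- column_frequencies(m2, 1)
  expect_equal(unname(cf2$freq["E"]), 1.0)
  expect_equal(cf2$gap_fraction, 0.5)

  m3 <- read_msa(text = ">a\nE\n>b\nE\n>c\nD\n>d\nS\n", format = "fasta")
  cf3 <- column_frequencies(m3, 1)
  expect_equal(unname(cf3$freq[c("E", "D", "S")]), c(0.5, 0.25, 0.25))

  m4 <- read_msa(text = ">a\nE\n>b\nX\n", format = "fasta")
  cf4 <- column_frequencies(m4, 1)
  expect_equal(cf4$gap_fraction, 0.5)
  expect_equal(unname(cf4$freq["E"]), 1.0)
  expect_error(column_frequencies(m4, 9), "out of range")
})

test_that("information content matches its closed forms", {
  uniform <- rep(1 / 20, 20)
  expect_equal(information_content(uniform), 0, tolerance = 1e-9)
  single <- c(1, rep(0, 19))
  expect_equal(information_content(single), log2(20), tolerance = 1e-9)
  half <- c(0.5, 0.5, rep(0, 18))
  expect_equal(information_content(half), log2(20) - 1, tolerance = 1e-9)
  expect_equal(information_content(rep(0, 20)), 0)
  expect_error(information_content(c(-0.1, 1.1, rep(0, 18))), "negative")
})

test_that("information content is bounded and decreases as mass spreads", {
  set.seed(9)
  for (i in 1:50) {
    f <- stats::runif(20)
    f <- f / sum(f)
    ic <- information_content(f)
    expect_gte(ic, 0)
    expect_lte(ic, log2(20))
  }
  expect_lt(information_content(c(0.5, 0.5, rep(0, 18))),
            information_content(c(1, rep(0, 19))))
})

test_that("exclusivity calls contrast the target group against all others", {
  gm <- generate_group_msas(group_msa_spec(
    ncol = 30L,
    planted = data.frame(column = c(10L, 20L), group = "D", residue = "E",
                         p_cons = 1.0, stringsAsFactors = FALSE),
    seed = 21))
  profiles <- lapply(gm$msas, conservation_profile)
  refmap <- map_columns_to_reference(gm$msas$D, "REFSEQ")
  ex <- group_exclusive_conservation(profiles, refmap, 10, "D")
  expect_true(ex$exclusive)
  expect_gt(ex$score, 0.8)

  # a column conserved identically in two groups is never exclusive
  gm2 <- generate_group_msas(group_msa_spec(
    ncol = 30L,
    planted = data.frame(column = c(10L, 10L), group = c("A", "D"),
                         residue = "E", p_cons = 1.0,
                         stringsAsFactors = FALSE),
    seed = 22))
  profiles2 <- lapply(gm2$msas, conservation_profile)
  refmap2 <- map_columns_to_reference(gm2$msas$D, "REFSEQ")
  ex2 <- group_exclusive_conservation(profiles2, refmap2, 10, "D")
  expect_false(ex2$exclusive)
  expect_lt(ex2$score, 0.1)
})

test_that("a fully conserved planted column reaches the maximum information content", {
  gm <- generate_group_msas(group_msa_spec(
    ncol = 10L,
    planted = data.frame(column = 5L, group = "D", residue = "E",
                         p_cons = 1.0, stringsAsFactors = FALSE),
    seed = 8))
  pd <- conservation_profile(gm$msas$D)
  expect_equal(pd$columns$info_content[5], log2(20), tolerance = 1e-12)
  expect_equal(pd$columns$consensus[5], "E")
})

test_that("hydroxyl preference sums serine and threonine frequencies", {
  m <- read_msa(text = ">a\nS\n>b\nS\n>c\nT\n>d\nT\n", format = "fasta")
  expect_equal(hydroxyl_preference(conservation_profile(m), 1), 1.0)
  m2 <- read_msa(text = ">a\nS\n>b\nS\n>c\nA\n>d\nA\n", format = "fasta")
  expect_equal(hydroxyl_preference(conservation_profile(m2), 1), 0.5)
  # moderately conserved S/T column at the planted rates
  gm <- generate_group_msas(group_msa_spec(
    groups = data.frame(label = c("C", "D"), n_seqs = 200L,
                        stringsAsFactors = FALSE),
    ncol = 4L,
    planted = data.frame(column = c(2L, 2L), group = "D",
                         residue = c("S", "T"), p_cons = c(0.5, 0.3),
                         stringsAsFactors = FALSE),
    seed = 11))
  pd <- conservation_profile(gm$msas$D)
  expect_equal(hydroxyl_preference(pd, 2), 0.8, tolerance = 0.12)
})
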