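# Labeled-alignment IO, the discrimination criterion, insertions,
# reference mapping and identities.

toy_aln <- function() {
  labeled_alignment(
    c(a1 = "MKT-LS", a2 = "MKT-LS",
      b1 = "MRT-LS", b2 = "MRT-IS",
      REF = "MKTALS"),
    c(a1 = "famA", a2 = "famA", b1 = "famB", b2 = "famB"),
    reference_id = "REF")
}

test_that("labeled-alignment invariants are enforced on construction", {
  expect_error(labeled_alignment(c(a = "MK", b = "MKT"),
                                 c(a = "x", b = "x")),
               class = "format_error")
  expect_error(labeled_alignment(c(a = "MK", b = "MK", c = "MK"),
                                 c(a = "x", b = "x")),
               class = "label_error")
  expect_error(labeled_alignment(c(a = "MK", b = "MK", c = "MK", d = "MK"),
                                 c(a = "x", b = "x", c = "y", d = "z")),
               class = "cardinality_error")
  expect_error(labeled_alignment(c(a = "MK", b = "MK", c = "MK"),
                                 c(a = "x", b = "x", c = "y")),
               class = "cardinality_error")
})

test_that("FASTA and Clustal renderings read to the identical object", {
  g <- gen_alignment(alignment_recipe(n_per_subfamily = 17, length = 80,
                                      k_discriminating = 4, seed = 13))
  d <- withr::local_tempdir()
  write_alignment_fasta(g$alignment, file.path(d, "a.fasta"))
  write_alignment_clustal(g$alignment, file.path(d, "a.aln"))
  write_label_map(g$alignment, file.path(d, "labels.tsv"))
  a1 <- read_labeled_alignment(file.path(d, "a.fasta"),
                               file.path(d, "labels.tsv"), "REF")
  a2 <- read_labeled_alignment(file.path(d, "a.aln"),
                               file.path(d, "labels.tsv"), "REF")
  expect_identical(a1, a2)
  expect_identical(a1$seqs, g$alignment$seqs)
  expect_equal(sum(a1$labels == a1$subfamilies[1]), 17)
})

test_that("discrimination criterion: gaps, ambiguity codes, shared consensus", {
  # both families share every consensus -> empty
  shared <- labeled_alignment(
    c(a1 = "MKTL", a2 = "MKTL", b1 = "MKTL", b2 = "MKTL"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_equal(nrow(detect_discriminating_positions(shared)), 0)

  # column 1 discriminating; col 2 has a gap inside famA; col 3 carries X;
  # col 4 all-gap in famB (insertion, not a discriminating position)
  aln <- labeled_alignment(
    c(a1 = "K-XAL", a2 = "KSXAL", b1 = "RSY-L", b2 = "RSY-L"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  det <- detect_discriminating_positions(aln)
  expect_identical(det$column, 1L)
  expect_identical(det$residue_a, "K")
  expect_identical(det$residue_b, "R")
})

test_that("label-swap symmetry preserves the column set and swaps residues", {
  g <- gen_alignment(alignment_recipe(n_per_subfamily = 5, length = 60,
                                      k_discriminating = 6, seed = 9,
                                      subfamilies = c("aaa", "bbb")))
  det1 <- detect_discriminating_positions(g$alignment)
  swapped <- g$alignment
  swapped$labels <- setNames(
    ifelse(g$alignment$labels == "aaa", "zzz", "aaa"),
    names(g$alignment$labels))
  swapped$subfamilies <- sort(unique(unname(swapped$labels)))
  det2 <- detect_discriminating_positions(swapped)
  expect_identical(det1$column, det2$column)
  # "aaa" members now labeled "zzz" = alphabetically second
  expect_identical(det1$residue_a, det2$residue_b)
  expect_identical(det1$residue_b, det2$residue_a)
})

test_that("detector agrees with the brute-force column-scan oracle", {
  for (seed in 1:30) {
    g <- gen_alignment(alignment_recipe(
      n_per_subfamily = 2 + seed %% 5, length = 40 + (seed * 7) %% 50,
      k_discriminating = seed %% 8,
      background_conservation = (seed %% 10) / 10, seed = seed))
    expect_identical(detect_discriminating_positions(g$alignment)$column,
                     oracle_discriminating_columns(g$alignment),
                     info = paste("seed", seed))
  }
})

test_that("reference mapping counts non-gap reference residues", {
  aln <- labeled_alignment(
    c(a1 = "MKTRLS", a2 = "MKTRLS", b1 = "MRTKLS", b2 = "MRTKLS",
      REF = "MK--LS"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"), reference_id = "REF")
  expect_identical(map_to_reference(aln, 1), "1")
  expect_identical(map_to_reference(aln, 3), "2+1")
  expect_identical(map_to_reference(aln, 4), "2+2")
  expect_identical(map_to_reference(aln, 5), "3")
  expect_error(map_to_reference(aln, 7), class = "bounds_error")

  # strictly non-decreasing in the column index, over random alignments
  g <- gen_alignment(study_alignment_recipe(seed = 4))
  refs <- map_to_reference(g$alignment, seq_len(nchar(g$alignment$seqs[[1]])))
  nums <- as.numeric(sub("\\+", ".", refs))
  expect_true(all(diff(nums) >= 0))

  # identity mapping on a gapless reference
  g2 <- gen_alignment(alignment_recipe(n_per_subfamily = 3, length = 25,
                                       k_discriminating = 2, seed = 2))
  expect_identical(map_to_reference(g2$alignment, 1:25), as.character(1:25))
})

test_that("pairwise identity uses jointly non-gap columns", {
  aln <- labeled_alignment(
    c(x = "MKTRLSAQWE--", y = "MKTKLSAQFY-A",
      b1 = "MMMMMMMMMM--", b2 = "MMMMMMMMMMM-"),
    c(x = "A", y = "A", b1 = "B", b2 = "B"))
  # 10 jointly non-gap columns, 7 identical
  expect_equal(pairwise_identity(aln, "x", "y"), 70)
  expect_equal(pairwise_identity(aln, "y", "x"), 70)
  expect_equal(pairwise_identity(aln, "x", "x"), 100)
  disjoint <- labeled_alignment(
    c(x = "MK--", y = "--MK", b1 = "MKMK", b2 = "MKMK"),
    c(x = "A", y = "A", b1 = "B", b2 = "B"))
  expect_error(pairwise_identity(disjoint, "x", "y"),
               class = "undefined_identity")
  expect_error(pairwise_identity(aln, "x", "nope"), class = "label_error")
})

test_that("insertion detection anchors maximal gap runs to the reference", {
  gapless <- gen_alignment(alignment_recipe(n_per_subfamily = 4, length = 30,
                                            k_discriminating = 0, seed = 6))
  expect_equal(nrow(detect_insertions(gapless$alignment)), 0)

  g <- gen_alignment(alignment_recipe(
    n_per_subfamily = 5, length = 43, k_discriminating = 0,
    insertions = list(list(anchor = 10, length = 3, subfamily = "famA",
                           consensus = "WYC")), seed = 8))
  ins <- detect_insertions(g$alignment)
  expect_equal(nrow(ins), 1)
  expect_equal(ins$anchor_ref_position, 10)
  expect_equal(ins$length, 3)
  expect_equal(ins$consensus, "WYC")

  no_ref <- labeled_alignment(
    c(a1 = "MK", a2 = "MK", b1 = "MR", b2 = "MR"),
    c(a1 = "A", a2 = "A", b1 = "B", b2 = "B"))
  expect_error(detect_insertions(no_ref), class = "precondition_error")
})

test_that("study-scale fixture yields the RT and GLS insertion signature", {
  g <- gen_alignment(study_alignment_recipe(seed = 1))
  det <- detect_discriminating_positions(g$alignment)
  expect_equal(nrow(det), 24)
  # named substitutions present with their reference numbering
  expect_true(all(c("119", "186", "195", "298", "301") %in% det$ref_position))
  expect_identical(det$residue_a[det$ref_position == "195"], "G")
  expect_identical(det$residue_b[det$ref_position == "195"], "S")
  ins <- detect_insertions(g$alignment)
  expect_equal(nrow(ins), 2)
  rt <- ins[ins$consensus == "RT", ]
  gls <- ins[ins$consensus == "GLS", ]
  expect_equal(rt$anchor_ref_position, 115)   # between Thr-115 and Gly-116
  expect_equal(rt$length, 2)
  expect_equal(gls$anchor_ref_position, 186)  # directly after the PXT motif
  expect_equal(gls$length, 3)
  expect_identical(unique(ins$subfamily), "mtRF1")
})
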