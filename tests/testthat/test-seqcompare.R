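test_that("pairwise differences count substitutions and indel events", {
  d <- count_pairwise_differences("MKVTAL", "MKI-AL")
  expect_equal(d$substitutions, 1L)
  expect_equal(d$deletion_events, 1L)
  expect_equal(d$insertion_events, 0L)
  expect_equal(d$compared_columns, 5L)

  same <- count_pairwise_differences("MKVTAL", "MKVTAL")
  expect_equal(same$substitutions, 0L)
  expect_equal(same$insertion_events + same$deletion_events, 0L)

  # labels swap under argument swap; substitution count is symmetric
  a <- "MK--TALR"; b <- "MKIPTA-R"
  ab <- count_pairwise_differences(a, b)
  ba <- count_pairwise_differences(b, a)
  expect_equal(ab$substitutions, ba$substitutions)
  expect_equal(ab$insertion_events, ba$deletion_events)
  expect_equal(ab$deletion_events, ba$insertion_events)

  # ambiguity treated as missing; both-gap columns ignored
  amb <- count_pairwise_differences("MXV-A", "MTI-A")
  expect_equal(amb$substitutions, 1L)
  expect_equal(amb$compared_columns, 3L)

  expect_error(count_pairwise_differences("MKV", "MK"), "lengths differ")
  expect_error(count_pairwise_differences("MKZ", "MKV"), "invalid")
})

test_that("pairwise matrix equals the brute-force oracle on random panels", {
  set.seed(1234)
  for (rep in 1:100) {
    seqs <- random_panel_seqs(n_seqs = sample(3:6, 1),
                              len = sample(15:40, 1))
    panel <- aligned_panel(unlist(seqs))
    m <- pairwise_matrix(panel)
    expect_identical(unname(m), unname(brute_matrix(seqs)))
    expect_true(all(diag(m) == 0))
    expect_identical(m, t(m))
  }
})

test_that("reference coordinate mapping handles gaps and insertions", {
  p <- aligned_panel(c(r = "M-KV", x = "MAKV"))
  m <- map_to_reference(p, "r")
  expect_equal(m$position, c(1, 1, 2, 3))
  expect_equal(m$is_insertion, c(FALSE, TRUE, FALSE, FALSE))

  gapless <- aligned_panel(c(r = "MKVTAL", x = "MKITAL"))
  expect_equal(map_to_reference(gapless, "r")$position, 1:6)

  allgap <- aligned_panel(c(r = "----", x = "MKVT"))
  expect_error(map_to_reference(allgap, "r"), "all gaps")
  expect_error(map_to_reference(gapless, "missing"), "not in panel")
})

test_that("planted site classes are recovered from toy panels", {
  tp <- simulate_toy_panel(seed = 42, n_ancestral = 4, n_novel_fixed = 1,
                           n_novel_poly = 8)
  cs <- classify_sites(tp$panel, tp$focal_nonC4, tp$focal_C4,
                       tp$reference)
  expect_equal(nrow(cs), 13)
  expect_setequal(cs$reference_position[cs$c4_state == "ancestral"],
                  tp$truth$ancestral)
  novel <- cs[cs$c4_state == "novel", ]
  expect_equal(nrow(novel), 9)
  expect_setequal(novel$reference_position[novel$fixation == "fixed"],
                  tp$truth$novel_fixed)
  expect_setequal(novel$reference_position[novel$fixation == "polymorphic"],
                  tp$truth$novel_poly)
  # positions strictly increasing in column order, and unique
  expect_true(all(diff(cs$reference_position) > 0))
})

test_that("site classification agrees with a brute-force classifier", {
  set.seed(777)
  for (rep in 1:100) {
    n <- sample(6:9, 1)
    seqs <- random_panel_seqs(n_seqs = n, len = sample(20:35, 1),
                              gap_p = 0.05)
    ids <- names(seqs)
    groups <- stats::setNames(
      c("reference", "non-C4",
        sample(c("non-C4", "weak-C4", "C4"), n - 3, replace = TRUE), "C4"),
      c("REF", ids[2], ids[3:(n - 1)], ids[n]))
    panel <- aligned_panel(unlist(seqs), groups = groups)
    got <- classify_sites(panel, ids[2], ids[n], "REF")
    want <- brute_classify(seqs, groups, ids[2], ids[n], "REF")
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got$reference_position, want$reference_position)
      expect_equal(got$c4_state, want$c4_state)
      expect_equal(got$fixation, want$fixation)
    }
  }
})

test_that("classification is invariant to sequence order within groups", {
  tp <- simulate_toy_panel(seed = 9)
  m <- tp$panel$matrix
  g <- tp$panel$groups
  set.seed(11)
  perm <- sample(nrow(m))
  seqs <- stats::setNames(apply(m, 1, paste, collapse = "")[perm],
                          rownames(m)[perm])
  shuffled <- aligned_panel(seqs, groups = g[perm])
  a <- classify_sites(tp$panel, tp$focal_nonC4, tp$focal_C4, tp$reference)
  b <- classify_sites(shuffled, tp$focal_nonC4, tp$focal_C4, tp$reference)
  expect_equal(a[c("reference_position", "c4_state", "fixation")],
               b[c("reference_position", "c4_state", "fixation")])
})

test_that("identical focal sequences yield an empty classification", {
  p <- aligned_panel(c(REF = "MKVTAL", a = "MKVTAL", b = "MKVTAL"),
                     groups = c(REF = "reference", a = "non-C4", b = "C4"))
  cs <- classify_sites(p, "a", "b", "REF")
  expect_equal(nrow(cs), 0)
  expect_error(classify_sites(aligned_panel(c(a = "MK", b = "ML")),
                              "a", "b", "a"), "no group labels")
})

test_that("pseudogene-like sequences are flagged and excluded from fixation", {
  p <- aligned_panel(
    c(REF = "MKVTAL", nc = "MKVTAL", c1 = "MKITAL", c2 = "MKI*AL"),
    groups = c(REF = "reference", nc = "non-C4", c1 = "C4", c2 = "C4"))
  fl <- flag_pseudogenes(p)
  expect_identical(unname(fl), c(FALSE, FALSE, FALSE, TRUE))
  # with the pseudogene excluded, V->I at position 3 is fixed in C4
  cs <- classify_sites(p, "nc", "c1", "REF")
  expect_equal(cs$fixation[cs$reference_position == 3], "fixed")
  cs2 <- classify_sites(p, "nc", "c1", "REF", include_pseudogenes = TRUE)
  expect_equal(cs2$fixation[cs2$reference_position == 3], "fixed")

  # nucleotide panel: internal stop detected after translation
  nt <- aligned_panel(c(a = "ATGTAAGGGTGA", b = "ATGAAAGGGTGA"),
                      alphabet = "nt")
  expect_identical(unname(flag_pseudogenes(nt)), c(TRUE, FALSE))
})

test_that("third codon positions are extracted with frame checks", {
  expect_equal(unname(extract_third_codon_positions(c(s = "ATGGCC"))),
               "GC")
  expect_equal(unname(extract_third_codon_positions(c(s = ""))), "")
  set.seed(5)
  cds <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
               collapse = "")
  third <- extract_third_codon_positions(c(x = cds))
  expect_equal(nchar(third[[1]]), 10)
  # brute-force slice oracle
  expect_equal(unname(third),
               paste(strsplit(cds, "")[[1]][seq(3, 30, 3)], collapse = ""))
  expect_warning(extract_third_codon_positions(c(s = "ATGGC")),
                 "not divisible by 3")
  expect_warning(extract_third_codon_positions(c(s = "ATG--CGGG",
                                                 t = "ATGCCCGGG")),
                 "frame shift")
})

test_that("aligned FASTA and group tables load into a panel", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">REF some description", "MKVTAL",
               ">seqA", "MKITAL", ">seqB", "MKIT-L"), fa)
  gr <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sequence_id\tgroup", "REF\treference",
               "seqA\tnon-C4", "seqB\tC4"), gr)
  panel <- read_aligned_panel(fa, groups = gr)
  expect_s3_class(panel, "aligned_panel")
  expect_equal(panel$length, 6)
  expect_equal(unname(panel$groups["seqB"]), "C4")
  expect_equal(panel$alphabet, "aa")
  # unequal lengths and unknown groups are rejected
  expect_error(aligned_panel(c(a = "MK", b = "MKV")), "equal length")
  expect_error(aligned_panel(c(a = "MK", b = "ML"),
                             groups = c(a = "non-C4", b = "alien")),
               "unknown group")
})

test_that("the shipped synthetic example panel loads and classifies", {
  fa <- system.file("extdata", "synthetic_pepc_panel.fasta",
                    package = "c4pepc")
  gr <- system.file("extdata", "synthetic_pepc_groups.tsv",
                    package = "c4pepc")
  panel <- read_aligned_panel(fa, groups = gr)
  expect_equal(panel$alphabet, "aa")
  cs <- classify_sites(panel, "focal_nonC4", "focal_C4", "REF")
  # the fixture was generated with the default planted class counts
  expect_equal(sum(cs$c4_state == "ancestral"), 4)
  expect_equal(sum(cs$c4_state == "novel"), 4)
})
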