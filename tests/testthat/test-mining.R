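# Perfect-SSR detection, thresholds, compounding, exon subtraction.

test_that("runs below their class threshold are not reported", {
  expect_equal(nrow(find_perfect_ssrs(strrep("T", 10))), 0L)
  expect_equal(nrow(find_perfect_ssrs(strrep("T", 11))), 0L)
  expect_equal(nrow(find_perfect_ssrs(strrep("T", 12))), 1L)
  expect_equal(nrow(find_perfect_ssrs(paste0("CCGAT", strrep("AG", 5),
                                             "TCCGA"))), 0L)
})

test_that("an embedded (AG)6 is found with exact coordinates", {
  hit <- find_perfect_ssrs(paste0("ACGTCACGTC", strrep("AG", 6), "CCATGCC"))
  expect_equal(hit$motif, "AG")
  expect_equal(hit$repeats, 6L)
  expect_equal(hit$length_bp, 12L)
  expect_equal(hit$start, 11L)
  expect_equal(hit$end, 22L)
  expect_false(hit$at_edge)
})

test_that("runs are reported under their primitive motif only", {
  hit <- find_perfect_ssrs(paste0("CCTGACTGAC", strrep("AG", 6),
                                  "TCAGTCATGC"))
  expect_equal(hit$motif, "AG")
  expect_equal(hit$class, 2L)
  hit2 <- find_perfect_ssrs(paste0("CCTGACTGAC", strrep("AGT", 8),
                                   "CAGTCATGC"))
  expect_equal(hit2$motif, "AGT")
})

test_that("'N' terminates repeat runs", {
  s <- paste0(strrep("AG", 5), "N", strrep("AG", 5))
  expect_equal(nrow(find_perfect_ssrs(s)), 0L)
  s2 <- paste0(strrep("AG", 6), "N", strrep("AG", 6))
  hits <- find_perfect_ssrs(s2)
  expect_equal(hits$repeats, c(6L, 6L))
  expect_equal(hits$start, c(1L, 14L))
})

test_that("alignment coordinates are lifted through the colmap", {
  aligned <- paste0("AC--", strrep("AG", 6), "--TT")
  s <- degap(aligned, "s1", "L1")
  hit <- find_perfect_ssrs(s)
  expect_equal(hit$start, 3L)
  expect_equal(hit$aln_start, 5L)
  expect_equal(hit$aln_end, 16L)
})

test_that("overlapping maximal runs are normalized into adjacent runs", {
  hits <- find_perfect_ssrs(paste0(strrep("GTAT", 3), strrep("GT", 12)))
  expect_equal(hits$motif, c("GTAT", "GT"))
  expect_equal(hits$repeats, c(3L, 12L))
  expect_equal(hits$start, c(1L, 13L))
  expect_equal(hits$end, c(12L, 36L))
})

test_that("minimum reportable lengths hold per motif class", {
  set.seed(23)
  for (i in 1:50) {
    s <- random_test_seq(sample(100:600, 1L))
    hits <- find_perfect_ssrs(s)
    if (nrow(hits) == 0L) next
    min_len <- c(12L, 12L, 12L, 12L, 15L, 18L)[hits$class]
    expect_true(all(hits$length_bp >= min_len))
    # maximality: not extendable by one motif copy on either side
    for (j in seq_len(nrow(hits))) {
      k <- hits$class[j]
      left <- substr(s, hits$start[j] - k, hits$start[j] - 1L)
      right <- substr(s, hits$end[j] + 1L, hits$end[j] + k)
      expect_false(identical(left, hits$motif[j]))
      # right extension may legitimately belong to an adjacent compound
      # component; only flag it when no SSR starts right after
      if (!any(hits$start == hits$end[j] + 1L)) {
        expect_false(identical(right, hits$motif[j]))
      }
    }
    # no overlaps within a fragment
    if (nrow(hits) > 1L) {
      expect_true(all(hits$start[-1L] > hits$end[-nrow(hits)]))
    }
  }
})

test_that("mining matches the brute-force oracle on random sequences", {
  set.seed(31)
  for (i in 1:150) {
    s <- random_test_seq(sample(50:500, 1L))
    got <- find_perfect_ssrs(s)[, c("start", "end", "class", "repeats",
                                    "motif")]
    expect_same_ssrs(got, oracle_mine(s), info = s)
  }
})

test_that("strictly adjacent SSRs merge into compounds, gapped ones do not", {
  # zero-interruption pair
  s <- paste0("ACCTGACTGA", strrep("GTAT", 3), strrep("GT", 12), "CAGTCATGC")
  m <- merge_compound(find_perfect_ssrs(s, default_thresholds()))
  expect_equal(nrow(m$compounds), 1L)
  expect_equal(m$compounds$n_components, 2L)
  expect_equal(m$compounds$notation, "(GTAT)3(GT)12")
  expect_equal(m$compounds$total_length_bp, 36L)
  expect_true(all(!is.na(m$ssrs$compound_id)))

  # one interspersed nucleotide keeps both simple
  s2 <- paste0("ACCTGACTGA", strrep("AG", 6), "C", strrep("TG", 7),
               "ACTGTCATGC")
  m2 <- merge_compound(find_perfect_ssrs(s2))
  expect_equal(nrow(m2$compounds), 0L)
  expect_true(all(is.na(m2$ssrs$compound_id)))

  # three mutually adjacent SSRs form one 3-component compound
  s3 <- paste0("CCTGACTGAC", strrep("AAG", 4), strrep("TG", 6),
               strrep("CTTA", 3), "GACTGTCATG")
  m3 <- merge_compound(find_perfect_ssrs(s3))
  expect_equal(m3$compounds$n_components, 3L)
  expect_equal(nrow(split_compound(m3)), 3L)
})

test_that("merge_compound rejects overlapping input", {
  ssrs <- find_perfect_ssrs(paste0("CCATGCATGC", strrep("AG", 6),
                                   "TCAGTCATGC"))
  ssrs <- rbind(ssrs, ssrs)
  expect_error(merge_compound(ssrs), "overlapping")
})

test_that("split_compound tallies equal component-level tallies", {
  set.seed(41)
  for (i in 1:10) {
    s <- random_test_seq(sample(200:800, 1L))
    hits <- find_perfect_ssrs(s)
    m <- merge_compound(hits)
    # merging/splitting never loses or duplicates a component
    expect_equal(nrow(m$ssrs), nrow(hits))
    expect_equal(table(m$ssrs$class), table(hits$class))
  }
})

test_that("exon subtraction is a multiset difference", {
  full <- data.frame(
    sample_id = "s1", locus_id = "L1",
    motif = c("AG", "AG", "GAT", "T", "GCTA"),
    repeats = c(6L, 6L, 4L, 12L, 3L),
    start = c(10L, 60L, 100L, 150L, 200L),
    stringsAsFactors = FALSE)
  exon <- full[c(1L, 3L), ]
  left <- subtract_exon_ssrs(full, exon)
  expect_equal(nrow(left), 3L)
  # one of the two identical (AG)6 rows is consumed, not both
  expect_equal(sum(left$motif == "AG"), 1L)
  expect_equal(nrow(subtract_exon_ssrs(full, full)), 0L)
  expect_equal(subtract_exon_ssrs(full, full[0, ]), full)
})

test_that("exon subtraction can match positions through an offset table", {
  full <- data.frame(sample_id = "s1", locus_id = "L1",
                     motif = c("AG", "AG"), repeats = c(6L, 6L),
                     start = c(30L, 90L), stringsAsFactors = FALSE)
  exon <- data.frame(sample_id = "s1", locus_id = "L1", motif = "AG",
                     repeats = 6L, start = 10L, stringsAsFactors = FALSE)
  offsets <- data.frame(sample_id = "s1", locus_id = "L1", offset = 21L,
                        stringsAsFactors = FALSE)
  left <- subtract_exon_ssrs(full, exon, offsets)
  # only the SSR whose mapped position (30 - 21 + 1 = 10) matches goes
  expect_equal(left$start, 90L)
})
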