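# Compound normalization, phase consensus, truncation flagging.

test_that("the overlap-notation example normalizes to the simple reading", {
  nc <- normalize_compound(paste0(strrep("GTAT", 3), strrep("GT", 12)))
  expect_true(nc$compound)
  expect_equal(nc$components$motif, c("GTAT", "GT"))
  expect_equal(nc$components$repeats, c(3L, 12L))
})

test_that("a pure run stays a single perfect SSR", {
  nc <- normalize_compound(strrep("AG", 10))
  expect_false(nc$compound)
  expect_equal(nc$components$motif, "AG")
  expect_equal(nc$components$repeats, 10L)
})

test_that("segments with no qualifying segmentation come back as non-SSR", {
  nc <- normalize_compound("ACGTACGTACG")
  expect_null(nc$components)
  expect_true(is.na(nc$compound))
})

test_that("normalization is lossless and optimal on random concatenations", {
  set.seed(53)
  thr <- default_thresholds()
  for (i in 1:60) {
    k1 <- sample(1:4, 1L); k2 <- sample(1:4, 1L)
    m1 <- random_primitive_motif(k1)
    m2 <- random_primitive_motif(k2)
    seg <- paste0(strrep(m1, thr[[k1]] + sample(0:4, 1L)),
                  strrep(m2, thr[[k2]] + sample(0:4, 1L)))
    nc <- normalize_compound(seg)
    if (is.null(nc$components)) next
    # lossless: components concatenate back to the segment
    rebuilt <- paste(strrep(nc$components$motif, nc$components$repeats),
                     collapse = "")
    expect_identical(rebuilt, seg)
    # optimal under the exhaustive segmentation enumerator
    want <- oracle_best_cover(
      oracle_covers(strsplit(seg, "", fixed = TRUE)[[1L]], thr))
    expect_equal(nc$components$motif, want$motif)
    expect_equal(nc$components$repeats, want$repeats)
  }
})

test_that("phase consensus follows the non-truncated majority", {
  group <- data.frame(
    sample_id = paste0("s", 1:6),
    motif = c("AAG", "AAG", "AAG", "AAG", "AAG", "AGA"),
    repeats = c(5L, 5L, 6L, 5L, 5L, 4L),
    at_edge = c(rep(FALSE, 5L), TRUE),
    stringsAsFactors = FALSE)
  pc <- consensus_phase(group)
  expect_equal(pc$chosen, "AAG")
  # edge member relabeled, repeats untouched
  expect_equal(pc$group$motif_consensus[6L], "AAG")
  expect_equal(pc$group$repeats, group$repeats)
})

test_that("phase consensus tie-breaks lexicographically and handles one sample", {
  tie <- data.frame(sample_id = paste0("s", 1:4),
                    motif = c("GAA", "GAA", "AGA", "AGA"),
                    repeats = 5L, at_edge = FALSE,
                    stringsAsFactors = FALSE)
  expect_equal(consensus_phase(tie)$chosen, "AGA")
  solo <- data.frame(sample_id = "s1", motif = "GAA", repeats = 5L,
                     at_edge = FALSE, stringsAsFactors = FALSE)
  expect_equal(consensus_phase(solo)$chosen, "GAA")
  bad <- data.frame(sample_id = c("s1", "s2"), motif = c("AAG", "ACG"),
                    repeats = 5L, at_edge = FALSE, stringsAsFactors = FALSE)
  expect_error(consensus_phase(bad), "rotation")
})

test_that("truncation flags SSRs touching fragment edges", {
  s <- degap(paste0(strrep("AG", 6), "CCTGAAGCCA", strrep("GAT", 4)))
  ssrs <- flag_truncation(find_perfect_ssrs(s), s)
  expect_equal(ssrs$truncated, c(TRUE, TRUE))
  s2 <- degap(paste0("ACCTG", strrep("AG", 6), "CCTGA"))
  ssrs2 <- flag_truncation(find_perfect_ssrs(s2), s2)
  expect_false(any(ssrs2$truncated))
})
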