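# Grouping in alignment-column space and unique/shared/polymorphic
# classification at taxonomic tiers.

mk_ssr <- function(sample_id, locus_id, motif, repeats, aln_start,
                   truncated = FALSE) {
  data.frame(sample_id = sample_id, locus_id = locus_id, motif = motif,
             class = nchar(motif), repeats = repeats,
             start = aln_start, end = aln_start + nchar(motif) * repeats - 1L,
             length_bp = nchar(motif) * repeats,
             aln_start = aln_start,
             aln_end = aln_start + nchar(motif) * repeats - 1L,
             at_edge = truncated, truncated = truncated,
             stringsAsFactors = FALSE)
}

mk_tax <- function(ids, species, genus) {
  data.frame(sample_id = ids, species = species, genus = genus,
             voucher = NA_character_, sequencing_id = NA_character_,
             stringsAsFactors = FALSE)
}

test_that("non-equivalent motifs at one interval form separate groups", {
  ssrs <- rbind(mk_ssr("s1", "L7", "CA", 9L, 100L),
                mk_ssr("s2", "L7", "TA", 9L, 100L))
  g <- group_by_locus(ssrs)
  expect_equal(nrow(g$groups), 2L)
  expect_equal(g$groups$n_samples, c(1L, 1L))
})

test_that("rotation-equivalent overlapping SSRs join one group", {
  ssrs <- rbind(mk_ssr("s1", "L1", "AAG", 5L, 100L),
                mk_ssr("s2", "L1", "AGA", 5L, 101L),
                mk_ssr("s3", "L1", "GAA", 6L, 99L))
  g <- group_by_locus(ssrs)
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$n_members, 3L)
  expect_true(all(g$members$overlap_fraction <= 1))
})

test_that("a widely shared SSR at identical columns is one group", {
  ssrs <- do.call(rbind, lapply(paste0("s", 1:16), function(s)
    mk_ssr(s, "L221", "AG", 6L, 500L)))
  g <- group_by_locus(ssrs)
  expect_equal(nrow(g$groups), 1L)
  expect_equal(g$groups$n_samples, 16L)
})

test_that("non-overlapping SSRs stay in separate groups", {
  ssrs <- rbind(mk_ssr("s1", "L1", "AG", 6L, 100L),
                mk_ssr("s2", "L1", "AG", 6L, 200L))
  expect_equal(nrow(group_by_locus(ssrs)$groups), 2L)
  # same columns, different locus
  ssrs2 <- rbind(mk_ssr("s1", "L1", "AG", 6L, 100L),
                 mk_ssr("s2", "L2", "AG", 6L, 100L))
  expect_equal(nrow(group_by_locus(ssrs2)$groups), 2L)
})

test_that("classification follows category and tier definitions", {
  tax <- mk_tax(paste0("s", 1:6),
                c("B. echo", "B. echo", "B. simplex", "B. lunaria",
                  "S. biternatum", "Sceptridium sp."),
                c(rep("Botrychium", 4L), "Sceptridium", "Sceptridium"))
  one <- function(members) classify_group(members, tax)

  # single sample -> unique
  u <- one(data.frame(sample_id = "s1", repeats = 6L, truncated = FALSE))
  expect_equal(u$category, "unique")
  expect_equal(u$tier, "not_applicable")

  # three species of one genus, identical counts -> shared within genus
  sh <- one(data.frame(sample_id = c("s1", "s3", "s4"), repeats = 6L,
                       truncated = FALSE))
  expect_equal(sh$category, "shared")
  expect_equal(sh$tier, "within_genus")

  # two genera with differing counts -> polymorphic across genera
  po <- one(data.frame(sample_id = c("s1", "s5"), repeats = c(6L, 8L),
                       truncated = FALSE))
  expect_equal(po$category, "polymorphic")
  expect_equal(po$tier, "across_genera")

  # same species pair differing only through a truncated member:
  # polymorphic within species, flagged as an edge artifact
  tr <- one(data.frame(sample_id = c("s1", "s2"), repeats = c(6L, 4L),
                       truncated = c(FALSE, TRUE)))
  expect_equal(tr$category, "polymorphic")
  expect_equal(tr$tier, "within_species")
  expect_true(tr$edge_artifact)

  # genuine polymorphism among non-truncated members is not flagged
  gp <- one(data.frame(sample_id = c("s1", "s2"), repeats = c(6L, 8L),
                       truncated = FALSE))
  expect_false(gp$edge_artifact)

  # genus-only samples count as distinct species
  gs <- one(data.frame(sample_id = c("s5", "s6"), repeats = 6L,
                       truncated = FALSE))
  expect_equal(gs$tier, "within_genus")

  expect_error(one(data.frame(sample_id = "nope", repeats = 3L,
                              truncated = FALSE)), "missing")
})

test_that("polymorphic tier is the narrowest rank with differing counts", {
  tax <- mk_tax(paste0("s", 1:4),
                c("B. echo", "B. echo", "B. simplex", "S. biternatum"),
                c("Botrychium", "Botrychium", "Botrychium", "Sceptridium"))
  # within-species difference dominates wider spread
  m <- data.frame(sample_id = paste0("s", 1:4),
                  repeats = c(6L, 8L, 6L, 6L), truncated = FALSE)
  expect_equal(classify_group(m, tax)$tier, "within_species")
  # only cross-species difference within one genus
  m2 <- data.frame(sample_id = c("s1", "s3", "s4"),
                   repeats = c(6L, 8L, 6L), truncated = FALSE)
  expect_equal(classify_group(m2, tax)$tier, "within_genus")
})

test_that("report counts partition the SSRs and survive relabeling", {
  tax <- mk_tax(paste0("s", 1:5),
                c("B. echo", "B. simplex", "B. lunaria", "S. biternatum",
                  "H. zeylanica"),
                c("Botrychium", "Botrychium", "Botrychium", "Sceptridium",
                  "Helminthostachys"))
  ssrs <- rbind(
    mk_ssr("s1", "L1", "AG", 6L, 100L),
    mk_ssr("s2", "L1", "GA", 6L, 101L),
    mk_ssr("s4", "L1", "AG", 8L, 100L),
    mk_ssr("s1", "L2", "GAT", 4L, 50L),
    mk_ssr("s5", "L3", "T", 12L, 10L))
  g <- group_by_locus(ssrs)
  cl <- classify_groups(g, tax)
  rep <- classification_report(cl, g)
  expect_equal(sum(rep$by_category$n_ssrs), nrow(ssrs))
  expect_equal(rep$total_ssrs, nrow(ssrs))
  expect_equal(sum(rep$by_class$n_ssrs), nrow(ssrs))

  # invariance under sample reordering
  perm <- ssrs[sample(nrow(ssrs)), ]
  g2 <- group_by_locus(perm)
  cl2 <- classify_groups(g2, tax)
  rep2 <- classification_report(cl2, g2)
  expect_equal(rep2$by_category$n_ssrs, rep$by_category$n_ssrs)

  # invariance under consistent rotation relabeling of one group
  rot <- ssrs
  rot$motif[rot$motif == "GAT"] <- "ATG"
  g3 <- group_by_locus(rot)
  rep3 <- classification_report(classify_groups(g3, tax), g3)
  expect_equal(rep3$by_category$n_ssrs, rep$by_category$n_ssrs)
})
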