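# Synthetic-data generator: determinism, ledger consistency, planted-SSR
# recovery, bundled fixture.

small_cfg <- function(seed = 9001L) {
  tax <- default_taxonomy()
  # keep duplicated species and several genera so every tier is realizable
  keep <- c("P015_WE12", "P015_WH11", "P028_WD08", "P015_WD12",
            "P055_WB10", "P03_WA06", "P072_WC08", "P063_WA11",
            "P028_WE08", "P03_WE06")
  simulation_config(
    taxonomy = tax[match(keep, tax$sample_id), ],
    n_loci = 12L, locus_length_range = c(159L, 500L),
    missing_range = c(0.1, 0.5),
    plan_counts = c(unique = 2L, shared = 3L, polymorphic = 3L),
    n_compound = 1L, n_truncated = 1L, seed = seed)
}

test_that("the same seed reproduces the dataset byte for byte", {
  s1 <- simulate_dataset(small_cfg())
  s2 <- simulate_dataset(small_cfg())
  expect_identical(lapply(s1$alignments, `[[`, "sequences"),
                   lapply(s2$alignments, `[[`, "sequences"))
  expect_identical(s1$ledger, s2$ledger)
  s3 <- simulate_dataset(small_cfg(seed = 9002L))
  expect_false(identical(lapply(s1$alignments, `[[`, "sequences"),
                         lapply(s3$alignments, `[[`, "sequences")))
})

test_that("ledger categories are consistent with planted repeats", {
  sim <- simulate_dataset(small_cfg())
  led <- sim$ledger$members
  for (id in unique(led$ssr_id)) {
    m <- led[led$ssr_id == id, ]
    n_counts <- length(unique(m$expected_repeats))
    if (nrow(m) == 1L) {
      expect_equal(m$category, "unique")
    } else if (n_counts >= 2L) {
      expect_equal(unique(m$category), "polymorphic")
    } else {
      expect_equal(unique(m$category), "shared")
    }
  }
  # carriers of one SSR share alignment columns: the planted block start
  # (expected start minus truncated copies) is constant per SSR
  block_start <- led$expected_aln_start -
    (led$planted_repeats - led$expected_repeats) * led$class
  expect_true(all(tapply(block_start, led$ssr_id,
                         function(x) length(unique(x)) == 1L)))
})

test_that("mining recovers every planted SSR exactly on a small run", {
  sim <- simulate_dataset(small_cfg())
  res <- analyze_dataset(sim$alignments, sim$taxonomy)
  led <- sim$ledger$members
  mined_key <- with(res$ssrs, paste(sample_id, locus_id, motif, repeats,
                                    aln_start, aln_end, sep = ":"))
  ledger_key <- with(led, paste(sample_id, locus_id, motif,
                                expected_repeats, expected_aln_start,
                                expected_aln_end, sep = ":"))
  expect_setequal(ledger_key, mined_key)
  # nothing extra was planted by accident
  expect_equal(nrow(res$ssrs), nrow(led))
})

test_that("an unplaceable planted SSR is rejected with the locus named", {
  tax <- default_taxonomy()[1:3, ]
  plan <- list(list(
    ssr_id = "ssr001", unit_id = "ssr001", unit_pos = 1L,
    motif = "ACGGAT", class = 6L, carriers = tax$sample_id[1L],
    repeats = stats::setNames(30L, tax$sample_id[1L]),
    truncate = stats::setNames(0L, tax$sample_id[1L]),
    intended_category = "unique", category = "unique",
    tier = "not_applicable", edge_artifact = FALSE))
  cfg <- simulation_config(taxonomy = tax, n_loci = 2L,
                           locus_length_range = c(159L, 165L),
                           plant_plan = plan, seed = 1L)
  expect_error(simulate_dataset(cfg), "too short")
})

test_that("seed is mandatory", {
  expect_error(simulation_config(), "seed")
})

test_that("the bundled fixture matches its stored expected tables", {
  fx <- fixture_small()
  res <- analyze_dataset(fx$alignments, fx$taxonomy)
  dir <- withr::local_tempdir()

  got_ssrs <- file.path(dir, "ssrs.tsv")
  write_ssr_tsv(res$ssrs, got_ssrs)
  want_ssrs <- system.file("extdata", "fixture_small_ssrs.tsv",
                           package = "ssrscape")
  expect_identical(readLines(got_ssrs), readLines(want_ssrs))

  got_cls <- file.path(dir, "cls.tsv")
  utils::write.table(res$classified, got_cls, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  want_cls <- system.file("extdata", "fixture_small_classification.tsv",
                          package = "ssrscape")
  expect_identical(readLines(got_cls), readLines(want_cls))

  # densities in the stored sample table recompute from counts and bp
  tab <- res$sample_table
  body <- tab[tab$sample_id != "Total", ]
  expect_equal(body$density,
               ifelse(body$sequence_bp > 0,
                      ssr_density(body$total, pmax(body$sequence_bp, 1)),
                      NA_real_))
})
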