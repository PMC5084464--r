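test_that("a degenerate model produces identical releases", {
  m <- churn_model(n_initial = 5, n_releases = 3, p_add = 0, p_delete = 0,
                   transition_matrix = diag(nrow(default_biotype_pool())),
                   frac_ott_only_early = 0, frac_dual_id = 0,
                   frac_ott_forever = 0, n_par = 0, n_ott_1ton_same = 0,
                   n_ott_1ton_cross = 0, dual_from = 4,
                   first_release_exon_only = FALSE, seed = 71)
  corpus <- generate_corpus(m, withr::local_tempdir())
  recs <- purrr::map(corpus$releases, "records")
  expect_identical(recs[[1]], recs[[2]])
  expect_identical(recs[[2]], recs[[3]])
  expect_identical(nrow(recs[[1]]), 5L)
})

test_that("generation is byte-identical under a fixed seed", {
  m <- small_model(73, n_initial = 60, n_releases = 4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- generate_corpus(m, d1)
  c2 <- generate_corpus(m, d2)
  expect_identical(unname(tools::md5sum(c1$paths)),
                   unname(tools::md5sum(c2$paths)))
  expect_identical(c1$ledger$codes, c2$ledger$codes)
  # a different seed changes the corpus
  c3 <- generate_corpus(small_model(74, n_initial = 60, n_releases = 4),
                        withr::local_tempdir())
  expect_false(identical(c1$ledger$codes, c3$ledger$codes))
})

test_that("certain deletion empties the second release in the ledger", {
  m <- churn_model(n_initial = 8, n_releases = 2, p_add = 0, p_delete = 1,
                   frac_ott_only_early = 0, frac_dual_id = 0,
                   frac_ott_forever = 0, n_par = 0, n_ott_1ton_same = 0,
                   n_ott_1ton_cross = 0, dual_from = 3,
                   first_release_exon_only = FALSE, seed = 75)
  corpus <- generate_corpus(m, withr::local_tempdir())
  expect_identical(corpus$ledger$census$deleted[2], 8L)
  expect_identical(corpus$ledger$census$n_transcripts, c(8L, 0L))
  expect_true(all(corpus$ledger$codes[, 2] == 0L))
})

test_that("model validation rejects inconsistent parameters", {
  expect_error(churn_model(p_add = 1.5))
  tm <- default_transition_matrix(); tm[1, 1] <- 0.5
  expect_error(churn_model(transition_matrix = tm), "sum to 1")
  expect_error(churn_model(n_releases = 2, dual_from = 3,
                           n_ott_1ton_same = 1), "dual_from")
})

test_that("the ledger is self-consistent under the conservation law", {
  for (seed in c(81L, 82L, 83L)) {
    corpus <- generate_corpus(small_model(seed, n_initial = 100, n_releases = 5),
                              withr::local_tempdir())
    expect_identical(conservation_violations(corpus$ledger$census), 0L)
  }
})

test_that("verification flags a corrupted cell with its location", {
  corpus <- generate_corpus(small_model(85, n_initial = 80, n_releases = 4),
                            withr::local_tempdir())
  res <- analyze_generated(corpus)
  expect_true(verify_against_ledger(res, corpus$ledger)$pass)
  broken <- res
  i <- which(broken$compendium$codes[, 2] != 0L)[1]
  broken$compendium$codes[i, 2] <- 999L
  v <- verify_against_ledger(broken, corpus$ledger)
  expect_false(v$pass)
  expect_match(v$mismatches[1], broken$compendium$ids[i], fixed = TRUE)
})

test_that("the ledger round-trips through its JSON serialization", {
  corpus <- generate_corpus(small_model(87, n_initial = 50, n_releases = 4),
                            withr::local_tempdir())
  p <- withr::local_tempfile(fileext = ".json")
  write_ledger_json(corpus$ledger, p)
  back <- read_ledger_json(p)
  expect_identical(back$codes, corpus$ledger$codes)
  expect_identical(as.data.frame(back$census),
                   as.data.frame(corpus$ledger$census))
  expect_identical(back$transitions_ignore_na,
                   corpus$ledger$transitions_ignore_na)
  expect_equal(as.data.frame(back$consistency),
               as.data.frame(corpus$ledger$consistency))
})
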