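test_that("transition counting follows the two NA conventions", {
  expect_identical(count_transitions(c(36L, 36L, 36L)), 0L)
  expect_identical(count_transitions(c(36L, 36L, 36L), "NA_AS_STATE"), 0L)
  expect_identical(count_transitions(c(36L, 0L, 36L, 20L)), 1L)
  expect_identical(count_transitions(c(36L, 0L, 36L, 20L), "NA_AS_STATE"), 3L)
  # leading/trailing absence never counts
  expect_identical(count_transitions(c(0L, 36L, 20L, 0L), "NA_AS_STATE"), 1L)
  expect_identical(count_transitions(0L, "NA_AS_STATE"), 0L)
  expect_error(count_transitions(integer(0)), "empty")
})

test_that("distinct biotype counting ignores the NA state", {
  expect_identical(distinct_biotypes(c(36L, 36L, 36L)), 1L)
  expect_identical(distinct_biotypes(c(36L, 0L, 20L, 3L)), 3L)
  expect_error(distinct_biotypes(c(0L, 0L)), "no observed state")
})

test_that("a static corpus yields zero deltas, zero transformations, full consistency", {
  corpus <- generate_corpus(static_model(seed = 3, n_initial = 12),
                            withr::local_tempdir())
  res <- analyze_generated(corpus)
  cen <- res$census
  expect_true(all(cen$added[-1] == 0L))
  expect_true(all(cen$deleted[-1] == 0L))
  tr <- res$transformation
  expect_true(all(unlist(tr[-1, -1]) == 0L))
  cons <- res$consistency
  expect_identical(cons$consistent_total,
                   rep(length(res$compendium$ids), 2L))
  expect_identical(conservation_violations(cen), 0L)
})

test_that("planted class flips are counted by the transformation census", {
  # 3 transcripts flip protein coding -> lincRNA at the third release
  ids <- sprintf("ENST%011d", 1:5)
  bts <- function(flip) c(rep(if (flip) "lincRNA" else "protein_coding", 3),
                          "miRNA", "snoRNA")
  rels <- list(
    tiny_release("1", ids, bts(FALSE)),
    tiny_release("2", ids, bts(FALSE)),
    tiny_release("2a", ids, bts(TRUE))
  )
  comp <- build_compendium(rels)
  tf <- transformation_census(comp)
  expect_identical(tf$to_lncrna[3], 3L)
  expect_identical(tf$from_pc[3], 3L)
  expect_identical(tf$to_pc[3], 0L)
  agg <- attr(tf, "aggregate")
  expect_identical(agg$pc_to_lncrna_transcripts, 3L)
  expect_identical(agg$lncrna_to_pc_transcripts, 0L)
})

test_that("moonlighting sets and reversion patterns are detected", {
  rels <- list(
    tiny_release("1", c("A", "B", "C"), c("lincRNA", "protein_coding", "miRNA")),
    tiny_release("2", c("A", "B", "C"), c("protein_coding", "protein_coding", "miRNA")),
    tiny_release("2a", c("A", "B", "C"), c("lincRNA", "protein_coding", "miRNA"))
  )
  comp <- build_compendium(rels)
  mo <- moonlighting(comp)
  expect_identical(mo$overlap, "A")
  expect_identical(mo$n_reverted_lncrna, 1L)
  expect_identical(mo$n_reverted_pc, 0L)
  # disjoint classes: empty overlap
  rels2 <- list(tiny_release("1", c("A", "B"), c("lincRNA", "protein_coding")),
                tiny_release("2", c("A", "B"), c("lincRNA", "protein_coding")))
  expect_length(moonlighting(build_compendium(rels2))$overlap, 0L)
})

test_that("strict consistency coincides with zero transitions under NA_AS_STATE plus full presence", {
  corpus <- generate_corpus(small_model(17, n_initial = 150, n_releases = 5),
                            withr::local_tempdir())
  res <- analyze_generated(corpus, na_mode = "NA_AS_STATE")
  st <- res$transcript_stats
  M <- res$compendium$codes
  always <- rowSums(M != 0L) == ncol(M)
  expect_identical(st$consistent_strict, always & st$transitions == 0L)
})

test_that("dynamics statistics equal a naive re-scan of the serialized matrix", {
  corpus <- generate_corpus(small_model(23, n_initial = 150, n_releases = 5),
                            withr::local_tempdir())
  res <- analyze_generated(corpus)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_compendium_tsv(res$compendium, p)
  M <- as.matrix(readr::read_tsv(p, show_col_types = FALSE)[, -1])

  naive_trans <- apply(M, 1, function(x) {
    x <- x[x != 0L]
    if (length(x) < 2L) 0L else sum(diff(x) != 0L)
  })
  expect_identical(unname(res$transcript_stats$transitions),
                   as.integer(unname(naive_trans)))

  naive_added <- vapply(2:ncol(M), function(j) {
    sum(M[, j - 1] == 0L & M[, j] != 0L)
  }, integer(1))
  expect_identical(res$census$added[-1], naive_added)
  expect_identical(conservation_violations(res$census), 0L)
})

test_that("census and summaries reproduce the generator ledger across seeds and NA modes", {
  for (seed in c(31L, 32L, 33L)) {
    mode <- if (seed %% 2L == 0L) "NA_AS_STATE" else "IGNORE_NA"
    corpus <- generate_corpus(small_model(seed, n_initial = 150, n_releases = 5),
                              withr::local_tempdir())
    res <- analyze_generated(corpus, with_sizes = TRUE, na_mode = mode)
    v <- verify_against_ledger(res, corpus$ledger)
    expect_true(v$pass, info = paste("seed", seed, ":",
                                     paste(v$mismatches, collapse = "; ")))
  }
})
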