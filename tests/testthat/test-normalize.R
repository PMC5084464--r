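test_that("pseudo-autosomal twins collapse onto the canonical identifier", {
  rel <- tiny_release("4", c("ENST00000000001", "ENSTR0000000001", "ENST00000000002"),
                      c("lincRNA", "lincRNA", "protein_coding"))
  out <- collapse_par_ids(rel)
  expect_identical(nrow(out$release$records), 2L)
  expect_identical(out$report$dedup_collapsed, 1L)
  expect_identical(out$report$n_rewritten, 1L)
  expect_identical(nrow(out$report$conflicts), 0L)
  expect_false(any(grepl("^ENSTR", out$release$records$transcript_id)))

  # no PAR ids: identity
  rel2 <- tiny_release("4", c("ENST00000000009"), "miRNA")
  out2 <- collapse_par_ids(rel2)
  expect_identical(out2$release$records, rel2$records)
  expect_identical(out2$report$n_rewritten, 0L)

  # differing-biotype twin: both biotypes retained, conflict logged
  rel3 <- tiny_release("4", c("ENST00000000001", "ENSTR0000000001"),
                       c("lincRNA", "protein_coding"))
  out3 <- collapse_par_ids(rel3)
  expect_identical(nrow(out3$release$records), 2L)
  expect_identical(nrow(out3$report$conflicts), 1L)
  expect_identical(out3$report$conflicts$transcript_id, "ENST00000000001")
})

test_that("the _PAR_Y suffix convention collapses too", {
  rel <- tiny_release("20", c("ENST00000000005", "ENST00000000005_PAR_Y"),
                      c("snoRNA", "snoRNA"))
  out <- collapse_par_ids(rel)
  expect_identical(out$release$records$transcript_id, "ENST00000000005")
})

make_series <- function(...) list(...)

test_that("OTT ids classify into the four reconciliation cases", {
  # 1TO1: OTT alone early, dual record later
  r1 <- tiny_release("1", "OTTHUMT00000000001", "lincRNA")
  r2 <- tiny_release("2", "ENST00000000001", "lincRNA",
                     alt_ids = "OTTHUMT00000000001")
  map <- build_otthumt_map(make_series(r1, r2))
  expect_identical(map$case, "OTT_1TO1")
  expect_identical(map$canonical_id, "ENST00000000001")
  expect_identical(map$release, "ALL")

  # same-version 1-to-N: two dual records share the OTT id in one release
  r3 <- tiny_release("4", c("ENST00000000011", "ENST00000000012"),
                     c("miRNA", "miRNA"),
                     alt_ids = rep("OTTHUMT00000000002", 2))
  map2 <- build_otthumt_map(make_series(r3))
  expect_setequal(unique(map2$case), "OTT_1TON_SAME_VERSION")
  rel_entries <- map2[map2$release == "4", ]
  expect_setequal(rel_entries$canonical_id,
                  c("ENST00000000011", "ENST00000000012"))

  # cross-version 1-to-N: single partner differing between releases
  r4 <- tiny_release("5", "ENST00000000021", "snoRNA",
                     alt_ids = "OTTHUMT00000000003")
  r5 <- tiny_release("6", "ENST00000000022", "snoRNA",
                     alt_ids = "OTTHUMT00000000003")
  map3 <- build_otthumt_map(make_series(r4, r5))
  expect_setequal(unique(map3$case), "OTT_1TON_CROSS_VERSION")
  expect_identical(map3$canonical_id[map3$release == "5"], "ENST00000000021")
  expect_identical(map3$canonical_id[map3$release == "6"], "ENST00000000022")

  # unmapped: never co-occurs with an ENST partner
  r6 <- tiny_release("1", "OTTHUMT00000000009", "miRNA")
  map4 <- build_otthumt_map(make_series(r6))
  expect_identical(map4$case, "OTT_UNMAPPED")
  expect_identical(map4$canonical_id, map4$raw_id)
})

test_that("structural partner detection pairs records by biotype and exon set", {
  rec <- tiny_records(c("OTTHUMT00000000004", "ENST00000000031"),
                      c("lincRNA", "lincRNA"))
  ex <- dplyr::bind_rows(
    tiny_exons("OTTHUMT00000000004", starts = 5000L),
    tiny_exons("ENST00000000031", starts = 5000L)
  )
  rel <- new_release("2", rec, ex, "TRANSCRIPT_LINES")
  map <- build_otthumt_map(make_series(rel))
  expect_identical(map$case, "OTT_1TO1")
  expect_identical(map$canonical_id, "ENST00000000031")
})

test_that("applying the map replaces, duplicates and deduplicates as classified", {
  # pure-ENST series passes through untouched
  r <- tiny_release("7", c("ENST00000000001", "ENST00000000002"),
                    c("miRNA", "snoRNA"))
  empty_map <- build_otthumt_map(make_series(r))
  out <- apply_id_map(make_series(r), empty_map)
  expect_identical(out$releases[[1]]$records, r$records)
  expect_identical(out$report$n_passthrough, 2L)

  # same-version 1-to-N duplicates the early OTT record under both partners
  early <- tiny_release("1", "OTTHUMT00000000002", "lincRNA")
  dual <- tiny_release("4", c("ENST00000000011", "ENST00000000012"),
                       c("miRNA", "miRNA"),
                       alt_ids = rep("OTTHUMT00000000002", 2))
  series <- make_series(early, dual)
  map <- build_otthumt_map(series)
  out2 <- apply_id_map(series, map)
  expect_setequal(out2$releases[[1]]$records$transcript_id,
                  c("ENST00000000011", "ENST00000000012"))
  expect_true(all(out2$releases[[1]]$records$biotype == "lincRNA"))
  expect_identical(out2$report$n_duplicated_records, 1L)

  # conservation: out = in - dedup + duplications
  n_in <- nrow(early$records) + nrow(dual$records)
  n_out <- sum(vapply(out2$releases, function(x) nrow(x$records), integer(1)))
  expect_identical(n_out,
                   n_in - out2$report$dedup_collapsed +
                     out2$report$n_duplicated_records)

  # idempotence
  out3 <- apply_id_map(out2$releases, map)
  expect_identical(
    purrr::map(out3$releases, "records"),
    purrr::map(out2$releases, "records")
  )

  # a map referencing a foreign release is rejected
  bad <- map
  bad$release[1] <- "24"
  expect_error(apply_id_map(series, bad), "not in the series")
})

test_that("normalization recovers the generator's planted identifier cases", {
  corpus <- generate_corpus(small_model(5), withr::local_tempdir())
  norm <- normalize_releases(corpus$releases, catalog = corpus$catalog)
  got <- norm$map |>
    dplyr::distinct(raw_id, case) |>
    dplyr::count(case, name = "n")
  want <- corpus$ledger$ott_cases |> dplyr::count(case, name = "n")
  expect_identical(as.data.frame(got), as.data.frame(want))
  # per-id assignment matches exactly
  got_ids <- norm$map |> dplyr::distinct(raw_id, case) |> dplyr::arrange(raw_id)
  want_ids <- corpus$ledger$ott_cases |>
    dplyr::rename(raw_id = ott_id) |> dplyr::arrange(raw_id)
  expect_identical(got_ids$case, want_ids$case)
  # PAR bookkeeping matches the planted pairs
  expect_identical(norm$report$par$dedup_collapsed,
                   corpus$ledger$expected_dedup$par)
})

test_that("id maps round-trip through their TSV serialization", {
  r1 <- tiny_release("1", "OTTHUMT00000000001", "lincRNA")
  r2 <- tiny_release("2", "ENST00000000001", "lincRNA",
                     alt_ids = "OTTHUMT00000000001")
  map <- build_otthumt_map(make_series(r1, r2))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_id_map(map, p)
  back <- read_id_map(p)
  expect_identical(as.data.frame(back), as.data.frame(map))
})
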