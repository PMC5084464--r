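test_that("absent releases encode as the NA state 0", {
  r1 <- tiny_release("1", "ENST00000000001", "protein_coding")
  r2 <- tiny_release("2", c("ENST00000000001", "ENST00000000002"),
                     c("protein_coding", "lincRNA"))
  comp <- build_compendium(list(r1, r2))
  expect_identical(unname(comp$codes["ENST00000000002", ]), c(0L, 20L))
  expect_identical(unname(comp$codes["ENST00000000001", ]), c(36L, 36L))
  expect_error(build_compendium(list()), "empty")
})

test_that("version suffixes collapse to one row across releases", {
  r1 <- tiny_release("1", "ENST00000000001.2", "protein_coding")
  r2 <- tiny_release("2", "ENST00000000001.3", "lincRNA")
  norm <- normalize_releases(list(r1, r2))
  comp <- build_compendium(norm$releases)
  expect_identical(comp$ids, "ENST00000000001")
  expect_identical(unname(comp$codes[1, ]), c(36L, 20L))
})

test_that("matrix construction is stable under record order permutation", {
  withr::local_seed(21)
  corpus <- generate_corpus(small_model(9, n_initial = 80, n_releases = 4),
                            withr::local_tempdir())
  rels <- purrr::map(corpus$releases, function(r) {
    perm <- sample.int(nrow(r$records))
    new_release(r$label, r$records[perm, ], r$exons, r$dialect)
  })
  c1 <- build_compendium(normalize_releases(rels, catalog = corpus$catalog)$releases)
  c2 <- build_compendium(normalize_releases(corpus$releases,
                                            catalog = corpus$catalog)$releases)
  expect_identical(c1$codes, c2$codes)
})

test_that("column nonzero counts equal normalized per-release record counts", {
  corpus <- generate_corpus(small_model(13, n_initial = 120, n_releases = 5),
                            withr::local_tempdir())
  norm <- normalize_releases(corpus$releases, catalog = corpus$catalog)
  comp <- build_compendium(norm$releases)
  got <- colSums(comp$codes != 0L)
  want <- vapply(norm$releases, function(r) nrow(r$records), integer(1))
  expect_identical(as.integer(unname(got)), want)
})

test_that("same-release biotype conflicts prefer the HAVANA record and are logged", {
  rec <- tiny_records(c("ENST00000000001", "ENST00000000001"),
                      c("lincRNA", "protein_coding"),
                      sources = c("ENSEMBL", "HAVANA"))
  ex <- tiny_exons(rec$transcript_id)
  rel <- new_release("1", rec, ex)
  comp <- build_compendium(list(rel))
  expect_identical(unname(comp$codes[1, 1]), 36L)
  expect_identical(nrow(comp$conflicts), 1L)
})

test_that("trajectories report the full per-release state sequence", {
  r1 <- tiny_release("1", "ENST00000000001", "protein_coding")
  r2 <- tiny_release("2", "ENST00000000002", "lincRNA")
  r3 <- tiny_release("2a", "ENST00000000001", "antisense")
  comp <- build_compendium(list(r1, r2, r3))
  tr <- trajectory(comp, "ENST00000000001.7")   # suffix tolerated
  expect_identical(tr$code, c(36L, 0L, 3L))
  expect_identical(tr$class, c("PROTEIN_CODING", "NA", "LNCRNA"))
  expect_identical(tr$biotype[2], NA_character_)
  expect_error(trajectory(comp, "ENST99999999999"), "not in compendium")
})

test_that("biotype presence tracks planted usage windows", {
  # miRNA only in the first two releases; lincRNA throughout
  rels <- list(
    tiny_release("1", c("T1", "T2"), c("lincRNA", "miRNA")),
    tiny_release("2", c("T1", "T2"), c("lincRNA", "miRNA")),
    tiny_release("2a", c("T1", "T2"), c("lincRNA", "lincRNA"))
  )
  comp <- build_compendium(rels)
  pm <- presence_matrix(comp)
  mirna <- pm$presence[pm$presence$biotype == "mirna", ]
  expect_identical(unname(unlist(mirna[, c("1", "2", "2a")])),
                   c(TRUE, TRUE, FALSE))
  expect_identical(pm$present_in_all, "lincrna")
  expect_identical(pm$absent_from_final, "mirna")
})

test_that("tidy and glance views agree with the matrix", {
  corpus <- generate_corpus(static_model(seed = 2), withr::local_tempdir())
  comp <- build_compendium(
    normalize_releases(corpus$releases, catalog = corpus$catalog)$releases)
  long <- tidy(comp)
  expect_identical(nrow(long), length(comp$ids) * length(comp$labels))
  expect_identical(sum(long$code != 0L), sum(comp$codes != 0L))
  g <- glance(comp)
  expect_identical(g$n_transcripts, length(comp$ids))
  expect_identical(g$n_releases, 3L)
  # wide TSV serialization round-trips the codes
  p <- withr::local_tempfile(fileext = ".tsv")
  write_compendium_tsv(comp, p)
  back <- readr::read_tsv(p, show_col_types = FALSE)
  m2 <- as.matrix(back[, -1])
  storage.mode(m2) <- "integer"
  expect_identical(unname(m2), unname(comp$codes))
})
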