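test_that("dialect detection distinguishes exon-only files from full files", {
  attrs <- 'gene_id "G1"; transcript_id "T1"; transcript_type "protein_coding";'
  exon_only <- write_gtf_lines(c(
    "# comment",
    paste("chr1", "HAVANA", "exon", "100", "200", ".", "+", ".", attrs,
          sep = "\t"),
    paste("chr1", "HAVANA", "exon", "300", "400", ".", "+", ".", attrs,
          sep = "\t")
  ))
  expect_identical(detect_gtf_dialect(exon_only), "EXON_ONLY")

  full <- write_gtf_lines(c(
    paste("chr1", "ENSEMBL", "transcript", "100", "400", ".", "+", ".", attrs,
          sep = "\t"),
    paste("chr1", "ENSEMBL", "exon", "100", "200", ".", "+", ".", attrs,
          sep = "\t")
  ))
  expect_identical(detect_gtf_dialect(full), "TRANSCRIPT_LINES")

  empty <- write_gtf_lines(character(0))
  expect_error(detect_gtf_dialect(empty), class = "annochron_format_error")
  expect_error(detect_gtf_dialect(file.path(tempdir(), "no-such-file.gtf")))
})

test_that("exon grouping yields one record per transcript with all exons", {
  attrs <- 'gene_id "G1"; transcript_id "ENST00000000001"; transcript_type "lincRNA";'
  path <- write_gtf_lines(vapply(c(100L, 300L, 500L), function(s) {
    paste("chr1", "HAVANA", "exon", s, s + 99L, ".", "+", ".", attrs,
          sep = "\t")
  }, character(1)))
  rel <- read_gtf_release(path, "1")
  expect_identical(nrow(rel$records), 1L)
  expect_identical(nrow(rel$exons), 3L)
  expect_identical(rel$records$biotype, "lincRNA")
  expect_identical(rel$dialect, "EXON_ONLY")
  expect_identical(rel$records$source, "HAVANA")
})

test_that("biotype attribute key fallback covers drifted spellings", {
  line <- paste("chr1", "ENSEMBL", "transcript", "1", "100", ".", "+", ".",
                'gene_id "G"; transcript_id "T1"; transcript_biotype "miRNA";',
                sep = "\t")
  rel <- read_gtf_release(write_gtf_lines(line), "4")
  expect_identical(rel$records$biotype, "miRNA")
})

test_that("parse errors name the offending line", {
  lines <- c(
    paste("chr1", "X", "transcript", "1", "100", ".", "+", ".",
          'gene_id "G"; transcript_id "T1"; transcript_type "miRNA";',
          sep = "\t"),
    paste("chr1", "X", "transcript", "1", "100", ".", "+", ".",
          'gene_id "G";', sep = "\t")
  )
  expect_error(read_gtf_release(write_gtf_lines(lines), "4"),
               "line 2", class = "annochron_parse_error")
  expect_error(read_gtf_release(write_gtf_lines(lines[1]), "nope"),
               "catalog")
})

test_that("within-file conflicting duplicate ids keep first and warn", {
  mk <- function(bt) {
    paste("chr1", "X", "transcript", "1", "100", ".", "+", ".",
          sprintf('gene_id "G"; transcript_id "T1"; transcript_type "%s";', bt),
          sep = "\t")
  }
  path <- write_gtf_lines(c(mk("miRNA"), mk("miRNA"), mk("lincRNA")))
  expect_warning(rel <- read_gtf_release(path, "4"), "conflicting")
  expect_identical(rel$records$biotype, "miRNA")
  expect_identical(rel$parse_report$dup_collapsed, 1L)
  expect_identical(nrow(rel$parse_report$conflicts), 2L)
})

test_that("write-read round trip preserves records and exons, and re-writing is byte identical", {
  corpus <- generate_corpus(small_model(3, n_initial = 100, n_releases = 4),
                            withr::local_tempdir())
  for (i in c(1L, 4L)) {   # exon-only dialect and dual-id dialect
    rel <- corpus$releases[[i]]
    p1 <- withr::local_tempfile(fileext = ".gtf")
    write_gtf_release(rel, p1)
    back <- read_gtf_release(p1, rel$label)
    expect_identical(back$dialect, rel$dialect)
    expect_identical(
      dplyr::arrange(back$records, transcript_id, biotype),
      dplyr::arrange(rel$records, transcript_id, biotype)
    )
    expect_identical(
      dplyr::arrange(back$exons, transcript_id, start),
      dplyr::arrange(rel$exons, transcript_id, start)
    )
    p2 <- withr::local_tempfile(fileext = ".gtf")
    write_gtf_release(back, p2)
    expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  }
})

test_that("gzip-compressed input is read transparently", {
  line <- paste("chr1", "ENSEMBL", "transcript", "1", "100", ".", "+", ".",
                'gene_id "G"; transcript_id "T1"; transcript_type "miRNA";',
                sep = "\t")
  gz <- withr::local_tempfile(fileext = ".gtf.gz")
  con <- gzfile(gz, "w"); writeLines(line, con); close(con)
  rel <- read_gtf_release(gz, "2")
  expect_identical(rel$records$transcript_id, "T1")
})
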