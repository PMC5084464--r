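mask_union <- function(exons, chrom_len = 1e6) {
  # brute-force boolean-mask oracle
  total <- 0
  for (ch in unique(exons$chrom)) {
    mask <- logical(chrom_len)
    s <- exons[exons$chrom == ch, , drop = FALSE]
    for (k in seq_len(nrow(s))) mask[s$start[k]:s$end[k]] <- TRUE
    total <- total + sum(mask)
  }
  total
}

release_from_exons <- function(exons) {
  ids <- unique(exons$transcript_id)
  new_release("1", tiny_records(ids, rep("lincRNA", length(ids))), exons,
              "TRANSCRIPT_LINES")
}

test_that("interval unions merge overlap and adjacency", {
  ex <- tibble::tibble(transcript_id = c("T1", "T2"), chrom = "chr1",
                       start = c(1L, 51L), end = c(100L, 150L), strand = "+")
  expect_identical(exon_union_length(release_from_exons(ex))$bases, 150)
  ex2 <- tibble::tibble(transcript_id = c("T1", "T2"), chrom = "chr1",
                        start = c(1L, 101L), end = c(100L, 200L), strand = "+")
  expect_identical(exon_union_length(release_from_exons(ex2))$bases, 200)
})

test_that("union length matches the boolean-mask oracle on random fixtures", {
  withr::local_seed(41)
  starts <- sample.int(999000L, 300L, replace = TRUE)
  ex <- tibble::tibble(
    transcript_id = sprintf("T%03d", seq_along(starts)),
    chrom = sample(c("chr1", "chr2"), length(starts), replace = TRUE),
    start = starts, end = starts + sample.int(900L, length(starts),
                                              replace = TRUE),
    strand = "+"
  )
  got <- sum(exon_union_length(release_from_exons(ex))$bases)
  expect_identical(got, mask_union(ex))
})

test_that("union length is invariant to input order and interval splitting", {
  withr::local_seed(43)
  starts <- sample.int(50000L, 50L)
  ex <- tibble::tibble(transcript_id = sprintf("T%02d", 1:50), chrom = "chr1",
                       start = starts, end = starts + 400L, strand = "+")
  base <- sum(exon_union_length(release_from_exons(ex))$bases)
  perm <- ex[sample.int(nrow(ex)), ]
  expect_identical(sum(exon_union_length(release_from_exons(perm))$bases), base)
  # split the first interval in two adjacent halves
  split1 <- dplyr::bind_rows(
    ex[-1, ],
    tibble::tibble(transcript_id = "T01a", chrom = "chr1",
                   start = ex$start[1], end = ex$start[1] + 199L, strand = "+"),
    tibble::tibble(transcript_id = "T01b", chrom = "chr1",
                   start = ex$start[1] + 200L, end = ex$end[1], strand = "+")
  )
  expect_identical(sum(exon_union_length(release_from_exons(split1))$bases), base)
})

test_that("transcribed fraction uses the whole assembly as denominator", {
  sizes <- tibble::tibble(chrom = c("chr1", "chr2"), size = c(500, 500))
  u <- tibble::tibble(chrom = "chr1", bases = 100)
  expect_identical(transcribed_fraction(u, sizes), 10)
  expect_identical(
    transcribed_fraction(tibble::tibble(chrom = character(0),
                                        bases = double(0)), sizes), 0)
  expect_error(transcribed_fraction(tibble::tibble(chrom = "chrX", bases = 1),
                                    sizes), "chrX")
})

test_that("coverage is monotone non-decreasing as records are added", {
  withr::local_seed(47)
  starts <- sample.int(900000L, 40L)
  ex <- tibble::tibble(transcript_id = sprintf("T%02d", 1:40), chrom = "chr1",
                       start = starts, end = starts + 300L, strand = "+")
  sizes <- tibble::tibble(chrom = "chr1", size = 1e6)
  fr <- vapply(c(10L, 20L, 40L), function(k) {
    transcribed_fraction(exon_union_length(release_from_exons(ex[1:k, ])),
                         sizes)
  }, double(1))
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr <= 100))
})

test_that("chrom.sizes files parse and validate", {
  p <- withr::local_tempfile(fileext = ".chrom.sizes")
  writeLines(c("chr1\t1000000", "chr2\t500000"), p)
  sz <- read_chrom_sizes(p)
  expect_identical(sz$size, c(1e6, 5e5))
  p2 <- withr::local_tempfile(fileext = ".chrom.sizes")
  writeLines(c("chr1\t10", "chr1\t20"), p2)
  expect_error(read_chrom_sizes(p2), "duplicate")
})
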