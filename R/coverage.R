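#' Read a chromosome-sizes table
#'
#' Standard two-column `chrom.sizes` TSV: chromosome name, length in bases.
#'
#' @param path File path.
#' @param assembly Optional assembly label attached as an attribute.
#' @return A tibble with columns `chrom`, `size`.
#' @export
read_chrom_sizes <- function(path, assembly = NA_character_) {
  tb <- readr::read_tsv(path, col_names = c("chrom", "size"),
                        col_types = "cd")
  if (anyDuplicated(tb$chrom)) stopf("duplicate chromosome names in '%s'", path)
  if (any(tb$size <= 0)) stopf("non-positive chromosome length in '%s'", path)
  attr(tb, "assembly") <- assembly
  tb
}

#' Exon interval-union length per chromosome
#'
#' Length of the union of all exon intervals of a release, per chromosome
#' (1-based inclusive coordinates; adjacent intervals merge, strands and
#' transcript identity are ignored — overlapping annotation counts once).
#'
#' @param release An `annotation_release`.
#' @return A tibble with columns `chrom`, `bases`.
#' @export
exon_union_length <- function(release) {
  ex <- release$exons
  if (nrow(ex) == 0L) return(tibble::tibble(chrom = character(0), bases = double(0)))
  parts <- split(ex, ex$chrom)
  tibble::tibble(
    chrom = names(parts),
    bases = vapply(parts, function(p) {
      sum(as.double(
        IRanges::width(IRanges::reduce(IRanges::IRanges(p$start, p$end)))
      ))
    }, double(1), USE.NAMES = FALSE)
  ) |> dplyr::arrange(.data$chrom)
}

#' Fraction of the genome covered by exons
#'
#' 100 x (total exon-union bases) / (total assembly length). Chromosomes with
#' zero coverage still count in the denominator.
#'
#' @param union_tbl Output of [exon_union_length()].
#' @param sizes Chromosome-sizes tibble; see [read_chrom_sizes()].
#' @return Percentage (scalar double).
#' @export
transcribed_fraction <- function(union_tbl, sizes) {
  missing <- setdiff(union_tbl$chrom, sizes$chrom)
  if (length(missing) > 0L) {
    stopf("covered chromosome(s) missing from sizes table: %s",
          paste(missing, collapse = ", "))
  }
  100 * sum(union_tbl$bases) / sum(sizes$size)
}

#' Per-release exon coverage table
#'
#' @param releases List of `annotation_release`.
#' @param sizes Chromosome-sizes tibble.
#' @return A tibble: `release`, `union_bases`, `pct_transcribed`.
#' @export
coverage_table <- function(releases, sizes) {
  purrr::map(releases, function(rel) {
    u <- exon_union_length(rel)
    tibble::tibble(release = rel$label,
                   union_bases = sum(u$bases),
                   pct_transcribed = transcribed_fraction(u, sizes))
  }) |> dplyr::bind_rows()
}
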