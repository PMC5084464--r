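#' Load an HGNC approved-symbol set
#'
#' Reads a tab-delimited HGNC complete-set export and returns the unique
#' approved symbols. Rows with an empty symbol cell are skipped and counted.
#'
#' @param path TSV path with a header row.
#' @param symbol_col Header name of the approved-symbol column; by default the
#'   first match among `"symbol"`, `"Approved symbol"`, `"approved_symbol"`.
#' @return A list with `symbols` (character vector), `n_skipped`, and
#'   `snapshot` (the file's modification date, as a provenance hint).
#' @export
load_hgnc_symbols <- function(path, symbol_col = NULL) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  if (is.null(symbol_col)) {
    candidates <- c("symbol", "Approved symbol", "approved_symbol")
    symbol_col <- candidates[candidates %in% names(tb)][1]
    if (is.na(symbol_col)) {
      stopf("no approved-symbol column found in '%s' (looked for: %s)",
            path, paste(candidates, collapse = ", "),
            class = "annochron_format_error")
    }
  } else if (!symbol_col %in% names(tb)) {
    stopf("column '%s' not present in '%s'", symbol_col, path,
          class = "annochron_format_error")
  }
  sym <- tb[[symbol_col]]
  empty <- is.na(sym) | !nzchar(sym)
  list(symbols = unique(sym[!empty]),
       n_skipped = sum(empty),
       snapshot = as.character(file.mtime(path)))
}

#' Overlap of genes deleted by the final release with an approved symbol set
#'
#' A gene counts as deleted when its symbol is attached to at least one
#' transcript in an earlier release but to none in the final release. Gene
#' identity is by symbol, case-sensitive. A deleted gene is classed lncRNA
#' when, in the last release where it was observed, at least one of its
#' transcripts is in the lncRNA class.
#'
#' @param comp A `compendium` built with gene names.
#' @param symbols Approved-symbol set from [load_hgnc_symbols()] (or a plain
#'   character vector).
#' @return A list with `n_deleted_genes`, `n_overlap`, `n_overlap_lncrna`,
#'   and `overlap` (tibble: `gene_name`, `last_release`, `lncrna`).
#' @export
deleted_gene_overlap <- function(comp, symbols) {
  if (is.list(symbols)) symbols <- symbols$symbols
  m <- length(comp$labels)
  final_symbols <- unique(comp$gene_names[, m][nzchar(comp$gene_names[, m]) &
                                                 comp$codes[, m] != 0L])
  clm <- class_matrix(comp)
  earlier <- tibble::tibble(
    gene_name = as.character(comp$gene_names[, -m, drop = FALSE]),
    release_idx = rep(seq_len(m - 1L), each = length(comp$ids)),
    lncrna = as.character(clm[, -m, drop = FALSE]) == "LNCRNA",
    present = as.integer(comp$codes[, -m, drop = FALSE]) != 0L
  ) |>
    dplyr::filter(.data$present, nzchar(.data$gene_name))
  candidates <- earlier |>
    dplyr::filter(!(.data$gene_name %in% final_symbols))
  if (nrow(candidates) == 0L) {
    deleted <- tibble::tibble(gene_name = character(0),
                              last_release = character(0),
                              lncrna = logical(0))
  } else {
    deleted <- candidates |>
      dplyr::group_by(.data$gene_name) |>
      dplyr::summarise(
        last_idx = max(.data$release_idx),
        lncrna = any(.data$lncrna[.data$release_idx == max(.data$release_idx)]),
        .groups = "drop"
      ) |>
      dplyr::mutate(last_release = comp$labels[.data$last_idx]) |>
      dplyr::select("gene_name", "last_release", "lncrna")
  }
  overlap <- deleted |> dplyr::filter(.data$gene_name %in% symbols)
  list(
    n_deleted_genes = nrow(deleted),
    n_overlap = nrow(overlap),
    n_overlap_lncrna = sum(overlap$lncrna),
    overlap = overlap
  )
}
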