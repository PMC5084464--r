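#' Build the transcript-by-release biotype-code matrix
#'
#' The compendium is the compiled record of all annotations across the series:
#' one row per transcript identifier observed in at least one release, one
#' column per release, each cell the integer biotype code (0 encodes the NA
#' state: transcript absent from that release). Version suffixes (".N") are
#' stripped so one accession is one row. When two normalized records share an
#' (id, release) but disagree on biotype, the record whose source is HAVANA
#' (the manual-annotation stream) wins, else the first seen; every such
#' conflict is logged.
#'
#' @param releases List of id-normalized `annotation_release` objects in
#'   chronological order.
#' @param registry Biotype registry; see [biotype_registry()].
#' @param class_map Class map used by downstream class-level statistics.
#' @return A `compendium` object: list with `ids`, `labels`, `codes` (integer
#'   matrix), `gene_names` and `gene_ids` (character matrices), `per_release`
#'   totals tibble, `registry`, `class_map`, `conflicts`.
#' @export
build_compendium <- function(releases, registry = biotype_registry(),
                             class_map = biotype_class_map()) {
  if (length(releases) == 0L) stopf("empty release list")
  labels <- vapply(releases, function(r) r$label, character(1))
  long <- purrr::map2(releases, labels, function(rel, lab) {
    rel$records |>
      dplyr::mutate(release = lab,
                    transcript_id = strip_version_suffix(.data$transcript_id))
  }) |> dplyr::bind_rows()

  canon <- canonicalize_biotype(long$biotype)
  bc <- biotype_codes(canon, registry)
  registry <- bc$registry
  long$code <- bc$code

  # same-(id, release) conflict policy: HAVANA wins, else first seen
  long$.ord <- seq_len(nrow(long))
  dup_key <- paste(long$transcript_id, long$release, sep = "\r")
  has_dup <- duplicated(dup_key) | duplicated(dup_key, fromLast = TRUE)
  conflicts <- tibble::tibble(transcript_id = character(0),
                              release = character(0),
                              biotypes = character(0))
  if (any(has_dup)) {
    dups <- long[has_dup, , drop = FALSE]
    conflicts <- dups |>
      dplyr::group_by(.data$transcript_id, .data$release) |>
      dplyr::summarise(biotypes = paste(.data$biotype, collapse = "|"),
                       .groups = "drop")
    resolved <- dups |>
      dplyr::group_by(.data$transcript_id, .data$release) |>
      dplyr::arrange(.data$source != "HAVANA", .data$.ord, .by_group = TRUE) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
    long <- dplyr::bind_rows(long[!has_dup, , drop = FALSE], resolved)
  }

  ids <- sort(unique(long$transcript_id), method = "radix")
  n <- length(ids)
  m <- length(labels)
  codes <- matrix(0L, n, m, dimnames = list(ids, labels))
  gene_names <- matrix("", n, m, dimnames = list(ids, labels))
  gene_ids <- matrix("", n, m, dimnames = list(ids, labels))
  ri <- match(long$transcript_id, ids)
  ci <- match(long$release, labels)
  codes[cbind(ri, ci)] <- long$code
  gene_names[cbind(ri, ci)] <- long$gene_name
  gene_ids[cbind(ri, ci)] <- long$gene_id

  cls <- class_of(registry$code, class_map, registry)
  class_lookup <- stats::setNames(cls, registry$code)
  per_release <- purrr::map2(releases, seq_along(labels), function(rel, j) {
    col <- codes[, j]
    nz <- col != 0L
    tibble::tibble(
      release = labels[j],
      n_transcripts = sum(nz),
      n_genes = length(unique(rel$records$gene_id[nzchar(rel$records$gene_id)])),
      n_biotypes = length(unique(col[nz])),
      n_lncrna = sum(class_lookup[as.character(col[nz])] == "LNCRNA"),
      n_pc = sum(class_lookup[as.character(col[nz])] == "PROTEIN_CODING")
    )
  }) |> dplyr::bind_rows()

  structure(
    list(ids = ids, labels = labels, codes = codes,
         gene_names = gene_names, gene_ids = gene_ids,
         per_release = per_release, registry = registry,
         class_map = class_map, conflicts = conflicts),
    class = "compendium"
  )
}

#' @export
print.compendium <- function(x, ...) {
  cat(sprintf("<compendium> %d transcripts x %d releases (%s .. %s)\n",
              length(x$ids), length(x$labels), x$labels[1],
              x$labels[length(x$labels)]))
  invisible(x)
}

# class of every cell, as a character matrix over
# {LNCRNA, PROTEIN_CODING, OTHER, NA}
class_matrix <- function(comp) {
  cls <- class_of(c(0L, comp$registry$code), comp$class_map, comp$registry)
  lookup <- stats::setNames(cls, c(0L, comp$registry$code))
  matrix(lookup[as.character(comp$codes)], nrow(comp$codes),
         ncol(comp$codes), dimnames = dimnames(comp$codes))
}

#' Per-transcript biotype trajectory
#'
#' @param comp A `compendium`.
#' @param id Transcript identifier (version suffix tolerated).
#' @return A tibble with one row per release: `release`, `code`, `biotype`
#'   (NA while absent), `class`, `gene_name`.
#' @export
trajectory <- function(comp, id) {
  key <- strip_version_suffix(id)
  i <- match(key, comp$ids)
  if (is.na(i)) stopf("transcript '%s' not in compendium", id)
  code <- comp$codes[i, ]
  tibble::tibble(
    transcript_id = key,
    release = comp$labels,
    code = unname(code),
    biotype = dplyr::if_else(
      code == 0L, NA_character_,
      comp$registry$canonical[match(code, comp$registry$code)]
    ),
    class = class_of(unname(code), comp$class_map, comp$registry),
    gene_name = unname(comp$gene_names[i, ])
  )
}

#' Presence/absence of each biotype across releases
#'
#' @param comp A `compendium`.
#' @return A list with `presence` (tibble: `biotype`, `code`, one logical
#'   column per release), `present_in_all` (biotypes used in every release)
#'   and `absent_from_final` (biotypes seen earlier but unused in the final
#'   release).
#' @export
presence_matrix <- function(comp) {
  used <- sort(unique(comp$codes[comp$codes != 0L]))
  pres <- vapply(seq_along(comp$labels), function(j) {
    used %in% comp$codes[, j]
  }, logical(length(used)))
  pres <- matrix(pres, nrow = length(used),
                 dimnames = list(NULL, comp$labels))
  names_used <- comp$registry$canonical[match(used, comp$registry$code)]
  out <- dplyr::bind_cols(
    tibble::tibble(biotype = names_used, code = used),
    tibble::as_tibble(pres)
  )
  list(
    presence = out,
    present_in_all = names_used[rowSums(pres) == ncol(pres)],
    absent_from_final = names_used[!pres[, ncol(pres)]]
  )
}

#' Serialize a compendium as wide TSV
#'
#' One row per transcript, one integer-code column per release — the exchange
#' format consumed by the dynamics and export tools.
#'
#' @param comp A `compendium`.
#' @param path Output path.
#' @export
write_compendium_tsv <- function(comp, path) {
  tb <- dplyr::bind_cols(
    tibble::tibble(transcript_id = comp$ids),
    tibble::as_tibble(comp$codes)
  )
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Long-format view of a compendium
#'
#' @param x A `compendium`.
#' @param drop_na Drop NA-state cells (absent transcript/release pairs).
#' @param ... Unused.
#' @return A tibble with `transcript_id`, `release`, `code`, `biotype`,
#'   `class`, `gene_name`.
#' @export
tidy.compendium <- function(x, drop_na = FALSE, ...) {
  n <- length(x$ids); m <- length(x$labels)
  code <- as.integer(x$codes)
  out <- tibble::tibble(
    transcript_id = rep(x$ids, times = m),
    release = rep(x$labels, each = n),
    code = code,
    biotype = dplyr::if_else(
      code == 0L, NA_character_,
      x$registry$canonical[match(code, x$registry$code)]
    ),
    class = class_of(code, x$class_map, x$registry),
    gene_name = as.character(x$gene_names)
  )
  if (drop_na) out <- out[out$code != 0L, , drop = FALSE]
  out
}

#' One-row summary of a compendium
#'
#' @param x A `compendium`.
#' @param ... Unused.
#' @export
glance.compendium <- function(x, ...) {
  clm <- class_matrix(x)
  tibble::tibble(
    n_transcripts = length(x$ids),
    n_releases = length(x$labels),
    n_biotypes_observed = length(unique(x$codes[x$codes != 0L])),
    n_ever_pc = sum(rowSums(clm == "PROTEIN_CODING") > 0L),
    n_ever_lncrna = sum(rowSums(clm == "LNCRNA") > 0L)
  )
}
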