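#' Default pseudo-autosomal identifier patterns
#'
#' Transcripts in the X/Y pseudo-autosomal regions historically carried
#' duplicate identifiers (`ENSTR`/`ENSTRR` prefixes, later `_PAR_Y` suffixes)
#' alongside the canonical `ENST0` accession. Each pattern is a regex with the
#' replacement that rewrites a PAR duplicate to its canonical form.
#'
#' @return A tibble with columns `pattern` and `replacement`, applied in order
#'   (first match wins).
#' @export
default_par_patterns <- function() {
  tibble::tibble(
    pattern = c("^ENSTRR", "^ENSTR", "_PAR_Y$"),
    replacement = c("ENST00", "ENST0", "")
  )
}

rewrite_par <- function(ids, par_patterns) {
  out <- ids
  done <- rep(FALSE, length(ids))
  for (i in seq_len(nrow(par_patterns))) {
    hit <- !done & stringr::str_detect(out, par_patterns$pattern[i])
    out[hit] <- stringr::str_replace(out[hit], par_patterns$pattern[i],
                                     par_patterns$replacement[i])
    done <- done | hit
  }
  out
}

dedup_release_records <- function(records, exons) {
  dup <- duplicated(records[, c("transcript_id", "biotype")])
  n <- sum(dup)
  if (n > 0L) {
    records <- records[!dup, , drop = FALSE]
  }
  exons <- dplyr::distinct(exons)
  list(records = records, exons = exons, n_collapsed = n)
}

#' Collapse pseudo-autosomal duplicate identifiers within a release
#'
#' Rewrites identifiers matching any configured PAR pattern to their canonical
#' form, then removes exact duplicates on (canonical id, biotype) within the
#' release. A PAR twin carrying a *different* biotype than its canonical
#' partner is retained (both biotypes kept under the canonical id) and logged
#' as a conflict.
#'
#' @param release An `annotation_release`.
#' @param par_patterns Pattern/replacement tibble; see [default_par_patterns()].
#' @return A list with `release` (collapsed) and `report`, a list holding
#'   `n_rewritten`, `dedup_collapsed` and a `conflicts` tibble
#'   (`release`, `transcript_id`, `biotypes`).
#' @export
collapse_par_ids <- function(release, par_patterns = default_par_patterns()) {
  stopifnot(inherits(release, "annotation_release"))
  rec <- release$records
  new_ids <- rewrite_par(rec$transcript_id, par_patterns)
  n_rewritten <- sum(new_ids != rec$transcript_id)
  rewritten_ids <- unique(new_ids[new_ids != rec$transcript_id])
  rec$transcript_id <- new_ids
  ex <- release$exons
  ex$transcript_id <- rewrite_par(ex$transcript_id, par_patterns)

  dd <- dedup_release_records(rec, ex)
  rec <- dd$records

  conflicts <- rec |>
    dplyr::filter(.data$transcript_id %in% rewritten_ids) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::filter(dplyr::n() > 1L) |>
    dplyr::summarise(biotypes = paste(.data$biotype, collapse = "|"),
                     .groups = "drop") |>
    dplyr::mutate(release = release$label, .before = 1L)

  out <- new_release(release$label, rec, dd$exons, release$dialect,
                     parse_report = release$parse_report)
  list(
    release = out,
    report = list(n_rewritten = n_rewritten,
                  dedup_collapsed = dd$n_collapsed,
                  conflicts = conflicts)
  )
}

partner_pairs_one_release <- function(release) {
  rec <- release$records
  # mechanism 1 (primary): both identifiers on the same record line
  dual_a <- rec |>
    dplyr::filter(is_enst_id(.data$transcript_id), !is.na(.data$alt_id),
                  is_ott_id(.data$alt_id)) |>
    dplyr::select(ott = "alt_id", enst = "transcript_id")
  dual_b <- rec |>
    dplyr::filter(is_ott_id(.data$transcript_id), !is.na(.data$alt_id),
                  is_enst_id(.data$alt_id)) |>
    dplyr::select(ott = "transcript_id", enst = "alt_id")
  # mechanism 2: separate OTT and ENST records with identical biotype and
  # identical exon span set within the release (only relevant while OTT ids
  # still appear as main record identifiers)
  if (any(is_ott_id(rec$transcript_id)) && any(is_enst_id(rec$transcript_id))) {
    sig <- exon_signature(release$exons)
    recs <- dplyr::left_join(rec, sig, by = "transcript_id")
    ott_rec <- recs |> dplyr::filter(is_ott_id(.data$transcript_id))
    enst_rec <- recs |> dplyr::filter(is_enst_id(.data$transcript_id))
    struct <- dplyr::inner_join(
      ott_rec |> dplyr::select(ott = "transcript_id", "biotype", "signature"),
      enst_rec |> dplyr::select(enst = "transcript_id", "biotype", "signature"),
      by = c("biotype", "signature"),
      relationship = "many-to-many"
    ) |>
      dplyr::filter(!is.na(.data$signature)) |>
      dplyr::select("ott", "enst")
  } else {
    struct <- tibble::tibble(ott = character(0), enst = character(0))
  }
  dplyr::bind_rows(dual_a, dual_b, struct) |>
    dplyr::distinct() |>
    dplyr::mutate(release = release$label)
}

#' Build the OTTHUMT-to-ENST identifier map across a release series
#'
#' Early releases identified transcripts by Havana (`OTTHUMT`) *or* Ensembl
#' (`ENST`) accessions; later releases carry both. Every `OTTHUMT` identifier
#' observed in the series (as a record's main id or as the companion id on an
#' Ensembl record) is classified into exactly one case:
#'
#' * `OTT_1TO1` — one ENST partner over its whole lifetime; mapped globally.
#' * `OTT_1TON_SAME_VERSION` — several ENST partners within one release;
#'   mapped to all partners of that release (a release where the id appears
#'   without partners falls back to the union of partners ever observed).
#' * `OTT_1TON_CROSS_VERSION` — different single partners in different
#'   releases; mapped per release (partnerless releases map to the
#'   chronologically nearest observed partner, earlier release winning ties).
#' * `OTT_UNMAPPED` — no ENST partner anywhere; identity mapping.
#'
#' Partners are detected from dual-identifier record lines (primary) and from
#' same-release records sharing biotype and exon span set.
#'
#' @param releases List of `annotation_release` in chronological order.
#' @param catalog Release catalog giving the chronology.
#' @return An `id_map` tibble with columns `raw_id`, `release` (`"ALL"` or a
#'   label), `canonical_id`, `case`.
#' @export
build_otthumt_map <- function(releases, catalog = gencode_releases()) {
  if (length(releases) == 0L) stopf("need at least one release")
  labels <- vapply(releases, function(r) r$label, character(1))
  ords <- catalog$ordinal[match(labels, catalog$label)]
  if (anyNA(ords)) stopf("release label(s) missing from catalog")
  if (is.unsorted(ords, strictly = TRUE)) {
    stopf("releases must be ordered chronologically")
  }

  pairs <- purrr::map(releases, partner_pairs_one_release) |> dplyr::bind_rows()
  # OTT ids needing a mapping decision: all observed anywhere in the series
  seen_main <- unlist(purrr::map(
    releases, function(r) r$records$transcript_id[is_ott_id(r$records$transcript_id)]
  ), use.names = FALSE)
  all_ott <- unique(c(seen_main, pairs$ott))
  if (length(all_ott) == 0L) {
    return(structure(
      tibble::tibble(raw_id = character(0), release = character(0),
                     canonical_id = character(0), case = character(0)),
      class = c("id_map", "tbl_df", "tbl", "data.frame")
    ))
  }
  ord_of <- function(lab) catalog$ordinal[match(lab, catalog$label)]
  main_releases <- purrr::map(releases, function(r) {
    ids <- r$records$transcript_id
    tibble::tibble(ott = ids[is_ott_id(ids)], release = r$label)
  }) |> dplyr::bind_rows() |> dplyr::distinct()

  pu <- dplyr::distinct(pairs[, c("ott", "enst", "release")])
  if (nrow(pu) == 0L) {
    partner_stats <- tibble::tibble(ott = character(0),
                                    n_partners = integer(0),
                                    max_per_release = integer(0))
  } else {
    partner_stats <- pu |>
      dplyr::group_by(.data$ott) |>
      dplyr::summarise(
        n_partners = dplyr::n_distinct(.data$enst),
        max_per_release = max(table(.data$release)),
        .groups = "drop"
      )
  }

  unmapped <- setdiff(all_ott, partner_stats$ott)
  unmapped_entries <- tibble::tibble(
    raw_id = unmapped, release = "ALL", canonical_id = unmapped,
    case = "OTT_UNMAPPED"
  )
  one_to_one <- partner_stats$ott[partner_stats$n_partners == 1L]
  one_to_one_entries <- pu |>
    dplyr::filter(.data$ott %in% one_to_one) |>
    dplyr::distinct(.data$ott, .data$enst) |>
    dplyr::transmute(raw_id = .data$ott, release = "ALL",
                     canonical_id = .data$enst, case = "OTT_1TO1")

  multi <- partner_stats |> dplyr::filter(.data$n_partners > 1L)
  multi_entries <- purrr::pmap(multi, function(ott, n_partners, max_per_release) {
    o <- ott
    p <- pu[pu$ott == o, , drop = FALSE]
    partners <- unique(p$enst)
    if (max_per_release > 1L) {
      dplyr::bind_rows(
        tibble::tibble(raw_id = o, release = p$release, canonical_id = p$enst,
                       case = "OTT_1TON_SAME_VERSION"),
        tibble::tibble(raw_id = o, release = "ALL", canonical_id = partners,
                       case = "OTT_1TON_SAME_VERSION")
      )
    } else {
      # releases where the id appears as a main id but no partner was seen:
      # adopt the chronologically nearest observed partner (earlier wins ties)
      appear <- main_releases$release[main_releases$ott == o]
      orphan <- setdiff(appear, p$release)
      orphan_map <- NULL
      if (length(orphan) > 0L) {
        obs_ord <- ord_of(p$release)
        orphan_map <- purrr::map(orphan, function(lab) {
          d <- abs(obs_ord - ord_of(lab))
          pick <- which(d == min(d))
          pick <- pick[which.min(obs_ord[pick])]
          tibble::tibble(release = lab, enst = p$enst[pick])
        }) |> dplyr::bind_rows()
      }
      dplyr::bind_rows(
        tibble::tibble(release = p$release, enst = p$enst), orphan_map
      ) |>
        dplyr::transmute(raw_id = o, release = .data$release,
                         canonical_id = .data$enst,
                         case = "OTT_1TON_CROSS_VERSION")
    }
  }) |> dplyr::bind_rows()

  entries <- dplyr::bind_rows(one_to_one_entries, multi_entries,
                              unmapped_entries)

  structure(entries, class = c("id_map", class(tibble::tibble())))
}

#' Apply an identifier map to a release series
#'
#' Replaces every record's transcript identifier according to the map;
#' release-specific entries win over `ALL` entries. An id mapping to several
#' canonical ids (same-version one-to-many case) duplicates the record, one
#' copy per canonical id, keeping the original biotype. Exact duplicates on
#' (canonical id, biotype) arising from the replacement are collapsed and
#' counted. Applying the map twice is a no-op.
#'
#' @param releases List of `annotation_release` in chronological order.
#' @param map An `id_map` from [build_otthumt_map()].
#' @return A list with `releases` (normalized) and `report`, a
#'   `normalization_report` list: per-case id counts, `dedup_collapsed`,
#'   `n_duplicated_records`, `n_passthrough`.
#' @export
apply_id_map <- function(releases, map) {
  labels <- vapply(releases, function(r) r$label, character(1))
  bad <- setdiff(unique(map$release), c("ALL", labels))
  if (length(bad) > 0L) {
    stopf("id map references release(s) not in the series: %s",
          paste(bad, collapse = ", "))
  }
  dedup_total <- 0L
  dup_records <- 0L
  out <- purrr::map(releases, function(rel) {
    rec <- rel$records
    lookup <- dplyr::bind_rows(
      map |> dplyr::filter(.data$release == rel$label),
      map |> dplyr::filter(.data$release == "ALL",
                           !(.data$raw_id %in% map$raw_id[map$release == rel$label]))
    ) |> dplyr::distinct(.data$raw_id, .data$canonical_id)
    hit <- rec$transcript_id %in% lookup$raw_id
    if (!any(hit)) return(rel)
    n_in <- nrow(rec)
    mapped <- rec[hit, , drop = FALSE] |>
      dplyr::inner_join(lookup, by = c(transcript_id = "raw_id"),
                        relationship = "many-to-many")
    ex_mapped <- rel$exons |>
      dplyr::filter(.data$transcript_id %in% rec$transcript_id[hit]) |>
      dplyr::inner_join(lookup, by = c(transcript_id = "raw_id"),
                        relationship = "many-to-many")
    mapped$transcript_id <- mapped$canonical_id
    mapped$canonical_id <- NULL
    ex_mapped$transcript_id <- ex_mapped$canonical_id
    ex_mapped$canonical_id <- NULL
    rec2 <- dplyr::bind_rows(rec[!hit, , drop = FALSE], mapped)
    ex2 <- dplyr::bind_rows(
      rel$exons |> dplyr::filter(!(.data$transcript_id %in% rec$transcript_id[hit])),
      ex_mapped
    )
    dup_records <<- dup_records + (nrow(rec2) - n_in)
    dd <- dedup_release_records(rec2, ex2)
    dedup_total <<- dedup_total + dd$n_collapsed
    new_release(rel$label, dd$records, dd$exons, rel$dialect,
                parse_report = rel$parse_report)
  })
  n_pass <- length(unique(unlist(purrr::map(
    releases, function(r) r$records$transcript_id[is_enst_id(r$records$transcript_id)]
  ), use.names = FALSE)))
  case_counts <- map |>
    dplyr::distinct(.data$raw_id, .data$case) |>
    dplyr::count(.data$case, name = "n_ids")
  report <- structure(
    list(case_counts = case_counts,
         dedup_collapsed = dedup_total,
         n_duplicated_records = dup_records,
         n_passthrough = n_pass),
    class = "normalization_report"
  )
  list(releases = out, report = report)
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("<normalization_report>\n")
  if (nrow(x$case_counts) > 0L) print(x$case_counts)
  cat(sprintf("  passthrough ENST ids: %d\n", x$n_passthrough))
  cat(sprintf("  duplicate (id, biotype) records collapsed: %d\n",
              x$dedup_collapsed))
  cat(sprintf("  records duplicated by one-to-many mapping: %d\n",
              x$n_duplicated_records))
  invisible(x)
}

strip_release_suffixes <- function(release) {
  rec <- release$records
  rec$transcript_id <- strip_version_suffix(rec$transcript_id)
  rec$alt_id <- dplyr::if_else(is.na(rec$alt_id), rec$alt_id,
                               strip_version_suffix(rec$alt_id))
  ex <- release$exons
  ex$transcript_id <- strip_version_suffix(ex$transcript_id)
  dd <- dedup_release_records(rec, ex)
  list(release = new_release(release$label, dd$records, dd$exons,
                             release$dialect, release$parse_report),
       n_collapsed = dd$n_collapsed)
}

#' Normalize a release series end to end
#'
#' Runs the full identifier-harmonization sequence: strip version suffixes
#' (".N") so one transcript is one identity across releases, collapse
#' pseudo-autosomal duplicates, build the OTTHUMT-to-ENST map, and apply it.
#'
#' @inheritParams build_otthumt_map
#' @param par_patterns See [default_par_patterns()].
#' @return A list with `releases` (normalized series), `map` (the `id_map`)
#'   and `report` (combined normalization bookkeeping).
#' @export
normalize_releases <- function(releases, par_patterns = default_par_patterns(),
                               catalog = gencode_releases()) {
  stripped <- purrr::map(releases, strip_release_suffixes)
  rels <- purrr::map(stripped, "release")
  n_suffix_dedup <- sum(vapply(stripped, function(s) s$n_collapsed, integer(1)))
  par <- purrr::map(rels, collapse_par_ids, par_patterns = par_patterns)
  rels <- purrr::map(par, "release")
  par_report <- list(
    n_rewritten = sum(vapply(par, function(p) p$report$n_rewritten, integer(1))),
    dedup_collapsed = sum(vapply(par, function(p) p$report$dedup_collapsed, integer(1))),
    conflicts = dplyr::bind_rows(purrr::map(par, function(p) p$report$conflicts))
  )
  map <- build_otthumt_map(rels, catalog = catalog)
  applied <- apply_id_map(rels, map)
  report <- applied$report
  report$par <- par_report
  report$suffix_dedup_collapsed <- n_suffix_dedup
  list(releases = applied$releases, map = map, report = report)
}

#' Write / read an identifier map as 4-column TSV
#'
#' @param map An `id_map`.
#' @param path Output path.
#' @return `path` (write) or the `id_map` (read).
#' @export
write_id_map <- function(map, path) {
  readr::write_tsv(tibble::as_tibble(map), path)
  invisible(path)
}

#' @rdname write_id_map
#' @export
read_id_map <- function(path) {
  m <- readr::read_tsv(path, col_types = "cccc")
  structure(m, class = c("id_map", class(m)))
}
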