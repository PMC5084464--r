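#' Construct an annotation release object
#'
#' An annotation release bundles the transcript records and exon spans of one
#' annotation freeze. `records` holds one row per distinct
#' (`transcript_id`, `biotype`) pair; `exons` holds the exon intervals keyed by
#' `transcript_id` (1-based inclusive coordinates).
#'
#' @param label Release label (e.g. `"2a"`).
#' @param records Tibble with columns `transcript_id`, `biotype`, `gene_id`,
#'   `gene_name`, `source`, `alt_id`.
#' @param exons Tibble with columns `transcript_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param dialect `"TRANSCRIPT_LINES"` or `"EXON_ONLY"` (the early-freeze
#'   dialect with no separate transcript records).
#' @param parse_report Optional list of load-time bookkeeping.
#' @return An object of class `"annotation_release"`.
#' @export
new_release <- function(label, records, exons,
                        dialect = c("TRANSCRIPT_LINES", "EXON_ONLY"),
                        parse_report = list()) {
  dialect <- match.arg(dialect)
  stopifnot(is.data.frame(records), is.data.frame(exons))
  if (nrow(records) > 0L) {
    if (any(!nzchar(records$transcript_id))) stopf("empty transcript_id")
    if (any(!nzchar(records$biotype))) stopf("empty biotype")
    if (anyDuplicated(records[, c("transcript_id", "biotype")])) {
      stopf("duplicate (transcript_id, biotype) records in release %s", label)
    }
  }
  if (nrow(exons) > 0L && any(exons$start > exons$end)) {
    stopf("exon with start > end in release %s", label)
  }
  structure(
    list(label = as.character(label), dialect = dialect,
         records = tibble::as_tibble(records),
         exons = tibble::as_tibble(exons),
         parse_report = parse_report),
    class = "annotation_release"
  )
}

#' @export
print.annotation_release <- function(x, ...) {
  cat(sprintf("<annotation_release> %s: %d records, %d exons (%s dialect)\n",
              x$label, nrow(x$records), nrow(x$exons), x$dialect))
  invisible(x)
}

gtf_attr <- function(attrs, key) {
  m <- stringr::str_match(
    attrs, paste0("(?:^|;\\s*)", key, "\\s+\"?([^\";]*)\"?")
  )
  m[, 2]
}

read_gtf_fields <- function(path) {
  if (!file.exists(path)) stopf("cannot read GTF: no such file '%s'", path)
  lines <- readr::read_lines(path)
  keep <- !stringr::str_starts(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stopf("'%s' contains no parseable GTF lines", path, class = "annochron_format_error")
  }
  f <- stringr::str_split_fixed(lines, "\t", 9L)
  if (any(!nzchar(f[, 9]) & !nzchar(f[, 3]))) {
    stopf("'%s' does not look like 9-column GTF", path, class = "annochron_format_error")
  }
  tibble::tibble(
    line = lineno,
    chrom = f[, 1], source = f[, 2], feature = f[, 3],
    start = suppressWarnings(as.integer(f[, 4])),
    end = suppressWarnings(as.integer(f[, 5])),
    strand = f[, 7], attrs = f[, 9]
  )
}

#' Detect the GTF dialect of an annotation file
#'
#' The first GENCODE freeze shipped only exon feature lines with no separate
#' transcript records; later freezes carry explicit `transcript` lines.
#'
#' @param path Path to a GTF file (optionally gzip-compressed).
#' @return `"EXON_ONLY"` if no line has feature `"transcript"`, else
#'   `"TRANSCRIPT_LINES"`.
#' @export
detect_gtf_dialect <- function(path) {
  fields <- read_gtf_fields(path)
  if (any(fields$feature == "transcript")) "TRANSCRIPT_LINES" else "EXON_ONLY"
}

#' Read one annotation release from a GTF file
#'
#' Tolerates the dialect drift across the release series: files with explicit
#' `transcript` lines and early exon-only files (transcripts are then derived
#' by grouping exon lines on the transcript identifier). The transcript
#' biotype is read from the first attribute key present among `biotype_keys`,
#' covering the attribute-name drift (`transcript_type` vs
#' `transcript_biotype` vs `biotype`). Comment lines are skipped. Within-file
#' duplicates on (`transcript_id`, `biotype`) are collapsed; a duplicate id
#' with a *conflicting* biotype keeps the first occurrence, warns, and is
#' logged in the parse report.
#'
#' @param path GTF file path (optionally gzip-compressed).
#' @param label Release label; must be present in `catalog`.
#' @param biotype_keys Attribute keys searched (in order) for the biotype.
#' @param alt_id_keys Attribute keys searched (in order) for a companion
#'   transcript identifier on the same record (e.g. the Havana `OTTHUMT` id
#'   carried on an Ensembl record).
#' @param catalog Release catalog used to validate `label`; see
#'   [release_catalog()] for non-GENCODE series.
#' @return An `annotation_release`.
#' @export
read_gtf_release <- function(path, label,
                             biotype_keys = c("transcript_type",
                                              "transcript_biotype", "biotype"),
                             alt_id_keys = c("havana_transcript",
                                             "ott_transcript_id",
                                             "ensembl_transcript"),
                             catalog = gencode_releases()) {
  if (!label %in% catalog$label) {
    stopf("release label '%s' is not in the catalog", label)
  }
  fields <- read_gtf_fields(path)
  fields <- fields[fields$feature %in% c("transcript", "exon"), , drop = FALSE]
  if (nrow(fields) == 0L) {
    stopf("'%s' has no transcript or exon features", path,
          class = "annochron_format_error")
  }

  fields$transcript_id <- gtf_attr(fields$attrs, "transcript_id")
  missing_tx <- is.na(fields$transcript_id) | !nzchar(fields$transcript_id)
  if (any(missing_tx)) {
    stopf("line %d of '%s' lacks a transcript_id attribute",
          fields$line[which(missing_tx)[1]], path,
          class = "annochron_parse_error")
  }

  biotype <- rep(NA_character_, nrow(fields))
  for (key in biotype_keys) {
    idx <- is.na(biotype)
    if (!any(idx)) break
    biotype[idx] <- gtf_attr(fields$attrs[idx], key)
  }
  fields$biotype <- biotype
  alt <- rep(NA_character_, nrow(fields))
  for (key in alt_id_keys) {
    idx <- is.na(alt)
    if (!any(idx)) break
    alt[idx] <- gtf_attr(fields$attrs[idx], key)
  }
  fields$alt_id <- dplyr::if_else(is.na(alt) | !nzchar(alt), NA_character_, alt)
  fields$gene_id <- dplyr::coalesce(gtf_attr(fields$attrs, "gene_id"), "")
  fields$gene_name <- dplyr::coalesce(gtf_attr(fields$attrs, "gene_name"), "")
  fields$src <- dplyr::case_when(
    stringr::str_detect(fields$source, stringr::regex("havana", ignore_case = TRUE)) ~ "HAVANA",
    stringr::str_detect(fields$source, stringr::regex("ensembl", ignore_case = TRUE)) ~ "ENSEMBL",
    .default = "OTHER"
  )

  dialect <- if (any(fields$feature == "transcript")) "TRANSCRIPT_LINES" else "EXON_ONLY"

  exons <- fields |>
    dplyr::filter(.data$feature == "exon") |>
    dplyr::select("transcript_id", "chrom", "start", "end", "strand")

  if (dialect == "TRANSCRIPT_LINES") {
    rec_lines <- fields[fields$feature == "transcript", , drop = FALSE]
    # tolerate transcripts present only as exon lines in a mixed file
    orphan <- fields[fields$feature == "exon" &
                       !(fields$transcript_id %in% rec_lines$transcript_id), ,
                     drop = FALSE]
    if (nrow(orphan) > 0L) {
      orphan <- orphan[!duplicated(orphan$transcript_id), , drop = FALSE]
    }
    rec_lines <- dplyr::bind_rows(rec_lines, orphan)
  } else {
    rec_lines <- fields[!duplicated(fields$transcript_id), , drop = FALSE]
  }

  no_bt <- is.na(rec_lines$biotype) | !nzchar(rec_lines$biotype)
  if (any(no_bt)) {
    stopf("line %d of '%s' lacks a biotype attribute (searched: %s)",
          rec_lines$line[which(no_bt)[1]], path,
          paste(biotype_keys, collapse = ", "),
          class = "annochron_parse_error")
  }

  records <- rec_lines |>
    dplyr::select("transcript_id", "biotype", "gene_id", "gene_name",
                  source = "src", "alt_id")

  exact_dup <- duplicated(records[, c("transcript_id", "biotype")])
  n_exact <- sum(exact_dup)
  records <- records[!exact_dup, , drop = FALSE]
  conflict_dup <- duplicated(records$transcript_id)
  conflicts <- tibble::tibble(
    transcript_id = character(0), biotype = character(0)
  )
  if (any(conflict_dup)) {
    conflicts <- records[records$transcript_id %in%
                           records$transcript_id[conflict_dup],
                         c("transcript_id", "biotype")]
    warnf("%d transcript id(s) in '%s' carry conflicting biotypes; keeping first",
          length(unique(records$transcript_id[conflict_dup])), path)
    records <- records[!conflict_dup, , drop = FALSE]
  }

  new_release(
    label, records, exons, dialect,
    parse_report = list(
      path = path, n_lines = nrow(fields),
      n_records = nrow(records),
      dup_collapsed = n_exact,
      conflicts = conflicts
    )
  )
}

format_gtf_attrs <- function(gene_id, transcript_id, biotype, gene_name, alt_id) {
  a <- sprintf('gene_id "%s"; transcript_id "%s"; transcript_type "%s";',
               gene_id, transcript_id, biotype)
  a <- ifelse(nzchar(gene_name),
              paste0(a, sprintf(' gene_name "%s";', gene_name)), a)
  a <- ifelse(!is.na(alt_id),
              paste0(a, sprintf(' havana_transcript "%s";', alt_id)), a)
  a
}

#' Write an annotation release as GTF
#'
#' Emits standard 9-column GTF preserving the release dialect: transcript plus
#' exon lines, or exon lines only for `EXON_ONLY` releases. Reading the file
#' back reproduces the release's (`transcript_id`, `biotype`, exon spans)
#' exactly, and a write-read-write cycle is byte identical.
#'
#' @param release An `annotation_release`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_gtf_release <- function(release, path) {
  stopifnot(inherits(release, "annotation_release"))
  rec <- release$records
  if (nrow(rec) == 0L) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  ex <- dplyr::left_join(
    release$exons,
    rec |> dplyr::mutate(.ord = dplyr::row_number()),
    by = "transcript_id",
    relationship = "many-to-many"
  )
  if (anyNA(ex$biotype)) stopf("exon without a matching record")
  exon_lines <- sprintf(
    "%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
    ex$chrom, ex$source, ex$start, ex$end, ex$strand,
    format_gtf_attrs(ex$gene_id, ex$transcript_id, ex$biotype,
                     ex$gene_name, ex$alt_id)
  )
  if (release$dialect == "EXON_ONLY") {
    lines <- exon_lines
  } else {
    gidx <- split(seq_len(nrow(release$exons)), release$exons$transcript_id)
    span <- tibble::tibble(
      transcript_id = names(gidx),
      chrom = release$exons$chrom[vapply(gidx, `[`, integer(1), 1L)],
      start = vapply(gidx, function(i) min(release$exons$start[i]), integer(1)),
      end = vapply(gidx, function(i) max(release$exons$end[i]), integer(1)),
      strand = release$exons$strand[vapply(gidx, `[`, integer(1), 1L)]
    )
    tr <- dplyr::left_join(rec, span, by = "transcript_id")
    if (anyNA(tr$start)) stopf("record without exons cannot be written")
    tx_lines <- sprintf(
      "%s\t%s\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
      tr$chrom, tr$source, tr$start, tr$end, tr$strand,
      format_gtf_attrs(tr$gene_id, tr$transcript_id, tr$biotype,
                       tr$gene_name, tr$alt_id)
    )
    # interleave: each transcript line followed by its exon lines
    all_lines <- c(tx_lines, exon_lines)
    key_rec <- c(seq_len(nrow(rec)), ex$.ord)
    key_kind <- c(rep(0L, nrow(rec)), seq_along(exon_lines))
    lines <- all_lines[order(key_rec, key_kind, method = "radix")]
  }
  readr::write_lines(lines, path)
  invisible(path)
}
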