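# fixtures are built in code: small hand-assembled releases plus a compact
# churn model for end-to-end runs

`%||%` <- function(a, b) if (is.null(a)) b else a

tiny_records <- function(ids, biotypes, gene_names = NULL, gene_ids = NULL,
                         sources = NULL, alt_ids = NULL) {
  n <- length(ids)
  tibble::tibble(
    transcript_id = ids,
    biotype = biotypes,
    gene_id = gene_ids %||% sprintf("ENSG%011d", seq_len(n)),
    gene_name = gene_names %||% sprintf("GENE%05d", seq_len(n)),
    source = sources %||% rep("ENSEMBL", n),
    alt_id = alt_ids %||% rep(NA_character_, n)
  )
}

tiny_exons <- function(ids, starts = NULL) {
  n <- length(ids)
  starts <- starts %||% (seq_len(n) * 1000L)
  tibble::tibble(
    transcript_id = ids, chrom = "chr1",
    start = starts, end = starts + 199L, strand = "+"
  )
}

tiny_release <- function(label, ids, biotypes, dialect = "TRANSCRIPT_LINES",
                         starts = NULL, ...) {
  new_release(label, tiny_records(ids, biotypes, ...),
              tiny_exons(ids, starts), dialect)
}

small_model <- function(seed, n_initial = 200, n_releases = 6, ...) {
  churn_model(n_initial = n_initial, n_releases = n_releases, seed = seed, ...)
}

# a static model: no churn, no identifier games, no dual era
static_model <- function(seed = 1, n_initial = 10, n_releases = 3) {
  churn_model(
    n_initial = n_initial, n_releases = n_releases,
    p_add = 0, p_delete = 0,
    transition_matrix = diag(nrow(default_biotype_pool())),
    frac_ott_only_early = 0, frac_dual_id = 0, frac_ott_forever = 0,
    n_par = 0, n_ott_1ton_same = 0, n_ott_1ton_cross = 0,
    dual_from = n_releases + 1L, first_release_exon_only = FALSE,
    seed = seed
  )
}

analyze_generated <- function(corpus, with_sizes = FALSE, ...) {
  sizes <- if (with_sizes) read_chrom_sizes(corpus$sizes_path)
  analyze_corpus(corpus$paths, corpus$labels, catalog = corpus$catalog,
                 sizes = sizes, ...)
}

write_gtf_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".gtf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
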