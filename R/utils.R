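# internal helpers shared across modules

stopf <- function(fmt, ..., class = "annochron_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) {
  rlang::warn(sprintf(fmt, ...))
}

# exon signature: order-insensitive fingerprint of a transcript's exon set,
# used for structural identity checks (PAR twins, OTT/ENST partner detection)
exon_signature <- function(exons) {
  if (nrow(exons) == 0L) {
    return(tibble::tibble(transcript_id = character(0),
                          signature = character(0)))
  }
  s <- paste0(exons$chrom, ":", exons$start, "-", exons$end, ":",
              exons$strand)
  parts <- split(s, exons$transcript_id)
  tibble::tibble(
    transcript_id = names(parts),
    signature = vapply(parts, function(v) paste(sort(v), collapse = ";"),
                       character(1), USE.NAMES = FALSE)
  )
}

is_ott_id <- function(x) stringr::str_starts(x, "OTTHUMT")
is_enst_id <- function(x) stringr::str_starts(x, "ENST")

# version suffixes (".N") make the same transcript look distinct across
# releases; identity across releases requires the unsuffixed accession
strip_version_suffix <- function(x) stringr::str_remove(x, "\\.\\d+$")

# seed partitioning: derive a stream seed per (base seed, block index) so
# extending a corpus with more releases never perturbs earlier ones
derive_seed <- function(seed, block) {
  as.integer((as.double(seed) * 7919 + as.double(block) * 104729 + 11) %% 2147483587)
}
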