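#' Registry of GENCODE transcript biotypes and their integer codes
#'
#' The 72 biotype names that have appeared across the GENCODE release series,
#' each with the integer code used throughout this package (0 is reserved for
#' the NA state, i.e. a transcript absent from a release). Names are stored in
#' canonical form: lower case, with underscores/hyphens mapped to spaces.
#'
#' Two historical labels, "ig gene" (code 11) and "IG gene" (code 12), differ
#' only by case; under canonicalization every raw spelling resolves to code 11,
#' and code 12 is retained in the registry for completeness but is not
#' reachable from raw strings.
#'
#' @return A tibble with columns `canonical` (canonical biotype name), `code`
#'   (integer 1-72) and `display` (the conventional mixed-case spelling).
#' @examples
#' biotype_registry()
#' @export
biotype_registry <- function() {
  display <- c(
    "3 prime overlapping ncrna", "Ambiguous orf", "Antisense", "Artifact",
    "Bidirectional promoter lncrna", "C segment", "Disrupted domain",
    "IG C gene", "IG C pseudogene", "IG D gene", "ig gene", "IG gene",
    "IG J gene", "IG J pseudogene", "IG pseudogene", "IG V gene",
    "IG V pseudogene", "J segment", "Known ncrna", "lincRNA", "macro lncRNA",
    "miRNA", "miRNA pseudogene", "misc RNA", "misc RNA pseudogene", "Mt rRNA",
    "Mt tRNA", "Mt tRNA pseudogene", "ncrna host", "Non-coding",
    "Non-stop decay", "Nonsense-mediated decay", "Polymorphic pseudogene",
    "Processed pseudogene", "Processed transcript", "Protein coding",
    "Pseudogene", "Retained intron", "Retrotransposed", "Ribozyme", "rRNA",
    "rRNA pseudogene", "scaRNA", "scRNA", "scRNA pseudogene", "Sense intronic",
    "Sense overlapping", "snoRNA", "snoRNA pseudogene", "snRNA",
    "snRNA pseudogene", "TEC", "TR C gene", "TR D gene", "TR gene",
    "TR J gene", "TR J pseudogene", "TR pseudogene", "TR V gene",
    "TR V pseudogene", "Transcribed processed pseudogene",
    "Transcribed pseudogene", "Transcribed unitary pseudogene",
    "Transcribed unprocessed pseudogene", "Translated processed pseudogene",
    "Translated unprocessed pseudogene", "tRNA pseudogene",
    "Unitary pseudogene", "Unprocessed pseudogene", "V segment", "Vaultrna",
    "sRNA"
  )
  tibble::tibble(
    canonical = normalize_biotype_string(display),
    code = seq_along(display),
    display = display
  )
}

# spelling variants seen in real GTF attribute values that do not reduce to a
# registry name by case/underscore normalization alone
default_biotype_synonyms <- function() {
  c(
    "3prime overlapping ncrna" = "3 prime overlapping ncrna",
    "vault rna"                = "vaultrna"
  )
}

normalize_biotype_string <- function(x) {
  x <- stringr::str_to_lower(x)
  x <- stringr::str_replace_all(x, "[_\\-]", " ")
  x <- stringr::str_squish(x)
  x
}

#' Canonicalize raw biotype strings
#'
#' Lower-cases, maps underscores and hyphens to spaces, collapses repeated
#' whitespace, and resolves known spelling synonyms, so that e.g.
#' `"protein_coding"`, `"Protein coding"` and `"protein-coding"` all become
#' `"protein coding"`. Idempotent.
#'
#' @param raw Character vector of raw biotype strings (non-empty).
#' @param synonyms Named character vector mapping normalized variants to
#'   canonical names; defaults cover drifted GENCODE spellings.
#' @return Character vector of canonical names.
#' @examples
#' canonicalize_biotype(c("protein_coding", "TEC", "lincRNA"))
#' @export
canonicalize_biotype <- function(raw, synonyms = default_biotype_synonyms()) {
  if (length(raw) > 0L && any(!nzchar(raw) | is.na(raw))) {
    stopf("biotype strings must be non-empty")
  }
  x <- normalize_biotype_string(raw)
  hit <- match(x, names(synonyms))
  x[!is.na(hit)] <- unname(synonyms[hit[!is.na(hit)]])
  x
}

#' Map canonical biotype names to integer codes
#'
#' Unknown names are auto-registered with fresh codes starting at 73 and a
#' warning, so a corpus using a biotype outside the historical catalog still
#' gets a stable encoding within a session's registry.
#'
#' @param canonical Character vector of canonical biotype names (see
#'   [canonicalize_biotype()]).
#' @param registry Registry tibble from [biotype_registry()], possibly already
#'   extended.
#' @return A list with `code` (integer vector, parallel to `canonical`) and
#'   `registry` (the registry, extended if new names were met).
#' @export
biotype_codes <- function(canonical, registry = biotype_registry()) {
  idx <- match(canonical, registry$canonical)
  if (anyNA(idx)) {
    new_names <- unique(canonical[is.na(idx)])
    warnf("auto-registering %d biotype name(s) outside the catalog: %s",
          length(new_names), paste(new_names, collapse = ", "))
    add <- tibble::tibble(
      canonical = new_names,
      code = max(registry$code, 72L) + seq_along(new_names),
      display = new_names
    )
    registry <- dplyr::bind_rows(registry, add)
    idx <- match(canonical, registry$canonical)
  }
  list(code = registry$code[idx], registry = registry)
}

#' The lncRNA umbrella class used for class-level statistics
#'
#' The default groups 23 sub-biotypes under the lncRNA class — lincRNA,
#' antisense, sense intronic/overlapping, processed transcript, retained
#' intron, TEC, the pseudogene subtypes, and the other historical noncoding
#' labels — mirroring how class-level lncRNA censuses are computed for the
#' GENCODE series. A stricter alternative (`strict = TRUE`) drops the
#' pseudogene subtypes, misc RNA and TEC for users who want a conservative
#' lncRNA definition.
#'
#' @param strict Logical; use the conservative membership instead of the
#'   23-member default.
#' @return A list with elements `lncrna` (canonical names in the lncRNA
#'   class) and `pc` (canonical names in the protein-coding class).
#' @examples
#' length(biotype_class_map()$lncrna)  # 23
#' @export
biotype_class_map <- function(strict = FALSE) {
  members <- c(
    "3 prime overlapping ncrna", "tec", "ambiguous orf", "antisense",
    "bidirectional promoter lncrna", "disrupted domain", "known ncrna",
    "lincrna", "macro lncrna", "misc rna", "ncrna host", "non coding",
    "processed pseudogene", "processed transcript", "pseudogene",
    "retained intron", "retrotransposed", "sense intronic",
    "sense overlapping", "transcribed processed pseudogene",
    "transcribed unprocessed pseudogene", "unitary pseudogene",
    "unprocessed pseudogene"
  )
  if (strict) {
    drop <- c(
      "tec", "misc rna", "processed pseudogene", "pseudogene",
      "transcribed processed pseudogene", "transcribed unprocessed pseudogene",
      "unitary pseudogene", "unprocessed pseudogene", "disrupted domain",
      "ambiguous orf", "retrotransposed"
    )
    members <- setdiff(members, drop)
  }
  list(lncrna = members, pc = "protein coding")
}

#' Classify biotype codes into lncRNA / protein-coding / other / NA
#'
#' @param code Integer vector of biotype codes (0 = NA state).
#' @param class_map Class map from [biotype_class_map()].
#' @param registry Registry tibble the codes were issued from.
#' @return Character vector over `{"LNCRNA", "PROTEIN_CODING", "OTHER", "NA"}`.
#' @examples
#' reg <- biotype_registry()
#' class_of(c(0L, 20L, 36L))
#' @export
class_of <- function(code, class_map = biotype_class_map(),
                     registry = biotype_registry()) {
  bad <- code != 0L & !(code %in% registry$code)
  if (any(bad)) {
    stopf("unregistered biotype code(s): %s",
          paste(unique(code[bad]), collapse = ", "))
  }
  name <- registry$canonical[match(code, registry$code)]
  out <- rep("OTHER", length(code))
  out[code == 0L] <- "NA"
  out[!is.na(name) & name %in% class_map$pc] <- "PROTEIN_CODING"
  out[!is.na(name) & name %in% class_map$lncrna] <- "LNCRNA"
  out
}
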