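#' Published headline counts for the 2008-2015 GENCODE release series
#'
#' The headline numbers reported for the longitudinal census of the 28 human
#' GENCODE freezes (V1-V24), shipped as reference inputs for analytic
#' cross-checks: e.g. the consistent-lncRNA percentage is
#' 100 x `consistent_lncrna_all` / `ever_lncrna`. These are published
#' observations on the real release series, not quantities this package
#' computes from synthetic data.
#'
#' @return A tibble with columns `quantity`, `value`.
#' @examples
#' pc <- published_counts()
#' with(as.list(stats::setNames(pc$value, pc$quantity)),
#'      100 * consistent_lncrna_all / ever_lncrna)
#' @export
published_counts <- function() {
  tibble::tribble(
    ~quantity, ~value,
    "compendium_transcripts",      251614,
    "ever_protein_coding",         114114,
    "ever_lncrna",                 120864,
    "moonlighting_overlap",        11069,
    "consistent_total",            54840,
    "consistent_pc",               32458,
    "consistent_other",            22382,
    "consistent_lncrna_all",       29512,
    "ever_noncoding",              137909,
    "mean_added_per_release",      6277,
    "mean_deleted_per_release",    2160,
    "max_added_v3b",               26715,
    "max_deleted_v20",             11410,
    "pc_to_lncrna_transcripts",    6560,
    "lncrna_to_pc_transcripts",    5463,
    "reverted_lncrna",             650,
    "reverted_pc",                 688,
    "biotypes_observed",           70,
    "biotypes_stable",             17,
    "pct_transcribed_v24",         4.18,
    "pct_transcribed_v1",          2.6,
    "hgnc_deleted_overlap",        285,
    "hgnc_deleted_overlap_lncrna", 35
  )
}

#' Consistent-lncRNA percentage from a pair of census counts
#'
#' 100 x (transcripts consistently annotated in the lncRNA class) /
#' (transcripts ever in the lncRNA class).
#'
#' @param consistent_lncrna,ever_lncrna Counts.
#' @return Percentage (double).
#' @export
pct_consistent_lncrna <- function(consistent_lncrna, ever_lncrna) {
  100 * consistent_lncrna / ever_lncrna
}
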