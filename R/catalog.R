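#' Catalog of the 28 human GENCODE releases
#'
#' The chronological catalog of GENCODE human annotation freezes analysed by
#' this package: V1 through V24 including the sub-releases 2a, 2b, 3b, 3c and
#' 3d (V3a was never published), 28 releases in total spanning 2008-2015.
#'
#' @return A tibble with columns `label` (character release label, e.g. `"2a"`),
#'   `ordinal` (0-based chronological position) and `year` (freeze year).
#' @examples
#' gencode_releases()
#' @export
gencode_releases <- function() {
  labels <- c(
    "1", "2", "2a", "2b", "3b", "3c", "3d",
    as.character(4:24)
  )
  years <- c(
    2008, 2009, 2009, 2009, 2009, 2009, 2009,
    2010, 2010, 2010, 2010,
    2011, 2011, 2011, 2011, 2011,
    2012, 2012, 2012, 2012,
    2013, 2013, 2013,
    2014, 2014, 2014,
    2015, 2015
  )
  tibble::tibble(label = labels, ordinal = seq_along(labels) - 1L, year = years)
}

#' Validate a set of release labels against a catalog
#'
#' @param labels Character vector of release labels.
#' @param catalog A release catalog tibble; defaults to [gencode_releases()].
#'   Any tibble with unique `label` and integer `ordinal` columns works, so
#'   synthetic series with labels outside the GENCODE catalog can opt in.
#' @return The input labels, invisibly, ordered by catalog ordinal.
#' @export
validate_release_labels <- function(labels, catalog = gencode_releases()) {
  if (anyDuplicated(labels)) {
    stopf("duplicate release labels: %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  unknown <- setdiff(labels, catalog$label)
  if (length(unknown) > 0L) {
    stopf("release labels not in catalog: %s", paste(unknown, collapse = ", "))
  }
  ord <- catalog$ordinal[match(labels, catalog$label)]
  invisible(labels[order(ord)])
}

#' Build a catalog for an arbitrary ordered release series
#'
#' Synthetic corpora and non-GENCODE series carry their own labels; this
#' helper turns an ordered label vector into a catalog tibble accepted by the
#' `catalog` arguments throughout the package.
#'
#' @param labels Character vector of release labels in chronological order.
#' @return A tibble with `label` and `ordinal` columns.
#' @export
release_catalog <- function(labels) {
  if (anyDuplicated(labels)) stopf("release labels must be unique")
  tibble::tibble(label = as.character(labels), ordinal = seq_along(labels) - 1L)
}
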