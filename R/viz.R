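#' Sankey flow decomposition of the compendium
#'
#' One node per (release, state); a link from state `s` at release `v` to
#' state `t` at `v+1` counts the transcripts in `s` at `v` and `t` at `v+1`.
#' The NA state (absent transcript) is a state like any other, so flows are
#' conserved: each non-terminal node's size equals the sum of its outgoing
#' link values, and each non-initial node's size the sum of its incoming ones.
#'
#' @param comp A `compendium`.
#' @param grouping `"BY_CLASS"` (lncRNA / protein coding / others / NA) or
#'   `"BY_BIOTYPE"` (one state per biotype code).
#' @return A `sankey_flow` list with `nodes` (tibble: `node_id`, `release`,
#'   `state`, `size`) and `links` (tibble: `source`, `target`, `value`,
#'   `release_from`, `release_to`, `state_from`, `state_to`).
#' @export
sankey_flows <- function(comp, grouping = c("BY_CLASS", "BY_BIOTYPE")) {
  grouping <- match.arg(grouping)
  if (grouping == "BY_CLASS") {
    S <- class_matrix(comp)
  } else {
    S <- matrix(as.character(comp$codes), nrow(comp$codes), ncol(comp$codes),
                dimnames = dimnames(comp$codes))
    S[comp$codes == 0L] <- "NA"
  }
  m <- ncol(S)
  nodes <- purrr::map(seq_len(m), function(j) {
    tb <- table(S[, j])
    tibble::tibble(release = comp$labels[j],
                   state = names(tb), size = as.integer(tb))
  }) |> dplyr::bind_rows()
  nodes$node_id <- seq_len(nrow(nodes)) - 1L
  nodes <- nodes[, c("node_id", "release", "state", "size")]
  links <- purrr::map(seq_len(m - 1L), function(j) {
    tb <- table(S[, j], S[, j + 1L])
    df <- as.data.frame(tb, stringsAsFactors = FALSE)
    names(df) <- c("state_from", "state_to", "value")
    df <- df[df$value > 0L, , drop = FALSE]
    tibble::tibble(
      release_from = comp$labels[j], release_to = comp$labels[j + 1L],
      state_from = df$state_from, state_to = df$state_to,
      value = as.integer(df$value)
    )
  }) |> dplyr::bind_rows()
  key <- paste(nodes$release, nodes$state, sep = "\r")
  links$source <- nodes$node_id[match(paste(links$release_from, links$state_from, sep = "\r"), key)]
  links$target <- nodes$node_id[match(paste(links$release_to, links$state_to, sep = "\r"), key)]
  structure(list(nodes = nodes,
                 links = links[, c("source", "target", "value", "release_from",
                                   "release_to", "state_from", "state_to")],
                 grouping = grouping),
            class = "sankey_flow")
}

#' @export
print.sankey_flow <- function(x, ...) {
  cat(sprintf("<sankey_flow> %s: %d nodes, %d links\n", x$grouping,
              nrow(x$nodes), nrow(x$links)))
  invisible(x)
}

#' @rdname sankey_flows
#' @param x A `sankey_flow`.
#' @param ... Unused.
#' @export
tidy.sankey_flow <- function(x, ...) x$links

#' Export a Sankey flow as nodes/links JSON or long TSV
#'
#' The JSON follows the generic alluvial schema (`nodes[]` with `name`,
#' `links[]` with `source`/`target`/`value`) consumed by d3-style plotting
#' tools.
#'
#' @param flow A `sankey_flow`.
#' @param path Output path.
#' @export
write_sankey_json <- function(flow, path) {
  obj <- list(
    nodes = purrr::pmap(flow$nodes, function(node_id, release, state, size) {
      list(id = node_id, name = paste0(release, ":", state), size = size)
    }),
    links = purrr::pmap(
      flow$links[, c("source", "target", "value")],
      function(source, target, value) {
        list(source = source, target = target, value = value)
      })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_sankey_json
#' @export
write_sankey_tsv <- function(flow, path) {
  readr::write_tsv(flow$links, path)
  invisible(path)
}

#' Per-release growth table
#'
#' One row per release with the transcript count, distinct gene count, and
#' (when a coverage table is supplied) the percentage of the genome covered
#' by exons — the data behind a growth-curve figure.
#'
#' @param comp A `compendium`.
#' @param coverage Optional output of [coverage_table()].
#' @return A tibble: `release`, `n_transcripts`, `n_genes`, `n_biotypes`,
#'   `n_lncrna`, `pct_transcribed` (NA when no coverage given).
#' @export
growth_table <- function(comp, coverage = NULL) {
  out <- comp$per_release
  if (!is.null(coverage)) {
    out <- dplyr::left_join(out,
                            coverage[, c("release", "pct_transcribed")],
                            by = "release")
  } else {
    out$pct_transcribed <- NA_real_
  }
  out
}

#' Write the biotype presence heatmap as 0/1 TSV
#'
#' @param comp A `compendium`.
#' @param path Output path.
#' @export
write_presence_tsv <- function(comp, path) {
  pm <- presence_matrix(comp)$presence
  pm |>
    dplyr::mutate(dplyr::across(-c("biotype", "code"), as.integer)) |>
    readr::write_tsv(path)
  invisible(path)
}
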