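# Ground-truth ledger construction and pipeline verification.
# Every ledger statistic is computed here with naive per-row scans and
# boolean-mask interval unions, independently of the vectorized dynamics
# module, so the ledger doubles as the oracle in property tests.

build_ledger <- function(M, G, GI, model, ott_cases, par_pairs, releases) {
  R <- ncol(M)
  n <- nrow(M)
  labels <- colnames(M)
  pool <- model$biotype_pool
  code_of_pool <- biotype_codes(pool$name)$code
  cmap <- biotype_class_map()
  class_of_code <- function(code) {
    if (code == 0L) return("NA")
    nm <- pool$name[match(code, code_of_pool)]
    if (is.na(nm)) return("OTHER")
    if (nm %in% cmap$pc) "PROTEIN_CODING"
    else if (nm %in% cmap$lncrna) "LNCRNA"
    else "OTHER"
  }
  CL <- matrix("NA", n, R, dimnames = dimnames(M))
  for (i in seq_len(n)) for (j in seq_len(R)) CL[i, j] <- class_of_code(M[i, j])

  # additions / deletions per consecutive pair, stratified by class
  census <- vector("list", R)
  for (j in seq_len(R)) {
    if (j == 1L) {
      census[[j]] <- tibble::tibble(
        release = labels[1], added = NA_integer_, added_lncrna = NA_integer_,
        added_pc = NA_integer_, added_other = NA_integer_,
        deleted = NA_integer_, deleted_lncrna = NA_integer_,
        deleted_pc = NA_integer_, deleted_other = NA_integer_,
        n_transcripts = sum(M[, 1] != 0L))
      next
    }
    add <- al <- ap <- ao <- del <- dl <- dp <- dd <- 0L
    for (i in seq_len(n)) {
      if (M[i, j - 1L] == 0L && M[i, j] != 0L) {
        add <- add + 1L
        cl <- CL[i, j]
        if (cl == "LNCRNA") al <- al + 1L
        else if (cl == "PROTEIN_CODING") ap <- ap + 1L
        else ao <- ao + 1L
      }
      if (M[i, j - 1L] != 0L && M[i, j] == 0L) {
        del <- del + 1L
        cl <- CL[i, j - 1L]
        if (cl == "LNCRNA") dl <- dl + 1L
        else if (cl == "PROTEIN_CODING") dp <- dp + 1L
        else dd <- dd + 1L
      }
    }
    census[[j]] <- tibble::tibble(
      release = labels[j], added = add, added_lncrna = al, added_pc = ap,
      added_other = ao, deleted = del, deleted_lncrna = dl, deleted_pc = dp,
      deleted_other = dd, n_transcripts = sum(M[, j] != 0L))
  }
  census <- dplyr::bind_rows(census)

  # class transformations per pair, both NA conventions
  transf <- function(mode) {
    rows <- vector("list", R)
    rows[[1]] <- tibble::tibble(release = labels[1], to_lncrna = NA_integer_,
                                from_lncrna = NA_integer_,
                                to_pc = NA_integer_, from_pc = NA_integer_)
    for (j in seq_len(R)[-1]) {
      tl <- fl <- tp <- fp <- 0L
      for (i in seq_len(n)) {
        a <- M[i, j - 1L]; b <- M[i, j]
        in_scope <- if (mode == "IGNORE_NA") a != 0L && b != 0L
                    else a != 0L || b != 0L
        if (!in_scope) next
        ca <- CL[i, j - 1L]; cb <- CL[i, j]
        if (ca == cb) next
        if (cb == "LNCRNA") tl <- tl + 1L
        if (ca == "LNCRNA") fl <- fl + 1L
        if (cb == "PROTEIN_CODING") tp <- tp + 1L
        if (ca == "PROTEIN_CODING") fp <- fp + 1L
      }
      rows[[j]] <- tibble::tibble(release = labels[j], to_lncrna = tl,
                                  from_lncrna = fl, to_pc = tp, from_pc = fp)
    }
    dplyr::bind_rows(rows)
  }

  # per-transcript scans
  naive_transitions <- function(x, mode) {
    if (mode == "IGNORE_NA") x <- x[x != 0L]
    else {
      nz <- which(x != 0L)
      x <- x[nz[1]:nz[length(nz)]]
    }
    t <- 0L
    if (length(x) >= 2L) {
      for (k in 2:length(x)) if (x[k] != x[k - 1L]) t <- t + 1L
    }
    t
  }
  trans_ign <- integer(n); trans_nas <- integer(n); ndist <- integer(n)
  always <- logical(n); ever_l <- logical(n); ever_p <- logical(n)
  single_class <- character(n)
  for (i in seq_len(n)) {
    x <- M[i, ]
    trans_ign[i] <- naive_transitions(x, "IGNORE_NA")
    trans_nas[i] <- naive_transitions(x, "NA_AS_STATE")
    ndist[i] <- length(unique(x[x != 0L]))
    always[i] <- all(x != 0L)
    ever_l[i] <- any(CL[i, ] == "LNCRNA")
    ever_p[i] <- any(CL[i, ] == "PROTEIN_CODING")
    single_class[i] <- CL[i, which(x != 0L)[1]]
  }
  strict <- always & ndist == 1L
  lenient <- ndist == 1L
  cons <- function(flag, mode) tibble::tibble(
    mode = mode, consistent_total = sum(flag),
    consistent_pc = sum(flag & single_class == "PROTEIN_CODING"),
    consistent_lncrna = sum(flag & single_class == "LNCRNA"),
    consistent_other = sum(flag & single_class == "OTHER"),
    ever_lncrna = sum(ever_l),
    pct_consistent_lncrna = 100 * sum(flag & single_class == "LNCRNA") /
      sum(ever_l))
  consistency <- dplyr::bind_rows(cons(strict, "strict"),
                                  cons(lenient, "lenient"))

  # moonlighting + reversions
  overlap_ids <- rownames(M)[ever_l & ever_p]
  rev_l <- 0L; rev_pc <- 0L
  for (id in overlap_ids) {
    i <- match(id, rownames(M))
    x <- CL[i, ][M[i, ] != 0L]
    collapsed <- x[c(TRUE, x[-1] != x[-length(x)])]
    s <- paste(ifelse(collapsed == "LNCRNA", "L",
                      ifelse(collapsed == "PROTEIN_CODING", "P", "o")),
               collapse = "")
    if (grepl("L.*P.*L", s)) rev_l <- rev_l + 1L
    if (grepl("P.*L.*P", s)) rev_pc <- rev_pc + 1L
  }

  # Sankey class links per consecutive pair
  links <- list()
  for (j in seq_len(R - 1L)) {
    acc <- list()
    for (i in seq_len(n)) {
      key <- paste(CL[i, j], CL[i, j + 1L], sep = "->")
      acc[[key]] <- (acc[[key]] %||% 0L) + 1L
    }
    links[[j]] <- tibble::tibble(
      release_from = labels[j], release_to = labels[j + 1L],
      state_from = sub("->.*", "", names(acc)),
      state_to = sub(".*->", "", names(acc)),
      value = as.integer(unlist(acc)))
  }
  links <- dplyr::bind_rows(links)

  # per-release totals
  per_release <- purrr::map(seq_len(R), function(j) {
    nz <- M[, j] != 0L
    tibble::tibble(
      release = labels[j], n_transcripts = sum(nz),
      n_genes = length(unique(GI[, j][nz & nzchar(GI[, j])])),
      n_biotypes = length(unique(M[nz, j])),
      n_lncrna = sum(CL[nz, j] == "LNCRNA"),
      n_pc = sum(CL[nz, j] == "PROTEIN_CODING"))
  }) |> dplyr::bind_rows()

  # biotype presence
  used_codes <- sort(unique(M[M != 0L]))
  pres <- matrix(FALSE, length(used_codes), R)
  for (j in seq_len(R)) pres[, j] <- used_codes %in% M[, j]
  pool_names <- pool$name[match(used_codes, code_of_pool)]

  # exon-union coverage by brute-force boolean mask on the toy genome
  coverage <- purrr::map(releases, function(rel) {
    spans <- dplyr::distinct(rel$exons[, c("chrom", "start", "end")])
    total <- 0
    for (ch in unique(spans$chrom)) {
      mask <- logical(model$chrom_len)
      s <- spans[spans$chrom == ch, , drop = FALSE]
      for (k in seq_len(nrow(s))) mask[s$start[k]:s$end[k]] <- TRUE
      total <- total + sum(mask)
    }
    tibble::tibble(release = rel$label, union_bases = total,
                   pct_transcribed = 100 * total /
                     (as.double(model$n_chrom) * model$chrom_len))
  }) |> dplyr::bind_rows()

  # expected identifier-normalization bookkeeping
  par_canon <- par_pairs$canonical_id
  n_par_dedup <- 0L
  if (length(par_canon) > 0L) {
    for (id in par_canon) n_par_dedup <- n_par_dedup + sum(M[id, ] != 0L)
  }
  n_apply_dedup <- if (model$dual_from > 1L) model$n_ott_1ton_cross else 0L

  list(
    labels = labels, ids = rownames(M), codes = M, classes = CL,
    gene_names = G, gene_ids = GI,
    census = census,
    transformation_ignore_na = transf("IGNORE_NA"),
    transformation_na_state = transf("NA_AS_STATE"),
    transitions_ignore_na = stats::setNames(trans_ign, rownames(M)),
    transitions_na_state = stats::setNames(trans_nas, rownames(M)),
    distinct_biotypes = stats::setNames(ndist, rownames(M)),
    consistency = consistency,
    moonlighting = tibble::tibble(
      n_ever_pc = sum(ever_p), n_ever_lncrna = sum(ever_l),
      n_moonlighting = length(overlap_ids),
      n_reverted_lncrna = rev_l, n_reverted_pc = rev_pc),
    sankey_class_links = links,
    per_release = per_release,
    presence = list(codes = used_codes, names = pool_names, matrix = pres),
    coverage = coverage,
    ott_cases = ott_cases,
    par_pairs = par_pairs,
    expected_dedup = list(par = n_par_dedup, apply = n_apply_dedup)
  )
}

sorted_links <- function(links) {
  links |>
    dplyr::select("release_from", "release_to", "state_from", "state_to",
                  "value") |>
    dplyr::arrange(.data$release_from, .data$state_from, .data$state_to)
}

#' Verify pipeline outputs against a ground-truth ledger
#'
#' Compares every statistic computed by the pipeline on a synthetic corpus —
#' the compendium matrix, addition/deletion and transformation censuses,
#' per-transcript transitions, consistency and moonlighting summaries, Sankey
#' class links, per-release totals, exon-union coverage, and the identifier
#' case census — against the generator's ledger.
#'
#' @param results Output of [analyze_releases()] / [analyze_corpus()] run on
#'   the generated corpus.
#' @param ledger Ledger from [generate_corpus()].
#' @return A list with `pass` (logical) and `mismatches` (character vector;
#'   the first entry describes the first mismatch found, with context).
#' @export
verify_against_ledger <- function(results, ledger) {
  bad <- character(0)
  note <- function(fmt, ...) bad <<- c(bad, sprintf(fmt, ...))
  comp <- results$compendium

  if (!identical(comp$ids, ledger$ids)) {
    extra <- setdiff(comp$ids, ledger$ids)
    miss <- setdiff(ledger$ids, comp$ids)
    note("transcript id sets differ (extra: %s; missing: %s)",
         paste(utils::head(extra, 3), collapse = ","),
         paste(utils::head(miss, 3), collapse = ","))
  } else {
    diff_cells <- which(comp$codes != ledger$codes, arr.ind = TRUE)
    if (nrow(diff_cells) > 0L) {
      i <- diff_cells[1, 1]; j <- diff_cells[1, 2]
      note("code matrix differs in %d cell(s); first at (%s, %s): got %d want %d",
           nrow(diff_cells), comp$ids[i], comp$labels[j],
           comp$codes[i, j], ledger$codes[i, j])
    }
    diff_g <- which(comp$gene_names != ledger$gene_names, arr.ind = TRUE)
    if (nrow(diff_g) > 0L) {
      i <- diff_g[1, 1]; j <- diff_g[1, 2]
      note("gene-name matrix differs at (%s, %s): got '%s' want '%s'",
           comp$ids[i], comp$labels[j], comp$gene_names[i, j],
           ledger$gene_names[i, j])
    }
  }

  cmp_tbl <- function(got, want, name) {
    g <- as.data.frame(got); w <- as.data.frame(want)
    rownames(g) <- rownames(w) <- NULL
    if (nrow(g) != nrow(w)) {
      note("%s differs from ledger (row count %d vs %d)", name, nrow(g), nrow(w))
      return(invisible())
    }
    for (col in names(w)) {
      if (!isTRUE(all.equal(g[[col]], w[[col]], check.attributes = FALSE))) {
        i <- which(!(g[[col]] == w[[col]]) |
                     (is.na(g[[col]]) != is.na(w[[col]])))[1]
        note("%s differs from ledger in column '%s' (first at row %s: got %s want %s)",
             name, col, i, as.character(g[[col]][i]), as.character(w[[col]][i]))
        return(invisible())
      }
    }
  }
  cmp_tbl(results$census, ledger$census, "version census")
  want_tr <- if (results$na_mode == "IGNORE_NA") {
    ledger$transformation_ignore_na
  } else {
    ledger$transformation_na_state
  }
  cmp_tbl(results$transformation, want_tr, "transformation census")
  want_trans <- if (results$na_mode == "IGNORE_NA") {
    ledger$transitions_ignore_na
  } else {
    ledger$transitions_na_state
  }
  st <- results$transcript_stats
  if (!identical(as.integer(st$transitions),
                 as.integer(want_trans[st$transcript_id]))) {
    i <- which(st$transitions != want_trans[st$transcript_id])[1]
    note("transition count differs for %s: got %d want %d",
         st$transcript_id[i], st$transitions[i],
         want_trans[st$transcript_id[i]])
  }
  if (!identical(as.integer(st$distinct_biotypes),
                 as.integer(ledger$distinct_biotypes[st$transcript_id]))) {
    note("distinct-biotype counts differ from ledger")
  }
  cmp_tbl(results$consistency, ledger$consistency, "consistency summary")
  cmp_tbl(results$moonlighting$summary, ledger$moonlighting, "moonlighting")
  cmp_tbl(sorted_links(results$sankey_class$links),
          sorted_links(ledger$sankey_class_links), "sankey class links")
  cmp_tbl(comp$per_release, ledger$per_release, "per-release totals")
  if (!is.null(results$coverage)) {
    got <- results$coverage
    want <- ledger$coverage
    if (!isTRUE(all.equal(got$union_bases, want$union_bases)) ||
        !isTRUE(all.equal(got$pct_transcribed, want$pct_transcribed))) {
      note("coverage differs from ledger")
    }
  }
  got_cases <- results$map |>
    dplyr::distinct(.data$raw_id, .data$case) |>
    dplyr::arrange(.data$raw_id)
  want_cases <- ledger$ott_cases |>
    dplyr::rename(raw_id = "ott_id") |>
    dplyr::arrange(.data$raw_id)
  cmp_tbl(got_cases, want_cases, "identifier case census")

  list(pass = length(bad) == 0L, mismatches = bad)
}

#' Conservation-law check on a version census
#'
#' For every consecutive release pair, the number of observed transcripts at
#' `v+1` must equal the count at `v` plus additions minus deletions.
#'
#' @param census A `version_census` tibble.
#' @return Number of violated pairs (0 means the law holds).
#' @export
conservation_violations <- function(census) {
  n <- census$n_transcripts
  if (length(n) < 2L) return(0L)
  expected <- n[-length(n)] + census$added[-1L] - census$deleted[-1L]
  sum(expected != n[-1L])
}

#' Write / read a ground-truth ledger as JSON
#'
#' @param ledger Ledger list from [generate_corpus()].
#' @param path Output path.
#' @export
write_ledger_json <- function(ledger, path) {
  obj <- list(
    labels = ledger$labels, ids = ledger$ids,
    codes = unname(apply(ledger$codes, 1, as.integer, simplify = FALSE)),
    gene_names = unname(apply(ledger$gene_names, 1, as.character,
                              simplify = FALSE)),
    census = as.data.frame(ledger$census),
    transformation_ignore_na = as.data.frame(ledger$transformation_ignore_na),
    transformation_na_state = as.data.frame(ledger$transformation_na_state),
    transitions_ignore_na = unname(ledger$transitions_ignore_na),
    transitions_na_state = unname(ledger$transitions_na_state),
    distinct_biotypes = unname(ledger$distinct_biotypes),
    consistency = as.data.frame(ledger$consistency),
    moonlighting = as.data.frame(ledger$moonlighting),
    sankey_class_links = as.data.frame(ledger$sankey_class_links),
    per_release = as.data.frame(ledger$per_release),
    coverage = as.data.frame(ledger$coverage),
    ott_cases = as.data.frame(ledger$ott_cases),
    par_pairs = as.data.frame(ledger$par_pairs)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_ledger_json
#' @export
read_ledger_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_mat <- function(v) if (is.list(v)) do.call(rbind, v) else v
  codes <- as_mat(x$codes)
  storage.mode(codes) <- "integer"
  gene_names <- as_mat(x$gene_names)
  dimnames(codes) <- dimnames(gene_names) <- list(x$ids, x$labels)
  list(
    labels = x$labels, ids = x$ids, codes = codes, gene_names = gene_names,
    census = tibble::as_tibble(x$census),
    transformation_ignore_na = tibble::as_tibble(x$transformation_ignore_na),
    transformation_na_state = tibble::as_tibble(x$transformation_na_state),
    transitions_ignore_na = stats::setNames(x$transitions_ignore_na, x$ids),
    transitions_na_state = stats::setNames(x$transitions_na_state, x$ids),
    distinct_biotypes = stats::setNames(x$distinct_biotypes, x$ids),
    consistency = tibble::as_tibble(x$consistency),
    moonlighting = tibble::as_tibble(x$moonlighting),
    sankey_class_links = tibble::as_tibble(x$sankey_class_links),
    per_release = tibble::as_tibble(x$per_release),
    coverage = tibble::as_tibble(x$coverage),
    ott_cases = tibble::as_tibble(x$ott_cases),
    par_pairs = tibble::as_tibble(x$par_pairs)
  )
}
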