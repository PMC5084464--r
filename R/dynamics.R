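#' Count biotype transitions along one trajectory
#'
#' A transition is a change of biotype between consecutive observed states.
#' Under `IGNORE_NA` (the default throughout the package) the NA state is
#' skipped: transitions are counted between consecutive *nonzero* codes, so a
#' transcript that disappears and returns with the same biotype has zero
#' transitions. Under `NA_AS_STATE` the full code sequence is scanned with NA
#' (0) as a state of its own, excluding the leading and trailing runs of
#' absence.
#'
#' @param codes Integer vector of biotype codes (0 = NA state), ordered by
#'   release.
#' @param na_mode `"IGNORE_NA"` or `"NA_AS_STATE"`.
#' @return Integer transition count.
#' @examples
#' count_transitions(c(36L, 0L, 36L, 20L))                 # 1
#' count_transitions(c(36L, 0L, 36L, 20L), "NA_AS_STATE")  # 3
#' @export
count_transitions <- function(codes, na_mode = c("IGNORE_NA", "NA_AS_STATE")) {
  na_mode <- match.arg(na_mode)
  if (length(codes) == 0L) stopf("empty trajectory")
  if (na_mode == "IGNORE_NA") {
    x <- codes[codes != 0L]
    if (length(x) < 2L) return(0L)
    sum(x[-1L] != x[-length(x)])
  } else {
    nz <- which(codes != 0L)
    if (length(nz) == 0L) return(0L)
    x <- codes[nz[1L]:nz[length(nz)]]
    if (length(x) < 2L) return(0L)
    sum(x[-1L] != x[-length(x)])
  }
}

#' Number of distinct biotypes a trajectory attains
#'
#' @param codes Integer code vector (must contain at least one nonzero code).
#' @return Integer count of distinct nonzero codes.
#' @export
distinct_biotypes <- function(codes) {
  x <- unique(codes[codes != 0L])
  if (length(x) == 0L) stopf("trajectory has no observed state")
  length(x)
}

#' Per-transcript trajectory statistics
#'
#' @param comp A `compendium`.
#' @param na_mode Transition-counting mode; see [count_transitions()].
#' @return A tibble with one row per transcript: `transcript_id`,
#'   `transitions`, `distinct_biotypes`, `consistent_strict` (present in
#'   every release with a single code), `consistent_lenient` (single distinct
#'   nonzero code, presence not required), `ever_lncrna`, `ever_pc`.
#' @export
transcript_stats <- function(comp, na_mode = c("IGNORE_NA", "NA_AS_STATE")) {
  na_mode <- match.arg(na_mode)
  M <- comp$codes
  n <- nrow(M); m <- ncol(M)
  trans <- integer(n)
  if (na_mode == "IGNORE_NA") {
    prev <- integer(n)
    for (j in seq_len(m)) {
      cur <- M[, j]
      trans <- trans + (cur != 0L & prev != 0L & cur != prev)
      seen <- cur != 0L
      prev[seen] <- cur[seen]
    }
  } else {
    first <- rep(m + 1L, n); last <- rep(0L, n)
    for (j in seq_len(m)) {
      nz <- M[, j] != 0L
      first[nz & first > m] <- j
      last[nz] <- j
    }
    if (m >= 2L) {
      for (j in 2L:m) {
        inside <- first < j & last >= j
        trans <- trans + (inside & M[, j] != M[, j - 1L])
      }
    }
  }
  nd <- vapply(seq_len(n), function(i) {
    x <- M[i, ]
    length(unique(x[x != 0L]))
  }, integer(1))
  always_present <- rowSums(M != 0L) == m
  clm <- class_matrix(comp)
  tibble::tibble(
    transcript_id = comp$ids,
    transitions = as.integer(trans),
    distinct_biotypes = nd,
    consistent_strict = always_present & nd == 1L & trans == 0L,
    consistent_lenient = nd == 1L,
    ever_lncrna = rowSums(clm == "LNCRNA") > 0L,
    ever_pc = rowSums(clm == "PROTEIN_CODING") > 0L
  )
}

#' Per-release addition/deletion census
#'
#' For each consecutive release pair, the number of transcripts added (NA
#' state to an observed biotype) and deleted (observed to NA), stratified by
#' the class the transcript holds on its observed side (lncRNA class,
#' protein coding, other).
#'
#' @param comp A `compendium`.
#' @return A `version_census` tibble, one row per release (first row all-NA
#'   counts since it has no predecessor): `release`, `added`, `added_lncrna`,
#'   `added_pc`, `added_other`, `deleted`, `deleted_lncrna`, `deleted_pc`,
#'   `deleted_other`, `n_transcripts`. Per-release totals travel in
#'   `attr(, "totals")`; [glance()] gives series-level averages.
#' @export
version_census <- function(comp) {
  M <- comp$codes
  clm <- class_matrix(comp)
  m <- ncol(M)
  rows <- purrr::map(seq_len(m), function(j) {
    if (j == 1L) {
      return(tibble::tibble(
        release = comp$labels[1], added = NA_integer_,
        added_lncrna = NA_integer_, added_pc = NA_integer_,
        added_other = NA_integer_, deleted = NA_integer_,
        deleted_lncrna = NA_integer_, deleted_pc = NA_integer_,
        deleted_other = NA_integer_,
        n_transcripts = sum(M[, 1] != 0L)
      ))
    }
    prev <- M[, j - 1L]; cur <- M[, j]
    add <- prev == 0L & cur != 0L
    del <- prev != 0L & cur == 0L
    tibble::tibble(
      release = comp$labels[j],
      added = sum(add),
      added_lncrna = sum(add & clm[, j] == "LNCRNA"),
      added_pc = sum(add & clm[, j] == "PROTEIN_CODING"),
      added_other = sum(add & clm[, j] == "OTHER"),
      deleted = sum(del),
      deleted_lncrna = sum(del & clm[, j - 1L] == "LNCRNA"),
      deleted_pc = sum(del & clm[, j - 1L] == "PROTEIN_CODING"),
      deleted_other = sum(del & clm[, j - 1L] == "OTHER"),
      n_transcripts = sum(cur != 0L)
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "totals") <- comp$per_release
  class(out) <- c("version_census", class(out))
  out
}

#' @export
glance.version_census <- function(x, ...) {
  d <- x[-1L, , drop = FALSE]
  tibble::tibble(
    n_release_pairs = nrow(d),
    mean_added = mean(d$added),
    mean_deleted = mean(d$deleted),
    max_added = max(d$added),
    max_added_release = d$release[which.max(d$added)],
    max_deleted = max(d$deleted),
    max_deleted_release = d$release[which.max(d$deleted)]
  )
}

#' Class-transformation census across consecutive releases
#'
#' For each release, the number of transcripts whose class changed relative
#' to the previous release, split into flows into/out of the lncRNA class and
#' into/out of protein coding. Under `IGNORE_NA` only transcripts observed in
#' both releases are considered (absence is not a switch); under
#' `NA_AS_STATE` the NA state participates as a class of its own.
#'
#' Distinct-transcript aggregates over the whole series (how many transcripts
#' ever moved protein coding to lncRNA and vice versa, between consecutive
#' observed states) travel in `attr(, "aggregate")`.
#'
#' @param comp A `compendium`.
#' @param na_mode See [count_transitions()].
#' @return A tibble: `release`, `to_lncrna`, `from_lncrna`, `to_pc`,
#'   `from_pc` (first row NA).
#' @export
transformation_census <- function(comp,
                                  na_mode = c("IGNORE_NA", "NA_AS_STATE")) {
  na_mode <- match.arg(na_mode)
  M <- comp$codes
  clm <- class_matrix(comp)
  m <- ncol(M)
  rows <- purrr::map(seq_len(m), function(j) {
    if (j == 1L) {
      return(tibble::tibble(release = comp$labels[1],
                            to_lncrna = NA_integer_, from_lncrna = NA_integer_,
                            to_pc = NA_integer_, from_pc = NA_integer_))
    }
    a <- clm[, j - 1L]; b <- clm[, j]
    if (na_mode == "IGNORE_NA") {
      scope <- M[, j - 1L] != 0L & M[, j] != 0L
    } else {
      scope <- M[, j - 1L] != 0L | M[, j] != 0L
    }
    changed <- scope & a != b
    tibble::tibble(
      release = comp$labels[j],
      to_lncrna = sum(changed & b == "LNCRNA"),
      from_lncrna = sum(changed & a == "LNCRNA"),
      to_pc = sum(changed & b == "PROTEIN_CODING"),
      from_pc = sum(changed & a == "PROTEIN_CODING")
    )
  })
  out <- dplyr::bind_rows(rows)

  # series-level distinct-transcript flows between consecutive observed states
  n <- nrow(M)
  prev <- character(n); prev_set <- logical(n)
  pc2l <- logical(n); l2pc <- logical(n)
  for (j in seq_len(m)) {
    nz <- M[, j] != 0L
    cur <- clm[, j]
    hit <- nz & prev_set
    pc2l <- pc2l | (hit & prev == "PROTEIN_CODING" & cur == "LNCRNA")
    l2pc <- l2pc | (hit & prev == "LNCRNA" & cur == "PROTEIN_CODING")
    prev[nz] <- cur[nz]
    prev_set <- prev_set | nz
  }
  attr(out, "aggregate") <- tibble::tibble(
    pc_to_lncrna_transcripts = sum(pc2l),
    lncrna_to_pc_transcripts = sum(l2pc)
  )
  class(out) <- c("transformation_census", class(out))
  out
}

#' Annotation-consistency summary
#'
#' A transcript is consistent in *strict* mode when it is present in every
#' release and always under the same biotype; *lenient* mode requires only a
#' single distinct observed biotype, tolerating absence. Both modes are
#' reported, with class breakdowns and the consistent-lncRNA percentage
#' (100 x consistent lncRNA / transcripts ever in the lncRNA class).
#'
#' @param comp A `compendium`.
#' @return A tibble with one row per mode: `mode`, `consistent_total`,
#'   `consistent_pc`, `consistent_lncrna`, `consistent_other`, `ever_lncrna`,
#'   `pct_consistent_lncrna`.
#' @export
consistency_summary <- function(comp) {
  st <- transcript_stats(comp)
  clm <- class_matrix(comp)
  # the single observed class of a consistent transcript
  single_class <- vapply(seq_len(nrow(comp$codes)), function(i) {
    x <- clm[i, ][comp$codes[i, ] != 0L]
    x[1L]
  }, character(1))
  ever_l <- sum(st$ever_lncrna)
  one_mode <- function(flag, mode) {
    tibble::tibble(
      mode = mode,
      consistent_total = sum(flag),
      consistent_pc = sum(flag & single_class == "PROTEIN_CODING"),
      consistent_lncrna = sum(flag & single_class == "LNCRNA"),
      consistent_other = sum(flag & single_class == "OTHER"),
      ever_lncrna = ever_l,
      pct_consistent_lncrna =
        100 * sum(flag & single_class == "LNCRNA") / ever_l
    )
  }
  dplyr::bind_rows(
    one_mode(st$consistent_strict, "strict"),
    one_mode(st$consistent_lenient, "lenient")
  )
}

#' Moonlighting identities between protein-coding and lncRNA classes
#'
#' A moonlighting transcript is annotated protein-coding in at least one
#' release and lncRNA-class in at least one other. Reversion counts capture
#' trajectories that return to their starting class: lncRNA ... PC ... lncRNA
#' (over consecutive observed states) and the symmetric protein-coding
#' pattern.
#'
#' @param comp A `compendium`.
#' @return A list with `ever_pc`, `ever_lncrna`, `overlap` (id character
#'   vectors), `n_reverted_lncrna`, `n_reverted_pc`, and `summary` (one-row
#'   tibble of the counts).
#' @export
moonlighting <- function(comp) {
  st <- transcript_stats(comp)
  clm <- class_matrix(comp)
  ever_pc <- comp$ids[st$ever_pc]
  ever_l <- comp$ids[st$ever_lncrna]
  overlap <- intersect(ever_pc, ever_l)

  has_subseq <- function(x, pat) {
    i <- 1L
    for (v in x) {
      if (v == pat[i]) {
        i <- i + 1L
        if (i > length(pat)) return(TRUE)
      }
    }
    FALSE
  }
  idx <- match(overlap, comp$ids)
  rev_l <- 0L; rev_pc <- 0L
  for (i in idx) {
    x <- clm[i, ][comp$codes[i, ] != 0L]
    x <- rle(x)$values
    if (has_subseq(x, c("LNCRNA", "PROTEIN_CODING", "LNCRNA"))) rev_l <- rev_l + 1L
    if (has_subseq(x, c("PROTEIN_CODING", "LNCRNA", "PROTEIN_CODING"))) rev_pc <- rev_pc + 1L
  }
  list(
    ever_pc = ever_pc, ever_lncrna = ever_l, overlap = overlap,
    n_reverted_lncrna = rev_l, n_reverted_pc = rev_pc,
    summary = tibble::tibble(
      n_ever_pc = length(ever_pc), n_ever_lncrna = length(ever_l),
      n_moonlighting = length(overlap),
      n_reverted_lncrna = rev_l, n_reverted_pc = rev_pc
    )
  )
}
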