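#' Default biotype sampling pool for synthetic corpora
#'
#' A realistic mix of the frequent GENCODE biotypes: roughly half protein
#' coding, the rest spread over the common lncRNA-class and small-RNA
#' biotypes.
#'
#' @return A tibble with columns `name` (canonical biotype) and `weight`.
#' @export
default_biotype_pool <- function() {
  tibble::tibble(
    name = c("protein coding", "processed transcript", "retained intron",
             "lincrna", "antisense", "processed pseudogene",
             "unprocessed pseudogene", "nonsense mediated decay", "mirna",
             "snorna", "tec"),
    weight = c(0.45, 0.10, 0.08, 0.08, 0.07, 0.06, 0.04, 0.05, 0.03,
               0.02, 0.02)
  )
}

#' Default biotype transition matrix
#'
#' Row-stochastic matrix over the pool: a transcript keeps its biotype with
#' probability `p_stay` and otherwise moves uniformly to another pool
#' biotype, emulating the few-percent per-release annotation churn observed
#' in the GENCODE series.
#'
#' @param pool Biotype pool tibble.
#' @param p_stay Probability of keeping the current biotype per release.
#' @return A `K x K` row-stochastic matrix with dimnames from the pool.
#' @export
default_transition_matrix <- function(pool = default_biotype_pool(),
                                      p_stay = 0.97) {
  k <- nrow(pool)
  tm <- matrix((1 - p_stay) / (k - 1), k, k,
               dimnames = list(pool$name, pool$name))
  diag(tm) <- p_stay
  tm
}

#' Specify a generative model for a synthetic release series
#'
#' The model emulates the structural features of the GENCODE series: per
#' release transcript additions and deletions, biotype switching driven by a
#' transition matrix, early releases identifying transcripts by Havana
#' (`OTTHUMT`) accessions only with dual `OTTHUMT`+`ENST` identifiers
#' appearing from release `dual_from`, pseudo-autosomal duplicate
#' identifiers, version-suffixed accessions in the dual era, and an exon-only
#' GTF dialect for the first release. Defaults give a corpus of about 2,000
#' transcripts over 8 releases with a few percent churn per release.
#'
#' @param n_initial Transcripts in the first release.
#' @param n_releases Number of releases.
#' @param labels Release labels; defaults to the first `n_releases` GENCODE
#'   catalog labels.
#' @param biotype_pool Tibble of canonical biotype names with weights.
#' @param p_add Per-release expected additions as a fraction of current size.
#' @param p_delete Per-release per-transcript deletion probability
#'   (deletions are permanent).
#' @param transition_matrix Row-stochastic biotype transition matrix.
#' @param frac_ott_only_early Fraction of pre-dual-era transcripts presented
#'   under their `OTTHUMT` id only.
#' @param frac_dual_id Fraction of transcripts carrying the `OTTHUMT`
#'   companion id in the dual era.
#' @param frac_ott_forever Fraction presented under `OTTHUMT` in every
#'   release (never acquiring an `ENST` id).
#' @param n_par Pseudo-autosomal duplicate pairs.
#' @param n_ott_1ton_same Planted `OTTHUMT` ids with two `ENST` partners in
#'   the same release.
#' @param n_ott_1ton_cross Planted `OTTHUMT` ids whose single `ENST` partner
#'   differs between releases.
#' @param dual_from 1-based release index where dual identifiers begin.
#' @param first_release_exon_only Emit the first release in the exon-only
#'   dialect.
#' @param n_chrom,chrom_len Toy genome: number of chromosomes and length of
#'   each, in bases.
#' @param p_gene_rename Fraction of genes renamed at the series midpoint.
#' @param seed Integer seed; the random stream is partitioned per release so
#'   extending the series never perturbs earlier releases.
#' @return A validated `churn_model` list.
#' @export
churn_model <- function(n_initial = 2000, n_releases = 8, labels = NULL,
                        biotype_pool = default_biotype_pool(),
                        p_add = 0.04, p_delete = 0.015,
                        transition_matrix = NULL,
                        frac_ott_only_early = 0.6, frac_dual_id = 0.9,
                        frac_ott_forever = 0.02,
                        n_par = 10, n_ott_1ton_same = 8, n_ott_1ton_cross = 8,
                        dual_from = 3, first_release_exon_only = TRUE,
                        n_chrom = 3, chrom_len = 1e6,
                        p_gene_rename = 0.02, seed = 1) {
  if (is.null(transition_matrix)) {
    transition_matrix <- default_transition_matrix(biotype_pool)
  }
  if (is.null(labels)) {
    cat_labels <- gencode_releases()$label
    if (n_releases > length(cat_labels)) {
      stopf("default labels cover at most %d releases", length(cat_labels))
    }
    labels <- cat_labels[seq_len(n_releases)]
  }
  stopifnot(n_initial >= 1, n_releases >= 1,
            length(labels) == n_releases,
            nrow(biotype_pool) >= 2,
            all(c(p_add, p_delete, frac_ott_only_early, frac_dual_id,
                  frac_ott_forever, p_gene_rename) >= 0),
            all(c(p_add, p_delete, frac_ott_only_early, frac_dual_id,
                  frac_ott_forever, p_gene_rename) <= 1))
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stopf("transition matrix rows must sum to 1")
  }
  if (nrow(transition_matrix) != nrow(biotype_pool)) {
    stopf("transition matrix dimension must match the biotype pool")
  }
  if (n_ott_1ton_same > 0 && dual_from > n_releases) {
    stopf("same-version one-to-many plants need dual_from <= n_releases")
  }
  if (n_ott_1ton_cross > 0 && dual_from + 1 > n_releases) {
    stopf("cross-version one-to-many plants need dual_from + 1 <= n_releases")
  }
  structure(
    list(n_initial = as.integer(n_initial),
         n_releases = as.integer(n_releases), labels = as.character(labels),
         biotype_pool = biotype_pool, p_add = p_add, p_delete = p_delete,
         transition_matrix = transition_matrix,
         frac_ott_only_early = frac_ott_only_early,
         frac_dual_id = frac_dual_id, frac_ott_forever = frac_ott_forever,
         n_par = as.integer(n_par),
         n_ott_1ton_same = as.integer(n_ott_1ton_same),
         n_ott_1ton_cross = as.integer(n_ott_1ton_cross),
         dual_from = as.integer(dual_from),
         first_release_exon_only = isTRUE(first_release_exon_only),
         n_chrom = as.integer(n_chrom), chrom_len = as.integer(chrom_len),
         p_gene_rename = p_gene_rename, seed = as.integer(seed)),
    class = "churn_model"
  )
}

sample_chain_step <- function(cur, tm) {
  # vectorized Markov step: cur is a vector of pool indices
  out <- integer(length(cur))
  for (k in sort(unique(cur))) {
    idx <- which(cur == k)
    out[idx] <- sample.int(ncol(tm), length(idx), replace = TRUE,
                           prob = tm[k, ])
  }
  out
}

make_exons <- function(n_tx, n_chrom, chrom_len) {
  n_ex <- sample.int(5L, n_tx, replace = TRUE)
  chrom <- paste0("chr", sample.int(n_chrom, n_tx, replace = TRUE))
  strand <- sample(c("+", "-"), n_tx, replace = TRUE)
  start1 <- sample.int(chrom_len - 40000L, n_tx, replace = TRUE)
  rows <- vector("list", 5L)
  cur <- start1
  for (k in 1:5) {
    len <- sample(50:500, n_tx, replace = TRUE)
    gap <- sample(100:5000, n_tx, replace = TRUE)
    has <- n_ex >= k
    rows[[k]] <- tibble::tibble(tx = which(has), exon = k,
                                chrom = chrom[has], start = cur[has],
                                end = cur[has] + len[has] - 1L,
                                strand = strand[has])
    cur <- cur + len + gap
  }
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$tx, .data$exon)
}

#' Generate a synthetic multi-release GTF corpus with ground truth
#'
#' Simulates the model, writes one GTF file per release (the first one in the
#' exon-only dialect when configured) plus a `chrom.sizes` table, and returns
#' a ground-truth ledger holding the true transcript-by-release code matrix
#' and every summary statistic computed independently by naive per-row scans
#' — the oracle the pipeline is verified against. Fully deterministic given
#' the model seed.
#'
#' @param model A `churn_model`.
#' @param out_dir Output directory (created if needed).
#' @return A list: `paths` (GTF files in chronological order), `labels`,
#'   `catalog`, `sizes_path`, `releases` (the in-memory release objects as
#'   written) and `ledger` (see details).
#' @export
generate_corpus <- function(model, out_dir) {
  stopifnot(inherits(model, "churn_model"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  R <- model$n_releases
  pool <- model$biotype_pool
  K <- nrow(pool)
  tm <- model$transition_matrix
  dual_from <- model$dual_from

  cap <- ceiling(model$n_initial * (1 + model$p_add)^R * 2) + 200L
  bt <- matrix(0L, cap, R)            # pool index per (transcript, release)
  first_r <- integer(cap); last_r <- integer(cap)

  n <- 0L
  alive <- integer(0)
  for (r in seq_len(R)) {
    set.seed(derive_seed(model$seed, r))
    if (r == 1L) {
      n <- model$n_initial
      alive <- seq_len(n)
      first_r[alive] <- 1L
      bt[alive, 1L] <- sample.int(K, n, replace = TRUE, prob = pool$weight)
    } else {
      u <- runif(length(alive))
      dead <- alive[u < model$p_delete]
      last_r[dead] <- r - 1L
      alive <- setdiff(alive, dead)
      bt[alive, r] <- sample_chain_step(bt[alive, r - 1L], tm)
      n_new <- rbinom(1L, length(alive), model$p_add)
      if (n_new > 0L) {
        newborn <- n + seq_len(n_new)
        n <- n + n_new
        first_r[newborn] <- r
        bt[newborn, r] <- sample.int(K, n_new, replace = TRUE,
                                     prob = pool$weight)
        alive <- c(alive, newborn)
      }
    }
  }
  last_r[alive] <- R
  n_base <- n
  bt <- bt[seq_len(n_base), , drop = FALSE]
  first_r <- first_r[seq_len(n_base)]; last_r <- last_r[seq_len(n_base)]

  # identity flags
  set.seed(derive_seed(model$seed, R + 1L))
  ott_forever <- runif(n_base) < model$frac_ott_forever
  has_ott_early <- !ott_forever & first_r < dual_from &
    runif(n_base) < model$frac_ott_only_early
  dual_alt <- !ott_forever & runif(n_base) < model$frac_dual_id
  enst <- sprintf("ENST%011d", seq_len(n_base))
  ott <- sprintf("OTTHUMT%011d", seq_len(n_base))
  in_dual_era <- last_r >= dual_from
  ott_unmapped_early <- has_ott_early & !in_dual_era
  has_alt_in_dual <- (has_ott_early | dual_alt) & in_dual_era & !ott_forever
  row_key <- ifelse(ott_forever | ott_unmapped_early, ott, enst)
  ott_observed <- ott_forever | has_ott_early | has_alt_in_dual
  ott_case <- rep(NA_character_, n_base)
  ott_case[ott_observed] <- "OTT_1TO1"
  ott_case[ott_forever | ott_unmapped_early] <- "OTT_UNMAPPED"

  # exons and genes
  set.seed(derive_seed(model$seed, R + 2L))
  exon_tbl <- make_exons(n_base, model$n_chrom, model$chrom_len)
  set.seed(derive_seed(model$seed, R + 3L))
  n_genes <- max(1L, ceiling(n_base / 2))
  gene_of <- sample.int(n_genes, n_base, replace = TRUE)
  renamed <- runif(n_genes) < model$p_gene_rename
  rename_at <- if (R >= 2L) floor(R / 2) + 1L else R + 1L
  gene_id_of <- sprintf("ENSG%011d", gene_of)
  gene_name_at <- function(g, r) {
    base <- sprintf("GENE%05d", g)
    ifelse(renamed[g] & r >= rename_at, paste0(base, "B"), base)
  }

  # planted one-to-many identities and PAR pairs
  set.seed(derive_seed(model$seed, R + 4L))
  sp_counter <- n_base
  next_ids <- function(k) {
    out <- sp_counter + seq_len(k)
    sp_counter <<- sp_counter + k
    out
  }
  plant_chain <- function() {
    x <- integer(R)
    x[1] <- sample.int(K, 1L, prob = pool$weight)
    for (r in seq_len(R)[-1]) x[r] <- sample_chain_step(x[r - 1L], tm)
    x
  }
  same_plants <- purrr::map(seq_len(model$n_ott_1ton_same), function(k) {
    ids <- next_ids(3L)
    shared <- plant_chain()
    a_chain <- shared; b_chain <- shared
    if (dual_from <= R) {
      span <- dual_from:R
      start <- if (dual_from > 1L) shared[dual_from - 1L] else shared[1L]
      ac <- start; bc <- start
      for (r in span) {
        ac <- sample_chain_step(ac, tm); bc <- sample_chain_step(bc, tm)
        a_chain[r] <- ac; b_chain[r] <- bc
      }
    }
    list(ott = sprintf("OTTHUMT%011d", ids[1]),
         a = sprintf("ENST%011d", ids[2]), b = sprintf("ENST%011d", ids[3]),
         shared = shared, a_chain = a_chain, b_chain = b_chain,
         gene = sprintf("SPGENE%05d", ids[1]),
         exons_a = make_exons(1L, model$n_chrom, model$chrom_len),
         exons_b = make_exons(1L, model$n_chrom, model$chrom_len))
  })
  cross_plants <- purrr::map(seq_len(model$n_ott_1ton_cross), function(k) {
    ids <- next_ids(3L)
    chain <- plant_chain()
    m_switch <- dual_from + max(0L, floor((R - dual_from) / 2))
    list(ott = sprintf("OTTHUMT%011d", ids[1]),
         a = sprintf("ENST%011d", ids[2]), b = sprintf("ENST%011d", ids[3]),
         chain = chain, m_switch = m_switch,
         gene = sprintf("SPGENE%05d", ids[1]),
         exons_a = make_exons(1L, model$n_chrom, model$chrom_len),
         exons_b = make_exons(1L, model$n_chrom, model$chrom_len))
  })
  par_eligible <- which(!ott_forever & !has_ott_early & !dual_alt)
  n_par <- min(model$n_par, length(par_eligible))
  par_base <- sort(par_eligible[sample.int(length(par_eligible), n_par)])
  par_twin <- sub("^ENST0", "ENSTR", enst[par_base])

  # ---- assemble releases -------------------------------------------------
  pool_raw <- gsub(" ", "_", pool$name)   # GTF-style raw biotype spelling
  releases <- vector("list", R)
  for (r in seq_len(R)) {
    idx <- which(first_r <= r & last_r >= r)
    in_dual <- r >= dual_from
    show_ott <- ott_forever[idx] | (!in_dual & has_ott_early[idx])
    main_id <- ifelse(show_ott, ott[idx],
                      if (in_dual) paste0(enst[idx], ".", r) else enst[idx])
    alt_id <- ifelse(in_dual & (has_ott_early[idx] | dual_alt[idx]) &
                       !ott_forever[idx], ott[idx], NA_character_)
    rec <- tibble::tibble(
      transcript_id = main_id,
      biotype = pool_raw[bt[idx, r]],
      gene_id = gene_id_of[idx],
      gene_name = gene_name_at(gene_of[idx], r),
      source = ifelse(ott_forever[idx] | has_ott_early[idx], "HAVANA",
                      "ENSEMBL"),
      alt_id = alt_id
    )
    ex <- exon_tbl |>
      dplyr::filter(.data$tx %in% idx) |>
      dplyr::mutate(transcript_id = main_id[match(.data$tx, idx)]) |>
      dplyr::select("transcript_id", "chrom", "start", "end", "strand")

    sp_rec <- list(); sp_ex <- list()
    relabel <- function(exdf, id) {
      tibble::tibble(transcript_id = id, chrom = exdf$chrom,
                     start = exdf$start, end = exdf$end, strand = exdf$strand)
    }
    for (p in same_plants) {
      gname <- p$gene
      if (!in_dual) {
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = p$ott, biotype = pool_raw[p$shared[r]],
          gene_id = gname, gene_name = gname, source = "HAVANA",
          alt_id = NA_character_)
        sp_ex[[length(sp_ex) + 1L]] <- relabel(p$exons_a, p$ott)
      } else {
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = paste0(p$a, ".", r),
          biotype = pool_raw[p$a_chain[r]],
          gene_id = gname, gene_name = gname, source = "HAVANA",
          alt_id = p$ott)
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = paste0(p$b, ".", r),
          biotype = pool_raw[p$b_chain[r]],
          gene_id = gname, gene_name = gname, source = "HAVANA",
          alt_id = p$ott)
        sp_ex[[length(sp_ex) + 1L]] <- relabel(p$exons_a, paste0(p$a, ".", r))
        sp_ex[[length(sp_ex) + 1L]] <- relabel(p$exons_b, paste0(p$b, ".", r))
      }
    }
    for (p in cross_plants) {
      gname <- p$gene
      btr <- pool_raw[p$chain[r]]
      if (r == 1L && dual_from > 1L) {
        # structural-partner release: OTT record plus its ENST twin
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = p$ott, biotype = btr, gene_id = gname,
          gene_name = gname, source = "HAVANA", alt_id = NA_character_)
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = p$a, biotype = btr, gene_id = gname,
          gene_name = gname, source = "ENSEMBL", alt_id = NA_character_)
        sp_ex[[length(sp_ex) + 1L]] <- relabel(p$exons_a, p$ott)
        sp_ex[[length(sp_ex) + 1L]] <- relabel(p$exons_a, p$a)
      } else if (!in_dual) {
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = p$ott, biotype = btr, gene_id = gname,
          gene_name = gname, source = "HAVANA", alt_id = NA_character_)
        sp_ex[[length(sp_ex) + 1L]] <- relabel(p$exons_a, p$ott)
      } else {
        partner <- if (r <= p$m_switch) p$a else p$b
        pex <- if (r <= p$m_switch) p$exons_a else p$exons_b
        sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
          transcript_id = paste0(partner, ".", r), biotype = btr,
          gene_id = gname, gene_name = gname, source = "HAVANA",
          alt_id = p$ott)
        sp_ex[[length(sp_ex) + 1L]] <- relabel(pex, paste0(partner, ".", r))
      }
    }
    # pseudo-autosomal twins of base transcripts
    par_here <- par_base[first_r[par_base] <= r & last_r[par_base] >= r]
    if (length(par_here) > 0L) {
      pos <- match(par_here, idx)
      twin_id <- sub("^ENST0", "ENSTR", main_id[pos])
      sp_rec[[length(sp_rec) + 1L]] <- tibble::tibble(
        transcript_id = twin_id, biotype = pool_raw[bt[par_here, r]],
        gene_id = gene_id_of[par_here],
        gene_name = gene_name_at(gene_of[par_here], r),
        source = "ENSEMBL", alt_id = NA_character_)
      twin_ex <- exon_tbl |>
        dplyr::filter(.data$tx %in% par_here) |>
        dplyr::mutate(transcript_id = twin_id[match(.data$tx, par_here)]) |>
        dplyr::select("transcript_id", "chrom", "start", "end", "strand")
      sp_ex[[length(sp_ex) + 1L]] <- twin_ex
    }
    rec <- dplyr::bind_rows(c(list(rec), sp_rec))
    ex <- dplyr::bind_rows(c(list(ex), sp_ex))
    dialect <- if (r == 1L && model$first_release_exon_only) {
      "EXON_ONLY"
    } else {
      "TRANSCRIPT_LINES"
    }
    releases[[r]] <- new_release(model$labels[r], rec, ex, dialect)
  }

  # ---- ground-truth ledger (naive, loop-based computations) --------------
  code_of_pool <- biotype_codes(pool$name)$code
  truth_rows <- list()
  add_row <- function(id, codes, gene, gene_id) {
    truth_rows[[length(truth_rows) + 1L]] <<-
      list(id = id, codes = codes, gene = gene, gene_id = gene_id)
  }
  for (i in seq_len(n_base)) {
    codes <- integer(R)
    span <- first_r[i]:last_r[i]
    codes[span] <- code_of_pool[bt[i, span]]
    gname <- character(R)
    gname[span] <- gene_name_at(gene_of[i], span)
    gid <- character(R); gid[span] <- gene_id_of[i]
    add_row(row_key[i], codes, gname, gid)
  }
  for (p in same_plants) {
    a_codes <- integer(R); b_codes <- integer(R)
    for (r in seq_len(R)) {
      a_codes[r] <- code_of_pool[if (r < dual_from) p$shared[r] else p$a_chain[r]]
      b_codes[r] <- code_of_pool[if (r < dual_from) p$shared[r] else p$b_chain[r]]
    }
    g <- rep(p$gene, R)
    add_row(p$a, a_codes, g, g)
    add_row(p$b, b_codes, g, g)
  }
  for (p in cross_plants) {
    a_codes <- integer(R); b_codes <- integer(R)
    for (r in seq_len(R)) {
      if (r <= p$m_switch) a_codes[r] <- code_of_pool[p$chain[r]]
      else b_codes[r] <- code_of_pool[p$chain[r]]
    }
    ga <- ifelse(a_codes != 0L, p$gene, "")
    gb <- ifelse(b_codes != 0L, p$gene, "")
    add_row(p$a, a_codes, ga, ga)
    add_row(p$b, b_codes, gb, gb)
  }
  ids <- vapply(truth_rows, function(x) x$id, character(1))
  ord <- order(ids, method = "radix")
  truth_rows <- truth_rows[ord]
  ids <- ids[ord]
  M <- do.call(rbind, lapply(truth_rows, function(x) x$codes))
  G <- do.call(rbind, lapply(truth_rows, function(x) x$gene))
  GI <- do.call(rbind, lapply(truth_rows, function(x) x$gene_id))
  dimnames(M) <- dimnames(G) <- dimnames(GI) <- list(ids, model$labels)

  ott_cases <- dplyr::bind_rows(
    tibble::tibble(ott_id = ott[ott_observed], case = ott_case[ott_observed]),
    tibble::tibble(ott_id = vapply(same_plants, function(p) p$ott, character(1)),
                   case = rep("OTT_1TON_SAME_VERSION", length(same_plants))),
    tibble::tibble(ott_id = vapply(cross_plants, function(p) p$ott, character(1)),
                   case = rep("OTT_1TON_CROSS_VERSION", length(cross_plants)))
  )

  ledger <- build_ledger(M, G, GI, model, ott_cases,
                         tibble::tibble(canonical_id = enst[par_base],
                                        par_id = par_twin),
                         releases)

  # ---- write files -------------------------------------------------------
  paths <- file.path(out_dir,
                     paste0("release_", gsub("[^A-Za-z0-9]", "_", model$labels),
                            ".gtf"))
  for (r in seq_len(R)) write_gtf_release(releases[[r]], paths[r])
  sizes_path <- file.path(out_dir, "toy.chrom.sizes")
  readr::write_tsv(
    tibble::tibble(chrom = paste0("chr", seq_len(model$n_chrom)),
                   size = model$chrom_len),
    sizes_path, col_names = FALSE
  )
  list(paths = paths, labels = model$labels,
       catalog = release_catalog(model$labels),
       sizes_path = sizes_path, releases = releases, ledger = ledger,
       model = model)
}
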