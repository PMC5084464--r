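#' Run the full analysis over an in-memory release series
#'
#' Convenience composition of the pipeline: identifier normalization,
#' compendium construction, and every longitudinal statistic.
#'
#' @param releases List of `annotation_release` objects in chronological
#'   order.
#' @param catalog Release catalog for the series.
#' @param registry Biotype registry.
#' @param class_map Biotype class map.
#' @param na_mode NA convention for transition counting; see
#'   [count_transitions()].
#' @param sizes Optional chromosome-sizes tibble; enables coverage.
#' @param par_patterns PAR identifier patterns.
#' @return A named list: `compendium`, `map`, `normalization`, `census`,
#'   `transformation`, `transcript_stats`, `consistency`, `moonlighting`,
#'   `sankey_class`, `presence`, `growth`, `coverage` (NULL without sizes),
#'   `na_mode`.
#' @export
analyze_releases <- function(releases, catalog = gencode_releases(),
                             registry = biotype_registry(),
                             class_map = biotype_class_map(),
                             na_mode = c("IGNORE_NA", "NA_AS_STATE"),
                             sizes = NULL,
                             par_patterns = default_par_patterns()) {
  na_mode <- match.arg(na_mode)
  norm <- normalize_releases(releases, par_patterns = par_patterns,
                             catalog = catalog)
  comp <- build_compendium(norm$releases, registry, class_map)
  coverage <- if (!is.null(sizes)) coverage_table(norm$releases, sizes)
  list(
    compendium = comp,
    map = norm$map,
    normalization = norm$report,
    census = version_census(comp),
    transformation = transformation_census(comp, na_mode),
    transcript_stats = transcript_stats(comp, na_mode),
    consistency = consistency_summary(comp),
    moonlighting = moonlighting(comp),
    sankey_class = sankey_flows(comp, "BY_CLASS"),
    presence = presence_matrix(comp),
    growth = growth_table(comp, coverage),
    coverage = coverage,
    na_mode = na_mode
  )
}

#' Run the full analysis over GTF files on disk
#'
#' @param paths GTF file paths in chronological order.
#' @param labels Release labels, parallel to `paths`.
#' @inheritParams analyze_releases
#' @param ... Passed to [read_gtf_release()].
#' @return See [analyze_releases()].
#' @export
analyze_corpus <- function(paths, labels, catalog = gencode_releases(),
                           registry = biotype_registry(),
                           class_map = biotype_class_map(),
                           na_mode = "IGNORE_NA", sizes = NULL, ...) {
  stopifnot(length(paths) == length(labels))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stopf("release file(s) not found: %s", paste(missing, collapse = ", "),
          class = "annochron_input_error")
  }
  releases <- purrr::map2(paths, labels, read_gtf_release,
                          catalog = catalog, ...)
  analyze_releases(releases, catalog = catalog, registry = registry,
                   class_map = class_map, na_mode = na_mode, sizes = sizes)
}

check_config <- function(config, fields) {
  miss <- setdiff(fields, names(config))
  if (length(miss) > 0L) {
    stopf("config is missing field(s): %s", paste(miss, collapse = ", "),
          class = "annochron_config_error")
  }
}

#' Orchestrate the pipeline from a declarative configuration
#'
#' The command-line surface of the package: one command plus one config (a
#' YAML file path or an equivalent named list) produces artifacts under
#' `config$out_dir`, along with `run_report.json` stating the exact setting
#' combination used (NA mode, consistency definitions, PAR patterns, conflict
#' policies) and a `manifest.tsv` with an MD5 per artifact.
#'
#' Commands: `build` (compendium matrix + id map), `census`
#' (addition/deletion, transformation and totals tables + summary JSON),
#' `transitions` (per-transcript statistics + distribution tables), `sankey`
#' (nodes/links JSON + long TSV), `coverage` (per-release exon-union table;
#' needs `chrom_sizes`), `hgnc` (deleted-gene overlap; needs `hgnc_path`),
#' `simulate` (synthetic corpus + ledger JSON).
#'
#' @param command One of the commands above.
#' @param config Named list or YAML file path. Recognized fields: `paths`,
#'   `labels`, `out_dir`, `na_mode`, `strict_lncrna_class`, `chrom_sizes`,
#'   `hgnc_path`, `catalog` (`"gencode"` or `"as_given"`), `model` (list of
#'   [churn_model()] arguments, for `simulate`).
#' @return Invisibly, a named character vector of artifact paths.
#' @export
run_annochron <- function(command = c("build", "census", "transitions",
                                      "sankey", "coverage", "hgnc",
                                      "simulate"),
                          config) {
  command <- match.arg(command)
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stopf("config file '%s' not found", config,
            class = "annochron_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    stopf("config must be a list or a YAML file path",
          class = "annochron_config_error")
  }
  check_config(config, "out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    readr::write_tsv(tibble::as_tibble(x), p)
    artifacts[name] <<- p
  }

  if (command == "simulate") {
    model <- do.call(churn_model, config$model %||% list())
    corpus <- generate_corpus(model, out_dir)
    ledger_path <- file.path(out_dir, "ledger.json")
    write_ledger_json(corpus$ledger, ledger_path)
    artifacts <- c(stats::setNames(corpus$paths, basename(corpus$paths)),
                   ledger.json = ledger_path,
                   chrom.sizes = corpus$sizes_path)
  } else {
    check_config(config, c("paths", "labels"))
    if (length(config$paths) != length(config$labels)) {
      stopf("paths and labels differ in length",
            class = "annochron_config_error")
    }
    catalog <- if (identical(config$catalog, "as_given")) {
      release_catalog(unlist(config$labels))
    } else {
      gencode_releases()
    }
    validate_release_labels(unlist(config$labels), catalog)
    na_mode <- config$na_mode %||% "IGNORE_NA"
    class_map <- biotype_class_map(strict = isTRUE(config$strict_lncrna_class))
    sizes <- if (!is.null(config$chrom_sizes)) {
      read_chrom_sizes(config$chrom_sizes)
    }
    res <- analyze_corpus(unlist(config$paths), unlist(config$labels),
                          catalog = catalog, class_map = class_map,
                          na_mode = na_mode, sizes = sizes)
    comp <- res$compendium

    if (command == "build") {
      p <- file.path(out_dir, "matrix.tsv")
      write_compendium_tsv(comp, p)
      artifacts["matrix.tsv"] <- p
      p <- file.path(out_dir, "id_map.tsv")
      write_id_map(res$map, p)
      artifacts["id_map.tsv"] <- p
      save_tsv(res$normalization$case_counts, "id_case_counts.tsv")
    } else if (command == "census") {
      save_tsv(res$census, "census.tsv")
      save_tsv(res$transformation, "transformation.tsv")
      save_tsv(comp$per_release, "totals.tsv")
      p <- file.path(out_dir, "summary.json")
      jsonlite::write_json(
        list(census = glance(res$census),
             consistency = as.data.frame(res$consistency),
             moonlighting = as.data.frame(res$moonlighting$summary)),
        p, auto_unbox = TRUE, digits = NA)
      artifacts["summary.json"] <- p
    } else if (command == "transitions") {
      save_tsv(res$transcript_stats, "transcript_stats.tsv")
      save_tsv(dplyr::count(res$transcript_stats, .data$transitions,
                            name = "n_transcripts"),
               "transition_distribution.tsv")
      save_tsv(dplyr::count(res$transcript_stats, .data$distinct_biotypes,
                            name = "n_transcripts"),
               "biotype_count_distribution.tsv")
    } else if (command == "sankey") {
      p <- file.path(out_dir, "sankey_class.json")
      write_sankey_json(res$sankey_class, p)
      artifacts["sankey_class.json"] <- p
      save_tsv(res$sankey_class$links, "sankey_class.tsv")
      p <- file.path(out_dir, "presence.tsv")
      write_presence_tsv(comp, p)
      artifacts["presence.tsv"] <- p
    } else if (command == "coverage") {
      check_config(config, "chrom_sizes")
      save_tsv(res$coverage, "coverage.tsv")
      save_tsv(res$growth, "growth.tsv")
    } else if (command == "hgnc") {
      check_config(config, "hgnc_path")
      symbols <- load_hgnc_symbols(config$hgnc_path)
      ov <- deleted_gene_overlap(comp, symbols)
      save_tsv(ov$overlap, "hgnc_overlap.tsv")
      p <- file.path(out_dir, "hgnc_summary.json")
      jsonlite::write_json(
        list(n_deleted_genes = ov$n_deleted_genes,
             n_overlap = ov$n_overlap,
             n_overlap_lncrna = ov$n_overlap_lncrna,
             n_hgnc_symbols = length(symbols$symbols)),
        p, auto_unbox = TRUE, digits = NA)
      artifacts["hgnc_summary.json"] <- p
    }
  }

  report <- list(
    command = command,
    settings = list(
      na_mode = config$na_mode %||% "IGNORE_NA",
      consistency_modes = c("strict", "lenient"),
      lncrna_class = if (isTRUE(config$strict_lncrna_class)) "strict" else "default_23",
      par_patterns = as.data.frame(default_par_patterns()),
      same_release_conflict_policy = "havana_first",
      version_suffixes = "stripped"
    ),
    inputs = if (!is.null(config$paths)) {
      data.frame(path = unlist(config$paths),
                 md5 = unname(tools::md5sum(unlist(config$paths))))
    }
  )
  report_path <- file.path(out_dir, "run_report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA)
  artifacts["run_report.json"] <- report_path
  manifest <- tibble::tibble(artifact = names(artifacts),
                             path = unname(artifacts),
                             md5 = unname(tools::md5sum(unname(artifacts))))
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  invisible(c(artifacts, manifest.tsv = manifest_path))
}
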