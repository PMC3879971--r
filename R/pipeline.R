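#' Default pipeline configuration
#'
#' Thresholds default to the analysis settings: e-value <= 1e-3, BSR >=
#' 0.33, 80% reciprocal coverage, 30% identity above 150 aligned residues
#' (higher below), 50% identity for the localization subset, Ks windows
#' nested from (0, 0.05) to (0, 1), gene-conversion exclusion above 5
#' matches, Ka/Ks positive-selection cut 1.5, 60-residue NTP window.
#'
#' @param fasta,id_map,predictions Input paths (`predictions` may be NULL
#'   when no localization analysis is wanted).
#' @param out_dir Output directory for report tables.
#' @param ... Overrides for any default listed above.
#' @return A config list (class `psr_config`).
#' @export
pipeline_config <- function(fasta = NULL, id_map = NULL, predictions = NULL,
                            out_dir = NULL, ...) {
  cfg <- list(
    fasta = fasta, id_map = id_map, predictions = predictions,
    out_dir = out_dir,
    max_e = 1e-3, min_bsr = 0.33, min_coverage = 0.8,
    long_cutoff_length = 150, long_cutoff_identity = 30,
    min_loc_identity = 50,
    gene_conversion_max_matches = 5,
    apply_gene_conversion_filter = FALSE,
    omega_threshold = 1.5,
    ks_min = 0,
    ks_windows = list(
      c(0, 0.05), c(0, 0.1), c(0, 0.25),
      c(0, 0.5), c(0, 0.75), c(0, 1)
    ),
    ntp_window = 60, complete_min_gap = 30,
    ties = "efron",
    genetic_code = 1L,
    seed = 1L
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(cfg)))
  cfg[names(over)] <- over
  structure(cfg, class = "psr_config")
}

#' Read / write a pipeline configuration
#'
#' Configurations serialise to YAML and round-trip unchanged.
#'
#' @param path YAML file.
#' @return For `read_config`, a `psr_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$ks_windows)) {
    raw$ks_windows <- purrr::map(raw$ks_windows, as.numeric)
  }
  do.call(pipeline_config, raw)
}

#' @rdname read_config
#' @param cfg A `psr_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full retention-analysis pipeline
#'
#' Executes the stages in order: load and translate CDSs, all-vs-all
#' alignment and pair filtering, double-linkage family clustering with
#' supercluster merging, Ks/Ka estimation, relocalization classification,
#' N-terminal mutation classification, and the Cox hazard-ratio table
#' over Ks windows. When `cfg$out_dir` is set, report tables and a run
#' manifest are written there.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of stage results: `proteome`, `pairs`, `families`,
#'   `duplication_proportion`, `divergence`, `statuses`, `ntp`,
#'   `ntp_summary`, `hazard_table`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "psr_config"), !is.null(cfg$fasta))
  records <- load_cds_fasta(cfg$fasta, cfg$id_map)
  proteome <- records |>
    select_representatives() |>
    build_proteome(table = cfg$genetic_code)
  aln <- align_all_pairs(proteome)
  idp <- identity_threshold_params(
    long_cutoff_length = cfg$long_cutoff_length,
    long_cutoff_identity = cfg$long_cutoff_identity
  )
  pairs <- filter_pairs(aln$pairs,
    max_e = cfg$max_e, min_bsr = cfg$min_bsr,
    identity_params = idp, min_coverage = cfg$min_coverage,
    min_loc_identity = cfg$min_loc_identity
  )
  g <- pair_graph(pairs)
  if (isTRUE(cfg$apply_gene_conversion_filter)) {
    g <- gene_conversion_filter(g, cfg$gene_conversion_max_matches)
  }
  families <- g |>
    double_linkage_clusters() |>
    merge_superclusters()
  dup_prop <- duplication_proportion(families, nrow(proteome))
  reciprocal <- dplyr::filter(pairs, .data$passed_reciprocal)
  divergence <- if (nrow(reciprocal) > 0) {
    estimate_pair_divergence(
      reciprocal[, c("id_a", "id_b")], proteome
    )
  } else {
    tibble::tibble()
  }
  loc_pairs <- dplyr::filter(pairs, .data$passed_localization_subset)
  statuses <- NULL
  ntp <- NULL
  ntp_summary <- NULL
  hazard <- NULL
  if (!is.null(cfg$predictions) && nrow(loc_pairs) > 0) {
    calls <- parse_predictions(cfg$predictions, dialect = "simple")
    statuses <- classify_relocalization(
      loc_pairs[, c("id_a", "id_b")], calls
    )
    ntp <- classify_pair_ntp(statuses, proteome,
      window_length = cfg$ntp_window,
      complete_min_gap = cfg$complete_min_gap
    )
    ntp_summary <- category_frequencies(ntp)
    dated <- dplyr::inner_join(
      statuses, divergence,
      by = c("id_a", "id_b")
    )
    if (nrow(dated) > 0 && length(unique(dated$status)) == 2) {
      hazard <- withCallingHandlers(
        ks_window_hazard_table(dated,
          windows = cfg$ks_windows,
          ties = cfg$ties, ks_min = cfg$ks_min
        ),
        warning = function(w) invokeRestart("muffleWarning")
      )
    }
  }
  results <- list(
    proteome = proteome,
    pairs = pairs,
    families = families,
    duplication_proportion = dup_prop,
    divergence = divergence,
    statuses = statuses,
    ntp = ntp,
    ntp_summary = ntp_summary,
    hazard_table = hazard,
    manifest = list(
      n_genes = nrow(proteome),
      n_aligned_pairs = nrow(aln$pairs),
      n_candidate = sum(pairs$passed_candidate),
      n_reciprocal = sum(pairs$passed_reciprocal),
      n_localization_subset = sum(pairs$passed_localization_subset),
      n_families = family_count(families),
      duplication_proportion = dup_prop,
      config = unclass(cfg)
    )
  )
  if (!is.null(cfg$out_dir)) {
    write_tables(results, cfg$out_dir)
  }
  results
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
}

#' Write the report tables of a pipeline run
#'
#' Writes `table1.tsv` (duplication proportions), `table2.tsv`
#' (relocalized/total counts and 2-dp frequency), `table3.tsv` (Ks-window
#' hazard ratios with significance stars), `fig1.tsv` (NTP category
#' frequencies with both PSR denominators), the per-pair stage TSVs and a
#' JSON-lines manifest.
#'
#' @param results Output of [run_pipeline()].
#' @param outdir Output directory (created when absent).
#' @return Invisibly, the vector of files written.
#' @export
write_tables <- function(results, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  written <- character(0)
  w <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv_file(df, p)
    written <<- c(written, p)
  }
  w(
    tibble::tibble(
      measure = "duplication_proportion",
      value = sprintf("%.2f", results$duplication_proportion)
    ),
    "table1.tsv"
  )
  if (!is.null(results$statuses)) {
    fr <- relocalization_frequency(results$statuses)
    w(
      tibble::tibble(
        rd = fr$rd, tnd = fr$tnd, fr = sprintf("%.2f", fr$fr)
      ),
      "table2.tsv"
    )
  }
  if (!is.null(results$hazard_table)) {
    ht <- results$hazard_table |>
      dplyr::mutate(
        window = sprintf("%g < Ks < %g", .data$window_lo, .data$window_hi)
      ) |>
      dplyr::select(
        "window", "n0", "n1", "hazard_ratio",
        "ci_lo", "ci_hi", "p_value", "stars"
      )
    w(ht, "table3.tsv")
  }
  if (!is.null(results$ntp_summary)) w(results$ntp_summary, "fig1.tsv")
  if (nrow(results$pairs) > 0) {
    w(
      results$pairs[, c(
        "id_a", "id_b", "pident", "length", "cov_a", "cov_b",
        "evalue", "bitscore", "bsr", "passed_candidate",
        "passed_reciprocal", "passed_localization_subset"
      )],
      "pairs.tsv"
    )
  }
  if (nrow(results$families) > 0) {
    w(
      results$families |>
        dplyr::mutate(members = purrr::map_chr(
          .data$members, paste,
          collapse = ","
        )),
      "families.tsv"
    )
  }
  if (!is.null(results$divergence) && nrow(results$divergence) > 0) {
    w(results$divergence, "divergence.tsv")
  }
  manifest <- file.path(outdir, "manifest.jsonl")
  m <- results$manifest
  writeLines(
    sprintf(
      paste0(
        '{"n_genes":%d,"n_aligned_pairs":%d,"n_candidate":%d,',
        '"n_reciprocal":%d,"n_localization_subset":%d,"n_families":%d,',
        '"duplication_proportion":%.6f}'
      ),
      m$n_genes, m$n_aligned_pairs, m$n_candidate, m$n_reciprocal,
      m$n_localization_subset, m$n_families, m$duplication_proportion
    ),
    manifest
  )
  written <- c(written, manifest)
  invisible(written)
}
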