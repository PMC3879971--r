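#' Default protein scoring scheme
#'
#' BLOSUM62 with affine gaps (open 11, extend 1, as BLAST's protein
#' defaults) and the matching gapped Karlin-Altschul parameters used to
#' convert raw scores to bit scores and e-values.
#'
#' @param gap_open,gap_extend Positive gap costs.
#' @param lambda,K Karlin-Altschul statistics for the scheme.
#' @return A list describing the scheme.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041) {
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  list(
    substitution_matrix = get("BLOSUM62", envir = environment()),
    gap_open = gap_open, gap_extend = gap_extend,
    lambda = lambda, K = K
  )
}

raw_to_bits <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$K)) / log(2)
}

#' Optimal local alignment of two proteins
#'
#' Smith-Waterman alignment under the given scoring scheme, with bit score
#' and e-value derived from Karlin-Altschul statistics over a search space
#' of `len(a) * len(b) * database_count`.
#'
#' @param a,b Protein sequences (plain strings).
#' @param scheme A [scoring_scheme()].
#' @param id_a,id_b Identifiers attached to the result.
#' @param database_count Effective number of database sequences for the
#'   e-value (1 for a single pairwise comparison).
#' @return A one-row tibble with columns `id_a`, `id_b`, `raw_score`,
#'   `bitscore`, `evalue`, `pident`, `length` (alignment columns), `cov_a`,
#'   `cov_b`, `aligned_a`, `aligned_b`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        id_a = "a", id_b = "b", database_count = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "local",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(ga)
  ident <- sum(strsplit(ga, "")[[1]] == strsplit(gb, "")[[1]] &
    strsplit(ga, "")[[1]] != "-")
  raw <- Biostrings::score(aln)
  bits <- raw_to_bits(raw, scheme)
  tibble::tibble(
    id_a = id_a, id_b = id_b,
    raw_score = raw,
    bitscore = bits,
    evalue = nchar(a) * nchar(b) * database_count * 2^(-bits),
    pident = 100 * ident / len,
    length = len,
    cov_a = sum(strsplit(ga, "")[[1]] != "-") / nchar(a),
    cov_b = sum(strsplit(gb, "")[[1]] != "-") / nchar(b),
    aligned_a = ga, aligned_b = gb
  )
}

#' All-vs-all intraspecific alignment
#'
#' Aligns every unordered pair of proteins in a proteome and computes each
#' protein's self-alignment bit score, the ingredients of the BLAST score
#' ratio.
#'
#' @param proteome A tibble with `protein_id` and `protein` columns (see
#'   [build_proteome()]).
#' @param scheme A [scoring_scheme()].
#' @return A list with `pairs` (tibble of pairwise alignments including a
#'   `bsr` column) and `self_scores` (tibble `protein_id`, `self_bits`).
#' @export
align_all_pairs <- function(proteome, scheme = scoring_scheme()) {
  stopifnot(nrow(proteome) >= 1)
  ids <- proteome$protein_id
  seqs <- stats::setNames(proteome$protein, ids)
  n <- length(ids)
  self <- tibble::tibble(
    protein_id = ids,
    self_bits = purrr::map_dbl(
      ids,
      function(i) local_align(seqs[[i]], seqs[[i]], scheme)$bitscore
    )
  )
  if (n < 2) {
    return(list(pairs = tibble::tibble(), self_scores = self))
  }
  combos <- utils::combn(ids, 2)
  pairs <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]
    j <- combos[2, k]
    local_align(seqs[[i]], seqs[[j]], scheme,
      id_a = i, id_b = j, database_count = n
    )
  })
  sv <- stats::setNames(self$self_bits, self$protein_id)
  pairs$bsr <- unname(compute_bsr(pairs$bitscore, sv[pairs$id_a], sv[pairs$id_b]))
  list(pairs = pairs, self_scores = self)
}

#' BLAST score ratio
#'
#' Normalises a pair's alignment bit score by the larger of the two
#' self-alignment scores, giving a length- and composition-normalised
#' similarity in (0, 1]. With `convention = "both"` the function instead
#' returns the smaller of the two per-query ratios, so a downstream
#' threshold requires both ratios to pass.
#'
#' @param score_ab Bit score of the A-B alignment.
#' @param self_a,self_b Self-alignment bit scores (must be positive).
#' @param convention `"max"` (default: divide by the larger self score) or
#'   `"both"` (minimum of the two per-query ratios; equivalent for
#'   thresholding to requiring both).
#' @return The score ratio (vectorised).
#' @export
compute_bsr <- function(score_ab, self_a, self_b, convention = c("max", "both")) {
  convention <- match.arg(convention)
  if (any(self_a <= 0) || any(self_b <= 0)) {
    stop("nonpositive self-score: degenerate protein")
  }
  if (convention == "max") {
    score_ab / pmax(self_a, self_b)
  } else {
    pmin(score_ab / self_a, score_ab / self_b)
  }
}

#' Identity-threshold parameters
#'
#' For alignments of at least `long_cutoff_length` residues a flat identity
#' cutoff applies; shorter alignments need a higher identity following an
#' empirical twilight-zone curve
#' `p(L) = n0 + scale * L^(-exponent * (1 + exp(-L/1000)))`, with the offset
#' `n0` calibrated so the curve is continuous at the cutoff length.
#'
#' @param long_cutoff_length Alignment length (residues) above which the
#'   flat cutoff applies (default 150).
#' @param long_cutoff_identity Flat identity cutoff in percent (default 30).
#' @param curve_scale,curve_exponent Curve parameters.
#' @return A parameter list consumed by [min_identity_threshold()].
#' @export
identity_threshold_params <- function(long_cutoff_length = 150,
                                      long_cutoff_identity = 30,
                                      curve_scale = 480,
                                      curve_exponent = 0.32) {
  raw <- function(L) {
    curve_scale * L^(-curve_exponent * (1 + exp(-L / 1000)))
  }
  offset <- long_cutoff_identity - raw(long_cutoff_length)
  list(
    long_cutoff_length = long_cutoff_length,
    long_cutoff_identity = long_cutoff_identity,
    curve_scale = curve_scale,
    curve_exponent = curve_exponent,
    curve_offset = offset
  )
}

#' Minimum percent identity required at a given alignment length
#'
#' @param L Alignment length in columns (vectorised).
#' @param params From [identity_threshold_params()].
#' @return Percent identity threshold; constant for
#'   `L >= long_cutoff_length`, higher and nonincreasing below it.
#' @examples
#' min_identity_threshold(c(50, 150, 400))
#' @export
min_identity_threshold <- function(L, params = identity_threshold_params()) {
  stopifnot(all(L >= 1))
  curve <- params$curve_offset +
    params$curve_scale * L^(-params$curve_exponent * (1 + exp(-L / 1000)))
  ifelse(L >= params$long_cutoff_length, params$long_cutoff_identity, curve)
}

#' Candidate-pair filter (e-value and BSR gates)
#'
#' @param pairs A tibble with `evalue` and `bsr` columns.
#' @param max_e Inclusive e-value ceiling (default 1e-3).
#' @param min_bsr Inclusive BSR floor (default 0.33).
#' @return The input with a logical `passed_candidate` column.
#' @export
candidate_filter <- function(pairs, max_e = 1e-3, min_bsr = 0.33) {
  dplyr::mutate(pairs,
    passed_candidate = .data$evalue <= max_e & .data$bsr >= min_bsr
  )
}

#' Reciprocal filter (coverage and length-dependent identity)
#'
#' A pair passes only if the alignment covers at least `min_coverage` of
#' BOTH proteins' full lengths and the percent identity meets the
#' length-dependent threshold.
#'
#' @param pairs Output of [candidate_filter()] with `pident`, `length`,
#'   `cov_a`, `cov_b` columns.
#' @param params Identity-threshold parameters.
#' @param min_coverage Fraction of each full protein length that must be
#'   aligned (default 0.8).
#' @return The input with a logical `passed_reciprocal` column (always
#'   `FALSE` where `passed_candidate` is).
#' @export
reciprocal_filter <- function(pairs, params = identity_threshold_params(),
                              min_coverage = 0.8) {
  dplyr::mutate(pairs,
    passed_reciprocal = .data$passed_candidate &
      .data$cov_a >= min_coverage & .data$cov_b >= min_coverage &
      .data$pident >= min_identity_threshold(.data$length, params)
  )
}

#' Localization-study subset filter
#'
#' The stricter gate applied before subcellular-localization comparison:
#' at least 50% identity and 80% coverage of both proteins.
#'
#' @param pairs Output of [reciprocal_filter()].
#' @param min_identity Percent identity floor (default 50).
#' @param min_coverage Coverage floor (default 0.8).
#' @return The input with a logical `passed_localization_subset` column.
#' @export
localization_subset_filter <- function(pairs, min_identity = 50,
                                       min_coverage = 0.8) {
  dplyr::mutate(pairs,
    passed_localization_subset = .data$passed_reciprocal &
      .data$pident >= min_identity &
      .data$cov_a >= min_coverage & .data$cov_b >= min_coverage
  )
}

#' Read BLAST tabular (outfmt 6) alignments
#'
#' Reads the 12-column BLAST tabular dialect plus a sidecar of full protein
#' lengths (for coverage). Self-hits become self-scores; duplicate
#' unordered pairs collapse to the highest bit score. Pairs involving a
#' protein with no self-hit are dropped with a warning (the BSR is
#' undefined for them).
#'
#' @param path BLAST tabular file (qseqid sseqid pident length mismatch
#'   gapopen qstart qend sstart send evalue bitscore).
#' @param lengths_path Tab-separated sidecar `protein_id<TAB>length`.
#' @return A list with `pairs` (tibble incl. `bsr`, `cov_a`, `cov_b`) and
#'   `self_scores`.
#' @export
read_tabular_alignments <- function(path, lengths_path) {
  cols <- c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"
  )
  tab <- utils::read.table(path,
    sep = "\t", header = FALSE, quote = "",
    col.names = cols,
    colClasses = c(
      "character", "character", rep("numeric", 4),
      rep("integer", 4), rep("numeric", 2)
    )
  ) |> tibble::as_tibble()
  lens <- utils::read.table(lengths_path,
    sep = "\t", header = FALSE,
    col.names = c("protein_id", "plen"),
    colClasses = c("character", "integer")
  ) |> tibble::as_tibble()
  self <- tab |>
    dplyr::filter(.data$qseqid == .data$sseqid) |>
    dplyr::group_by(protein_id = .data$qseqid) |>
    dplyr::summarise(self_bits = max(.data$bitscore), .groups = "drop")
  hits <- tab |>
    dplyr::filter(.data$qseqid != .data$sseqid) |>
    dplyr::mutate(
      id_a = pmin(.data$qseqid, .data$sseqid),
      id_b = pmax(.data$qseqid, .data$sseqid)
    ) |>
    dplyr::group_by(.data$id_a, .data$id_b) |>
    dplyr::arrange(dplyr::desc(.data$bitscore), .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  known <- self$protein_id
  orphan <- !(hits$qseqid %in% known) | !(hits$sseqid %in% known)
  if (any(orphan)) {
    warning(
      sum(orphan), " pair(s) dropped: missing self-hit for ",
      paste(unique(c(
        hits$qseqid[!(hits$qseqid %in% known)],
        hits$sseqid[!(hits$sseqid %in% known)]
      )), collapse = ", ")
    )
    hits <- hits[!orphan, , drop = FALSE]
  }
  sv <- stats::setNames(self$self_bits, self$protein_id)
  lv <- stats::setNames(lens$plen, lens$protein_id)
  pairs <- hits |>
    dplyr::mutate(
      bsr = compute_bsr(.data$bitscore, sv[.data$id_a], sv[.data$id_b]),
      cov_a = (abs(.data$qend - .data$qstart) + 1) /
        lv[ifelse(.data$qseqid == .data$id_a, .data$id_a, .data$id_b)],
      cov_b = (abs(.data$send - .data$sstart) + 1) /
        lv[ifelse(.data$sseqid == .data$id_b, .data$id_b, .data$id_a)]
    ) |>
    dplyr::select(
      "id_a", "id_b", "pident", "length", "evalue",
      "bitscore", "bsr", "cov_a", "cov_b"
    )
  # cov_a must refer to id_a's length regardless of query/subject order
  swapped <- hits$qseqid != hits$id_a
  qcov <- unname((abs(hits$qend - hits$qstart) + 1) / lv[hits$qseqid])
  scov <- unname((abs(hits$send - hits$sstart) + 1) / lv[hits$sseqid])
  pairs$cov_a <- ifelse(swapped, scov, qcov)
  pairs$cov_b <- ifelse(swapped, qcov, scov)
  pairs$bsr <- unname(pairs$bsr)
  list(pairs = pairs, self_scores = self)
}

#' Run the full pair-filter cascade
#'
#' Convenience wrapper applying [candidate_filter()], [reciprocal_filter()]
#' and [localization_subset_filter()] in order.
#'
#' @param pairs An alignment tibble with `evalue`, `bsr`, `pident`,
#'   `length`, `cov_a`, `cov_b`.
#' @param max_e,min_bsr,identity_params,min_coverage,min_loc_identity
#'   Thresholds forwarded to the three filters.
#' @return The input with the three `passed_*` flag columns.
#' @export
filter_pairs <- function(pairs, max_e = 1e-3, min_bsr = 0.33,
                         identity_params = identity_threshold_params(),
                         min_coverage = 0.8, min_loc_identity = 50) {
  pairs |>
    candidate_filter(max_e = max_e, min_bsr = min_bsr) |>
    reciprocal_filter(params = identity_params, min_coverage = min_coverage) |>
    localization_subset_filter(
      min_identity = min_loc_identity,
      min_coverage = min_coverage
    )
}
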