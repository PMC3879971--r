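#' End-to-end global alignment of two proteins
#'
#' Needleman-Wunsch alignment (end gaps penalised) used before N-terminal
#' window extraction: a local alignment clips termini and would hide
#' terminal indels.
#'
#' @param a,b Protein strings.
#' @param scheme A [scoring_scheme()].
#' @return A list with `aligned_a`, `aligned_b` (equal-length gapped
#'   strings) and `score`.
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global",
    substitutionMatrix = scheme$substitution_matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  list(
    aligned_a = as.character(Biostrings::alignedPattern(aln)),
    aligned_b = as.character(Biostrings::alignedSubject(aln)),
    score = Biostrings::score(aln)
  )
}

#' Extract the N-terminal peptide window from an alignment
#'
#' Returns the leading alignment columns containing the first
#' `window_length` residues of the longer member, gaps included. If the
#' alignment has fewer residues than the window, the whole alignment is
#' returned with a warning.
#'
#' @param aligned_a,aligned_b Equal-length gapped strings from a global
#'   alignment.
#' @param window_length N-terminal window in residues (default 60, the
#'   midpoint of the 13-85-residue range typical of N-terminal targeting
#'   peptides).
#' @return A list `sub_a`, `sub_b` of equal-length gapped strings.
#' @export
extract_ntp_window <- function(aligned_a, aligned_b, window_length = 60) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  na <- sum(ca != "-")
  nb <- sum(cb != "-")
  longer <- if (na >= nb) ca else cb
  res_count <- cumsum(longer != "-")
  if (max(res_count) < window_length) {
    warning("alignment shorter than NTP window; whole alignment used",
      call. = FALSE
    )
    cut <- length(longer)
  } else {
    cut <- which(res_count == window_length)[1]
  }
  list(
    sub_a = paste(ca[1:cut], collapse = ""),
    sub_b = paste(cb[1:cut], collapse = "")
  )
}

gap_runs <- function(x) {
  r <- rle(strsplit(x, "")[[1]] == "-")
  starts <- cumsum(c(1, r$lengths))[seq_along(r$lengths)]
  tibble::tibble(
    start = starts[r$values],
    length = r$lengths[r$values]
  )
}

#' Classify the N-terminal peptide mutation type of a pair
#'
#' Categories: `COMPLETE` if either string's gap content inside the window
#' includes a run of at least `complete_min_gap` residues or spans the
#' whole window (gain/loss of the peptide); else `TERMINAL` if a gap run
#' touches the first alignment column; else `PARTIAL` for any internal
#' indel; else `NONE` (substitutions only, including identical windows).
#'
#' @param sub_a,sub_b Equal-length gapped strings (the NTP window).
#' @param complete_min_gap Minimal single gap-run length for COMPLETE
#'   (default 30 residues).
#' @return One of `"NONE"`, `"PARTIAL"`, `"TERMINAL"`, `"COMPLETE"`.
#' @export
classify_ntp_mutation <- function(sub_a, sub_b, complete_min_gap = 30) {
  if (nchar(sub_a) != nchar(sub_b)) {
    stop("NTP window strings must have equal length")
  }
  w <- nchar(sub_a)
  runs <- dplyr::bind_rows(gap_runs(sub_a), gap_runs(sub_b))
  if (nrow(runs) == 0) {
    return("NONE")
  }
  if (any(runs$length >= complete_min_gap) || any(runs$length == w)) {
    return("COMPLETE")
  }
  if (any(runs$start == 1)) {
    return("TERMINAL")
  }
  "PARTIAL"
}

#' N-terminal mutation classes for a table of pairs
#'
#' Re-aligns each pair end-to-end, extracts the N-terminal window and
#' classifies it.
#'
#' @param pairs Tibble with `id_a`, `id_b`.
#' @param proteome Tibble with `protein_id`, `protein`.
#' @param window_length,complete_min_gap See [extract_ntp_window()] and
#'   [classify_ntp_mutation()].
#' @return `pairs` with an added `ntp_class` column.
#' @export
classify_pair_ntp <- function(pairs, proteome, window_length = 60,
                              complete_min_gap = 30) {
  prot <- stats::setNames(proteome$protein, proteome$protein_id)
  cls <- purrr::map_chr(seq_len(nrow(pairs)), function(i) {
    aln <- global_align(prot[[pairs$id_a[i]]], prot[[pairs$id_b[i]]])
    win <- suppressWarnings(
      extract_ntp_window(aln$aligned_a, aln$aligned_b, window_length)
    )
    classify_ntp_mutation(win$sub_a, win$sub_b, complete_min_gap)
  })
  dplyr::mutate(pairs, ntp_class = cls)
}

#' Category frequencies and PSR frequency per NTP mutation class
#'
#' For each mutation category reports the pair count, its fraction of all
#' pairs, and two relocalization summaries: `psr_within` (relocalized
#' pairs in the category / pairs in the category) and `share_of_reloc`
#' (relocalized pairs in the category / all relocalized pairs).
#'
#' @param classified Tibble with `ntp_class` and `status` columns.
#' @return A tibble with one row per category present.
#' @export
category_frequencies <- function(classified) {
  stopifnot(nrow(classified) > 0)
  total <- nrow(classified)
  total_reloc <- sum(classified$status == "RELOCALIZED")
  classified |>
    dplyr::group_by(ntp_class = factor(.data$ntp_class,
      levels = c("NONE", "PARTIAL", "TERMINAL", "COMPLETE")
    )) |>
    dplyr::summarise(
      n = dplyr::n(),
      fraction = dplyr::n() / total,
      n_reloc = sum(.data$status == "RELOCALIZED"),
      psr_within = .data$n_reloc / .data$n,
      share_of_reloc = if (total_reloc > 0) {
        .data$n_reloc / total_reloc
      } else {
        NA_real_
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(ntp_class = as.character(.data$ntp_class))
}
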