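#' Default compartment vocabulary for fixtures and examples
#' @export
default_compartment_vocabulary <- function() {
  c("cytoplasm", "nucleus", "mitochondrion", "secreted")
}

#' Parse subcellular-localization predictions
#'
#' Two dialects are supported. `simple`: one tab-separated line per
#' protein, `protein_id<TAB>compartment[<TAB>confidence]`. `multiloc2`:
#' one line per protein with the protein ID followed by
#' `compartment: score` fields; the top-scoring compartment wins, score
#' ties broken by vocabulary order with a warning.
#'
#' @param path Prediction file.
#' @param dialect `"simple"` or `"multiloc2"`.
#' @param vocabulary Closed set of allowed compartment labels.
#' @return A tibble `protein_id`, `compartment`, `confidence` (NA when the
#'   dialect carries none).
#' @export
parse_predictions <- function(path, dialect = c("simple", "multiloc2"),
                              vocabulary = default_compartment_vocabulary()) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "simple") {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- tibble::tibble(
      protein_id = purrr::map_chr(parts, 1),
      compartment = purrr::map_chr(parts, 2),
      confidence = purrr::map_dbl(
        parts,
        function(p) if (length(p) >= 3) as.numeric(p[3]) else NA_real_
      )
    )
  } else {
    out <- purrr::map_dfr(lines, function(l) {
      toks <- strsplit(trimws(l), "\\s+")[[1]]
      id <- toks[1]
      rest <- paste(toks[-1], collapse = " ")
      m <- gregexpr("([A-Za-z_]+):\\s*([0-9.]+)", rest)[[1]]
      fields <- regmatches(rest, list(m))[[1]]
      comps <- sub(":.*$", "", fields)
      scores <- as.numeric(sub("^.*:\\s*", "", fields))
      top <- max(scores)
      tied <- comps[scores == top]
      if (length(tied) > 1) {
        tied <- tied[order(match(tied, vocabulary))]
        warning(
          "tie at top score for ", id, "; broken by vocabulary order",
          call. = FALSE
        )
      }
      tibble::tibble(
        protein_id = id, compartment = tied[1], confidence = top
      )
    })
  }
  unknown <- setdiff(unique(out$compartment), vocabulary)
  if (length(unknown) > 0) {
    stop(
      "unknown compartment label(s): ", paste(unknown, collapse = ", "),
      "; vocabulary is: ", paste(vocabulary, collapse = ", ")
    )
  }
  out
}

#' Classify duplicate pairs as relocalized or nonrelocalized
#'
#' A pair is RELOCALIZED when its two proteins have different predicted
#' compartments and NONRELOCALIZED when the compartments are identical.
#' Pairs with a missing prediction for either member are excluded with a
#' warning.
#'
#' @param pairs Tibble with `id_a`, `id_b` (typically the
#'   localization-subset pairs).
#' @param calls Tibble from [parse_predictions()].
#' @return `pairs` with added `compartment_a`, `compartment_b`, `status`
#'   columns, restricted to pairs with both calls present.
#' @export
classify_relocalization <- function(pairs, calls) {
  cv <- stats::setNames(calls$compartment, calls$protein_id)
  out <- pairs |>
    dplyr::mutate(
      compartment_a = unname(cv[.data$id_a]),
      compartment_b = unname(cv[.data$id_b])
    )
  missing <- is.na(out$compartment_a) | is.na(out$compartment_b)
  if (any(missing)) {
    warning(
      sum(missing), " pair(s) excluded: missing localization call"
    )
    out <- out[!missing, , drop = FALSE]
  }
  dplyr::mutate(out,
    status = ifelse(.data$compartment_a == .data$compartment_b,
      "NONRELOCALIZED", "RELOCALIZED"
    )
  )
}

#' Relocalization frequency
#'
#' @param statuses Tibble with a `status` column.
#' @return A one-row tibble `rd` (relocalized duplicates), `tnd` (total
#'   number of duplicates), `fr` (frequency rd/tnd). Rounding is left to
#'   report writers.
#' @export
relocalization_frequency <- function(statuses) {
  if (nrow(statuses) == 0) stop("no relocalization statuses supplied")
  tibble::tibble(
    rd = sum(statuses$status == "RELOCALIZED"),
    tnd = nrow(statuses),
    fr = sum(statuses$status == "RELOCALIZED") / nrow(statuses)
  )
}

#' Pooled relocalization frequencies per eukaryotic group
#'
#' @param per_species Tibble with `species`, `rd`, `tnd`.
#' @param groups Tibble with `species`, `group`.
#' @return Per-group tibble `group`, `rd`, `tnd`, `fr` with pooled counts
#'   (`fr = sum(rd)/sum(tnd)`); groups with no species are omitted.
#' @export
group_summary <- function(per_species, groups) {
  stopifnot(all(per_species$species %in% groups$species))
  per_species |>
    dplyr::inner_join(groups, by = "species") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      rd = sum(.data$rd), tnd = sum(.data$tnd),
      fr = sum(.data$rd) / sum(.data$tnd),
      .groups = "drop"
    )
}
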