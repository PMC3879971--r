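#' Load coding sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) FASTA of coding sequences and returns one
#' row per entry. Headers are taken to carry transcript IDs (first
#' whitespace-delimited token); the remainder of the header line is kept as a
#' free-text description. An optional ID map links transcripts to gene and
#' protein IDs; transcripts absent from the map fall back to
#' `gene_id = transcript_id` with a warning.
#'
#' @param path Path to a FASTA file of CDS (A/C/G/T/N alphabet, case
#'   insensitive).
#' @param id_map Optional path to a 3-column tab-separated file with columns
#'   `gene_id`, `transcript_id`, `protein_id` (no header required; a header
#'   row with those names is tolerated).
#' @return A tibble with columns `gene_id`, `transcript_id`, `protein_id`,
#'   `description`, `cds`, `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 demo", "ATGAAATAA"), fa)
#' load_cds_fasta(fa)
#' @export
load_cds_fasta <- function(path, id_map = NULL) {
  stopifnot(file.exists(path))
  # read as raw strings so the A/C/G/T/N alphabet rule is enforced here,
  # with an error naming the offending entries
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tibble::tibble(
      gene_id = character(), transcript_id = character(),
      protein_id = character(), description = character(),
      cds = character(), length = integer()
    ))
  }
  headers <- names(set)
  transcript_id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
    sub("^\\S+\\s+", "", headers), ""
  )
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop(
      "non-IUPAC characters (outside A/C/G/T/N) in CDS entries: ",
      paste(transcript_id[bad], collapse = ", ")
    )
  }
  out <- tibble::tibble(
    transcript_id = unname(transcript_id),
    description = unname(description),
    cds = unname(seqs),
    length = unname(nchar(seqs))
  )
  if (!is.null(id_map)) {
    map <- read_id_map(id_map)
    out <- dplyr::left_join(out, map, by = "transcript_id")
    missing <- is.na(out$gene_id)
    if (any(missing)) {
      warning(
        sum(missing), " transcript(s) absent from id_map; ",
        "gene_id defaulted to transcript_id"
      )
      out$gene_id[missing] <- out$transcript_id[missing]
      out$protein_id[missing] <- out$transcript_id[missing]
    }
  } else {
    out$gene_id <- out$transcript_id
    out$protein_id <- out$transcript_id
  }
  dplyr::select(
    out, "gene_id", "transcript_id", "protein_id",
    "description", "cds", "length"
  )
}

read_id_map <- function(path) {
  map <- utils::read.table(path,
    sep = "\t", header = FALSE, quote = "",
    col.names = c("gene_id", "transcript_id", "protein_id"),
    colClasses = "character"
  )
  if (nrow(map) > 0 && identical(map$gene_id[1], "gene_id")) {
    map <- map[-1, , drop = FALSE]
  }
  tibble::as_tibble(map)
}

#' Select one representative CDS per gene
#'
#' For genes with alternative transcripts the longest CDS represents the
#' gene; equal lengths are broken by the lexicographically smallest
#' transcript ID so the choice is deterministic.
#'
#' @param records A tibble as returned by [load_cds_fasta()].
#' @return A tibble with one row per `gene_id`.
#' @export
select_representatives <- function(records) {
  stopifnot(nrow(records) > 0)
  records |>
    dplyr::arrange(
      .data$gene_id, dplyr::desc(.data$length),
      .data$transcript_id
    ) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE)
}

#' Translate a coding sequence
#'
#' Standard-code conceptual translation. An incomplete trailing codon is
#' trimmed with a warning; one trailing stop codon is stripped silently.
#' A stop codon internal to the sequence marks the translation invalid
#' (excluded from downstream pairing) rather than raising an error.
#'
#' @param cds A CDS string over A/C/G/T/N.
#' @param table NCBI genetic-code identifier (default 1, the standard code).
#' @return A list with elements `residues` (character), `valid` (logical)
#'   and `trimmed` (logical, whether trailing bases were discarded).
#' @examples
#' translate_cds("ATGAAATAA")$residues # "MK"
#' @export
translate_cds <- function(cds, table = 1L) {
  stopifnot(is.character(cds), length(cds) == 1, nchar(cds) >= 3)
  trimmed <- FALSE
  extra <- nchar(cds) %% 3
  if (extra > 0) {
    warning("CDS length not a multiple of 3; trailing ", extra,
      " base(s) trimmed",
      call. = FALSE
    )
    cds <- substr(cds, 1, nchar(cds) - extra)
    trimmed <- TRUE
  }
  code <- Biostrings::getGeneticCode(as.character(table))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds),
    genetic.code = code, if.fuzzy.codon = "solve"
  ))
  # strip exactly one trailing stop
  if (endsWith(aa, "*")) aa <- substr(aa, 1, nchar(aa) - 1)
  list(
    residues = aa,
    valid = nchar(aa) >= 1 && !grepl("\\*", aa, fixed = FALSE),
    trimmed = trimmed
  )
}

#' Build a species proteome from representative CDSs
#'
#' Translates every representative CDS and drops genes whose translation
#' contains an internal stop codon (with a warning naming them).
#'
#' @param representatives A tibble from [select_representatives()].
#' @param table Genetic-code identifier passed to [translate_cds()].
#' @return The input tibble with added `protein` and `protein_length`
#'   columns, restricted to valid translations.
#' @export
build_proteome <- function(representatives, table = 1L) {
  tr <- purrr::map(representatives$cds, function(s) {
    withCallingHandlers(
      translate_cds(s, table = table),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  res <- representatives |>
    dplyr::mutate(
      protein = purrr::map_chr(tr, "residues"),
      protein_valid = purrr::map_lgl(tr, "valid")
    )
  if (any(!res$protein_valid)) {
    warning(
      "excluded gene(s) with internal stop codons: ",
      paste(res$gene_id[!res$protein_valid], collapse = ", ")
    )
  }
  res |>
    dplyr::filter(.data$protein_valid) |>
    dplyr::mutate(protein_length = nchar(.data$protein)) |>
    dplyr::select(-"protein_valid")
}
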