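#' Simulate a duplicate-retention survival dataset
#'
#' Draws duplicate pairs whose Ks "lifetimes" follow group-specific
#' constant-hazard (exponential) death processes: relocalized pairs die at
#' rate `death_rate_reloc`, nonrelocalized at `death_rate_nonreloc`, so
#' the ground-truth hazard ratio (nonrelocalized vs relocalized) is
#' `death_rate_nonreloc / death_rate_reloc`. Relocalization status is
#' Bernoulli. Lifetimes are truncated to the open Ks window by rejection
#' sampling, exactly matching the window filter of the analysis.
#'
#' @param n_pairs Number of observed pairs.
#' @param p_relocalized Probability a pair is relocalized.
#' @param death_rate_reloc,death_rate_nonreloc Exponential hazards per Ks
#'   unit (must be positive).
#' @param ks_window Open observation window `c(lo, hi)`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A list with `records` (tibble `time`, `dp`, `status`) and
#'   `truth` (list incl. `true_hr`).
#' @export
simulate_retention_dataset <- function(n_pairs = 5000,
                                       p_relocalized = 0.25,
                                       death_rate_reloc = 1,
                                       death_rate_nonreloc = 1.5,
                                       ks_window = c(0, 1),
                                       seed = 1L) {
  stopifnot(
    n_pairs >= 1, p_relocalized >= 0, p_relocalized <= 1,
    death_rate_reloc > 0, death_rate_nonreloc > 0,
    ks_window[1] < ks_window[2]
  )
  acc <- function(rate) {
    stats::pexp(ks_window[2], rate) - stats::pexp(ks_window[1], rate)
  }
  if (min(acc(death_rate_reloc), acc(death_rate_nonreloc)) < 1e-6) {
    stop("ks_window has vanishing acceptance probability")
  }
  set.seed(seed)
  times <- numeric(0)
  dps <- integer(0)
  while (length(times) < n_pairs) {
    m <- max(2 * n_pairs, 100)
    status <- stats::rbinom(m, 1, p_relocalized) # 1 = relocalized
    rate <- ifelse(status == 1, death_rate_reloc, death_rate_nonreloc)
    t <- stats::rexp(m, rate)
    keep <- t > ks_window[1] & t < ks_window[2]
    times <- c(times, t[keep])
    dps <- c(dps, 1L - status[keep]) # dp = 1 for nonrelocalized
  }
  times <- times[seq_len(n_pairs)]
  dps <- dps[seq_len(n_pairs)]
  list(
    records = tibble::tibble(
      time = times, dp = dps,
      status = ifelse(dps == 1L, "NONRELOCALIZED", "RELOCALIZED")
    ),
    truth = list(
      true_hr = death_rate_nonreloc / death_rate_reloc,
      p_relocalized = p_relocalized,
      ks_window = ks_window,
      seed = seed
    )
  )
}

#' Point-mutate a coding sequence
#'
#' Per round, each site is substituted with the given probability to a
#' uniformly chosen different base; substitutions that would create an
#' internal stop codon are redrawn among the remaining bases.
#'
#' @param cds CDS string (length a multiple of 3, no internal stops).
#' @param rounds Number of mutation rounds.
#' @param rate Per-site substitution probability per round.
#' @param rng_seed Optional integer seed (when `NULL` the current RNG
#'   stream is used, so callers can manage determinism themselves).
#' @return The mutated CDS string.
#' @export
mutate_sequence <- function(cds, rounds = 1, rate = 0.01, rng_seed = NULL) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  s <- strsplit(cds, "")[[1]]
  n <- length(s)
  for (r in seq_len(rounds)) {
    hit <- which(stats::runif(n) < rate)
    for (i in hit) {
      codon_start <- 3 * ((i - 1) %/% 3) + 1
      alts <- setdiff(bases, s[i])
      alts <- sample(alts)
      for (b in alts) {
        cand <- s
        cand[i] <- b
        codon <- paste(cand[codon_start:(codon_start + 2)], collapse = "")
        if (!(codon %in% stops)) {
          s <- cand
          break
        }
      }
    }
  }
  paste(s, collapse = "")
}

random_cds <- function(n_codons) {
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(
    expand.grid(bases, bases, bases), 1, paste,
    collapse = ""
  )
  pool <- setdiff(all_codons, stops)
  paste0(
    "ATG",
    paste(sample(pool, n_codons - 1, replace = TRUE), collapse = "")
  )
}

delete_codons <- function(cds, from_codon, n_codons) {
  start <- 3 * (from_codon - 1) + 1
  paste0(substr(cds, 1, start - 1), substr(cds, start + 3 * n_codons, nchar(cds)))
}

#' Simulate duplicated CDS families with N-terminal peptide events
#'
#' Generates one ancestral CDS per family (uniform non-stop codons behind
#' an ATG start, with the leading `ntp_codons` codons designated the
#' N-terminal peptide), duplicates it, applies point substitutions to both
#' copies, draws one NTP event per pair (`none`: substitutions only;
#' `partial`: internal in-frame deletion of 1-5 codons inside the NTP;
#' `terminal`: in-frame deletion at codon 1; `complete`: deletion of at
#' least 30 NTP codons), and assigns subcellular compartments so that
#' relocalization occurs with an event-specific probability.
#'
#' @param n_families Number of duplicate pairs (families of size 2).
#' @param codons_per_gene Ancestral gene length in codons.
#' @param ntp_codons Length of the N-terminal peptide region in codons
#'   (must be at least 30 when `complete` has positive probability).
#' @param substitution_rate Per-site substitution probability applied once
#'   to each copy.
#' @param indel_rate Per-gene probability of an additional small internal
#'   deletion downstream of the NTP.
#' @param ntp_event_probs Named probabilities for
#'   `none`/`partial`/`terminal`/`complete` (must sum to 1).
#' @param reloc_prob_given_event Named per-event relocalization
#'   probabilities.
#' @param vocabulary Compartment labels to draw from.
#' @param seed Integer seed.
#' @param dir Optional directory; when given, a FASTA, an ID-map TSV and a
#'   simple-dialect prediction TSV are written there.
#' @return A list with `sequences` (tibble `gene_id`, `transcript_id`,
#'   `protein_id`, `cds`), `predictions` (tibble `protein_id`,
#'   `compartment`), `truth` (tibble per pair: `id_a`, `id_b`, `family`,
#'   `true_ntp_class`, `true_status`) and `paths` (when written).
#' @export
simulate_duplicate_sequences <- function(n_families = 20,
                                         codons_per_gene = 120,
                                         ntp_codons = 40,
                                         substitution_rate = 0.01,
                                         indel_rate = 0,
                                         ntp_event_probs = c(
                                           none = 0.55, partial = 0.2,
                                           terminal = 0.15, complete = 0.1
                                         ),
                                         reloc_prob_given_event = c(
                                           none = 0.15, partial = 0.3,
                                           terminal = 0.4, complete = 0.7
                                         ),
                                         vocabulary = default_compartment_vocabulary(),
                                         seed = 1L,
                                         dir = NULL) {
  stopifnot(
    abs(sum(ntp_event_probs) - 1) < 1e-9,
    all(ntp_event_probs >= 0),
    all(reloc_prob_given_event >= 0), all(reloc_prob_given_event <= 1),
    codons_per_gene > ntp_codons + 10
  )
  if (ntp_codons < 30 && ntp_event_probs[["complete"]] > 0) {
    stop("ntp_codons < 30 cannot realize a complete (>= 30 codon) deletion")
  }
  set.seed(seed)
  events <- names(ntp_event_probs)
  seq_rows <- list()
  pred_rows <- list()
  truth_rows <- list()
  for (f in seq_len(n_families)) {
    anc <- random_cds(codons_per_gene)
    a <- mutate_sequence(anc, rounds = 1, rate = substitution_rate)
    b <- mutate_sequence(anc, rounds = 1, rate = substitution_rate)
    event <- sample(events, 1, prob = ntp_event_probs)
    if (event == "partial") {
      k <- sample(1:5, 1)
      from <- sample(2:(ntp_codons - k), 1)
      b <- delete_codons(b, from, k)
    } else if (event == "terminal") {
      k <- sample(1:5, 1)
      b <- delete_codons(b, 1, k)
    } else if (event == "complete") {
      k <- sample(30:ntp_codons, 1)
      b <- delete_codons(b, 1, k)
    }
    if (indel_rate > 0 && stats::runif(1) < indel_rate) {
      k <- sample(1:3, 1)
      from <- sample((ntp_codons + 2):(nchar(b) / 3 - k), 1)
      b <- delete_codons(b, from, k)
    }
    comp_a <- sample(vocabulary, 1)
    reloc <- stats::runif(1) < reloc_prob_given_event[[event]]
    comp_b <- if (reloc) {
      sample(setdiff(vocabulary, comp_a), 1)
    } else {
      comp_a
    }
    ida <- sprintf("F%03dA", f)
    idb <- sprintf("F%03dB", f)
    seq_rows[[f]] <- tibble::tibble(
      gene_id = c(ida, idb), transcript_id = c(ida, idb),
      protein_id = c(ida, idb), cds = c(a, b)
    )
    pred_rows[[f]] <- tibble::tibble(
      protein_id = c(ida, idb), compartment = c(comp_a, comp_b)
    )
    truth_rows[[f]] <- tibble::tibble(
      id_a = ida, id_b = idb, family = f,
      true_ntp_class = toupper(event),
      true_status = if (reloc) "RELOCALIZED" else "NONRELOCALIZED"
    )
  }
  out <- list(
    sequences = dplyr::bind_rows(seq_rows),
    predictions = dplyr::bind_rows(pred_rows),
    truth = dplyr::bind_rows(truth_rows),
    paths = NULL
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fasta <- file.path(dir, "duplicates.fa")
    writeLines(
      paste0(">", out$sequences$transcript_id, "\n", out$sequences$cds),
      fasta
    )
    idmap <- file.path(dir, "id_map.tsv")
    utils::write.table(
      out$sequences[, c("gene_id", "transcript_id", "protein_id")],
      idmap,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    pred <- file.path(dir, "predictions.tsv")
    utils::write.table(out$predictions, pred,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
    truth <- file.path(dir, "truth.jsonl")
    writeLines(
      purrr::map_chr(seq_len(nrow(out$truth)), function(i) {
        r <- out$truth[i, ]
        sprintf(
          '{"id_a":"%s","id_b":"%s","family":%d,"ntp_class":"%s","status":"%s"}',
          r$id_a, r$id_b, r$family, r$true_ntp_class, r$true_status
        )
      }),
      truth
    )
    out$paths <- list(
      fasta = fasta, id_map = idmap, predictions = pred, truth = truth
    )
  }
  out
}
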