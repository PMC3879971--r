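genetic_code <- function() {
  code <- as.list(Biostrings::GENETIC_CODE)
  stats::setNames(unlist(code), names(code))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Maps each aligned residue back to its source codon, inserting `"---"`
#' gap codons where the protein alignment has gaps. The ungapped protein
#' strings must equal the CDS translations exactly (a trailing stop codon
#' on the CDS is ignored).
#'
#' @param aligned_a,aligned_b Gapped, equal-length protein strings.
#' @param cds_a,cds_b The coding sequences the proteins came from.
#' @return A tibble with one row per alignment column: `codon_a`,
#'   `codon_b`.
#' @export
codon_backtranslate <- function(aligned_a, aligned_b, cds_a, cds_b) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b))
  back_one <- function(aligned, cds, label) {
    residues <- strsplit(aligned, "")[[1]]
    prot <- residues[residues != "-"]
    tr <- translate_cds(cds)
    got <- strsplit(tr$residues, "")[[1]]
    if (length(got) < length(prot) ||
      any(got[seq_along(prot)] != prot)) {
      bad <- which(got[seq_along(prot)] != prot)[1]
      if (is.na(bad)) bad <- length(got) + 1
      stop(
        "translation of ", label, " does not match aligned protein at ",
        "residue ", bad
      )
    }
    codons <- substring(cds, seq(1, 3 * length(prot), 3), seq(3, 3 * length(prot), 3))
    out <- rep("---", length(residues))
    out[residues != "-"] <- codons
    out
  }
  tibble::tibble(
    codon_a = back_one(aligned_a, cds_a, "cds_a"),
    codon_b = back_one(aligned_b, cds_b, "cds_b")
  )
}

# per-codon synonymous site fractions; substitutions to stop codons are
# excluded from both numerator and denominator
ng86_sites_one <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  cs <- strsplit(codon, "")[[1]]
  aa <- code[[codon]]
  s <- 0
  for (pos in 1:3) {
    syn <- 0
    tot <- 0
    for (b in setdiff(bases, cs[pos])) {
      alt <- cs
      alt[pos] <- b
      alt_aa <- code[[paste(alt, collapse = "")]]
      if (alt_aa == "*") next
      tot <- tot + 1
      if (alt_aa == aa) syn <- syn + 1
    }
    if (tot > 0) s <- s + syn / tot
  }
  s
}

# averaged synonymous/nonsynonymous difference counts between two codons,
# over all substitution orderings; paths through stop codons are excluded
ng86_diffs_one <- function(ca, cb, code) {
  pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  k <- length(pos)
  if (k == 0) {
    return(c(sd = 0, nd = 0))
  }
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  perms <- if (k == 1) {
    list(pos)
  } else if (k == 2) {
    list(pos, rev(pos))
  } else {
    p <- pos
    list(
      p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
      p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)]
    )
  }
  acc <- c(0, 0)
  used <- 0
  for (ord in perms) {
    cur <- a
    sd <- 0
    nd <- 0
    ok <- TRUE
    for (p in ord) {
      prev_aa <- code[[paste(cur, collapse = "")]]
      cur[p] <- b[p]
      new_aa <- code[[paste(cur, collapse = "")]]
      if (new_aa == "*" && paste(cur, collapse = "") != cb) {
        ok <- FALSE
        break
      }
      if (new_aa == prev_aa) sd <- sd + 1 else nd <- nd + 1
    }
    if (ok) {
      acc <- acc + c(sd, nd)
      used <- used + 1
    }
  }
  if (used == 0) {
    # every path crosses a stop codon; fall back to unrestricted averaging
    for (ord in perms) {
      cur <- a
      sd <- 0
      nd <- 0
      for (p in ord) {
        prev_aa <- code[[paste(cur, collapse = "")]]
        cur[p] <- b[p]
        new_aa <- code[[paste(cur, collapse = "")]]
        if (new_aa == prev_aa) sd <- sd + 1 else nd <- nd + 1
      }
      acc <- acc + c(sd, nd)
      used <- used + 1
    }
  }
  c(sd = acc[1] / used, nd = acc[2] / used)
}

jc_correct <- function(p) {
  arg <- 1 - 4 * p / 3
  if (arg <= 0) {
    return(NA_real_)
  }
  -0.75 * log(arg)
}

#' Estimate Ks and Ka with the Nei-Gojobori (1986) method
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence by
#' per-codon mutation fractions (averaged over the two sequences), counts
#' synonymous and nonsynonymous differences by equal-weight averaging over
#' minimal mutation pathways (pathways through stop codons excluded), and
#' applies the Jukes-Cantor correction to the proportions pS and pN.
#' Columns with a gap, an ambiguous base, or a stop codon are excluded.
#' Saturation (pS or pN at or beyond 3/4, where the correction diverges)
#' marks the estimate invalid.
#'
#' @param codon_aln A tibble from [codon_backtranslate()] (`codon_a`,
#'   `codon_b`).
#' @return A one-row tibble: `ks`, `ka`, `omega` (NA when `ks` is 0 or the
#'   estimate invalid), `S`, `N`, `Sd`, `Nd`, `n_codons` (complete columns
#'   used), `method`, `valid`.
#' @export
estimate_ks_ka <- function(codon_aln) {
  code <- genetic_code()
  complete <- !grepl("[^ACGT]", codon_aln$codon_a) &
    !grepl("[^ACGT]", codon_aln$codon_b) &
    nchar(codon_aln$codon_a) == 3 & nchar(codon_aln$codon_b) == 3
  ca <- codon_aln$codon_a[complete]
  cb <- codon_aln$codon_b[complete]
  keep <- vapply(ca, function(x) code[[x]] != "*", logical(1)) &
    vapply(cb, function(x) code[[x]] != "*", logical(1))
  ca <- ca[keep]
  cb <- cb[keep]
  if (length(ca) == 0) stop("no complete, unambiguous codon columns")
  s_a <- sum(vapply(ca, ng86_sites_one, numeric(1), code = code))
  s_b <- sum(vapply(cb, ng86_sites_one, numeric(1), code = code))
  S <- (s_a + s_b) / 2
  N <- 3 * length(ca) - S
  d <- vapply(
    seq_along(ca),
    function(i) ng86_diffs_one(ca[i], cb[i], code),
    numeric(2)
  )
  Sd <- sum(d["sd", ])
  Nd <- sum(d["nd", ])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  ks <- jc_correct(pS)
  ka <- jc_correct(pN)
  valid <- !is.na(ks) && !is.na(ka)
  tibble::tibble(
    ks = ks, ka = ka,
    omega = ifelse(valid && ks > 0, ka / ks, NA_real_),
    S = S, N = N, Sd = Sd, Nd = Nd,
    n_codons = length(ca),
    method = "NG86",
    valid = valid
  )
}

#' Divergence estimates for a table of pairs
#'
#' Globally aligns each pair's proteins, back-translates to codons and
#' runs [estimate_ks_ka()].
#'
#' @param pairs Tibble with `id_a`, `id_b`.
#' @param proteome Tibble with `protein_id`, `protein`, `cds`.
#' @return `pairs` joined with the divergence estimate columns.
#' @export
estimate_pair_divergence <- function(pairs, proteome) {
  prot <- stats::setNames(proteome$protein, proteome$protein_id)
  cds <- stats::setNames(proteome$cds, proteome$protein_id)
  est <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    a <- pairs$id_a[i]
    b <- pairs$id_b[i]
    aln <- global_align(prot[[a]], prot[[b]])
    codon_backtranslate(aln$aligned_a, aln$aligned_b, cds[[a]], cds[[b]]) |>
      estimate_ks_ka()
  })
  dplyr::bind_cols(pairs, est)
}

#' Ks window filter
#'
#' Keeps valid estimates with `lo < ks < hi`, both bounds strict (the
#' analysis windows are open intervals such as 0 < Ks < 1; the lower bound
#' also implements the Ks < 0.01 sensitivity removal). Invalid estimates
#' are always excluded.
#'
#' @param pairs A tibble with `ks` and `valid` columns.
#' @param lo,hi Open window bounds.
#' @return The filtered tibble.
#' @export
ks_window_filter <- function(pairs, lo = 0, hi = 1) {
  stopifnot(lo < hi)
  dplyr::filter(pairs, .data$valid, .data$ks > lo, .data$ks < hi)
}

#' Positive-selection fraction by relocalization status
#'
#' Per-group fraction of valid pairs with Ka/Ks strictly above the
#' threshold, with a two-sided two-proportion test (normal-approximation
#' z-test without continuity correction; Fisher's exact test when any
#' contingency cell is below 5).
#'
#' @param pairs Tibble with `status` (RELOCALIZED/NONRELOCALIZED), `omega`
#'   and `valid`.
#' @param omega_threshold Strict Ka/Ks cut (default 1.5).
#' @return A list with `fractions` (tibble status, n, n_above, fraction),
#'   `p_value` and `test`.
#' @export
positive_selection_fraction <- function(pairs, omega_threshold = 1.5) {
  pairs <- dplyr::filter(pairs, .data$valid)
  tab <- pairs |>
    dplyr::group_by(.data$status) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_above = sum(!is.na(.data$omega) & .data$omega > omega_threshold),
      fraction = .data$n_above / .data$n,
      .groups = "drop"
    )
  if (nrow(tab) < 2 || any(tab$n == 0)) {
    stop("both relocalization groups must be nonempty")
  }
  x <- tab$n_above
  n <- tab$n
  cells <- c(x, n - x)
  if (any(cells < 5)) {
    p <- stats::fisher.test(cbind(x, n - x))$p.value
    test <- "fisher"
  } else {
    ph <- sum(x) / sum(n)
    z <- (x[1] / n[1] - x[2] / n[2]) /
      sqrt(ph * (1 - ph) * (1 / n[1] + 1 / n[2]))
    p <- 2 * stats::pnorm(-abs(z))
    test <- "z"
  }
  list(fractions = tab, p_value = p, test = test)
}

#' Read Ks/Ka estimates from a yn00 output file
#'
#' Parses the Yang & Nielsen (2000) results table of a `yn00` run so
#' real-data analyses can use the external estimator's values in place of
#' the built-in NG86 path. Sequence names are taken from the Nei-Gojobori
#' matrix block of the same file.
#'
#' @param path Path to a yn00 output file.
#' @return A tibble `id_a`, `id_b`, `ks`, `ka`, `omega`, `method`
#'   (`"external"`), `valid`.
#' @export
read_yn00 <- function(path) {
  lines <- readLines(path)
  a_start <- grep("Nei\\s*&\\s*Gojobori", lines)[1]
  b_start <- grep("Yang\\s*&\\s*Nielsen", lines)[1]
  if (is.na(a_start) || is.na(b_start)) {
    stop("not a recognisable yn00 output file")
  }
  name_lines <- lines[(a_start + 1):(b_start - 1)]
  name_lines <- name_lines[grepl("^\\S", name_lines) &
    !grepl("^\\(", name_lines)]
  nm <- sub("\\s.*$", "", name_lines)
  nm <- nm[nzchar(nm)]
  rows <- lines[b_start:length(lines)]
  rows <- rows[grepl("^\\s*\\d+\\s+\\d+\\s+[-0-9.]", rows)]
  parsed <- purrr::map_dfr(rows, function(l) {
    f <- strsplit(trimws(gsub("\\+-", " ", l)), "\\s+")[[1]]
    tibble::tibble(
      i = as.integer(f[1]), j = as.integer(f[2]),
      omega = as.numeric(f[7]), ka = as.numeric(f[8]),
      ks = as.numeric(f[10])
    )
  })
  tibble::tibble(
    id_a = nm[parsed$j], id_b = nm[parsed$i],
    ks = parsed$ks, ka = parsed$ka, omega = parsed$omega,
    method = "external",
    valid = is.finite(parsed$ks) & parsed$ks >= 0
  )
}
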