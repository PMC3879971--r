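codon_tbl <- function(a, b) tibble::tibble(codon_a = a, codon_b = b)

test_that("back-translation preserves the residue-codon correspondence", {
  # MK- / MKR over matching CDSs: third column pairs a gap codon with CGT
  aln <- codon_backtranslate("MK-", "MKR", "ATGAAA", "ATGAAACGT")
  expect_equal(aln$codon_a, c("ATG", "AAA", "---"))
  expect_equal(aln$codon_b, c("ATG", "AAA", "CGT"))
  ident <- codon_backtranslate("MKR", "MKR", "ATGAAACGT", "ATGAAACGT")
  expect_equal(ident$codon_a, ident$codon_b)
  # trailing stop on the CDS is tolerated
  ok <- codon_backtranslate("MK", "MK", "ATGAAATAA", "ATGAAA")
  expect_equal(ok$codon_a, c("ATG", "AAA"))
  expect_error(
    codon_backtranslate("RK", "MK", "ATGAAA", "ATGAAA"),
    "residue 1"
  )
})

test_that("NG86 reproduces the frozen hand-computed battery to 1e-9", {
  # Case 1: ATG + 9x GGC + AAA vs ATG + 9x GGC + AAG.
  # Per-codon synonymous sites: GGC = 1 (4-fold third position), AAA = 1/3
  # (AAG synonymous among three non-stop changes), ATG = 0. S = 9 + 1/3,
  # Sd = 1 (AAA->AAG), pS = 3/28, Ks = -3/4 ln(1 - 4/3 * 3/28) = -3/4 ln(6/7).
  a1 <- c("ATG", rep("GGC", 9), "AAA")
  b1 <- c("ATG", rep("GGC", 9), "AAG")
  e1 <- estimate_ks_ka(codon_tbl(a1, b1))
  expect_equal(e1$S, 28 / 3, tolerance = 1e-12)
  expect_equal(e1$Sd, 1)
  expect_equal(e1$ks, -0.75 * log(6 / 7), tolerance = 1e-9)
  expect_equal(e1$ka, 0, tolerance = 1e-12)
  expect_true(e1$valid)

  # Case 2: one nonsynonymous third-position change, GAA -> GAC.
  # S(GAA) = S(GAC) = 1/3, N = 6 - 1/3, Nd = 1, Ka = -3/4 ln(13/17), Ks = 0.
  e2 <- estimate_ks_ka(codon_tbl(c("ATG", "GAA"), c("ATG", "GAC")))
  expect_equal(e2$ks, 0)
  expect_equal(e2$ka, -0.75 * log(13 / 17), tolerance = 1e-9)
  expect_equal(e2$omega, NA_real_) # Ka/Ks undefined at Ks = 0

  # Case 3: two-position codon difference averages its two mutation
  # pathways. AAA vs AGG: both orderings give one synonymous and one
  # nonsynonymous step, so Sd = Nd = 1; sites S = (1/3 + 2/3)/2 + 18.
  a3 <- c("AAA", rep("GGC", 18))
  b3 <- c("AGG", rep("GGC", 18))
  e3 <- estimate_ks_ka(codon_tbl(a3, b3))
  expect_equal(e3$Sd, 1, tolerance = 1e-12)
  expect_equal(e3$Nd, 1, tolerance = 1e-12)
  expect_equal(e3$S, 18.5, tolerance = 1e-12)
  expect_equal(e3$ks, -0.75 * log(1 - 4 / (3 * 18.5)), tolerance = 1e-9)
  expect_equal(e3$ka, -0.75 * log(1 - 4 / (3 * 38.5)), tolerance = 1e-9)

  # Case 4: pathway through a stop codon is excluded. TAT vs TGG: the
  # route via TAG (stop) is dropped, leaving TAT->TGT->TGG with two
  # nonsynonymous steps. S(TAT) = 1 (both non-stop third-position changes
  # synonymous), S(TGG) = 0.
  a4 <- c("TAT", rep("GGC", 18))
  b4 <- c("TGG", rep("GGC", 18))
  e4 <- estimate_ks_ka(codon_tbl(a4, b4))
  expect_equal(e4$Sd, 0)
  expect_equal(e4$Nd, 2)
  expect_equal(e4$S, 18.5)
  expect_equal(e4$ka, -0.75 * log(1 - 8 / (3 * 38.5)), tolerance = 1e-9)
})

test_that("identical sequences give Ks = Ka = 0 and saturation invalidates", {
  same <- codon_tbl(c("ATG", "GGC", "AAA"), c("ATG", "GGC", "AAA"))
  e <- estimate_ks_ka(same)
  expect_equal(e$ks, 0)
  expect_equal(e$ka, 0)
  # a single synonymous difference over one synonymous site: pS = 1 >= 3/4
  sat <- estimate_ks_ka(codon_tbl(c("ATG", "GGC"), c("ATG", "GGT")))
  expect_false(sat$valid)
  expect_true(is.na(sat$ks))
})

test_that("gapped and ambiguous columns are excluded; empty alignment errors", {
  e <- estimate_ks_ka(codon_tbl(
    c("ATG", "---", "GGN", "AAA"),
    c("ATG", "CCC", "GGC", "AAG")
  ))
  expect_equal(e$n_codons, 2L) # only ATG and AAA/AAG survive
  expect_error(
    estimate_ks_ka(codon_tbl("---", "AAA")),
    "no complete"
  )
})

test_that("NG86 is symmetric, site-fraction invariant, and monotone on a mutation ladder", {
  a <- c("ATG", "GGC", "AAA", "TGC", "CTG", "GAA")
  b <- c("ATG", "GGT", "AAG", "TGC", "CTC", "GAC")
  e_ab <- estimate_ks_ka(codon_tbl(a, b))
  e_ba <- estimate_ks_ka(codon_tbl(b, a))
  expect_equal(e_ab$ks, e_ba$ks, tolerance = 1e-12)
  expect_equal(e_ab$ka, e_ba$ka, tolerance = 1e-12)
  # concatenating an alignment with itself changes no rate
  e_cat <- estimate_ks_ka(codon_tbl(c(a, a), c(b, b)))
  expect_equal(e_cat$ks, e_ab$ks, tolerance = 1e-12)
  expect_equal(e_cat$ka, e_ab$ka, tolerance = 1e-12)
  # ladder: adding synonymous substitutions one by one never lowers Ks
  base <- rep("GGC", 12)
  ks_ladder <- vapply(0:4, function(k) {
    mut <- base
    if (k > 0) mut[seq_len(k)] <- "GGT"
    estimate_ks_ka(codon_tbl(base, mut))$ks
  }, numeric(1))
  expect_true(all(diff(ks_ladder) > 0))
})

test_that("Ks window bounds are strict and invalid estimates always drop", {
  pairs <- tibble::tibble(
    ks = c(1.0, 0.005, 0.5, 0.3),
    valid = c(TRUE, TRUE, TRUE, FALSE)
  )
  expect_equal(ks_window_filter(pairs, 0, 1)$ks, c(0.005, 0.5))
  expect_equal(ks_window_filter(pairs, 0.01, 1)$ks, 0.5)
  expect_equal(nrow(ks_window_filter(pairs, 0.3, 0.4)), 0)
})

test_that("positive-selection fractions use a strict cut and the right test", {
  mk <- function(n_above_r, n_r, n_above_n, n_n) {
    tibble::tibble(
      status = c(rep("RELOCALIZED", n_r), rep("NONRELOCALIZED", n_n)),
      omega = c(
        rep(2, n_above_r), rep(0.5, n_r - n_above_r),
        rep(2, n_above_n), rep(0.5, n_n - n_above_n)
      ),
      valid = TRUE
    )
  }
  eq <- positive_selection_fraction(mk(10, 100, 10, 100))
  expect_equal(sort(eq$fractions$fraction), c(0.1, 0.1))
  expect_gt(eq$p_value, 0.99)
  # hand z statistic: phat = 0.2, z = 0.2 / sqrt(0.2*0.8*2/100) = 3.5355
  diff <- positive_selection_fraction(mk(10, 100, 30, 100))
  expect_equal(sort(diff$fractions$fraction), c(0.1, 0.3))
  expect_equal(diff$test, "z")
  expect_equal(diff$p_value, 2 * pnorm(-0.2 / sqrt(0.2 * 0.8 * 0.02)),
    tolerance = 1e-9
  )
  expect_lt(diff$p_value, 0.01)
  # omega exactly at the threshold is not counted
  at <- tibble::tibble(
    status = rep(c("RELOCALIZED", "NONRELOCALIZED"), each = 10),
    omega = 1.5, valid = TRUE
  )
  res <- positive_selection_fraction(at)
  expect_equal(res$fractions$n_above, c(0L, 0L))
  expect_equal(res$test, "fisher") # small cells fall back to Fisher
  expect_error(
    positive_selection_fraction(
      tibble::tibble(status = "RELOCALIZED", omega = 2, valid = TRUE)
    ),
    "nonempty"
  )
})

test_that("yn00 output files parse into divergence rows", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(
    "YN00 demo.nuc",
    "ns =   3\tls = 100",
    "",
    "(A) Nei-Gojobori (1986) method",
    "",
    "Nei & Gojobori 1986. dN/dS (dN, dS)",
    "(Note: This matrix is not used in later calculations.)",
    "",
    "seqA",
    "seqB                 0.1000 (0.0100 0.1000)",
    "seqC                 0.2000 (0.0200 0.1500)  0.3000 (0.0300 0.2000)",
    "",
    "(B) Yang & Nielsen (2000) method",
    "",
    "seq. seq.     S       N        t   kappa   omega     dN +- SE    dS +- SE",
    "",
    "   2    1    23.6    76.4   0.1234  2.1000  0.1100 0.0123 +- 0.0045  0.1118 +- 0.0678",
    "   3    1    25.0    75.0   0.2000  2.0000  0.1500 0.0300 +- 0.0050  0.2000 +- 0.0700",
    "   3    2    25.0    75.0   0.3000  2.0000  0.1600 0.0320 +- 0.0050  0.2000 +- 0.0700"
  ), f)
  res <- read_yn00(f)
  expect_equal(nrow(res), 3)
  expect_equal(res$id_a[1], "seqA")
  expect_equal(res$id_b[1], "seqB")
  expect_equal(res$ks[1], 0.1118)
  expect_equal(res$ka[1], 0.0123)
  expect_equal(res$omega[1], 0.11)
  expect_equal(res$method, rep("external", 3))
  expect_true(all(res$valid))
})
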