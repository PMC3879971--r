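# Independent oracles used by the test suite. These are deliberately
# simple, brute-force implementations kept separate from the package code
# paths they check.

# Affine-gap Smith-Waterman optimal raw score by direct dynamic
# programming (Gotoh three-matrix recurrence), gap of length k costing
# open + extend * k.
sw_score_oracle <- function(a, b, open = 11, extend = 1) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- get("BLOSUM62", envir = environment())
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  p <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, p + 1) # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, p + 1) # best ending in a gap in b (A aligned to -)
  Y <- matrix(NEG, n + 1, p + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:p) {
      X[i + 1, j + 1] <- max(
        M[i, j + 1] - open - extend,
        X[i, j + 1] - extend
      )
      Y[i + 1, j + 1] <- max(
        M[i + 1, j] - open - extend,
        Y[i + 1, j] - extend
      )
      sc <- m[A[i], B[j]]
      M[i + 1, j + 1] <- max(
        0,
        M[i, j] + sc, X[i, j] + sc, Y[i, j] + sc
      )
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

random_peptide <- function(len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

# Maximal cliques (size >= 2) of an adjacency matrix by exhaustive subset
# enumeration, then connected components of the clique-overlap graph.
clique_oracle <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  subsets <- list()
  for (mask in 1:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(idx) < 2) next
    pairs <- utils::combn(idx, 2)
    if (all(adj[t(pairs)] == 1)) subsets[[length(subsets) + 1]] <- idx
  }
  # keep maximal ones
  is_max <- vapply(subsets, function(s) {
    !any(vapply(
      subsets,
      function(t) length(t) > length(s) && all(s %in% t),
      logical(1)
    ))
  }, logical(1))
  cliques <- subsets[is_max]
  lapply(cliques, function(s) sort(nodes[s]))
}

components_oracle <- function(cliques) {
  if (length(cliques) == 0) {
    return(list())
  }
  comps <- lapply(cliques, identity)
  repeat {
    merged <- FALSE
    for (i in seq_along(comps)) {
      for (j in seq_along(comps)) {
        if (j <= i) next
        if (length(intersect(comps[[i]], comps[[j]])) > 0) {
          comps[[i]] <- sort(union(comps[[i]], comps[[j]]))
          comps[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  comps[order(vapply(comps, function(x) paste(x, collapse = ","), ""))]
}

# Vectorised Breslow log partial likelihood for UNTIED binary-covariate
# data, used for grid-search maximisation (equals Efron when tie-free).
grid_lpl <- function(beta_grid, time, x) {
  ord <- order(time)
  x <- x[ord]
  n <- length(x)
  # risk set at the i-th smallest time = indices i..n
  n1_at_risk <- rev(cumsum(rev(x)))
  n_at_risk <- n:1
  n0_at_risk <- n_at_risk - n1_at_risk
  vapply(beta_grid, function(b) {
    sum(b * x) - sum(log(n0_at_risk + n1_at_risk * exp(b)))
  }, numeric(1))
}

cox_grid_oracle <- function(time, x, lo = -6, hi = 6, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  grid[which.max(grid_lpl(grid, time, x))]
}

random_gapped_pair <- function(len, gap_prob = 0.2) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  draw <- function() {
    x <- sample(aa, len, replace = TRUE)
    g <- runif(len) < gap_prob
    x[g] <- "-"
    x
  }
  a <- draw()
  b <- draw()
  # a column cannot be gap in both strings in a real alignment
  both <- a == "-" & b == "-"
  b[both] <- sample(aa, sum(both), replace = TRUE)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}

# stop-free random CDS for mutation tests
random_cds_fixture <- function(n_codons, seed = 97) {
  set.seed(seed)
  stops <- c("TAA", "TAG", "TGA")
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  pool <- setdiff(all_codons, stops)
  paste0("ATG", paste(sample(pool, n_codons - 1, replace = TRUE), collapse = ""))
}
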