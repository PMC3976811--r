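# Independent oracles used across the suite. These deliberately do NOT
# share code with the package internals they check.

# Affine-gap Needleman-Wunsch score by direct dynamic programming
# (Gotoh). Gap of length L costs open + L * ext, matching the package's
# alignment engine conventions.
nw_score_oracle <- function(a, b, submat, open, ext) {
  av <- strsplit(a, "")[[1L]]
  bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (consume b)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

nt_submat_oracle <- function() {
  b <- c("A", "C", "G", "T")
  m <- matrix(-3, 4, 4, dimnames = list(b, b))
  diag(m) <- 2
  m
}

# Brute-force codon likelihood on a 3-taxon star tree via Matrix::expm,
# summing over the root state.
star3_loglik_oracle <- function(states, t_abc, kappa, omega, pi) {
  Q <- wrkyscan::gy94_Q(kappa, omega, pi)
  cods <- wrkyscan::sense_codons()
  P <- lapply(t_abc, function(t) as.matrix(Matrix::expm(Q * t)))
  s <- match(states, cods)
  tot <- 0
  for (site in seq_len(ncol(states))) {
    tot <- tot + log(sum(pi * P[[1]][, s[site * 3 - 2]] *
                           P[[2]][, s[site * 3 - 1]] * P[[3]][, s[site * 3]]))
  }
  tot
}

# Random unrooted tree with sorted-taxa additive distances.
random_additive_case <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.1, 1)
  D <- stats::cophenetic(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Background amino-acid sampler for scanner tests (no W/C/H, so no
# accidental domain grammar matches).
random_bg_protein <- function(n) {
  paste(sample(c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "Y"), n, replace = TRUE),
        collapse = "")
}
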