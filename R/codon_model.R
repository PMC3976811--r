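# GY94 codon substitution machinery: the 61-state rate matrix, eigen
# solution of P(t) for the reversible chain, F3x4 frequencies, the codon
# alignment container, and the Felsenstein pruning likelihood used by
# the site models. Universal genetic code only.

.codon_tables <- local({
  env <- NULL
  function() {
    if (!is.null(env)) return(env)
    bases <- c("A", "C", "G", "T")
    all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    all64 <- sort(all64)
    gc <- Biostrings::GENETIC_CODE
    sense <- all64[gc[all64] != "*"]
    aa <- unname(gc[sense])
    n <- length(sense)  # 61
    mats <- matrix(0, n, n)
    ts_m <- matrix(FALSE, n, n)
    syn_m <- matrix(FALSE, n, n)
    chars <- do.call(rbind, strsplit(sense, ""))
    is_ts <- function(x, y) (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C")
    for (i in seq_len(n)) {
      diffs <- sweep(chars, 2, chars[i, ], `!=`)
      nd <- rowSums(diffs)
      j <- which(nd == 1L)
      mats[i, j] <- 1
      for (jj in j) {
        pos <- which(diffs[jj, ])
        ts_m[i, jj] <- is_ts(chars[i, pos], chars[jj, pos])
        syn_m[i, jj] <- aa[i] == aa[jj]
      }
    }
    env <<- list(codons = sense, aa = aa, single = mats, ts = ts_m, syn = syn_m)
    env
  }
})

#' Sense codons of the universal genetic code
#' @return Character vector of the 61 sense codons (alphabetical).
#' @export
sense_codons <- function() .codon_tables()$codons

#' GY94 codon rate matrix
#'
#' Builds the 61x61 generator of the Goldman-Yang codon model:
#' `q_ij = 0` for multi-nucleotide changes and
#' `q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous]` for single
#' nucleotide changes; rows sum to zero. When `scale = TRUE` the matrix
#' is normalized so the mean substitution rate at stationarity is one
#' substitution per codon per unit time.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega dN/dS ratio (>= 0).
#' @param codon_freqs Stationary codon frequencies (length 61, summing
#'   to 1); default uniform.
#' @param scale Normalize the mean rate to 1.
#' @return 61x61 numeric matrix with codon dimnames.
#' @export
gy94_Q <- function(kappa, omega, codon_freqs = NULL, scale = TRUE) {
  tab <- .codon_tables()
  n <- length(tab$codons)
  if (is.null(codon_freqs)) codon_freqs <- rep(1 / n, n)
  if (length(codon_freqs) != n || any(codon_freqs < 0) ||
      abs(sum(codon_freqs) - 1) > 1e-6)
    .stopf("gy94_Q: codon_freqs must be a simplex over the 61 sense codons")
  if (!is.numeric(kappa) || kappa <= 0) .stopf("gy94_Q: kappa must be > 0")
  if (!is.numeric(omega) || omega < 0) .stopf("gy94_Q: omega must be >= 0")
  rate <- tab$single * ifelse(tab$ts, kappa, 1) * ifelse(tab$syn, 1, omega)
  Q <- sweep(rate, 2, codon_freqs, `*`)
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mean_rate <- -sum(codon_freqs * diag(Q))
    if (mean_rate > 0) Q <- Q / mean_rate
  }
  dimnames(Q) <- list(tab$codons, tab$codons)
  Q
}

# Eigen solution of a reversible generator via similarity to a symmetric
# matrix; returns closures for P(t).
.q_eigen <- function(Q, pi) {
  sp <- sqrt(pi)
  A <- (sp * Q) %*% diag(1 / sp)
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  L <- (1 / sp) * e$vectors          # diag(1/sp) %*% U
  R <- t(e$vectors * sp)             # t(U) %*% diag(sp)  (row scaling of U)
  list(values = e$values, L = L, R = R)
}

.p_matrix <- function(eig, t) {
  P <- eig$L %*% (exp(eig$values * t) * eig$R)
  P[P < 0] <- 0
  P
}

#' F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies estimated from the data,
#' multiplied across the three codon positions, zeroed on stop codons
#' and renormalized over the 61 sense codons (the customary default of
#' codon-model software).
#'
#' @param aln A `codon_alignment`.
#' @return Numeric vector of 61 codon frequencies.
#' @export
estimate_f3x4 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  cods <- aln$codons[aln$codons != "---"]
  if (!length(cods)) .stopf("estimate_f3x4: alignment has no ungapped codons")
  bases <- c("A", "C", "G", "T")
  f <- sapply(1:3, function(p) {
    x <- substr(cods, p, p)
    tab <- table(factor(x, levels = bases))
    as.numeric(tab) / sum(tab)
  })
  tabs <- .codon_tables()
  chars <- do.call(rbind, strsplit(tabs$codons, ""))
  pi <- f[match(chars[, 1], bases), 1] *
    f[match(chars[, 2], bases), 2] *
    f[match(chars[, 3], bases), 3]
  pi <- pmax(pi, 1e-10)
  pi / sum(pi)
}

#' Codon alignment container
#'
#' @param codons Character matrix (taxa x codon columns); each cell a
#'   sense codon or `"---"` for a gap. Cells containing anything else
#'   (ambiguity codes) are converted to `"---"` with a warning; stop
#'   codons are rejected.
#' @return Object of class `codon_alignment` with fields `taxa` and
#'   `codons`.
#' @export
codon_alignment <- function(codons) {
  stopifnot(is.matrix(codons), !is.null(rownames(codons)))
  codons[] <- toupper(codons)
  sense <- sense_codons()
  bad <- !(codons %in% c(sense, "---"))
  if (any(bad)) {
    stops <- codons[bad][codons[bad] %in% c("TAA", "TAG", "TGA")]
    if (length(stops)) .stopf("codon_alignment: stop codon %s in data", stops[[1L]])
    warning("ambiguous codons converted to gaps", call. = FALSE)
    codons[bad] <- "---"
  }
  structure(list(taxa = rownames(codons), codons = codons),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa x %d codons\n",
              length(x$taxa), ncol(x$codons)))
  invisible(x)
}

# Integer state matrix (1..61, NA for gaps).
.codon_index <- function(aln) {
  idx <- match(aln$codons, sense_codons())
  matrix(idx, nrow = nrow(aln$codons), dimnames = dimnames(aln$codons))
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Each amino-acid column expands to its source codon; alignment gaps
#' expand to `"---"`. Every CDS must translate exactly to its ungapped
#' protein (a terminal stop codon is tolerated and dropped).
#'
#' @param protein_msa Named character vector: aligned protein sequences.
#' @param cds_map Named character vector of coding sequences (names
#'   matching `protein_msa`).
#' @return A `codon_alignment`.
#' @export
backtranslate <- function(protein_msa, cds_map) {
  m <- msa_matrix(protein_msa)
  out <- matrix("---", nrow(m), ncol(m), dimnames = dimnames(m))
  for (tx in rownames(m)) {
    if (!tx %in% names(cds_map)) .stopf("backtranslate: no CDS for taxon %s", tx)
    cds <- toupper(cds_map[[tx]])
    aa_row <- m[tx, ]
    ungapped <- paste(aa_row[aa_row != "-"], collapse = "")
    trans <- translate_cds(cds)
    if (!identical(trans, ungapped)) {
      pos <- which(strsplit(trans, "")[[1L]][seq_len(min(nchar(trans), nchar(ungapped)))] !=
                     strsplit(ungapped, "")[[1L]][seq_len(min(nchar(trans), nchar(ungapped)))])
      .stopf("backtranslate: CDS of %s does not translate to its protein (first mismatch at residue %s)",
             tx, if (length(pos)) pos[1L] else nchar(ungapped))
    }
    k <- 0L
    for (col in seq_len(ncol(m))) {
      if (aa_row[col] == "-") next
      k <- k + 1L
      out[tx, col] <- substr(cds, 3L * k - 2L, 3L * k)
    }
  }
  codon_alignment(out)
}

#' Translate a codon alignment back to a protein alignment
#' @param aln A `codon_alignment`.
#' @return Named character vector of aligned protein sequences.
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  gc <- Biostrings::GENETIC_CODE
  m <- aln$codons
  am <- matrix("-", nrow(m), ncol(m), dimnames = dimnames(m))
  ok <- m != "---"
  am[ok] <- unname(gc[m[ok]])
  apply(am, 1L, paste, collapse = "")
}

# ---- pruning likelihood -----------------------------------------------------

# Per-class site log-likelihoods by Felsenstein pruning.
# tree: ape phylo with edge.length; omegas/weights: mixture classes.
# Returns list(lnL, class_site_loglik [K x S], log_weights).
.codon_loglik <- function(idx, tree, kappa, omegas, weights, pi) {
  stopifnot(abs(sum(weights) - 1) < 1e-8)
  taxa <- rownames(idx)
  if (!setequal(tree$tip.label, taxa))
    .stopf("tree leaves do not match alignment taxa")
  S <- ncol(idx)
  K <- length(omegas)
  Qs <- lapply(omegas, function(w) gy94_Q(kappa, w, pi, scale = FALSE))
  rates <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1))
  factor <- sum(weights * rates)
  if (factor <= 0) factor <- 1
  phy <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  tip_idx <- idx[phy$tip.label, , drop = FALSE]
  cs_loglik <- matrix(NA_real_, K, S)
  for (k in seq_len(K)) {
    eig <- .q_eigen(Qs[[k]] / factor, pi)
    partial <- vector("list", n_tip + n_node)
    logscale <- rep(0, S)
    Ps <- lapply(phy$edge.length, function(t) .p_matrix(eig, max(t, 0)))
    # initialize internal partials to 1
    for (v in (n_tip + 1L):(n_tip + n_node)) partial[[v]] <- matrix(1, 61, S)
    for (e in seq_len(nrow(phy$edge))) {
      par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
      P <- Ps[[e]]
      if (child <= n_tip) {
        st <- tip_idx[child, ]
        contrib <- matrix(1, 61, S)
        ok <- !is.na(st)
        if (any(ok)) contrib[, ok] <- P[, st[ok], drop = FALSE]
      } else {
        contrib <- P %*% partial[[child]]
        mx <- apply(contrib, 2L, max)
        mx[mx <= 0] <- 1
        contrib <- sweep(contrib, 2L, mx, `/`)
        logscale <- logscale + log(mx)
      }
      partial[[par]] <- partial[[par]] * contrib
    }
    root <- n_tip + 1L
    site_l <- colSums(pi * partial[[root]])
    cs_loglik[k, ] <- log(site_l) + logscale
  }
  lw <- log(weights)
  mix <- apply(cs_loglik + lw, 2L, function(col) {
    mx <- max(col); mx + log(sum(exp(col - mx)))
  })
  list(lnL = sum(mix), class_site_loglik = cs_loglik, site_loglik = mix)
}

#' Codon log-likelihood of an alignment on a tree
#'
#' Felsenstein pruning over the 61 codon states under a (possibly
#' mixture) GY94 model. Gaps are missing data. Branch lengths are in
#' expected substitutions per codon (mixture-averaged rate normalized
#' to 1).
#'
#' @param aln A `codon_alignment`.
#' @param tree `ape::phylo` with branch lengths; leaves must match the
#'   alignment taxa.
#' @param kappa Transition/transversion ratio.
#' @param omegas Vector of dN/dS class values.
#' @param weights Mixture weights (same length, summing to 1).
#' @param codon_freqs Codon frequencies; default F3x4 from the data.
#' @return List with `lnL`, `site_loglik` (per-site mixture
#'   log-likelihood) and `class_site_loglik` (classes x sites).
#' @export
log_likelihood <- function(aln, tree, kappa, omegas, weights = NULL,
                           codon_freqs = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (is.null(weights)) weights <- rep(1 / length(omegas), length(omegas))
  if (is.null(codon_freqs)) codon_freqs <- estimate_f3x4(aln)
  if (is.null(tree$edge.length)) .stopf("tree must have branch lengths")
  .codon_loglik(.codon_index(aln), tree, kappa, omegas, weights, codon_freqs)
}
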