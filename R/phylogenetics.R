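# Distance phylogenetics: p / Poisson distances, Neighbor-Joining with a
# deterministic tie-break, bootstrap supports, and a small progressive
# protein aligner (guide tree + profile-profile Needleman-Wunsch).

# Coerce an alignment (named equal-length strings, or character matrix
# with taxa as rows) to a character matrix.
msa_matrix <- function(msa) {
  if (is.matrix(msa)) {
    if (is.null(rownames(msa))) .stopf("alignment matrix must have row names")
    return(msa)
  }
  if (is.null(names(msa))) .stopf("alignment must be named")
  lens <- nchar(msa)
  if (length(unique(lens)) != 1L)
    .stopf("aligned sequences must all have the same length")
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  rownames(m) <- names(msa)
  m
}

#' Pairwise p / Poisson distances from an alignment
#'
#' Gaps are handled by pairwise deletion: for each pair only columns
#' where both sequences are ungapped are compared. `p` is the fraction
#' of mismatching compared sites; `poisson` applies the correction
#' `-ln(1 - p)`.
#'
#' @param msa Alignment (named character vector of equal-length strings,
#'   or character matrix with taxa as rows).
#' @param model `"poisson"` (default) or `"p"`.
#' @return Symmetric numeric matrix with taxa dimnames.
#' @export
p_distance <- function(msa, model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- msa_matrix(msa)
  n <- nrow(m)
  gap <- m == "-"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(max(n - 1L, 0L))) {
    for (j in (i + 1L):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        .stopf("no comparable sites between %s and %s",
               rownames(m)[i], rownames(m)[j])
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      if (model == "poisson") {
        if (p >= 1) .stopf("saturated pair %s / %s (p = 1)",
                           rownames(m)[i], rownames(m)[j])
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-Joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix. Ties in the Q
#' criterion are broken by the smallest (row, column) index pair, so the
#' result is deterministic. Negative branch lengths are clamped to zero
#' with the deficit moved to the sister branch (their sum is preserved).
#' The result is unrooted (trifurcating root).
#'
#' @param dm Symmetric distance matrix with taxa dimnames (>= 3 taxa).
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    .stopf("nj_tree: dm must be a square matrix")
  n <- nrow(dm)
  if (n < 3L) .stopf("nj_tree: need at least 3 taxa")
  labels <- rownames(dm)
  if (is.null(labels)) .stopf("nj_tree: dm must have dimnames")
  D <- dm
  nodes <- labels
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (length(nodes) > 3L) {
    k <- length(nodes)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j), i < j
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- D[i, j]; bi <- 0 }
    if (bj < 0) { bi <- D[i, j]; bj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(bi), nodes[j], fmt(bj))
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
    dimnames(D2) <- list(NULL, NULL)
    D <- D2
  }
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(b1),
                 nodes[2], fmt(b2), nodes[3], fmt(b3))
  read_newick(text = txt)
}

#' Bootstrap supports for a Neighbor-Joining tree
#'
#' Builds the full-data NJ tree, then resamples alignment columns with
#' replacement `n_reps` times (via [ape::boot.phylo()]), rebuilding the
#' tree each time; the support of each internal node is the percentage
#' of replicate trees containing the same bipartition. Supports are
#' attached to the full-data tree as `node.label`.
#'
#' @param msa Alignment as in [p_distance()].
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; fixed seed gives identical supports.
#' @param model Distance model passed to [p_distance()].
#' @return The full-data `phylo` tree with percentage supports in
#'   `node.label` (the root label is `NA`).
#' @export
bootstrap_support <- function(msa, n_reps = 1000, seed = 1,
                              model = c("poisson", "p")) {
  model <- match.arg(model)
  m <- msa_matrix(msa)
  build <- function(x) nj_tree(p_distance(x, model = model))
  full <- build(m)
  set.seed(seed)
  counts <- ape::boot.phylo(full, m, build, B = n_reps, rooted = FALSE,
                            quiet = TRUE)
  support <- round(100 * counts / n_reps)
  support[1L] <- NA  # root pseudo-node of an unrooted tree
  full$node.label <- as.character(support)
  full
}

# ---- progressive alignment -------------------------------------------------

#' Progressive multiple protein alignment
#'
#' A basic progressive aligner: pairwise global alignments give an
#' identity-based guide tree (UPGMA / average-linkage), and profiles are
#' merged along it by profile-profile Needleman-Wunsch (mean BLOSUM62
#' column score, linear gap penalty). Deterministic; intended for the
#' short, highly conserved domain sequences this package works with.
#'
#' @param seqs Named character vector of at least 2 protein sequences.
#' @param gap_penalty Linear per-column gap penalty.
#' @return Named character vector: the aligned sequences, in input
#'   order, all the same length (>= the longest input).
#' @export
progressive_align <- function(seqs, gap_penalty = 8) {
  if (length(seqs) < 2L || is.null(names(seqs)))
    .stopf("progressive_align: need >= 2 named sequences")
  n <- length(seqs)
  if (n == 2L) {
    al <- global_align(seqs[[1L]], seqs[[2L]], mode = "aa")
    return(setNames(c(al$aligned_a, al$aligned_b), names(seqs)))
  }
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    al <- .batch_align_aa(seqs[[i]], unname(seqs[js]))
    D[i, js] <- D[js, i] <- 1 - al$identity
  }
  hc <- hclust(as.dist(D), method = "average")
  profiles <- lapply(seq_len(n), function(i) {
    m <- matrix(strsplit(toupper(seqs[[i]]), "")[[1L]], nrow = 1L)
    rownames(m) <- names(seqs)[i]
    m
  })
  merged <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    pick <- function(v) if (v < 0) profiles[[-v]] else merged[[v]]
    merged[[k]] <- .profile_nw(pick(hc$merge[k, 1L]), pick(hc$merge[k, 2L]),
                               gap_penalty)
  }
  final <- merged[[n - 1L]]
  out <- apply(final, 1L, paste, collapse = "")
  out[names(seqs)]
}

# Profile-profile Needleman-Wunsch on character matrices (rows = seqs).
.profile_nw <- function(A, B, gap_penalty) {
  syms <- c(rownames(get_blosum62()), "-")
  M <- matrix(-4, length(syms), length(syms), dimnames = list(syms, syms))
  bl <- get_blosum62()
  M[rownames(bl), colnames(bl)] <- bl
  M["-", "-"] <- 0
  freq <- function(P) {
    f <- apply(P, 2L, function(col) tabulate(factor(col, levels = syms),
                                             nbins = length(syms)))
    f / nrow(P)
  }
  FA <- freq(A); FB <- freq(B)
  S <- t(FA) %*% M %*% FB
  na <- ncol(A); nb <- ncol(B)
  score <- matrix(0, na + 1L, nb + 1L)
  ptr <- matrix(0L, na + 1L, nb + 1L)  # 1 diag, 2 up (gap in B), 3 left
  score[, 1L] <- -gap_penalty * (0:na)
  score[1L, ] <- -gap_penalty * (0:nb)
  ptr[-1L, 1L] <- 2L; ptr[1L, -1L] <- 3L
  for (i in seq_len(na)) {
    diag_s <- score[i, seq_len(nb)] + S[i, ]
    row_prev <- score[i, -1L] - gap_penalty   # up moves
    cur <- numeric(nb); p <- integer(nb)
    left_s <- score[i + 1L, 1L]
    for (j in seq_len(nb)) {
      best <- diag_s[j]; pb <- 1L
      if (row_prev[j] > best) { best <- row_prev[j]; pb <- 2L }
      lft <- left_s - gap_penalty
      if (lft > best) { best <- lft; pb <- 3L }
      cur[j] <- best; p[j] <- pb
      left_s <- best
    }
    score[i + 1L, -1L] <- cur
    ptr[i + 1L, -1L] <- p
  }
  # traceback
  i <- na + 1L; j <- nb + 1L
  colsA <- integer(0); colsB <- integer(0)  # 0 = gap column
  while (i > 1L || j > 1L) {
    mv <- ptr[i, j]
    if (mv == 1L) { colsA <- c(i - 1L, colsA); colsB <- c(j - 1L, colsB); i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) { colsA <- c(i - 1L, colsA); colsB <- c(0L, colsB); i <- i - 1L }
    else { colsA <- c(0L, colsA); colsB <- c(j - 1L, colsB); j <- j - 1L }
  }
  take <- function(P, cols) {
    out <- matrix("-", nrow(P), length(cols), dimnames = list(rownames(P), NULL))
    out[, cols != 0L] <- P[, cols[cols != 0L], drop = FALSE]
    out
  }
  rbind(take(A, colsA), take(B, colsB))
}
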