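# Chromosomal organization: gene mapping, 200-kb clusters, duplications.

#' Detect duplicated gene pairs (70/70 rule)
#'
#' Tests every unordered pair of genes and calls a duplication when the
#' alignable nucleotide sequence covers more than 70% of the longer CDS
#' AND the amino-acid identity exceeds 70% (both thresholds strict).
#' Pairs on the same chromosome are tandem duplications; all others,
#' including pairs with an unplaced member, are segmental (unplaced
#' pairs are flagged, since tandem status cannot be excluded).
#'
#' @param records List of `gene_record` objects with `protein` and
#'   `cds` filled in.
#' @param min_coverage,min_identity Strict lower thresholds.
#' @return Data frame with `id_a`, `id_b` (canonical order),
#'   `nt_coverage`, `aa_identity`, `mode` (`"TANDEM"`/`"SEGMENTAL"`),
#'   `unplaced_member`.
#' @export
detect_duplications <- function(records, min_coverage = 0.70,
                                min_identity = 0.70) {
  n <- length(records)
  empty <- data.frame(id_a = character(0), id_b = character(0),
                      nt_coverage = numeric(0), aa_identity = numeric(0),
                      mode = character(0), unplaced_member = logical(0))
  if (n < 2L) return(empty)
  prot <- vapply(records, `[[`, character(1), "protein")
  rows <- list()
  # amino-acid identity screened first (vectorized, one call per gene);
  # the nucleotide coverage criterion is then checked pair by pair
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    js <- js[!is.na(prot[js])]
    if (is.na(prot[i]) || !length(js)) next
    aa <- .batch_align_aa(prot[i], prot[js])
    for (kk in seq_along(js)) {
      j <- js[kk]
      a <- records[[i]]; b <- records[[j]]
      if (aa$identity[kk] <= min_identity) next
      if (is.na(a$cds) || is.na(b$cds)) next
      nt <- global_align(a$cds, b$cds, mode = "nt")
      if (nt$coverage <= min_coverage) next
      ids <- sort(c(a$gene_id, b$gene_id))
      unpl <- identical(a$chromosome, "UNPLACED") ||
        identical(b$chromosome, "UNPLACED")
      mode <- if (!unpl && identical(a$chromosome, b$chromosome))
        "TANDEM" else "SEGMENTAL"
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ids[1L], id_b = ids[2L], nt_coverage = nt$coverage,
        aa_identity = aa$identity[kk], mode = mode, unplaced_member = unpl,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call chromosomal gene clusters
#'
#' Single-linkage chaining on representative gene coordinates: within a
#' chromosome, consecutive genes (by position) whose gap does not exceed
#' `window_bp` join the same cluster; clusters with at least two members
#' are reported. The result is independent of input order.
#'
#' @param loci Data frame with columns `gene_id`, `chromosome`,
#'   `position` (1-based bp). Unplaced genes (`chromosome` equal to
#'   `"UNPLACED"` or `"nd"`, or `NA` position) are ignored.
#' @param window_bp Maximum gap between consecutive cluster members
#'   (default 200 kb).
#' @return Data frame with one row per cluster: `chromosome`,
#'   `members` (comma-separated gene ids ordered by position),
#'   `n_members`, `span_bp`.
#' @export
detect_clusters <- function(loci, window_bp = 200000) {
  loci <- loci[!is.na(loci$position) &
                 !loci$chromosome %in% c("UNPLACED", "nd"), , drop = FALSE]
  out <- list()
  for (chrom in sort(unique(loci$chromosome))) {
    sub <- loci[loci$chromosome == chrom, , drop = FALSE]
    sub <- sub[order(sub$position, sub$gene_id), , drop = FALSE]
    if (nrow(sub) < 2L) next
    gap <- diff(sub$position)
    cluster_id <- cumsum(c(1L, as.integer(gap > window_bp)))
    for (cid in unique(cluster_id)) {
      m <- sub[cluster_id == cid, , drop = FALSE]
      if (nrow(m) < 2L) next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = chrom,
        members = paste(m$gene_id, collapse = ","),
        n_members = nrow(m),
        span_bp = max(m$position) - min(m$position),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(0), members = character(0),
                      n_members = integer(0), span_bp = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-chromosome gene counts
#'
#' @param loci Data frame with `gene_id`, `chromosome`, optionally a
#'   `group` column for a per-group breakdown.
#' @param chromosomes Chromosome names expected in the genome.
#' @return Data frame with one row per chromosome (plus `UNPLACED`) and
#'   a `n_genes` column; per-group columns when `group` is present.
#' @export
chromosome_distribution <- function(loci, chromosomes = as.character(1:6)) {
  chrom <- ifelse(is.na(loci$chromosome) | loci$chromosome %in% c("nd", "UNPLACED"),
                  "UNPLACED", loci$chromosome)
  lv <- c(chromosomes, "UNPLACED")
  counts <- table(factor(chrom, levels = lv))
  out <- data.frame(chromosome = lv, n_genes = as.integer(counts),
                    stringsAsFactors = FALSE)
  if ("group" %in% names(loci)) {
    major <- sub("^(I{1,3})[a-ex]*$", "\\1", loci$group)
    major[!major %in% c("I", "II", "III")] <- "other"
    tab <- table(factor(chrom, levels = lv),
                 factor(major, levels = c("I", "II", "III", "other")))
    out <- cbind(out, as.data.frame.matrix(tab))
    names(out)[3:6] <- c("group_I", "group_II", "group_III", "group_other")
    rownames(out) <- NULL
  }
  out
}

#' Loci table from the curated gene table or gene records
#'
#' @param x A data frame from [load_ljwrky_table()] or a list of
#'   `gene_record` objects.
#' @return Data frame with `gene_id`, `chromosome`, `position` and,
#'   when available, `group`.
#' @export
as_loci <- function(x) {
  if (is.data.frame(x)) {
    data.frame(gene_id = x$gene_name, chromosome = x$chromosome,
               position = x$location, group = x$group,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = vapply(x, `[[`, character(1), "gene_id"),
               chromosome = vapply(x, `[[`, character(1), "chromosome"),
               position = vapply(x, `[[`, numeric(1), "start"),
               stringsAsFactors = FALSE)
  }
}
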