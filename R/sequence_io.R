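#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] returning plain
#' upper-case character vectors, which is what the scanning and
#' alignment layers of this package work on.
#'
#' @param path Path to a FASTA file.
#' @param rna_to_dna Logical; when `TRUE`, `U` is normalized to `T`
#'   (nucleotide mode convenience).
#' @return Named character vector of upper-case sequences, in file
#'   order. Names are the first whitespace-delimited token of each
#'   header.
#' @export
read_fasta <- function(path, rna_to_dna = FALSE) {
  if (!file.exists(path)) .stopf("FASTA file not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) .stopf("empty FASTA file: %s", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) .stopf("duplicate FASTA id: %s", dup[[1L]])
  seqs <- toupper(as.character(set))
  if (rna_to_dna) seqs <- gsub("U", "T", seqs, fixed = TRUE)
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || anyNA(names(seqs)) || any(names(seqs) == ""))
    .stopf("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    chunks <- substring(s, seq(1L, nchar(s), width),
                        pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s)))
    writeLines(c(paste0(">", names(seqs)[i]), chunks), con)
  }
  invisible(path)
}

#' Construct a gene record
#'
#' The central per-gene container. Coordinates use a 0-based half-open
#' convention on the gene's own (transcript-oriented) frame; the
#' genomic anchors (`chromosome`, `start`) stay 1-based as annotation
#' formats print them.
#'
#' @param gene_id Gene identifier.
#' @param chromosome Chromosome name, or `"UNPLACED"`.
#' @param start 1-based genomic position of the gene (representative
#'   coordinate used for mapping and clustering), or `NA`.
#' @param protein Amino acid sequence (may be `NA` for skeletons).
#' @param cds Coding nucleotide sequence 5'->3' (may be `NA`).
#' @param exons Integer matrix with columns `start`, `end`: coding exon
#'   intervals, 0-based half-open, on the transcript-oriented gene
#'   frame, sorted and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @param group_label Optional classification label.
#' @param pseudogene Logical flag.
#' @return An object of class `gene_record`.
#' @export
gene_record <- function(gene_id, chromosome = "UNPLACED", start = NA_integer_,
                        protein = NA_character_, cds = NA_character_,
                        exons = NULL, strand = "+",
                        group_label = NA_character_, pseudogene = FALSE) {
  if (!is.null(exons)) {
    exons <- matrix(as.integer(exons), ncol = 2L,
                    dimnames = list(NULL, c("start", "end")))
    if (nrow(exons) > 1L) {
      o <- order(exons[, 1L])
      exons <- exons[o, , drop = FALSE]
      if (any(exons[-1L, 1L] < exons[-nrow(exons), 2L]))
        .stopf("overlapping exons in gene %s", gene_id)
    }
    if (any(exons[, 2L] <= exons[, 1L]))
      .stopf("empty or inverted exon interval in gene %s", gene_id)
  }
  structure(list(gene_id = gene_id, chromosome = chromosome,
                 start = as.numeric(start), protein = protein, cds = cds,
                 exons = exons, strand = strand, group_label = group_label,
                 pseudogene = isTRUE(pseudogene)),
            class = "gene_record")
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record> %s  %s:%s (%s)  exons: %s  cds: %s nt\n",
              x$gene_id, x$chromosome,
              ifelse(is.na(x$start), "?", format(x$start, big.mark = ",")),
              x$strand,
              if (is.null(x$exons)) 0L else nrow(x$exons),
              ifelse(is.na(x$cds), 0L, nchar(x$cds))))
  invisible(x)
}

#' Spliced CDS length implied by the coding exons of a record
#' @param record A `gene_record`.
#' @return Integer number of coding nucleotides.
#' @export
coding_length <- function(record) {
  if (is.null(record$exons)) return(0L)
  sum(record$exons[, 2L] - record$exons[, 1L])
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features (via [rtracklayer::import()]) into
#' `gene_record` skeletons, one per mRNA. CDS intervals are converted to
#' the package's 0-based half-open convention on a transcript-oriented
#' gene frame: position 0 is the genomic start of the gene for `+`
#' strand genes and the genomic end for `-` strand genes, so exon order
#' always follows transcription.
#'
#' @param path Path to a GFF3 file (with a `##gff-version` header).
#' @param gene_seqs Optional named character vector of per-gene genomic
#'   sequences already in transcript orientation (as written by
#'   [generate_genome()]); when given, `cds` and `protein` are filled in
#'   by splicing and translating.
#' @return List of `gene_record` objects.
#' @export
read_gff3 <- function(path, gene_seqs = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  parent <- vapply(gr$Parent, function(p) if (length(p)) p[[1L]] else NA_character_,
                   character(1))
  ids <- gr$ID
  is_mrna <- type == "mRNA"
  is_cds <- type == "CDS"
  if (any(is.na(parent[is_cds])))
    .stopf("CDS feature without an mRNA parent in %s", path)
  if (!all(parent[is_cds] %in% ids[is_mrna]))
    .stopf("CDS feature whose Parent is not an mRNA in %s", path)
  gene_start <- setNames(GenomicRanges::start(gr)[type == "gene"],
                         ids[type == "gene"])
  gene_end <- setNames(GenomicRanges::end(gr)[type == "gene"],
                       ids[type == "gene"])
  records <- vector("list", sum(is_mrna))
  k <- 0L
  for (i in which(is_mrna)) {
    mid <- ids[i]
    gid <- parent[i]
    if (is.na(gid) || !gid %in% names(gene_start))
      .stopf("mRNA %s has no gene parent", mid)
    m_start <- GenomicRanges::start(gr)[i]
    m_end <- GenomicRanges::end(gr)[i]
    if (m_start < gene_start[[gid]] || m_end > gene_end[[gid]])
      .stopf("mRNA %s not contained in its gene %s", mid, gid)
    strand <- as.character(GenomicRanges::strand(gr)[i])
    if (!strand %in% c("+", "-")) strand <- "+"
    sel <- is_cds & parent == mid
    if (!any(sel)) .stopf("mRNA %s has no CDS features", mid)
    cs <- GenomicRanges::start(gr)[sel]
    ce <- GenomicRanges::end(gr)[sel]
    if (any(cs < gene_start[[gid]]) || any(ce > gene_end[[gid]]))
      .stopf("CDS of %s extends outside gene %s", mid, gid)
    gs <- gene_start[[gid]]; ge <- gene_end[[gid]]
    if (strand == "+") {
      exons <- cbind(cs - gs, ce - gs + 1L)
    } else {
      exons <- cbind(ge - ce, ge - cs + 1L)
    }
    rec <- gene_record(gene_id = gid,
                       chromosome = as.character(GenomicRanges::seqnames(gr)[i]),
                       start = gs, exons = exons, strand = strand)
    if (!is.null(gene_seqs) && gid %in% names(gene_seqs)) {
      gseq <- gene_seqs[[gid]]
      cds <- paste(substring(gseq, rec$exons[, 1L] + 1L, rec$exons[, 2L]),
                   collapse = "")
      rec$cds <- cds
      rec$protein <- translate_cds(cds)
    }
    k <- k + 1L
    records[[k]] <- rec
  }
  records[seq_len(k)]
}

#' Write gene models to GFF3
#'
#' Emits gene, mRNA and CDS features for each record. Coordinates are
#' converted back from the internal 0-based transcript frame to 1-based
#' genomic intervals. Records without a placed chromosome are written on
#' a `"scaffold_unplaced"` pseudo-sequence at their stored start.
#'
#' @param records List of `gene_record` objects with exons.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path) {
  lines <- "##gff-version 3"
  for (rec in records) {
    if (is.null(rec$exons)) .stopf("record %s has no exons", rec$gene_id)
    chrom <- if (identical(rec$chromosome, "UNPLACED")) "scaffold_unplaced" else rec$chromosome
    gs <- if (is.na(rec$start)) 1 else rec$start
    glen <- max(rec$exons[, 2L])
    ge <- gs + glen - 1
    if (rec$strand == "+") {
      cs <- gs + rec$exons[, 1L]
      ce <- gs + rec$exons[, 2L] - 1L
    } else {
      cs <- ge - rec$exons[, 2L] + 1L
      ce <- ge - rec$exons[, 1L]
    }
    o <- order(cs)
    cs <- cs[o]; ce <- ce[o]
    gid <- rec$gene_id
    lines <- c(lines,
      sprintf("%s\twrkyscan\tgene\t%.0f\t%.0f\t.\t%s\t.\tID=%s", chrom, gs, ge, rec$strand, gid),
      sprintf("%s\twrkyscan\tmRNA\t%.0f\t%.0f\t.\t%s\t.\tID=%s.m;Parent=%s", chrom, gs, ge, rec$strand, gid, gid),
      sprintf("%s\twrkyscan\texon\t%.0f\t%.0f\t.\t%s\t.\tID=%s.e%d;Parent=%s.m", chrom, cs, ce, rec$strand, gid, seq_along(cs), gid),
      sprintf("%s\twrkyscan\tCDS\t%.0f\t%.0f\t.\t%s\t0\tID=%s.c%d;Parent=%s.m", chrom, cs, ce, rec$strand, gid, seq_along(cs), gid))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Load the curated L. japonicus WRKY gene table
#'
#' Returns the packaged table of all 71 WRKY family members annotated in
#' the Lotus japonicus genome (build 2.5): gene name, group/subgroup
#' label, chromosome, representative genomic coordinate and pseudogene
#' flag. Genes whose classification or position could not be determined
#' carry `"nd"`. Locations are 1-based base pairs with thousands
#' separators already stripped.
#'
#' @return A data frame with columns `annotation_id`, `gene_name`,
#'   `group`, `chromosome`, `location`, `pseudogene`.
#' @export
load_ljwrky_table <- function() {
  path <- system.file("extdata", "ljwrky_genes.tsv", package = "wrkyscan",
                      mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "character",
                                   "character", "character", "logical"))
  tab$location <- suppressWarnings(as.numeric(gsub(",", "", tab$location)))
  stopifnot(nrow(tab) == 71L,
            all(tab$group %in% c("I", "IIa", "IIb", "IIc", "IId", "IIe",
                                 "IIx", "III", "nd")),
            all(tab$chromosome %in% c(as.character(1:6), "nd")))
  tab
}

#' Read / write Newick trees
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] so all
#' tree I/O in the package goes through one point. Round-trips preserve
#' topology, branch lengths and node support labels.
#'
#' @param path File path (for `read_newick`) or output path.
#' @param text Optional Newick string instead of a file.
#' @param tree An `ape::phylo` object.
#' @return `read_newick`: a `phylo`; `write_newick`: the Newick string,
#'   invisibly (written to `path` when given).
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- tryCatch(
    if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text),
    error = function(e) .stopf("Newick parse error: %s", conditionMessage(e)))
  if (is.null(tr)) .stopf("Newick parse error in %s",
                          if (is.null(text)) path else "text")
  tr
}

#' @rdname read_newick
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree, digits = 6)
  if (!is.null(path)) writeLines(txt, path)
  invisible(txt)
}

# Universal-code translation of a CDS string; internal stops become '*',
# a terminal stop is dropped (mirrors how conceptual translations are
# reported for putative pseudogenes).
translate_cds <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  codons <- substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  if (aa[n] == "*") aa <- aa[-n]
  paste(aa, collapse = "")
}
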