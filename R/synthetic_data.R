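# Synthetic genome generator with exact planted ground truth.
#
# Genes are assembled from the packaged domain templates plus random
# background drawn from a 17-letter alphabet (no W, C or H, so the only
# heptapeptides and zinc fingers present are the planted ones; any
# residual risk from frameshift-garbled tails is removed by rejection
# sampling against the scanner's expected call).

.BG_ALPHABET <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N",
                  "P", "Q", "R", "S", "T", "V", "Y")

# Deterministic back-translation: one fixed codon per amino acid.
.aa_codon_map <- local({
  map <- NULL
  function() {
    if (is.null(map)) {
      gc <- Biostrings::GENETIC_CODE
      aa <- unique(unname(gc))
      map <<- vapply(aa, function(a) names(gc)[gc == a][1L], character(1))
    }
    map
  }
})

.backtranslate_fixed <- function(protein) {
  map <- .aa_codon_map()
  aas <- strsplit(protein, "")[[1L]]
  paste(c(map[aas], "TAA"), collapse = "")
}

#' Synthetic genome configuration
#'
#' Defaults mirror the architecture of the L. japonicus WRKY family:
#' 12/5/8/13/5/9/2/7 genes in groups I, IIa-IIe, IIx, III (61 genes),
#' plus 10 structurally defective candidates that the filter should
#' drop; 9 pseudogenes (3 in I, 2 in IIa, 2 in IIc, 1 in IIe, 1 in IIx);
#' 48 genes placed on chromosomes 1-6 (14/8/4/13/5/4) and the rest
#' unplaced; one planted tandem duplicate pair (90% amino-acid identity,
#' 129 kb apart on chromosome 4) and additional sub-200-kb clusters on
#' chromosomes 1, 2 and 5; R-type introns in subgroups Ic (the group I
#' C-terminal domain), IIc, IId, IIe and III and V-type introns in IIa
#' and IIb, with lengths around 600 bp.
#'
#' @param n_per_class Named integer vector of gene counts per class.
#' @param n_defective Count of planted defective candidates.
#' @param pseudogenes Named vector: pseudogene count per class.
#' @param chromosome_genes Named vector: placed-gene quota per
#'   chromosome (in gene construction order); remaining genes are
#'   unplaced.
#' @param clusters List of `list(chromosome=, size=, gap_bp=)` planted
#'   clusters (the first `size` genes of the chromosome are spaced
#'   `gap_bp` apart).
#' @param tandem_identity Target amino-acid identity of the planted
#'   tandem pair (on chromosome 4).
#' @param spacing_bp Default gap between non-cluster neighbors.
#' @param intron_mean_bp,intron_sd_bp Planted intron length
#'   distribution.
#' @param n_mut Background mutations per gene (sequence distinctness).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_per_class = c(I = 12, IIa = 5, IIb = 8, IIc = 13,
                                         IId = 5, IIe = 9, IIx = 2, III = 7),
                         n_defective = 10,
                         pseudogenes = c(I = 3, IIa = 2, IIc = 2, IIe = 1,
                                         IIx = 1),
                         chromosome_genes = c(`1` = 14, `2` = 8, `3` = 4,
                                              `4` = 13, `5` = 5, `6` = 4),
                         clusters = list(
                           list(chromosome = "1", size = 2, gap_bp = 32000),
                           list(chromosome = "2", size = 3, gap_bp = 80000),
                           list(chromosome = "4", size = 2, gap_bp = 129000),
                           list(chromosome = "5", size = 2, gap_bp = 78000)),
                         tandem_identity = 0.90, spacing_bp = 500000,
                         intron_mean_bp = 600, intron_sd_bp = 120,
                         n_mut = 4, seed = 42) {
  stopifnot(all(n_per_class >= 0), n_defective >= 0,
            all(names(pseudogenes) %in% names(n_per_class)),
            all(pseudogenes <= n_per_class[names(pseudogenes)]),
            tandem_identity > 0, tandem_identity <= 1)
  structure(list(n_per_class = n_per_class, n_defective = n_defective,
                 pseudogenes = pseudogenes,
                 chromosome_genes = chromosome_genes, clusters = clusters,
                 tandem_identity = tandem_identity, spacing_bp = spacing_bp,
                 intron_mean_bp = intron_mean_bp, intron_sd_bp = intron_sd_bp,
                 n_mut = n_mut, seed = seed),
            class = "synth_config")
}

.rand_bg <- function(n) paste(sample(.BG_ALPHABET, n, replace = TRUE),
                              collapse = "")

# Intron plan by class: which conserved intron a planted gene carries.
.intron_plan <- function(class) {
  switch(class,
         I = "R", IIc = "R", IId = "R", IIe = "R", III = "R",
         IIa = "V", IIb = "V",
         "none")
}

#' Generate a synthetic genome with planted WRKY genes
#'
#' Builds proteins from the packaged domain templates (group I genes get
#' an In and an Ic domain; group III a C2HC finger), back-translates
#' them to CDS, plants pseudogene lesions (premature stop codons and
#' single-nucleotide frameshifts in the C-terminal tail), a tandem
#' duplicate pair, chromosomal clusters, and R-/V-type introns at the
#' grammar-defined anchor codons. Every planted label is recorded in the
#' truth table. Output is deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @param out_dir Optional directory; when given, writes `proteins.fa`,
#'   `cds.fa`, `genes_genomic.fa` (per-gene genomic sequence, transcript
#'   orientation), `genes.gff3` and `truth.tsv`.
#' @return List with `records` (list of `gene_record`), `proteins`,
#'   `cds`, `gene_seqs` (named character vectors), `truth` (data frame)
#'   and `config`; invisibly writes files when `out_dir` is given.
#' @export
generate_genome <- function(config = synth_config(), out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  tpl <- wrky_domain_templates()
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n_good <- length(classes)
  ids <- sprintf("SYNW%03d", seq_len(n_good + config$n_defective))

  # which genes are pseudogenes (last k of each class) / the tandem pair
  pseudo <- rep(FALSE, n_good)
  pseudo_type <- rep(NA_character_, n_good)
  for (cl in names(config$pseudogenes)) {
    k <- config$pseudogenes[[cl]]
    if (k == 0) next
    idx <- rev(which(classes == cl))[seq_len(k)]
    pseudo[idx] <- TRUE
    pseudo_type[idx] <- rep(c("premature_stop", "frameshift"),
                            length.out = k)
  }
  # tandem pair: first two genes of the chromosome-4 block (see placement)
  placed_quota <- config$chromosome_genes
  block_start <- cumsum(c(0, placed_quota))[seq_along(placed_quota)] + 1L
  names(block_start) <- names(placed_quota)
  pair_a <- block_start[["4"]]
  pair_b <- pair_a + 1L
  if (pair_b > n_good) pair_a <- pair_b <- NA_integer_

  build_gene <- function(i) {
    cl <- classes[i]
    n_tail <- 22L + (i %% 7L)   # varied lengths
    c_tail <- 18L + (i %% 5L)
    expected <- function(protein) {
      d <- scan_wrky_domains(protein)
      g <- classify_group(d)$group
      if (cl == "I") g == "I"
      else if (cl == "III") g == "III" && length(d) == 1L
      else g == "II" && length(d) == 1L && d[[1L]]$zf_class == "C2H2"
    }
    for (try in 1:60) {
      core <- if (cl == "I") {
        paste0(tpl[["In"]], .rand_bg(28L + (i %% 5L)), tpl[["Ic"]])
      } else tpl[[cl]]
      protein <- paste0(.rand_bg(n_tail), core, .rand_bg(c_tail))
      # background mutations for distinctness (domain untouched)
      aas <- strsplit(protein, "")[[1L]]
      dom_lo <- n_tail + 1L
      dom_hi <- n_tail + nchar(core)
      bg_pos <- setdiff(seq_along(aas), dom_lo:dom_hi)
      if (config$n_mut > 0 && length(bg_pos) > config$n_mut) {
        mut <- sample(bg_pos, config$n_mut)
        aas[mut] <- sample(.BG_ALPHABET, config$n_mut, replace = TRUE)
      }
      protein <- paste(aas, collapse = "")
      cds <- .backtranslate_fixed(protein)
      if (pseudo[i]) {
        tail_codon0 <- nchar(protein) - c_tail + 4L  # 0-based aa index in tail
        if (pseudo_type[i] == "premature_stop") {
          substr(cds, 3L * tail_codon0 + 1L, 3L * tail_codon0 + 3L) <- "TAA"
        } else {
          cut <- 3L * tail_codon0 + 2L
          cds <- paste0(substr(cds, 1L, cut - 1L),
                        substr(cds, cut + 1L, nchar(cds)))
        }
      }
      protein_final <- translate_cds(cds)
      if (expected(protein_final))
        return(list(protein = protein_final, cds = cds, class = cl))
    }
    .stopf("generate_genome: could not realize a %s gene after 60 draws", cl)
  }

  genes <- lapply(seq_len(n_good), build_gene)

  # tandem duplicate: rebuild pair_b as a mutated copy of pair_a
  dup_of <- rep(NA_character_, n_good)
  if (!is.na(pair_a)) {
    src <- genes[[pair_a]]
    aas <- strsplit(src$protein, "")[[1L]]
    d <- scan_wrky_domains(src$protein)[[1L]]
    dom_span <- (d$hepta_start + 1L):(d$hepta_start + d$span)
    bg_pos <- setdiff(seq_along(aas), dom_span)
    k <- round((1 - config$tandem_identity) * length(aas))
    for (try in 1:60) {
      aa2 <- aas
      mut <- sample(bg_pos, min(k, length(bg_pos)))
      repl <- vapply(aa2[mut], function(x)
        sample(setdiff(.BG_ALPHABET, x), 1L), character(1))
      aa2[mut] <- repl
      prot2 <- paste(aa2, collapse = "")
      doms2 <- scan_wrky_domains(prot2)
      if (length(doms2) == 1L && doms2[[1L]]$complete &&
          doms2[[1L]]$zf_class == "C2H2") {
        genes[[pair_b]] <- list(protein = prot2,
                                cds = .backtranslate_fixed(prot2),
                                class = classes[pair_b])
        dup_of[pair_b] <- ids[pair_a]
        break
      }
    }
  }

  # defective candidates: heptapeptide with no zinc finger
  defective <- lapply(seq_len(config$n_defective), function(i) {
    protein <- paste0(.rand_bg(20L), "WRKYGQK", .rand_bg(10L), .rand_bg(15L))
    list(protein = protein, cds = .backtranslate_fixed(protein),
         class = "defective")
  })

  all_genes <- c(genes, defective)
  all_classes <- c(classes, rep("defective", config$n_defective))

  # chromosome placement
  chroms <- rep("UNPLACED", length(all_genes))
  positions <- rep(NA_real_, length(all_genes))
  gi <- 1L
  for (chrom in names(placed_quota)) {
    quota <- placed_quota[[chrom]]
    cluster <- Filter(function(cc) cc$chromosome == chrom, config$clusters)
    gaps <- rep(config$spacing_bp, quota - 1L)
    if (length(cluster)) {
      sz <- cluster[[1L]]$size
      gaps[seq_len(min(sz - 1L, length(gaps)))] <- cluster[[1L]]$gap_bp
    }
    pos <- 400000 + cumsum(c(0, gaps))
    for (j in seq_len(quota)) {
      if (gi > n_good) break
      chroms[gi] <- chrom
      positions[gi] <- pos[j]
      gi <- gi + 1L
    }
  }

  # introns + records
  records <- vector("list", length(all_genes))
  intron_type <- rep("none", length(all_genes))
  intron_len <- rep(NA_integer_, length(all_genes))
  subgroups <- ifelse(grepl("^II", all_classes), all_classes, "none")
  for (i in seq_along(all_genes)) {
    g <- all_genes[[i]]
    cds_len <- nchar(g$cds)
    plan <- if (all_classes[i] == "defective") "none" else .intron_plan(all_classes[i])
    exons <- NULL
    gene_seq <- g$cds
    if (plan != "none") {
      doms <- scan_wrky_domains(g$protein)
      complete <- vapply(doms, `[[`, logical(1), "complete")
      dom <- doms[[rev(which(complete))[1L]]]  # C-terminal domain for group I
      len <- max(80L, round(rnorm(1, config$intron_mean_bp, config$intron_sd_bp)))
      if (plan == "R") {
        r_idx <- dom$hepta_start + 9L          # linker R (0-based)
        offset <- 3L * r_idx + 2L              # phase 2: 2 nt into the R codon
      } else {
        v_idx <- dom$zf_coords[2L] + 6L
        offset <- 3L * v_idx                   # phase 0: before the V codon
      }
      intron_seq <- paste0("GT", .rand_dna(len - 4L), "AG")
      exons <- rbind(c(0L, offset), c(offset + len, cds_len + len))
      gene_seq <- paste0(substr(g$cds, 1L, offset), intron_seq,
                         substr(g$cds, offset + 1L, cds_len))
      intron_type[i] <- plan
      intron_len[i] <- len
    } else {
      exons <- rbind(c(0L, cds_len))
    }
    strand <- if (i %% 17L == 0L) "-" else "+"
    records[[i]] <- gene_record(gene_id = ids[i], chromosome = chroms[i],
                                start = positions[i], protein = g$protein,
                                cds = g$cds, exons = exons, strand = strand,
                                group_label = all_classes[i],
                                pseudogene = i <= n_good && pseudo[i])
    records[[i]]$gene_seq <- gene_seq
  }

  truth <- data.frame(
    gene_id = ids,
    class = all_classes,
    group = ifelse(all_classes == "defective", "none",
                   sub("^(I{1,3}).*$", "\\1", all_classes)),
    subgroup = subgroups,
    defective = all_classes == "defective",
    pseudogene = c(pseudo, rep(FALSE, config$n_defective)),
    pseudo_type = c(pseudo_type, rep(NA_character_, config$n_defective)),
    chromosome = chroms, position = positions,
    intron_type = intron_type, intron_length = intron_len,
    duplicate_of = c(dup_of, rep(NA_character_, config$n_defective)),
    stringsAsFactors = FALSE)

  proteins <- setNames(vapply(all_genes, `[[`, character(1), "protein"), ids)
  cds <- setNames(vapply(all_genes, `[[`, character(1), "cds"), ids)
  gene_seqs <- setNames(vapply(records, `[[`, character(1), "gene_seq"), ids)

  out <- list(records = records, proteins = proteins, cds = cds,
              gene_seqs = gene_seqs, truth = truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(proteins, file.path(out_dir, "proteins.fa"))
    write_fasta(cds, file.path(out_dir, "cds.fa"))
    write_fasta(gene_seqs, file.path(out_dir, "genes_genomic.fa"))
    write_gff3(records, file.path(out_dir, "genes.gff3"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

.rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

#' Simulate a codon alignment under a GY94 site mixture
#'
#' Root codons are drawn from the stationary distribution; each site is
#' assigned an omega class and evolved down the tree with the matrix
#' exponential of the (mixture-rate-normalized) generator, so branch
#' lengths mean expected substitutions per codon exactly as in
#' [log_likelihood()].
#'
#' @param tree `ape::phylo` with branch lengths.
#' @param kappa Transition/transversion ratio.
#' @param omegas Vector of class omega values.
#' @param weights Class weights (default uniform).
#' @param n_codons Number of codon sites.
#' @param codon_freqs Stationary codon frequencies (default uniform over
#'   the 61 sense codons).
#' @param seed RNG seed.
#' @return List with `aln` (a `codon_alignment` over the tree's tips)
#'   and `site_class` (the planted class index per site).
#' @export
simulate_codon_alignment <- function(tree, kappa, omegas, weights = NULL,
                                     n_codons, codon_freqs = NULL, seed = 1) {
  if (is.null(weights)) weights <- rep(1 / length(omegas), length(omegas))
  stopifnot(length(weights) == length(omegas), abs(sum(weights) - 1) < 1e-8)
  pi <- if (is.null(codon_freqs)) rep(1 / 61, 61) else codon_freqs
  set.seed(seed)
  K <- length(omegas)
  site_class <- sample.int(K, n_codons, replace = TRUE, prob = weights)
  Qs <- lapply(omegas, function(w) gy94_Q(kappa, w, pi, scale = FALSE))
  rates <- vapply(Qs, function(Q) -sum(pi * diag(Q)), numeric(1))
  factor <- sum(weights * rates)
  if (factor <= 0) factor <- 1
  eigs <- lapply(Qs, function(Q) .q_eigen(Q / factor, pi))
  phy <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(phy$tip.label)
  n_node <- phy$Nnode
  states <- matrix(NA_integer_, n_tip + n_node, n_codons)
  root <- n_tip + 1L
  states[root, ] <- sample.int(61, n_codons, replace = TRUE, prob = pi)
  edges <- nrow(phy$edge)
  for (e in rev(seq_len(edges))) {   # reverse postorder = preorder
    par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    t <- max(phy$edge.length[e], 0)
    for (k in seq_len(K)) {
      sel <- which(site_class == k)
      if (!length(sel)) next
      P <- .p_matrix(eigs[[k]], t)
      P <- P / rowSums(P)
      for (s in sel) {
        states[child, s] <- sample.int(61, 1L, prob = P[states[par, s], ])
      }
    }
  }
  cods <- sense_codons()
  m <- matrix(cods[states[seq_len(n_tip), , drop = FALSE]], nrow = n_tip,
              dimnames = list(phy$tip.label, NULL))
  list(aln = codon_alignment(m), site_class = site_class,
       omegas = omegas, weights = weights)
}
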