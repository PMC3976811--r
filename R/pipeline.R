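# End-to-end orchestration: fixture mode (the packaged family table) and
# synthetic mode (a generated genome run through every stage), with all
# thresholds in one config and every report carrying the seed.

#' Pipeline configuration
#'
#' @param mode `"fixture"` (the packaged gene table) or `"synthetic"`
#'   (a generated genome run through scan/classify/filter/pseudogene/
#'   organize/structure/phylogeny stages).
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed recorded in every report and used for all
#'   randomness.
#' @param window_bp Gene-cluster window (default 200 kb).
#' @param dup_coverage,dup_identity Duplication thresholds (strict >).
#' @param min_domain_span Candidate filter: minimum complete-domain span.
#' @param bootstrap_reps Bootstrap replicates for the synthetic-mode
#'   domain tree.
#' @param run_phylo Build the domain NJ tree in synthetic mode.
#' @param synth A [synth_config()] for synthetic mode.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("fixture", "synthetic"), out_dir,
                            seed = 1, window_bp = 200000,
                            dup_coverage = 0.70, dup_identity = 0.70,
                            min_domain_span = 40L, bootstrap_reps = 100,
                            run_phylo = TRUE, synth = NULL) {
  mode <- match.arg(mode)
  if (is.null(synth)) synth <- synth_config(seed = seed)
  structure(list(mode = mode, out_dir = out_dir, seed = seed,
                 window_bp = window_bp, dup_coverage = dup_coverage,
                 dup_identity = dup_identity,
                 min_domain_span = min_domain_span,
                 bootstrap_reps = bootstrap_reps, run_phylo = run_phylo,
                 synth = synth),
            class = "pipeline_config")
}

.write_report <- function(df, path, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# wrkyscan report; seed=%d", seed), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Family group/subgroup summary
#'
#' Counts classified genes per group and group II subgroup. Accepts
#' either the packaged gene table (combined labels in `group`) or a
#' [classify_records()] data frame (`group` + `subgroup`); unclassified
#' / undetermined genes are excluded from the counts.
#'
#' @param x Data frame (see above) or a character vector of combined
#'   labels.
#' @return One-row data frame with columns `I`, `IIa`-`IIe`, `IIx`,
#'   `III` and `total`.
#' @export
summarize_family <- function(x) {
  labels <- if (is.character(x)) {
    x
  } else if (is.data.frame(x) && all(c("group", "subgroup") %in% names(x))) {
    ifelse(x$group == "II", x$subgroup, x$group)
  } else if (is.data.frame(x) && "group" %in% names(x)) {
    x$group
  } else .stopf("summarize_family: unsupported input")
  lv <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "IIx", "III")
  counts <- table(factor(labels, levels = lv))
  out <- as.data.frame(t(as.integer(counts)))
  names(out) <- lv
  out$total <- sum(out)
  out
}

#' Run the analysis pipeline
#'
#' Fixture mode reproduces the family-level summaries from the packaged
#' gene table: group/subgroup counts, pseudogene count, per-chromosome
#' distribution and 200-kb cluster calls (the cluster report is the
#' rule-faithful result of the chaining definition; the log records the
#' per-chromosome comparison). Synthetic mode generates a genome with
#' [generate_genome()] and runs scan, filter, classification, pseudogene
#' flagging, organization, intron typing and (optionally) domain
#' phylogenetics, writing one TSV per stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the stage results (also written as TSVs
#'   plus `log.txt` under `config$out_dir`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("wrkyscan %s", as.character(utils::packageVersion("wrkyscan"))),
                 sprintf("mode=%s seed=%d", config$mode, config$seed),
                 sprintf("thresholds: window_bp=%d dup_coverage=%.2f dup_identity=%.2f min_domain_span=%d",
                         config$window_bp, config$dup_coverage,
                         config$dup_identity, config$min_domain_span))
  res <- list(seed = config$seed)
  w <- function(df, name) .write_report(df, file.path(config$out_dir, name),
                                        config$seed)

  if (config$mode == "fixture") {
    tab <- load_ljwrky_table()
    loci <- as_loci(tab)
    res$family_summary <- summarize_family(tab[tab$group != "nd", ])
    res$chromosome_distribution <- chromosome_distribution(loci)
    res$clusters <- detect_clusters(loci, window_bp = config$window_bp)
    res$n_pseudogenes <- sum(tab$pseudogene)
    w(res$family_summary, "family_summary.tsv")
    w(res$chromosome_distribution, "chromosome_distribution.tsv")
    w(res$clusters, "clusters.tsv")
    per_chr <- table(factor(res$clusters$chromosome, levels = as.character(1:6)))
    log_lines <- c(log_lines,
      sprintf("pseudogenes flagged: %d", res$n_pseudogenes),
      sprintf("clusters (rule-faithful, %d kb chaining): total=%d genes=%d",
              config$window_bp %/% 1000, nrow(res$clusters),
              sum(res$clusters$n_members)),
      sprintf("clusters per chromosome: %s",
              paste(sprintf("chr%s=%d", names(per_chr), as.integer(per_chr)),
                    collapse = " ")))
  } else {
    gen <- generate_genome(config$synth)
    res$truth <- gen$truth
    cls <- classify_records(gen$proteins, gen$cds,
                            min_domain_span = config$min_domain_span)
    res$classification <- cls
    flt <- filter_candidates(cls)
    res$kept <- flt$kept; res$excluded <- flt$excluded
    res$family_summary <- summarize_family(flt$kept)
    kept_recs <- gen$records[match(flt$kept$gene_id,
                                   vapply(gen$records, `[[`, character(1), "gene_id"))]
    loci <- as_loci(kept_recs)
    loci$group <- flt$kept$group
    res$chromosome_distribution <- chromosome_distribution(loci)
    res$clusters <- detect_clusters(loci, window_bp = config$window_bp)
    res$duplications <- detect_duplications(kept_recs,
                                            min_coverage = config$dup_coverage,
                                            min_identity = config$dup_identity)
    introns <- lapply(kept_recs, function(r) {
      ann <- classify_intron_type(r)
      if (nrow(ann)) cbind(gene_id = r$gene_id, ann) else NULL
    })
    res$introns <- do.call(rbind, introns)
    res$intron_summary <- intron_length_summary(res$introns)
    w(cls[, setdiff(names(cls), "domains")], "classification.tsv")
    w(res$family_summary, "family_summary.tsv")
    w(res$chromosome_distribution, "chromosome_distribution.tsv")
    w(res$clusters, "clusters.tsv")
    w(res$duplications, "duplications.tsv")
    w(res$introns, "introns.tsv")
    if (config$run_phylo) {
      doms <- attr(cls, "domains")
      dom_seq <- vapply(flt$kept$gene_id, function(id) {
        d <- doms[[id]]
        dd <- d[[which(vapply(d, `[[`, logical(1), "complete"))[1L]]]
        substr(gen$proteins[[id]], dd$hepta_start + 1L,
               dd$hepta_start + dd$span)
      }, character(1))
      msa <- progressive_align(dom_seq)
      res$tree <- bootstrap_support(msa, n_reps = config$bootstrap_reps,
                                    seed = config$seed)
      write_newick(res$tree, file.path(config$out_dir, "domain_tree.nwk"))
    }
    log_lines <- c(log_lines,
      sprintf("genes kept/excluded: %d/%d", nrow(flt$kept), nrow(flt$excluded)),
      sprintf("pseudogenes flagged: %d", sum(flt$kept$pseudogene)),
      sprintf("clusters: %d; duplications: %d (tandem %d)",
              nrow(res$clusters), nrow(res$duplications),
              sum(res$duplications$mode == "TANDEM")))
  }
  writeLines(log_lines, file.path(config$out_dir, "log.txt"))
  invisible(res)
}
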