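test_that("global alignment statistics are exact on simple cases", {
  al <- global_align("ACGTACGTAC", "ACGTACGTAC", mode = "nt")
  expect_equal(al$identity, 1)
  expect_equal(al$coverage, 1)
  al2 <- global_align("ACGTACGTAC", "ACGTACGTTC", mode = "nt")
  expect_equal(al2$identity, 0.9)   # 9/10
  expect_error(global_align("ACGU", "ACGT", mode = "nt"), "non-ACGT")
  expect_error(global_align("", "A", mode = "aa"), "empty")
})

test_that("alignment scores match an independent dynamic-programming oracle", {
  set.seed(14)
  ntm <- nt_submat_oracle()
  for (i in 1:15) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(4:8, 1), TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(4:8, 1), TRUE), collapse = "")
    expect_equal(global_align(a, b, "nt")$score,
                 nw_score_oracle(a, b, ntm, open = 5, ext = 2))
  }
  # protein mode, random 50-mers against the same oracle with BLOSUM62
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  aas <- rownames(e$BLOSUM62)[1:20]
  for (i in 1:10) {
    a <- paste(sample(aas, 50, TRUE), collapse = "")
    b <- paste(sample(aas, 50, TRUE), collapse = "")
    expect_equal(global_align(a, b, "aa")$score,
                 nw_score_oracle(a, b, e$BLOSUM62, open = 10, ext = 1))
  }
})

test_that("duplication thresholds are strict and symmetric", {
  set.seed(4)
  base <- random_bg_protein(100)
  mutate_at <- function(p, k) {
    x <- strsplit(p, "")[[1]]
    i <- seq_len(k)
    x[i] <- vapply(x[i], function(ch)
      setdiff(c("A", "D", "E", "G", "K"), ch)[1], "")
    paste(x, collapse = "")
  }
  to_cds <- function(p) wrkyscan:::.backtranslate_fixed(p)
  mk <- function(id, prot, chrom, pos) gene_record(id, chrom, pos,
                                                   protein = prot,
                                                   cds = to_cds(prot))
  # exactly 70% identity (30/100 mutated): must NOT pass (strict >)
  recs <- list(mk("a", base, "1", 1e6), mk("b", mutate_at(base, 30), "1", 2e6))
  expect_equal(nrow(detect_duplications(recs)), 0L)
  # 90% identity on the same chromosome: one tandem pair
  recs2 <- list(mk("a", base, "4", 1e6), mk("b", mutate_at(base, 10), "4", 2e6))
  d2 <- detect_duplications(recs2)
  expect_equal(nrow(d2), 1L)
  expect_equal(d2$mode, "TANDEM")
  expect_equal(c(d2$id_a, d2$id_b), c("a", "b"))
  # symmetric: order of records is irrelevant
  d2r <- detect_duplications(rev(recs2))
  expect_equal(d2r[, c("id_a", "id_b")], d2[, c("id_a", "id_b")])
  # different chromosomes: segmental
  recs3 <- list(mk("a", base, "1", 1e6), mk("b", mutate_at(base, 10), "3", 2e6))
  expect_equal(detect_duplications(recs3)$mode, "SEGMENTAL")
  # an unplaced member: segmental, flagged
  recs4 <- list(mk("a", base, "1", 1e6),
                mk("b", mutate_at(base, 10), "UNPLACED", NA))
  d4 <- detect_duplications(recs4)
  expect_equal(d4$mode, "SEGMENTAL")
  expect_true(d4$unplaced_member)
})

test_that("cluster chaining reproduces the curated-table calls", {
  loci <- as_loci(load_ljwrky_table())
  cl <- detect_clusters(loci, window_bp = 200000)
  chr1 <- cl[cl$chromosome == "1", ]
  expect_equal(nrow(chr1), 1L)
  expect_equal(chr1$members, "LjWRKY2,LjWRKY3")
  expect_equal(chr1$span_bp, 32212)
  expect_equal(sum(cl$chromosome == "3"), 0L)
  expect_equal(sum(cl$chromosome == "6"), 0L)
  expect_equal(sum(cl$chromosome == "5"), 1L)
})

test_that("chaining links runs of near genes and is order-independent", {
  loci <- data.frame(gene_id = c("g1", "g2", "g3"), chromosome = "2",
                     position = c(0, 150000, 300000))
  cl <- detect_clusters(loci, window_bp = 200000)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_members, 3L)
  # permutation invariance
  cl2 <- detect_clusters(loci[c(3, 1, 2), ], window_bp = 200000)
  expect_identical(cl, cl2)
  # partition: no gene appears twice
  big <- as_loci(load_ljwrky_table())
  cl3 <- detect_clusters(big)
  members <- unlist(strsplit(cl3$members, ","))
  expect_equal(anyDuplicated(members), 0L)
  expect_true(all(members %in% big$gene_id))
  # monotonicity: a larger window never declusters genes
  n_small <- sum(detect_clusters(big, window_bp = 150000)$n_members)
  n_large <- sum(detect_clusters(big, window_bp = 400000)$n_members)
  expect_gte(n_large, n_small)
})

test_that("chromosome distribution matches the curated table", {
  loci <- as_loci(load_ljwrky_table())
  cd <- chromosome_distribution(loci)
  expect_equal(cd$n_genes, c(14L, 8L, 4L, 13L, 5L, 4L, 23L))
  expect_equal(cd$n_genes[cd$chromosome == "UNPLACED"], 23L)
  # per-group breakdown on chromosome 1: 2 group I, 10 group II, 2 group III
  chr1 <- cd[cd$chromosome == "1", ]
  expect_equal(c(chr1$group_I, chr1$group_II, chr1$group_III), c(2L, 10L, 2L))
  # order independence and empty input
  cd2 <- chromosome_distribution(loci[sample(nrow(loci)), ])
  expect_identical(cd, cd2)
  empty <- chromosome_distribution(data.frame(gene_id = character(0),
                                              chromosome = character(0),
                                              position = numeric(0)))
  expect_true(all(empty$n_genes == 0L))
})
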