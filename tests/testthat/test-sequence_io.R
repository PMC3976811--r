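test_that("FASTA reading handles single records, order, and errors", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1", "ACGT"), f)
  expect_equal(read_fasta(f), c(g1 = "ACGT"))

  # 71 synthetic records: count cross-checked by an independent line scan
  ids <- sprintf("p%02d", 1:71)
  seqs <- setNames(vapply(1:71, function(i)
    paste(rep(LETTERS[(i %% 20) + 1], 10), collapse = ""), ""), ids)
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  n_headers <- sum(startsWith(readLines(f2), ">"))
  got <- read_fasta(f2)
  expect_equal(length(got), n_headers)
  expect_equal(names(got), ids)   # input order preserved
  expect_equal(got, seqs)         # round trip

  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate.*a")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty")

  f3 <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r", "acgu"), f3)
  expect_equal(unname(read_fasta(f3, rna_to_dna = TRUE)), "ACGT")
})

test_that("GFF3 coordinate conversion is exact on both strands", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t300\t.\t+\t.\tID=gp",
    "chr1\tx\tmRNA\t1\t300\t.\t+\t.\tID=gp.m;Parent=gp",
    "chr1\tx\tCDS\t1\t100\t.\t+\t0\tID=gp.c1;Parent=gp.m",
    "chr1\tx\tCDS\t201\t300\t.\t+\t1\tID=gp.c2;Parent=gp.m",
    "chr2\tx\tgene\t1001\t1300\t.\t-\t.\tID=gm",
    "chr2\tx\tmRNA\t1001\t1300\t.\t-\t.\tID=gm.m;Parent=gm",
    "chr2\tx\tCDS\t1001\t1100\t.\t-\t0\tID=gm.c1;Parent=gm.m",
    "chr2\tx\tCDS\t1201\t1300\t.\t-\t1\tID=gm.c2;Parent=gm.m"), g)
  recs <- read_gff3(g)
  plus <- recs[[which(vapply(recs, `[[`, "", "gene_id") == "gp")]]
  expect_equal(unname(plus$exons[, 1]), c(0L, 200L))
  expect_equal(unname(plus$exons[, 2]), c(100L, 300L))
  expect_equal(coding_length(plus), 200L)
  # minus strand: transcript frame runs from the genomic end, so the
  # genomically-last CDS segment comes first
  minus <- recs[[which(vapply(recs, `[[`, "", "gene_id") == "gm")]]
  expect_equal(unname(minus$exons[, 1]), c(0L, 200L))
  expect_equal(unname(minus$exons[, 2]), c(100L, 300L))
  expect_equal(minus$strand, "-")
})

test_that("GFF3 rejects orphan CDS features", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tx\tgene\t1\t100\t.\t+\t.\tID=g1",
    "chr1\tx\tCDS\t1\t100\t.\t+\t0\tID=c1"), g)
  expect_error(read_gff3(g), "CDS")
})

test_that("synthetic genome round-trips through GFF3 + FASTA", {
  d <- withr::local_tempdir()
  cfg <- synth_config(n_per_class = c(I = 2, IIa = 2, IIb = 2, IIc = 2,
                                      IId = 1, IIe = 1, IIx = 1, III = 2),
                      n_defective = 1,
                      pseudogenes = c(I = 1, IIa = 1),
                      chromosome_genes = c(`1` = 4, `2` = 3, `3` = 2,
                                           `4` = 2, `5` = 1, `6` = 1),
                      seed = 31)
  gen <- generate_genome(cfg, out_dir = d)
  gseqs <- read_fasta(file.path(d, "genes_genomic.fa"))
  back <- read_gff3(file.path(d, "genes.gff3"), gene_seqs = gseqs)
  back_ids <- vapply(back, `[[`, "", "gene_id")
  for (rec in gen$records) {
    b <- back[[which(back_ids == rec$gene_id)]]
    expect_identical(b$exons, rec$exons)
    expect_identical(b$cds, rec$cds)
    expect_identical(b$protein, rec$protein)
    expect_identical(b$strand, rec$strand)
  }
})

test_that("packaged gene table matches the published family architecture", {
  tab <- load_ljwrky_table()
  expect_equal(nrow(tab), 71L)
  expect_equal(sum(tab$group == "nd"), 10L)
  expect_equal(sum(tab$pseudogene), 9L)
  w34 <- tab[tab$gene_name == "LjWRKY34", ]
  expect_equal(w34$group, "IIc")
  expect_equal(w34$chromosome, "4")
  expect_equal(w34$location, 32856509)
  w1 <- tab[tab$gene_name == "LjWRKY1", ]
  expect_equal(c(w1$group, w1$chromosome), c("I", "1"))
  expect_equal(w1$location, 58226335)
  expect_false(w1$pseudogene)
  w37 <- tab[tab$gene_name == "LjWRKY37", ]
  expect_true(w37$pseudogene)
  expect_equal(c(w37$group, w37$chromosome), c("IIx", "4"))
  expect_equal(w37$location, 7529554)
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  tr <- read_newick(text = "(A:1,B:1);")
  expect_equal(sort(tr$tip.label), c("A", "B"))
  expect_equal(tr$edge.length, c(1, 1))
  tr2 <- read_newick(text = "((A,B)95,C);")
  expect_equal(tr2$node.label[2], "95")
  expect_error(read_newick(text = "((A,B);"), "parse")

  set.seed(9)
  big <- ape::rtree(20)
  txt1 <- write_newick(big)
  txt2 <- write_newick(read_newick(text = txt1))
  expect_identical(txt1, txt2)   # write -> read -> write idempotent
})
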