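c2h2_dom <- paste0("WRKYGQK", strrep("A", 2), "C", strrep("A", 4), "C",
                   strrep("A", 22), "H", "A", "H")
c2hc_dom <- paste0("WRKYGQK", strrep("A", 2), "C", strrep("A", 6), "C",
                   strrep("A", 26), "H", "A", "C")

test_that("scanner detects the heptapeptide + zinc finger grammar", {
  d <- scan_wrky_domains(c2h2_dom)
  expect_length(d, 1L)
  expect_true(d[[1]]$complete)
  expect_equal(d[[1]]$zf_class, "C2H2")
  expect_equal(d[[1]]$hepta_start, 0L)
  expect_equal(d[[1]]$heptapeptide, "WRKYGQK")
  # conserved-residue coordinates (0-based): C at 9 and 14, H at 37, 39
  expect_equal(d[[1]]$zf_coords, c(9L, 14L, 37L, 39L))

  d2 <- scan_wrky_domains(c2hc_dom)
  expect_equal(d2[[1]]$zf_class, "C2HC")
  expect_true(d2[[1]]$complete)

  # named heptapeptide variant (the In/IIx WKKY replacement)
  d3 <- scan_wrky_domains(sub("WRKY", "WKKY", c2h2_dom))
  expect_length(d3, 1L)
  expect_true(d3[[1]]$complete)

  expect_equal(scan_wrky_domains("AAAA"), list())
  expect_error(scan_wrky_domains(""), "non-empty")
})

test_that("scan is invariant to trailing sequence and X never matches", {
  set.seed(21)
  tail_seq <- random_bg_protein(80)
  d1 <- scan_wrky_domains(c2h2_dom)
  d2 <- scan_wrky_domains(paste0(c2h2_dom, tail_seq))
  expect_equal(d1[[1]]$zf_coords, d2[[1]]$zf_coords)
  expect_equal(length(d1), length(d2))
  # X at a conserved position breaks the motif
  broken <- sub("^W", "X", c2h2_dom)
  expect_equal(scan_wrky_domains(broken), list())
})

test_that("packaged templates all conform to their class grammar", {
  tpl <- wrky_domain_templates()
  for (nm in names(tpl)) {
    d <- scan_wrky_domains(tpl[[nm]])
    expect_length(d, 1L)
    expect_true(d[[1]]$complete)
    expect_equal(d[[1]]$zf_class, if (nm == "III") "C2HC" else "C2H2",
                 info = nm)
    expect_gte(d[[1]]$span, 40L)
  }
})

test_that("group classification follows domain count and finger class", {
  expect_equal(classify_group(scan_wrky_domains(c2h2_dom))$group, "II")
  expect_equal(classify_group(scan_wrky_domains(c2hc_dom))$group, "III")
  # two single-domain proteins joined by a long spacer -> group I
  set.seed(3)
  two_dom <- paste0(c2h2_dom, random_bg_protein(100), c2h2_dom)
  cl <- classify_group(scan_wrky_domains(two_dom))
  expect_equal(cl$group, "I")
  expect_equal(cl$domains[[1]]$terminal, "N")
  expect_equal(cl$domains[[2]]$terminal, "C")
  # two heptapeptides, second finger missing: still group I
  trunc2 <- paste0(c2h2_dom, random_bg_protein(100), "WRKYGQK",
                   random_bg_protein(5))
  expect_equal(classify_group(scan_wrky_domains(trunc2))$group, "I")
  # one heptapeptide without a finger -> unclassified
  orphan <- paste0("WRKYGQK", random_bg_protein(10))
  expect_equal(classify_group(scan_wrky_domains(orphan))$group, "UNCLASSIFIED")
  expect_equal(classify_group(list())$group, "UNCLASSIFIED")
})

test_that("subgroup assignment is nearest-reference with deterministic ties", {
  refs <- wrky_reference_domains()
  hit <- assign_subgroup(refs[["IIa"]])
  expect_equal(hit$subgroup, "IIa")
  expect_equal(hit$distance, 0)
  # equidistant query takes the earlier reference
  tie <- assign_subgroup("QQQQQ", references = c(r1 = "PPPPP", r2 = "LLLLL"),
                         threshold = 1)
  expect_equal(tie$subgroup, "r1")
  # nothing close enough -> unplaced
  far <- assign_subgroup("QQQQQQQQQQ", references = c(r1 = "PPPPPPPPPP"),
                         threshold = 0.6)
  expect_equal(far$subgroup, "unplaced")
  expect_error(assign_subgroup("AAA", references = character(0)), "empty")
})

test_that("planted subgroups are recovered from the synthetic genome", {
  gen <- generate_genome(synth_config(seed = 77))
  cls <- classify_records(gen$proteins, gen$cds)
  m <- merge(cls[cls$group == "II", ], gen$truth, by = "gene_id")
  expect_gte(mean(m$subgroup.x == m$subgroup.y), 0.9)
  mg <- merge(cls[cls$kept, ], gen$truth, by = "gene_id")
  expect_gte(mean(mg$group.x == mg$group.y), 0.9)  # diagonal-dominant
})

test_that("candidate filter drops short/incomplete domains", {
  set.seed(8)
  prots <- c(
    good = paste0(random_bg_protein(10), c2h2_dom, random_bg_protein(10)),
    short = paste0(random_bg_protein(10), "WRKYGQKAC",
                   random_bg_protein(30)),  # heptapeptide, no finger
    none = random_bg_protein(60))
  cls <- classify_records(prots)
  flt <- filter_candidates(cls)
  expect_equal(flt$kept$gene_id, "good")
  expect_setequal(flt$excluded$gene_id, c("short", "none"))
})

test_that("pseudogene flags read premature stops and frameshifts from the CDS", {
  f <- detect_pseudogene("ATGTAAGGGTGA")
  expect_true(f$premature_stop)   # TAA at codon 2
  expect_false(f$frameshift)
  f2 <- detect_pseudogene("ATGGGGTGA")
  expect_false(f2$premature_stop)
  expect_false(f2$frameshift)
  f3 <- detect_pseudogene("ATGGGGGTGA")  # 10 nt
  expect_true(f3$frameshift)
  expect_error(detect_pseudogene("AT"), "codon")
})

test_that("zinc finger spacing report is diagnostic only", {
  cls <- classify_records(c(g1 = c2h2_dom, g2 = c2hc_dom))
  sp <- zinc_finger_spacing(cls)
  expect_equal(sp$spacing[sp$gene_id == "g1"], "CX4CX22HX1H")
  expect_equal(sp$spacing[sp$gene_id == "g2"], "CX6CX26HX1C")
})
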