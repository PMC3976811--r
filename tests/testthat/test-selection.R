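# Site-model machinery. The heavier ML fits are computed once here and
# shared across assertions.

test_that("GY94 generator has the stated structure", {
  pi <- rep(1 / 61, 61)
  # kappa = omega = 1, uniform frequencies: all single-step rates equal
  Q1 <- gy94_Q(1, 1, pi, scale = FALSE)
  off <- Q1[row(Q1) != col(Q1)]
  expect_setequal(round(unique(off), 12), round(c(0, 1 / 61), 12))
  # multi-nucleotide changes are forbidden
  expect_equal(Q1["AAA", "ACC"], 0)
  expect_equal(Q1["AAA", "TTT"], 0)
  # rows sum to zero; scaled mean rate is 1
  Q <- gy94_Q(2.5, 0.4, pi)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  # detailed balance (reversibility by construction)
  set.seed(30)
  pi2 <- runif(61); pi2 <- pi2 / sum(pi2)
  Q2 <- gy94_Q(3, 0.7, pi2)
  flux <- pi2 * Q2
  expect_lt(max(abs(flux - t(flux))), 1e-14)
  expect_error(gy94_Q(2, 0.5, rep(1, 61)), "simplex")
  expect_error(gy94_Q(-1, 0.5), "kappa")
})

test_that("pruning likelihood equals the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  pi <- rep(1 / 61, 61)
  tr <- ape::read.tree(text = "(A:0.3,B:0.2,C:0.4);")
  m <- matrix(c("ATG", "AAA", "CCT",
                "ATA", "AAA", "CCT",
                "ATG", "AAG", "CCA"), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), NULL))
  aln <- codon_alignment(m)
  ll <- log_likelihood(aln, tr, kappa = 2, omegas = 0.5, codon_freqs = pi)
  oracle <- star3_loglik_oracle(m, c(0.3, 0.2, 0.4), 2, 0.5, pi)
  expect_equal(ll$lnL, oracle, tolerance = 1e-8)
  # two-taxon, one-codon case against the same oracle machinery
  tr2 <- ape::read.tree(text = "(A:0.25,B:0.35);")
  aln2 <- codon_alignment(matrix(c("ATG", "ATA"), 2,
                                 dimnames = list(c("A", "B"), NULL)))
  Q <- gy94_Q(2, 0.5, pi)
  P <- as.matrix(Matrix::expm(Q * 0.6))
  i <- match("ATG", sense_codons()); j <- match("ATA", sense_codons())
  expect_equal(log_likelihood(aln2, tr2, 2, 0.5, codon_freqs = pi)$lnL,
               log(pi[i] * P[i, j]), tolerance = 1e-8)
})

test_that("likelihood respects the pulley principle and degenerate limits", {
  pi <- rep(1 / 61, 61)
  m <- matrix(c("ATG", "AAA", "ATA", "AAA", "ATG", "AAG", "TTA", "AAG"),
              nrow = 4, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), NULL))
  aln <- codon_alignment(m)
  t1 <- ape::read.tree(text = "((A:0.1,B:0.2):0.25,C:0.3,D:0.1);")
  t2 <- ape::read.tree(text = "((C:0.3,D:0.1):0.25,A:0.1,B:0.2);")
  l1 <- log_likelihood(aln, t1, 2, 0.5, codon_freqs = pi)$lnL
  l2 <- log_likelihood(aln, t2, 2, 0.5, codon_freqs = pi)$lnL
  expect_equal(l1, l2, tolerance = 1e-10)
  # zero-length star of identical sequences: lnL = sum log pi(codon)
  tr0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  m0 <- matrix(rep(c("ATG", "AAA"), each = 3), nrow = 3,
               dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(log_likelihood(codon_alignment(m0), tr0, 2, 0.5,
                              codon_freqs = pi)$lnL,
               2 * log(1 / 61), tolerance = 1e-10)
  # taxon mismatch is an error
  expect_error(log_likelihood(aln, tr0, 2, 0.5, codon_freqs = pi), "taxa")
})

test_that("back-translation expands residues to codons and validates", {
  aln <- backtranslate(c(t1 = "M-K", t2 = "MQK"),
                       c(t1 = "ATGAAA", t2 = "ATGCAAAAA"))
  expect_equal(unname(aln$codons["t1", ]), c("ATG", "---", "AAA"))
  expect_equal(unname(aln$codons["t2", ]), c("ATG", "CAA", "AAA"))
  expect_error(backtranslate(c(t1 = "MK"), c(t1 = "ATGCCC")),
               "does not translate")
  # terminal stop tolerated
  aln2 <- backtranslate(c(t1 = "MK"), c(t1 = "ATGAAATAA"))
  expect_equal(ncol(aln2$codons), 2L)
  # round trip: translate(backtranslate(x)) == x over random alignments
  set.seed(44)
  cods <- setdiff(sense_codons(), c("TGG"))
  for (rep in 1:5) {
    n <- 8
    m <- matrix(sample(cods, 3 * n, TRUE), nrow = 3,
                dimnames = list(c("a", "b", "c"), NULL))
    m[sample(length(m), 4)] <- "---"
    prot <- translate_alignment(codon_alignment(m))
    cds <- apply(m, 1, function(r) paste(r[r != "---"], collapse = ""))
    back <- backtranslate(prot, cds)
    expect_identical(back$codons, m)
  }
  expect_error(codon_alignment(matrix("TAA", 1, dimnames = list("a", NULL))),
               "stop codon")
})

test_that("simulation obeys forced and limiting regimes", {
  tr <- ape::read.tree(text = "(A:0.4,B:0.3,C:0.5);")
  # omega = 0: no nonsynonymous differences anywhere
  sim <- simulate_codon_alignment(tr, kappa = 2, omegas = 0, n_codons = 150,
                                  seed = 3)
  prot <- translate_alignment(sim$aln)
  expect_equal(length(unique(prot)), 1L)
  # t -> 0: all sequences identical
  tr0 <- tr; tr0$edge.length <- rep(1e-9, 3)
  sim0 <- simulate_codon_alignment(tr0, 2, 0.5, n_codons = 100, seed = 4)
  expect_true(all(sim0$aln$codons[1, ] == sim0$aln$codons[2, ]))
  # fixed seed: identical output
  simA <- simulate_codon_alignment(tr, 2, 0.5, n_codons = 50, seed = 9)
  simB <- simulate_codon_alignment(tr, 2, 0.5, n_codons = 50, seed = 9)
  expect_identical(simA$aln$codons, simB$aln$codons)
})

test_that("pairwise substitutions match the exp(Qt) expectation", {
  skip_if_not_installed("Matrix")
  pi <- rep(1 / 61, 61)
  tr <- ape::read.tree(text = "(A:0.25,B:0.25);")
  sim <- simulate_codon_alignment(tr, kappa = 2, omegas = 0.5,
                                  n_codons = 1000, codon_freqs = pi, seed = 8)
  p_obs <- mean(sim$aln$codons["A", ] != sim$aln$codons["B", ])
  P <- as.matrix(Matrix::expm(gy94_Q(2, 0.5, pi) * 0.5))
  p_exp <- 1 - sum(pi * diag(P))
  expect_lt(abs(p_obs - p_exp), 4 * sqrt(p_exp * (1 - p_exp) / 1000))
})

# ---- shared ML fits (one mixed-selection dataset) ---------------------------

sim_tree <- local({
  set.seed(12)
  tr <- ape::rtree(6, rooted = FALSE)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.5)
  tr
})
sim_mix <- simulate_codon_alignment(sim_tree, kappa = 2,
                                    omegas = c(0.2, 4), weights = c(0.9, 0.1),
                                    n_codons = 250, seed = 7)
topo <- sim_tree; topo$edge.length <- NULL
fit_m0 <- fit_site_model(sim_mix$aln, topo, "M0")
fit_m3 <- fit_site_model(sim_mix$aln, topo, "M3", m0 = fit_m0)
fit_m7 <- fit_site_model(sim_mix$aln, topo, "M7", m0 = fit_m0)
fit_m8 <- fit_site_model(sim_mix$aln, topo, "M8", m0 = fit_m0, m7 = fit_m7)

test_that("nested site models never lose likelihood", {
  expect_gte(fit_m3$lnL, fit_m0$lnL)
  expect_gte(fit_m8$lnL, fit_m7$lnL)
  expect_true(fit_m0$converged)
  # mixture weights are a simplex, omegas non-negative, lnL finite
  for (f in list(fit_m3, fit_m7, fit_m8)) {
    expect_equal(sum(f$weights), 1, tolerance = 1e-9)
    expect_true(all(f$omegas >= 0))
    expect_true(is.finite(f$lnL))
  }
})

test_that("LRTs detect the planted selection heterogeneity", {
  l1 <- lrt(fit_m0, fit_m3)
  expect_equal(l1$df, 4L)
  expect_lt(l1$p_value, 0.01)
  l2 <- lrt(fit_m7, fit_m8)
  expect_equal(l2$df, 2L)
  expect_lt(l2$p_value, 0.01)
  expect_error(lrt(fit_m0, fit_m8), "nested pair")
  expect_equal(lrt(10, 10, df = 4)$p_value, 1)      # stat 0 -> p = 1
  expect_equal(lrt(10, 9.9999, df = 4)$stat, 0)     # tolerance clamp
})

test_that("NEB posteriors recover planted positive sites", {
  post <- site_posteriors(fit_m8)
  expect_lt(max(abs(colSums(post) - 1)), 1e-9)
  pos <- positive_sites(fit_m8)
  planted <- which(sim_mix$site_class == 2)
  neutral <- which(sim_mix$site_class == 1)
  expect_gte(sum(pos$site %in% planted), length(planted) / 2)
  expect_lte(sum(pos$site %in% neutral), 0.05 * length(neutral))
})

test_that("report table carries chi-squared stars at the right thresholds", {
  rep1 <- selection_report(list(d1 = list(M0 = fit_m0, M3 = fit_m3,
                                          M7 = fit_m7, M8 = fit_m8)))
  expect_equal(nrow(rep1), 1L)
  expect_equal(rep1$stars_M3_vs_M0, "**")
  expect_lt(rep1$omega_M0, 1)
  # chi-squared df = 4 critical value at 0.01 is 13.2767 (qchisq oracle)
  expect_equal(qchisq(0.99, 4), 13.2767, tolerance = 1e-4)
  expect_equal(selection_report(list()), selection_report(list()))
  expect_equal(nrow(selection_report(list())), 0L)
})

test_that("M0 on (nearly) identical sequences flags unidentifiable omega", {
  m <- matrix(rep(c("ATG", "AAA", "CCT", "GGA"), each = 3), nrow = 3,
              dimnames = list(c("a", "b", "c"), NULL))
  aln <- codon_alignment(m)
  tr <- ape::read.tree(text = "(a:0.1,b:0.1,c:0.1);")
  f <- fit_site_model(aln, tr, "M0", n_starts = 1, maxit = 60)
  expect_lt(sum(f$tree$edge.length), 1e-3)
  expect_false(is.na(f$note))
})
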