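test_that("back-translation maps protein columns to codons and gaps to ---", {
  aln <- tlp_seqs(c(s1 = "MKV", s2 = "M-V"), alphabet = "protein",
                  aligned = TRUE)
  cds <- tlp_seqs(c(s1 = "ATGAAAGTT", s2 = "ATGGTG"), alphabet = "dna")
  ca <- backtranslate(aln, cds)
  expect_equal(unname(ca$codon_columns["s1", ]), c("ATG", "AAA", "GTT"))
  expect_equal(unname(ca$codon_columns["s2", ]), c("ATG", "---", "GTG"))

  # trailing stop codons are stripped
  cds2 <- tlp_seqs(c(s1 = "ATGAAAGTTTAA", s2 = "ATGGTGTGA"), alphabet = "dna")
  ca2 <- backtranslate(aln, cds2)
  expect_equal(degap_codons(ca2, "s1"), "ATGAAAGTT")

  # internal stop and translation mismatch are named errors
  bad <- tlp_seqs(c(s1 = "ATGTAAGTT", s2 = "ATGGTG"), alphabet = "dna")
  expect_error(backtranslate(aln, bad), "stop codon")
  short <- tlp_seqs(c(s1 = "ATGAAA", s2 = "ATGGTG"), alphabet = "dna")
  expect_error(backtranslate(aln, short), "length")
  mism <- tlp_seqs(c(s1 = "ATGCCCGTT", s2 = "ATGGTG"), alphabet = "dna")
  expect_error(backtranslate(aln, mism), "mismatch at codon 2")
})

test_that("back-translation round-trips simulated CDS pairs", {
  set.seed(61)
  for (i in 1:40) {
    cds <- random_cds(sample(20:60, 1))
    ev <- evolve_pair(cds, 0.2, 0.4, seed = i)
    prots <- c(a = translate_cds(ev$cds_a), b = translate_cds(ev$cds_b))
    aln <- tlp_seqs(prots, alphabet = "protein", aligned = TRUE)
    ca <- backtranslate(aln, tlp_seqs(c(a = ev$cds_a, b = ev$cds_b),
                                      alphabet = "dna"))
    expect_equal(degap_codons(ca, "a"), ev$cds_a)
    expect_equal(degap_codons(ca, "b"), ev$cds_b)
  }
})

test_that("NG86 handles identical, synonymous-only and saturated inputs", {
  r0 <- ng86_kaks(cds_a = "ATGGGAACC", cds_b = "ATGGGAACC")
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(is.na(r0$omega))

  # one third-position change at a four-fold degenerate site: pure Ks
  r1 <- ng86_kaks(cds_a = "GGAGGTCCA", cds_b = "GGAGGCCCA")
  expect_equal(r1$ka, 0)
  expect_gt(r1$ks, 0)

  # too few synonymous sites for the observed change: saturation flag
  r2 <- ng86_kaks(cds_a = "ATGAAA", cds_b = "ATGAAG")
  expect_true(r2$saturated_ks)
  expect_true(is.na(r2$ks))

  expect_error(ng86_kaks(cds_a = "---", cds_b = "---"), "usable")
})

test_that("NG86 is symmetric and monotone in appended differences", {
  set.seed(62)
  for (i in 1:10) {
    a <- random_cds(40); b <- random_cds(40)
    ra <- ng86_kaks(cds_a = a, cds_b = b)
    rb <- ng86_kaks(cds_a = b, cds_b = a)
    expect_identical(ra$ka, rb$ka)
    expect_identical(ra$ks, rb$ks)
  }
  # appending an extra differing codon can only increase ka and ks
  base_a <- "ATGGCTAAAGGAACCTTG"; base_b <- "ATGGCCGAAGGAACCTTG"
  r <- ng86_kaks(cds_a = base_a, cds_b = base_b)
  r_syn <- ng86_kaks(cds_a = paste0(base_a, "GGT"),
                     cds_b = paste0(base_b, "GGC"))
  r_non <- ng86_kaks(cds_a = paste0(base_a, "AAA"),
                     cds_b = paste0(base_b, "GAA"))
  expect_gte(r_syn$ks, r$ks)
  expect_gte(r_non$ka, r$ka)
})

test_that("NG86 equals the brute-force pathway oracle on random pairs", {
  set.seed(63)
  for (i in 1:10) {
    cds <- random_cds(40)
    ev <- evolve_pair(cds, 0.5, 0.6, seed = 100 + i)
    mine <- ng86_kaks(cds_a = ev$cds_a, cds_b = ev$cds_b)
    orac <- oracle_ng86(ev$cds_a, ev$cds_b)
    expect_equal(mine$ka, orac$ka, tolerance = 1e-9)
    expect_equal(mine$ks, orac$ks, tolerance = 1e-9)
    expect_equal(mine$usable_codons, orac$usable)
  }
})

test_that("divergence times follow T = Ks/2r at the grass clock rate", {
  expect_equal(divergence_time(1.0810)$t_mya_1dp, 83.2)
  expect_equal(divergence_time(0)$t_mya_1dp, 0)
  expect_equal(divergence_time(1.7816)$t_mya_1dp, 137.0)
  expect_error(divergence_time(-0.1), "negative")
  expect_error(divergence_time(NA_real_), "undefined")
})

test_that("selection calls split at omega = 1", {
  expect_equal(classify_selection(0.1020), "purifying")
  expect_equal(classify_selection(1.0), "neutral")
  expect_equal(classify_selection(1.7), "positive")
})

test_that("the relative-rate test reproduces published count arithmetic", {
  # construct an alignment with known column classes: na=47, nb=42
  nt <- 403
  a <- c(rep("A", nt), rep("C", 47), rep("A", 42))
  b <- c(rep("A", nt), rep("A", 47), rep("C", 42))
  o <- c(rep("A", nt), rep("A", 47), rep("A", 42))
  tj <- tajima_relative_rate(paste(a, collapse = ""), paste(b, collapse = ""),
                             paste(o, collapse = ""))
  expect_equal(c(tj$nt, tj$na, tj$nb), c(403, 47, 42))
  expect_equal(round(tj$chi2, 2), 0.28)
  expect_equal(round(tj$p, 5), 0.59611)

  # equal unique counts: chi2 = 0, p = 1
  b2 <- c(rep("A", nt), rep("G", 47), rep("C", 42))
  a2 <- c(rep("A", nt), rep("C", 47), rep("G", 42))
  tj2 <- tajima_relative_rate(paste(a2[1:89], collapse = ""),
                              paste(b2[1:89], collapse = ""),
                              paste(rep("A", 89), collapse = ""))
  expect_equal(tj2$na, tj2$nb)
  expect_equal(tj2$chi2, 0)
  expect_equal(tj2$p, 1)

  expect_error(tajima_relative_rate("ACGT", "ACG", "ACGT"), "equal length")
})

test_that("the relative-rate test is antisymmetric and skips ambiguity", {
  set.seed(64)
  a <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  b <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  o <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  t1 <- tajima_relative_rate(a, b, o)
  t2 <- tajima_relative_rate(b, a, o)
  expect_equal(t1$na, t2$nb)
  expect_equal(t1$nb, t2$na)
  expect_equal(t1$chi2, t2$chi2)
  expect_equal(t1$p, t2$p)

  gappy_a <- paste0("-N", substr(a, 3, 300))
  t3 <- tajima_relative_rate(gappy_a, b, o)
  expect_equal(t3$sites_used, 298)
})

test_that("the chi-square survival kernel matches reference values", {
  expect_equal(chi2_sf(0), 1)
  expect_equal(round(chi2_sf(2.4694), 5), 0.11608)
  expect_equal(round(chi2_sf(3.841459), 4), 0.05)
  expect_error(chi2_sf(-1), "non-negative")
})
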