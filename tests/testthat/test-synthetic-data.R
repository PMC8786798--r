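test_that("generators are deterministic functions of the seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  unlink(c(d1, d2), recursive = TRUE)
  spec <- family_spec(n_homeolog_groups = 3, seed = 91)
  generate_family(spec, dir = d1)
  generate_family(spec, dir = d2)
  for (f in c("proteins.fasta", "cds.fasta", "genes.gff3", "domains.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  p1 <- generate_promoters("g1", read_element_table(),
                           data.frame(gene_id = "g1", element_name = "GATABOX",
                                      count = 3), seed = 5)
  p2 <- generate_promoters("g1", read_element_table(),
                           data.frame(gene_id = "g1", element_name = "GATABOX",
                                      count = 3), seed = 5)
  expect_identical(unclass(p1$promoters), unclass(p2$promoters))
  e1 <- generate_expression(paste0("g", 1:8), noise_sd = 0.3, seed = 6)
  e2 <- generate_expression(paste0("g", 1:8), noise_sd = 0.3, seed = 6)
  expect_identical(e1$counts, e2$counts)
})

test_that("generated CDS translate cleanly and GFF3 passes the reader", {
  dir <- file.path(tempdir(), "roundtrip")
  unlink(dir, recursive = TRUE)
  fam <- generate_family(family_spec(n_homeolog_groups = 4, seed = 92),
                         dir = dir)
  prot <- read_fasta(file.path(dir, "proteins.fasta"), "protein")
  cds <- read_fasta(file.path(dir, "cds.fasta"), "dna")
  expect_setequal(names(prot), names(cds))
  for (id in names(cds)) {
    expect_identical(translate_cds(unclass(cds)[[id]]), unclass(prot)[[id]])
  }
  models <- read_gff3(file.path(dir, "genes.gff3"))
  expect_setequal(names(models), names(prot))
  # CDS length in the annotation equals the FASTA CDS length
  for (id in names(models)) {
    expect_equal(sum(models[[id]]$cds[, 2] - models[[id]]$cds[, 1] + 1),
                 nchar(unclass(cds)[[id]]))
  }
})

test_that("a full plant rate yields 100% screen acceptance", {
  fam <- generate_family(family_spec(n_homeolog_groups = 4,
                                     motif_plant_rate = 1, seed = 93))
  scr <- screen_candidates(fam$proteins)
  expect_length(scr$accepted, length(fam$proteins))
  # and the planted motif coordinates are among the reported hits
  tg <- fam$truth$genes
  for (i in seq_len(nrow(tg))) {
    h <- scr$hits[scr$hits$id == tg$gene_id[i], ]
    expect_true(any(h$start == tg$motif_start[i] & h$end == tg$motif_end[i]))
  }
})

test_that("evolve_pair respects its targets at the boundaries", {
  cds <- random_cds(100)
  ev0 <- evolve_pair(cds, 0.5, 0, seed = 94)
  expect_identical(ev0$cds_a, cds)
  expect_identical(ev0$cds_b, cds)
  expect_error(evolve_pair(cds, 0.5, 2.5, seed = 94), "target_ks")

  ev <- evolve_pair(cds, 0.1, 0.6, seed = 95)
  expect_equal(nchar(ev$cds_a), nchar(cds))
  expect_match(translate_cds(ev$cds_a), "^[^*]+$")  # no internal stops
  expect_true(all(ev$realized$syn_substitutions >= 0))

  # protected codons never change their amino acid
  prot_idx <- 1:20
  evp <- evolve_pair(cds, 1.0, 0.8, seed = 96, protect_codons = prot_idx)
  aa_anc <- strsplit(translate_cds(cds), "")[[1]]
  for (s in c(evp$cds_a, evp$cds_b)) {
    aa <- strsplit(translate_cds(s), "")[[1]]
    expect_equal(aa[prot_idx], aa_anc[prot_idx])
  }
})

test_that("planted promoter elements are recovered at their positions", {
  elements <- read_element_table()
  plan <- data.frame(gene_id = rep(c("gA", "gB"), each = 2),
                     element_name = c("GATABOX", "DRE2COREZMRAB17",
                                      "ARFAT", "ERELEE4"),
                     count = c(3, 1, 2, 1), stringsAsFactors = FALSE)
  pr <- generate_promoters(c("gA", "gB"), elements, plan, seed = 97)
  expect_equal(nrow(pr$truth), 7)
  for (g in c("gA", "gB")) {
    hits <- scan_elements(pr$promoters[g], elements)
    planted <- pr$truth[pr$truth$gene_id == g, ]
    for (i in seq_len(nrow(planted))) {
      expect_true(any(hits$element_name == planted$element_name[i] &
                        hits$strand == planted$strand[i] &
                        hits$start == planted$start[i] &
                        hits$end == planted$end[i]))
    }
  }
  # >= 3 GATA boxes on gA (planting may create extra chance hits)
  ga_hits <- scan_elements(pr$promoters["gA"], elements)
  expect_gte(sum(ga_hits$element_name == "GATABOX"), 3)
  # empty plan: background only, still 1.5 kb
  bg <- generate_promoters("gC", elements, NULL, seed = 98)
  expect_equal(nchar(unclass(bg$promoters)[[1]]), 1500)
  expect_equal(nrow(bg$truth), 0)
})

test_that("zero-noise expression reproduces archetype folds exactly", {
  expr <- generate_expression(paste0("g", 1:8), noise_sd = 0, seed = 99)
  m <- fpkm(expr$counts, expr$lengths, expr$totals)
  arch <- expression_archetypes()
  for (i in seq_len(nrow(expr$truth))) {
    mu <- arch[[expr$truth$archetype[i]]]
    expect_equal(unname(log2(m[expr$truth$gene_id[i], names(mu)])),
                 unname(mu), tolerance = 1e-9)
  }
})

test_that("the qPCR generator plants exact fold changes at zero noise", {
  plan <- data.frame(gene_id = "g1", condition = "t6h", fold = 2.5)
  qp <- generate_qpcr("g1", plan, noise_sd = 0, seed = 100)
  fc <- ddct_fold(qp$qpcr, "control")
  expect_equal(fc$fold[fc$condition == "t6h"], 2.5, tolerance = 1e-12)
  expect_equal(fc$fold[fc$condition == "t12h"], 1, tolerance = 1e-12)
})
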