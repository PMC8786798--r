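test_that("percent identity is column-exact and symmetric", {
  expect_equal(pairwise_identity("MKVLAT", "MKVLAT"), 100)
  expect_equal(pairwise_identity("AAAA", "AATA"), 75)
  set.seed(31)
  for (i in 1:10) {
    a <- random_protein(sample(20:50, 1))
    b <- random_protein(sample(20:50, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  }
})

test_that("alignment scores agree with an independent affine-gap DP", {
  set.seed(32)
  for (i in 1:12) {
    a <- random_protein(sample(10:45, 1))
    b <- random_protein(sample(10:45, 1))
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
      type = "global")
    expect_equal(Biostrings::score(aln), oracle_nw_score(a, b))
  }
})

test_that("duplicate detection enforces mutual best hits and disjoint pairs", {
  edges <- data.frame(
    gene_a = c("a", "a", "b"), gene_b = c("b", "c", "c"),
    identity_pct = c(95, 85, 70), aligned = TRUE,
    best_hit_a_to_b = c(TRUE, FALSE, FALSE),
    best_hit_b_to_a = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
  d <- find_duplicates(edges)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$gene_a, d$gene_b), c("a", "b"))

  low <- transform(edges, identity_pct = identity_pct - 30)
  expect_equal(nrow(find_duplicates(low)), 0)

  # invariance under row permutation
  set.seed(33)
  fam <- generate_family(family_spec(n_homeolog_groups = 3, seed = 33))
  e <- similarity_edges(fam$proteins)
  d1 <- find_duplicates(e)
  d2 <- find_duplicates(e[sample(nrow(e)), ])
  expect_equal(d1, d2)
})

test_that("tandem/segmental classification follows distance and chromosome", {
  mk <- function(id, chrom, start, len = 1000) {
    gene_model(id, chrom, "+", cbind(start, start + len),
               cds = cbind(start, start + len, 0))
  }
  models <- structure(list(a = mk("a", "3A", 100000), b = mk("b", "3A", 151000),
                           c = mk("c", "5D", 100000),
                           d = mk("d", "3A", 2100000)),
                      class = "gene_model_list")
  expect_equal(classify_duplication("a", "b", models)$kind, "tandem")
  expect_equal(classify_duplication("a", "c", models)$kind, "segmental")
  # distant same-chromosome pair with many intervening genes -> segmental
  many <- models
  for (i in 1:40) {
    id <- paste0("x", i)
    many[[id]] <- mk(id, "3A", 110000 + i * 45000)
  }
  class(many) <- "gene_model_list"
  cd <- classify_duplication("a", "d", many)
  expect_equal(cd$kind, "segmental")
  expect_gt(cd$intervening_genes, 5)
  # unplaced scaffold: kind left unset, flagged
  models$e <- mk("e", "scaffold_12", 5000)
  class(models) <- "gene_model_list"
  un <- classify_duplication("a", "e", models)
  expect_true(is.na(un$kind))
  expect_true(un$flagged)
  # every emitted tandem pair sits on one chromosome
  expect_equal(cd$chrom_a, cd$chrom_b)
})

test_that("homeolog grouping respects identity, chromosome number and subgenome", {
  mk <- function(id, chrom) {
    gene_model(id, chrom, "+", cbind(1000, 2000), cds = cbind(1000, 2000, 0),
               subgenome = sub("^[0-9]+", "", chrom))
  }
  models <- structure(list(gA = mk("gA", "5A"), gB = mk("gB", "5B"),
                           gD = mk("gD", "5D"), hA = mk("hA", "2A"),
                           hB = mk("hB", "2B"), hD = mk("hD", "2D")),
                      class = "gene_model_list")
  edges <- data.frame(
    gene_a = c("gA", "gA", "gB", "hA", "hA", "hB"),
    gene_b = c("gB", "gD", "gD", "hB", "hD", "hD"),
    identity_pct = c(97, 97, 97, 92, 88, 88), stringsAsFactors = FALSE)
  grps <- group_homeologs(edges, models)
  expect_length(grps, 2)
  expect_equal(grps[[1]], c("gA", "gB", "gD"))
  expect_equal(grps[[2]], c("hA", "hB"))  # the 88% member misses the cut
})

test_that("synthetic homeolog groups are recovered exactly at scale", {
  fam <- generate_family(family_spec(n_homeolog_groups = 32,
                                     duplicate_specs = NULL, seed = 44))
  edges <- similarity_edges(fam$proteins)
  grps <- group_homeologs(edges, fam$models)
  expect_length(grps, 32)
  expect_setequal(vapply(grps, paste, "", collapse = "+"),
                  vapply(fam$truth$groups, paste, "", collapse = "+"))
})

test_that("intron phases follow cumulative CDS length in transcription order", {
  m <- gene_model("g1", "1A", "+", cbind(c(1, 201), c(100, 400)),
                  cds = cbind(c(1, 201), c(100, 400), c(0, 2)))
  a <- intron_phases(m)
  expect_equal(a$exon_count, 2)
  expect_equal(a$intron_phases, 1)  # 100 mod 3

  single <- gene_model("g2", "1A", "+", cbind(1, 300), cds = cbind(1, 300, 0))
  a2 <- intron_phases(single)
  expect_true(a2$intronless)
  expect_length(a2$intron_phases, 0)

  m3 <- gene_model("g3", "1A", "+", cbind(c(1, 201, 401), c(99, 299, 499)),
                   cds = cbind(c(1, 201, 401), c(99, 299, 499), c(0, 0, 0)))
  expect_equal(intron_phases(m3)$intron_phases, c(0, 0))

  # CDS not a multiple of 3 warns but still reports phases
  m4 <- gene_model("g4", "1A", "+", cbind(c(1, 201), c(100, 300)),
                   cds = cbind(c(1, 201), c(100, 300), c(0, 2)))
  expect_warning(ph <- intron_phases(m4), "multiple of 3")
  expect_equal(ph$intron_phases, 1)
})

test_that("phases are invariant under strand reflection", {
  # same exonic structure written on + and as its mirror image on -
  plus <- gene_model("p", "1A", "+", cbind(c(1, 201), c(100, 400)),
                     cds = cbind(c(1, 201), c(100, 400), c(0, 2)))
  L <- 500
  minus <- gene_model("m", "1A", "-",
                      cbind(L - c(100, 400) + 1, L - c(1, 201) + 1),
                      cds = cbind(L - c(100, 400) + 1, L - c(1, 201) + 1,
                                  c(0, 2)))
  expect_equal(intron_phases(plus)$intron_phases,
               intron_phases(minus)$intron_phases)
})

test_that("chromosome counts sum to placed genes and recover planted layout", {
  fam <- generate_family(family_spec(n_homeolog_groups = 6, seed = 55))
  cd <- chromosome_distribution(fam$models)
  expect_equal(sum(cd$counts) + cd$unplaced, length(fam$models))
  planted <- table(fam$truth$genes$chromosome)
  expect_equal(cd$counts[names(planted)],
               setNames(as.integer(planted), names(planted)))
})
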