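mk_matrix <- function(values, genes, conds) {
  matrix(values, nrow = length(genes), dimnames = list(genes, conds),
         byrow = TRUE)
}

test_that("FPKM follows its defining formula and scaling laws", {
  m <- fpkm(matrix(10, 1, 1, dimnames = list("g", "s")),
            lengths = c(g = 1000), totals = c(s = 1e6))
  expect_equal(unname(m[1, 1]), 10)
  expect_equal(unname(fpkm(matrix(0, 1, 1, dimnames = list("g", "s")),
                           c(g = 500), c(s = 1e6))[1, 1]), 0)
  set.seed(81)
  counts <- matrix(rpois(12, 50), 3, 4,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  lens <- setNames(sample(500:2000, 3), rownames(counts))
  tot <- setNames(rep(2e7, 4), colnames(counts))
  base <- fpkm(counts, lens, tot)
  expect_equal(fpkm(counts * 3, lens, tot), base * 3)       # linear in counts
  expect_equal(fpkm(counts, lens, tot * 2), base / 2)       # inverse in totals
  expect_error(fpkm(counts, lens * 0, tot), "positive")
})

test_that("the 2-fold filter flags by ratio with pseudocount", {
  m <- mk_matrix(c(5, 11, 5, 9), c("up", "meh"), c("control", "treated"))
  de <- differential_filter(m, "control", "treated")
  expect_equal(de$flagged, "up")
  expect_equal(unname(de$folds["up", 1]), (11 + 0.01) / (5 + 0.01))

  # symmetry: swapping control and treated inverts folds, same flagged set
  de_rev <- differential_filter(m, "treated", "control")
  expect_setequal(de$flagged, de_rev$flagged)
  expect_equal(unname(de_rev$folds[, 1]), 1 / unname(de$folds[, 1]))

  # generator-planted 2.5-fold genes are exactly the flagged set
  expr <- generate_expression(paste0("g", 1:24), noise_sd = 0, seed = 82)
  mm <- fpkm(expr$counts, expr$lengths, expr$totals)
  de2 <- differential_filter(mm, "control", setdiff(colnames(mm), "control"))
  expect_setequal(de2$flagged, expr$truth$gene_id[expr$truth$differential])
})

test_that("clustering co-groups identical profiles and ignores row order", {
  m <- mk_matrix(c(1, 8, 2, 1, 8, 2, 50, 2, 9), paste0("g", 1:3),
                 paste0("c", 1:3))
  cl <- cluster_genes(m, k = 2)
  expect_equal(cl$groups[["g1"]], cl$groups[["g2"]])
  expect_false(cl$groups[["g1"]] == cl$groups[["g3"]])

  perm <- m[c(3, 1, 2), ]
  cl2 <- cluster_genes(perm, k = 2)
  agree <- outer(cl$groups[rownames(m)], cl$groups[rownames(m)], "==")
  agree2 <- outer(cl2$groups[rownames(m)], cl2$groups[rownames(m)], "==")
  expect_equal(agree, agree2)

  expect_warning(cluster_genes(mk_matrix(rep(1, 6), c("a", "b"), paste0("c", 1:3))),
                 "constant")
})

test_that("planted expression archetypes are recovered by clustering", {
  set.seed(83)
  ari <- function(a, b) {
    # adjusted Rand index, computed from the contingency table
    tab <- table(a, b)
    sum_comb <- function(x) sum(choose(x, 2))
    a_ <- sum_comb(rowSums(tab)); b_ <- sum_comb(colSums(tab))
    idx <- sum_comb(as.vector(tab)); n <- sum_comb(sum(tab))
    exp_idx <- a_ * b_ / n
    (idx - exp_idx) / ((a_ + b_) / 2 - exp_idx)
  }
  scores <- vapply(1:10, function(s) {
    expr <- generate_expression(paste0("g", 1:40), noise_sd = 0.15,
                                seed = 900 + s)
    m <- fpkm(expr$counts, expr$lengths, expr$totals)
    cl <- cluster_genes(m, k = 4)
    ari(cl$groups[expr$truth$gene_id], expr$truth$archetype)
  }, numeric(1))
  expect_gte(mean(scores >= 0.9), 0.9)
})

test_that("2^-ddCt folds and replicate statistics match the textbook route", {
  qp <- expand.grid(gene_id = "g1", condition = c("control", "treated"),
                    replicate = 1:3, stringsAsFactors = FALSE)
  qp$ct_reference <- 20
  qp$ct_target <- ifelse(qp$condition == "control",
                         c(23.0, 23.1, 22.9)[qp$replicate],
                         c(22.0, 22.1, 21.9)[qp$replicate])
  fc <- ddct_fold(qp, "control")
  expect_equal(fc$fold, 2.0, tolerance = 1e-12)
  expect_equal(fc$log2_fold, 1.0, tolerance = 1e-12)
  expect_equal(fc$p_value,
               oracle_ttest_p(c(2.0, 2.1, 1.9), c(3.0, 3.1, 2.9)),
               tolerance = 1e-9)

  # ddCt = 0 -> fold 1; reciprocal comparison inverts the fold
  qp0 <- qp; qp0$ct_target <- 23
  expect_equal(ddct_fold(qp0, "control")$fold, 1)
  fc_rev <- ddct_fold(transform(qp, condition = ifelse(condition == "control",
                                                       "treated", "control")),
                      "control")
  expect_equal(fc$fold * fc_rev$fold, 1, tolerance = 1e-12)

  # single replicate: fold reported, statistics flagged out
  qp1 <- qp[qp$replicate == 1, ]
  fc1 <- ddct_fold(qp1, "control")
  expect_true(fc1$flagged)
  expect_true(is.na(fc1$p_value))
  expect_equal(fc1$fold, 2, tolerance = 1e-12)
})

test_that("significance stars follow the p-value bands", {
  mkq <- function(shift, noise) {
    qp <- expand.grid(gene_id = "g", condition = c("control", "t"),
                      replicate = 1:3, stringsAsFactors = FALSE)
    qp$ct_reference <- 20
    set.seed(84)
    qp$ct_target <- 25 - ifelse(qp$condition == "t", shift, 0) +
      rnorm(6, 0, noise)
    ddct_fold(qp, "control")
  }
  expect_equal(mkq(0.001, 0.5)$significance, "ns")
  expect_true(mkq(8, 0.01)$significance == "***")
})

test_that("duplicate expression fates follow floor and correlation rules", {
  conds <- paste0("c", 1:4)
  m <- mk_matrix(c(5, 10, 2, 8,
                   5, 10, 2, 8,
                   0, 0.2, 0.1, 0,
                   8, 2, 10, 4), paste0("g", 1:4), conds)
  same <- duplicate_fate(m, "g1", "g2")
  expect_equal(same$fate, "retention")
  expect_equal(same$correlation, 1)
  dead <- duplicate_fate(m, "g1", "g3")
  expect_equal(dead$fate, "pseudo_functionalization")
  anti <- duplicate_fate(m, "g2", "g4")
  expect_equal(anti$fate, "neo_functionalization")
  expect_lt(anti$correlation, 0)
  # zero-variance profile: fate from floors alone, flagged
  mflat <- rbind(m, g5 = rep(3, 4))
  flat <- duplicate_fate(mflat, "g1", "g5")
  expect_true(flat$flagged)
})
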