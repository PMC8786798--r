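#' FPKM from fragment counts
#'
#' `fpkm[g, s] = counts[g, s] * 1e9 / (length[g] * total[s])` — fragments
#' per kilobase of exon per million mapped fragments. Effective length is
#' the annotated exonic length.
#'
#' @param counts gene x sample numeric matrix of fragment counts
#' @param lengths per-gene exonic lengths in bp (named or in row order)
#' @param totals per-sample mapped-fragment totals (named or in column order)
#' @return gene x sample FPKM matrix
#' @export
fpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (!is.null(names(totals)) && !is.null(colnames(counts))) {
    totals <- totals[colnames(counts)]
  }
  if (any(lengths <= 0)) stop_tlp("gene lengths must be positive")
  if (any(totals <= 0)) stop_tlp("library totals must be positive")
  if (any(counts < 0)) stop_tlp("negative counts")
  sweep(sweep(counts * 1e9, 1, lengths, "/"), 2, totals, "/")
}

#' Flag genes with >= 2-fold differential expression
#'
#' For each treated condition, `fold = (fpkm_treated + pseudo) /
#' (fpkm_control + pseudo)`; a gene is flagged when any treated condition
#' has fold >= `min_fold` or <= `1/min_fold`. The pseudocount guards
#' zero-FPKM ratios.
#'
#' @param matrix_fpkm gene x condition FPKM matrix
#' @param control_cond control condition (column name)
#' @param treated_conds treated condition column names
#' @param min_fold fold threshold (default 2)
#' @param pseudo pseudocount in FPKM units (default 0.01)
#' @return list: `flagged` (character vector of gene ids) and `folds`
#'   (gene x treated-condition fold matrix)
#' @export
differential_filter <- function(matrix_fpkm, control_cond, treated_conds,
                                min_fold = 2, pseudo = 0.01) {
  m <- as.matrix(matrix_fpkm)
  if (!control_cond %in% colnames(m)) stop_tlp("control condition not in matrix")
  if (!all(treated_conds %in% colnames(m))) stop_tlp("treated condition not in matrix")
  folds <- sweep(m[, treated_conds, drop = FALSE] + pseudo, 1,
                 m[, control_cond] + pseudo, "/")
  hit <- apply(folds, 1, function(f) any(f >= min_fold | f <= 1 / min_fold))
  list(flagged = rownames(m)[hit], folds = folds)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of `log2(fpkm + 1)` rows with Euclidean
#' distance and average (UPGMA) linkage, via [stats::hclust()]; with `k`
#' the tree is cut into `k` groups. A constant matrix yields a single
#' cluster with a warning.
#'
#' @param matrix_fpkm gene x condition FPKM matrix (>= 2 genes)
#' @param k optional number of groups
#' @return list: `hclust` (dendrogram) and `groups` (named integer vector
#'   when `k` given, else NULL)
#' @export
cluster_genes <- function(matrix_fpkm, k = NULL) {
  m <- log2(as.matrix(matrix_fpkm) + 1)
  if (nrow(m) < 2) stop_tlp("need >= 2 genes to cluster")
  d <- stats::dist(m, method = "euclidean")
  if (all(d == 0)) {
    warning("constant expression matrix: single cluster")
    groups <- stats::setNames(rep(1L, nrow(m)), rownames(m))
    return(list(hclust = NULL, groups = groups))
  }
  hc <- stats::hclust(d, method = "average")
  groups <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, groups = groups)
}

#' Plot an expression heat map
#'
#' Convenience wrapper around `pheatmap` on `log2(fpkm + 1)` with Euclidean
#' distance and average linkage (matching [cluster_genes()]).
#'
#' @param matrix_fpkm gene x condition FPKM matrix
#' @param ... passed to [pheatmap::pheatmap()]
#' @return the pheatmap object, invisibly
#' @export
expression_heatmap <- function(matrix_fpkm, ...) {
  if (!requireNamespace("pheatmap", quietly = TRUE)) {
    stop_tlp("the 'pheatmap' package is required for heat maps")
  }
  invisible(pheatmap::pheatmap(log2(as.matrix(matrix_fpkm) + 1),
                               clustering_distance_rows = "euclidean",
                               clustering_method = "average", ...))
}

#' qPCR fold changes by the 2^-ddCt method
#'
#' Per replicate, `dCt = ct_target - ct_reference`; per (gene, condition),
#' `ddCt = mean dCt(treated) - mean dCt(control)` and
#' `fold = 2^(-ddCt)`. The SD is that of the treated replicate `2^-dCt`
#' fold values around the control baseline; the p-value is a two-tailed
#' equal-variance two-sample t-test on the replicate dCt values
#' (treated vs control). Significance stars: `ns` (p > 0.05), `*`
#' (<= 0.05), `**` (<= 0.01), `***` (<= 0.001). Conditions with fewer than
#' two replicates get the fold but `NA` statistics and a flag.
#'
#' @param qpcr data.frame with columns `gene_id`, `condition`, `replicate`,
#'   `ct_target`, `ct_reference` (Ct values in (0, 45))
#' @param control_cond the designated control condition
#' @return data.frame: `gene_id`, `condition`, `fold`, `log2_fold`, `sd`,
#'   `p_value`, `significance`, `flagged`
#' @export
ddct_fold <- function(qpcr, control_cond) {
  need <- c("gene_id", "condition", "replicate", "ct_target", "ct_reference")
  if (!all(need %in% names(qpcr))) stop_tlp("qPCR table needs columns: ",
                                            paste(need, collapse = ", "))
  ct <- c(qpcr$ct_target, qpcr$ct_reference)
  if (any(ct <= 0 | ct >= 45)) stop_tlp("Ct values must lie in (0, 45)")
  if (!control_cond %in% qpcr$condition) stop_tlp("control condition absent")
  qpcr$dct <- qpcr$ct_target - qpcr$ct_reference
  out <- list()
  for (g in unique(qpcr$gene_id)) {
    gg <- qpcr[qpcr$gene_id == g, , drop = FALSE]
    ctrl <- gg$dct[gg$condition == control_cond]
    if (length(ctrl) == 0) stop_tlp("gene ", g, " lacks control replicates")
    for (cond in setdiff(unique(gg$condition), control_cond)) {
      tr <- gg$dct[gg$condition == cond]
      ddct <- mean(tr) - mean(ctrl)
      fold <- 2^(-ddct)
      flagged <- length(tr) < 2 || length(ctrl) < 2
      if (!flagged) {
        sdv <- stats::sd(2^(-(tr - mean(ctrl))))
        # zero-variance replicates make the t statistic degenerate
        p <- tryCatch(stats::t.test(tr, ctrl, var.equal = TRUE)$p.value,
                      error = function(e) NA_real_)
        stars <- if (is.na(p)) NA_character_
          else if (p > 0.05) "ns" else if (p > 0.01) "*"
          else if (p > 0.001) "**" else "***"
      } else {
        sdv <- NA_real_; p <- NA_real_; stars <- NA_character_
      }
      out[[length(out) + 1L]] <- data.frame(
        gene_id = g, condition = cond, fold = fold, log2_fold = log2(fold),
        sd = sdv, p_value = p, significance = stars, flagged = flagged,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Expression fate of a duplicate gene pair
#'
#' A gene is `expressed` when its maximum FPKM across conditions reaches
#' `floor`. Fates: `pseudo_functionalization` when exactly one gene is
#' expressed; `retention` when both are expressed and their profiles
#' correlate (Pearson r >= `r_min`); `neo_functionalization` when both are
#' expressed but diverged (r < `r_min`). With a zero-variance profile the
#' correlation is undefined and the call falls back to the expression
#' floors alone (flagged).
#'
#' @param matrix_fpkm gene x condition FPKM matrix
#' @param gene_a,gene_b the pair
#' @param floor expression floor in FPKM (default 1)
#' @param r_min correlation threshold for retention (default 0.6)
#' @return list: `gene_a`, `gene_b`, `fate`, `correlation`, `expressed_a`,
#'   `expressed_b`, `flagged`
#' @export
duplicate_fate <- function(matrix_fpkm, gene_a, gene_b, floor = 1.0, r_min = 0.6) {
  m <- as.matrix(matrix_fpkm)
  if (!all(c(gene_a, gene_b) %in% rownames(m))) stop_tlp("pair not in matrix")
  xa <- m[gene_a, ]; xb <- m[gene_b, ]
  ea <- max(xa) >= floor; eb <- max(xb) >= floor
  flagged <- FALSE
  if (xor(ea, eb)) {
    fate <- "pseudo_functionalization"; r <- NA_real_
  } else if (!ea && !eb) {
    fate <- "pseudo_functionalization"; r <- NA_real_; flagged <- TRUE
  } else if (stats::sd(xa) == 0 || stats::sd(xb) == 0) {
    fate <- "retention"; r <- NA_real_; flagged <- TRUE
  } else {
    r <- stats::cor(xa, xb)
    fate <- if (r >= r_min) "retention" else "neo_functionalization"
  }
  list(gene_a = gene_a, gene_b = gene_b, fate = fate, correlation = r,
       expressed_a = ea, expressed_b = eb, flagged = flagged)
}
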