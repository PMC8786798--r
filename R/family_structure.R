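#' Percent identity from a global protein alignment
#'
#' Sequences are globally aligned with [Biostrings::pairwiseAlignment()]
#' (BLOSUM62, affine gaps: opening 10, extension 0.5). Identity is the
#' number of identical columns divided by the number of alignment columns
#' after trimming terminal gap overhangs (columns inside the leading or
#' trailing gap run of either sequence), times 100. The measure is
#' symmetric in its arguments.
#'
#' @param a,b protein sequences (single-record [tlp_seqs] or strings)
#' @return identity percentage in \[0, 100\]
#' @export
pairwise_identity <- function(a, b) {
  sa <- if (inherits(a, "tlp_seqs")) unclass(a)[[1]] else toupper(a)
  sb <- if (inherits(b, "tlp_seqs")) unclass(b)[[1]] else toupper(b)
  if (!nzchar(sa) || !nzchar(sb)) stop_tlp("empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  pa <- chars(as.character(Biostrings::alignedPattern(aln)))
  pb <- chars(as.character(Biostrings::alignedSubject(aln)))
  identity_from_columns(pa, pb)
}

# identity over alignment columns, terminal gap overhangs excluded
identity_from_columns <- function(pa, pb) {
  n <- length(pa)
  keep <- rep(TRUE, n)
  for (v in list(pa, pb)) {
    nong <- which(v != "-")
    if (length(nong) == 0) return(0)
    keep[seq_len(n) < nong[1] | seq_len(n) > nong[length(nong)]] <- FALSE
  }
  pa <- pa[keep]; pb <- pb[keep]
  if (length(pa) == 0) return(0)
  100 * sum(pa == pb) / length(pa)
}

#' All-vs-all similarity edges with bidirectional best hits
#'
#' Computes [pairwise_identity()] for every pair and marks, for each gene,
#' its best-scoring partner (the bidirectional-best-hit criterion used for
#' paralog detection). Edges are stored with `gene_a < gene_b`
#' lexicographically.
#'
#' Like BLAST-style searches, a word-seed prefilter skips the full global
#' alignment for pairs that share (almost) no 6-residue words: such pairs
#' cannot approach the 80-90% identity range the downstream thresholds act
#' on (at 80% identity roughly a quarter of all 6-mers survive intact).
#' Skipped pairs carry the word-sharing fraction (capped well below any
#' threshold) as a surrogate identity and `aligned = FALSE`.
#'
#' @param proteins a protein [tlp_seqs] collection (>= 2 records)
#' @param kmer_prefilter apply the 6-mer seed prefilter (default TRUE);
#'   set to FALSE to align every pair exactly
#' @param min_shared minimum shared-6-mer fraction that triggers a full
#'   alignment (default 0.02)
#' @return data.frame: `gene_a`, `gene_b`, `identity_pct`, `aligned`,
#'   `best_hit_a_to_b`, `best_hit_b_to_a`
#' @export
similarity_edges <- function(proteins, kmer_prefilter = TRUE, min_shared = 0.02) {
  ids <- names(proteins)
  if (length(ids) < 2) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      identity_pct = numeric(0), aligned = logical(0),
                      best_hit_a_to_b = logical(0),
                      best_hit_b_to_a = logical(0), stringsAsFactors = FALSE))
  }
  ids <- sort(ids)
  seqs <- unclass(proteins)[ids]
  kmers <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 6) return(s)
    unique(substring(s, 1:(n - 5), 6:n))
  })
  rows <- vector("list", length(ids) - 1L)
  for (j in 2:length(ids)) {
    prev <- seq_len(j - 1L)
    share <- vapply(prev, function(i) {
      length(intersect(kmers[[i]], kmers[[j]])) /
        max(1L, min(length(kmers[[i]]), length(kmers[[j]])))
    }, numeric(1))
    do_align <- if (kmer_prefilter) share >= min_shared else rep(TRUE, j - 1L)
    idn <- pmin(50, 100 * share)   # surrogate for screened-out pairs
    if (any(do_align)) {
      pat <- Biostrings::AAStringSet(seqs[prev[do_align]])
      aln <- Biostrings::pairwiseAlignment(
        pat, Biostrings::AAString(seqs[[j]]),
        substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
        type = "global")
      pa <- as.character(Biostrings::alignedPattern(aln))
      pb <- as.character(Biostrings::alignedSubject(aln))
      idn[do_align] <- vapply(seq_along(pa), function(k)
        identity_from_columns(chars(pa[k]), chars(pb[k])), numeric(1))
    }
    rows[[j - 1L]] <- data.frame(gene_a = ids[prev], gene_b = ids[j],
                                 identity_pct = idn, aligned = do_align,
                                 stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, rows)
  best <- vapply(ids, function(g) {
    k <- edges$gene_a == g | edges$gene_b == g
    other <- ifelse(edges$gene_a[k] == g, edges$gene_b[k], edges$gene_a[k])
    # ties broken by id order so the best hit is well defined
    other[order(-edges$identity_pct[k], other)][1]
  }, character(1))
  edges$best_hit_a_to_b <- best[edges$gene_a] == edges$gene_b
  edges$best_hit_b_to_a <- best[edges$gene_b] == edges$gene_a
  edges
}

#' Detect duplicate gene pairs (bidirectional best hits)
#'
#' A pair qualifies when identity >= `identity_min` and each gene is the
#' other's best hit. Qualifying pairs are then made disjoint greedily by
#' descending identity (ties by id order), so each gene appears in at most
#' one emitted pair. Pairs within the same homeolog group can be excluded:
#' inter-subgenome homeologs are the product of polyploidization, not of
#' the within-genome duplication events being classified.
#'
#' @param edges output of [similarity_edges()]
#' @param identity_min minimum identity percentage (default 80)
#' @param exclude_groups optional list of character vectors (e.g. homeolog
#'   groups); pairs falling inside one group are skipped, and best-hit
#'   status is recomputed ignoring within-group edges
#' @return data.frame: `gene_a`, `gene_b`, `identity_pct`
#' @export
find_duplicates <- function(edges, identity_min = 80, exclude_groups = NULL) {
  e <- edges
  if (!is.null(exclude_groups) && length(exclude_groups) > 0) {
    grp <- unlist(lapply(seq_along(exclude_groups),
                         function(i) stats::setNames(rep(i, length(exclude_groups[[i]])),
                                                     exclude_groups[[i]])))
    ga <- grp[e$gene_a]; gb <- grp[e$gene_b]
    same <- !is.na(ga) & !is.na(gb) & ga == gb
    e <- e[!same, , drop = FALSE]
    if (nrow(e) > 0) {
      ids <- unique(c(e$gene_a, e$gene_b))
      best <- vapply(ids, function(g) {
        k <- e$gene_a == g | e$gene_b == g
        other <- ifelse(e$gene_a[k] == g, e$gene_b[k], e$gene_a[k])
        other[order(-e$identity_pct[k], other)][1]
      }, character(1))
      e$best_hit_a_to_b <- best[e$gene_a] == e$gene_b
      e$best_hit_b_to_a <- best[e$gene_b] == e$gene_a
    }
  }
  q <- e[e$identity_pct >= identity_min & e$best_hit_a_to_b & e$best_hit_b_to_a,
         , drop = FALSE]
  q <- q[order(-q$identity_pct, q$gene_a, q$gene_b), , drop = FALSE]
  used <- character(0); keep <- logical(nrow(q))
  for (i in seq_len(nrow(q))) {
    if (!(q$gene_a[i] %in% used) && !(q$gene_b[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, q$gene_a[i], q$gene_b[i])
    }
  }
  out <- q[keep, c("gene_a", "gene_b", "identity_pct"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a duplicate pair as tandem or segmental
#'
#' Tandem: same chromosome AND (genomic gap <= `tandem_gap_bp` OR at most
#' `max_intervening` other family genes between the two); segmental
#' otherwise. Pairs with an unplaced member get `kind = NA` and a flag.
#'
#' @param gene_a,gene_b gene ids
#' @param models a `gene_model_list` covering the family
#' @param tandem_gap_bp maximum tandem gap (default 100 kb)
#' @param max_intervening maximum intervening family genes (default 5)
#' @param unplaced_prefix chromosome prefix marking unplaced scaffolds
#' @return data.frame row: `gene_a`, `gene_b`, `kind`, `chrom_a`, `chrom_b`,
#'   `genomic_gap_bp`, `intervening_genes`, `flagged`
#' @export
classify_duplication <- function(gene_a, gene_b, models,
                                 tandem_gap_bp = 100000L, max_intervening = 5L,
                                 unplaced_prefix = "scaffold") {
  ma <- models[[gene_a]]; mb <- models[[gene_b]]
  if (is.null(ma) || is.null(mb)) stop_tlp("gene model missing for pair")
  unplaced <- startsWith(ma$chromosome, unplaced_prefix) ||
    startsWith(mb$chromosome, unplaced_prefix)
  if (unplaced) {
    return(data.frame(gene_a = gene_a, gene_b = gene_b, kind = NA_character_,
                      chrom_a = ma$chromosome, chrom_b = mb$chromosome,
                      genomic_gap_bp = NA_integer_, intervening_genes = NA_integer_,
                      flagged = TRUE, stringsAsFactors = FALSE))
  }
  if (ma$chromosome != mb$chromosome) {
    return(data.frame(gene_a = gene_a, gene_b = gene_b, kind = "segmental",
                      chrom_a = ma$chromosome, chrom_b = mb$chromosome,
                      genomic_gap_bp = NA_integer_, intervening_genes = NA_integer_,
                      flagged = FALSE, stringsAsFactors = FALSE))
  }
  gap <- max(0L, max(ma$start, mb$start) - min(ma$end, mb$end))
  lo <- min(ma$end, mb$end); hi <- max(ma$start, mb$start)
  interv <- sum(vapply(models, function(m) {
    m$chromosome == ma$chromosome && m$gene_id != gene_a && m$gene_id != gene_b &&
      m$start > lo && m$end < hi
  }, logical(1)))
  kind <- if (gap <= tandem_gap_bp || interv <= max_intervening) "tandem" else "segmental"
  data.frame(gene_a = gene_a, gene_b = gene_b, kind = kind,
             chrom_a = ma$chromosome, chrom_b = mb$chromosome,
             genomic_gap_bp = as.integer(gap), intervening_genes = as.integer(interv),
             flagged = FALSE, stringsAsFactors = FALSE)
}

# "5A" -> 5; "Bd4" -> 4; anything unnumbered -> NA
.chrom_number <- function(chrom) {
  m <- regmatches(chrom, regexpr("[0-9]+", chrom))
  if (length(m) == 0) NA_integer_ else as.integer(m)
}

#' Group hexaploid homeologs
#'
#' Homeologs are the corresponding copies on the A, B and D subgenomes of
#' hexaploid wheat. Groups are maximal cliques (via [igraph::max_cliques()])
#' over edges with identity >= `identity_min` restricted to genes on the
#' same chromosome *number* but distinct subgenomes; cliques rather than
#' connected components prevent chaining through a promiscuous member.
#' Overlapping cliques are resolved greedily (largest clique first, ties by
#' member ids) so that reported groups are disjoint; singletons are not
#' reported.
#'
#' @param edges output of [similarity_edges()]
#' @param models a `gene_model_list` supplying chromosome and subgenome
#' @param identity_min minimum identity percentage (default 90)
#' @return list of character vectors (sorted member ids), sorted by first id
#' @export
group_homeologs <- function(edges, models, identity_min = 90) {
  ok <- vapply(seq_len(nrow(edges)), function(i) {
    a <- models[[edges$gene_a[i]]]; b <- models[[edges$gene_b[i]]]
    if (is.null(a) || is.null(b)) return(FALSE)
    if (is.na(a$subgenome) || is.na(b$subgenome)) return(FALSE)
    edges$identity_pct[i] >= identity_min &&
      a$subgenome != b$subgenome &&
      identical(.chrom_number(a$chromosome), .chrom_number(b$chromosome))
  }, logical(1))
  e <- edges[ok, , drop = FALSE]
  if (nrow(e) == 0) return(list())
  g <- igraph::graph_from_data_frame(e[, c("gene_a", "gene_b")], directed = FALSE)
  cl <- igraph::max_cliques(g, min = 2)
  cl <- lapply(cl, function(v) sort(names(v)))
  # subgenomes must be distinct within a clique (pairwise check above allows
  # e.g. A-B, A-B' cliques only if B,B' also linked, which the distinct-
  # subgenome edge filter forbids, so cliques here are automatically valid)
  cl <- cl[order(-lengths(cl), vapply(cl, `[`, "", 1))]
  used <- character(0); out <- list()
  for (memb in cl) {
    if (!any(memb %in% used)) {
      out[[length(out) + 1L]] <- memb
      used <- c(used, memb)
    }
  }
  out[order(vapply(out, `[`, "", 1))]
}

#' Exon/intron architecture with intron phases
#'
#' The phase of intron *i* is the cumulative CDS length 5' of the intron,
#' modulo 3, computed in transcription order (so introns upstream of the CDS
#' have phase 0). A warning is raised when the total CDS length is not a
#' multiple of 3.
#'
#' @param model a [gene_model] with CDS segments
#' @return list: `gene_id`, `exon_count`, `intron_phases` (integer vector of
#'   length `exon_count - 1`), `intronless`
#' @export
intron_phases <- function(model) {
  if (is.null(model$cds)) stop_tlp(model$gene_id, ": CDS segments required")
  nex <- nrow(model$exons)
  if (nex == 1) {
    return(list(gene_id = model$gene_id, exon_count = 1L,
                intron_phases = integer(0), intronless = TRUE))
  }
  cds_len_total <- sum(model$cds[, 2] - model$cds[, 1] + 1L)
  if (cds_len_total %% 3 != 0) {
    warning(model$gene_id, ": CDS length ", cds_len_total, " not a multiple of 3")
  }
  phases <- integer(nex - 1L)
  for (i in seq_len(nex - 1L)) {
    # genomic interval of everything at or 5' (transcriptionally) of exon i
    upstream_exons <- model$exons[seq_len(i), , drop = FALSE]
    cum <- 0L
    for (j in seq_len(nrow(model$cds))) {
      for (k in seq_len(nrow(upstream_exons))) {
        lo <- max(model$cds[j, 1], upstream_exons[k, 1])
        hi <- min(model$cds[j, 2], upstream_exons[k, 2])
        if (lo <= hi) cum <- cum + (hi - lo + 1L)
      }
    }
    phases[i] <- cum %% 3L
  }
  list(gene_id = model$gene_id, exon_count = as.integer(nex),
       intron_phases = phases, intronless = FALSE)
}
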