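#' Gene model objects
#'
#' A `gene_model` stores the genomic placement and exonic structure of one
#' representative transcript: 1-based inclusive coordinates (the GFF3
#' convention), a strand, exons in transcription order (descending genomic
#' coordinate on the minus strand), and CDS segments (also transcription
#' order) with their annotated phases.
#'
#' @param gene_id gene identifier
#' @param chromosome chromosome/scaffold name (e.g. `"5A"`, `"Bd4"`)
#' @param strand `"+"` or `"-"`
#' @param exons two-column matrix (start, end), genomic coordinates
#' @param cds optional three-column matrix (start, end, phase)
#' @param subgenome optional subgenome letter (`"A"`, `"B"`, `"D"`)
#' @return a `gene_model` list
#' @export
gene_model <- function(gene_id, chromosome, strand, exons, cds = NULL,
                       subgenome = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (any(exons[, 1] > exons[, 2])) stop_tlp(gene_id, ": exon start > end")
  # transcription order
  ord <- order(exons[, 1], decreasing = (strand == "-"))
  exons <- exons[ord, , drop = FALSE]
  g <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(g) > 1 && any(g[-1, 1] <= g[-nrow(g), 2])) {
    stop_tlp(gene_id, ": overlapping exons")
  }
  if (!is.null(cds)) {
    cds <- matrix(as.integer(cds), ncol = 3,
                  dimnames = list(NULL, c("start", "end", "phase")))
    if (any(cds[, 1] > cds[, 2])) stop_tlp(gene_id, ": CDS start > end")
    cds <- cds[order(cds[, 1], decreasing = (strand == "-")), , drop = FALSE]
    for (i in seq_len(nrow(cds))) {
      inside <- any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
      if (!inside) {
        stop_tlp(gene_id, ": CDS segment (", cds[i, 1], ",", cds[i, 2],
                 ") outside exon span")
      }
    }
  }
  structure(list(gene_id = gene_id, chromosome = as.character(chromosome),
                 subgenome = subgenome, strand = strand,
                 start = min(exons), end = max(exons),
                 exons = exons, cds = cds),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s: %s:%d-%d(%s), %d exon(s), %d CDS segment(s)\n",
              x$gene_id, x$chromosome, x$start, x$end, x$strand,
              nrow(x$exons), if (is.null(x$cds)) 0L else nrow(x$cds)))
  invisible(x)
}

# genomic coordinates of the initiation codon side of the CDS
cds_genomic_range <- function(model) {
  if (is.null(model$cds)) stop_tlp(model$gene_id, ": no CDS segments")
  c(min(model$cds[, 1:2]), max(model$cds[, 1:2]))
}

#' Read gene models from a GFF3 file
#'
#' Parsing is delegated to [rtracklayer::readGFF()]. Features of type
#' `gene`, `mRNA` and `exon`/`CDS` are linked through their `Parent`
#' attributes; when a gene has several transcripts the one with the longest
#' total CDS is kept (ties broken by lexicographically smallest transcript
#' id). Coordinates stay 1-based inclusive; exons are re-ordered into
#' transcription order for minus-strand genes. Wheat-style chromosome names
#' (`1A`..`7D`) populate the `subgenome` field.
#'
#' @param path GFF3 file (a `##gff-version 3` pragma is required)
#' @return named list of [gene_model] objects, class `gene_model_list`
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop_tlp("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (!grepl("^##gff-version\\s+3", first)) {
    stop_tlp(path, ": missing ##gff-version 3 pragma")
  }
  g <- rtracklayer::readGFF(path)
  g$ID <- as.character(g$ID)
  parent1 <- vapply(g$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p)[1]
  }, character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrnas <- g[g$type == "mRNA", , drop = FALSE]
  if (nrow(mrnas) > 0 && anyNA(parent1[g$type == "mRNA"])) {
    stop_tlp("mRNA feature without Parent link")
  }
  sub <- g[g$type %in% c("exon", "CDS"), , drop = FALSE]
  sub_parent <- parent1[g$type %in% c("exon", "CDS")]
  if (anyNA(sub_parent)) stop_tlp("exon/CDS feature without Parent link")

  models <- list()
  for (i in seq_len(nrow(genes))) {
    gid <- genes$ID[i]
    tx <- mrnas[parent1[g$type == "mRNA"] == gid, , drop = FALSE]
    if (nrow(tx) == 0) {  # features may hang directly off the gene
      tx_ids <- gid
    } else {
      cds_len <- vapply(tx$ID, function(tid) {
        k <- sub$type == "CDS" & sub_parent == tid
        sum(sub$end[k] - sub$start[k] + 1L)
      }, numeric(1))
      tx_ids <- tx$ID[order(-cds_len, tx$ID)][1]
    }
    k_ex <- sub$type == "exon" & sub_parent %in% tx_ids
    k_cds <- sub$type == "CDS" & sub_parent %in% tx_ids
    strand <- as.character(genes$strand[i])
    exons <- if (any(k_ex)) cbind(sub$start[k_ex], sub$end[k_ex]) else
      cbind(genes$start[i], genes$end[i])
    cds <- NULL
    if (any(k_cds)) {
      ph <- suppressWarnings(as.integer(as.character(sub$phase[k_cds])))
      ph[is.na(ph)] <- 0L
      cds <- cbind(sub$start[k_cds], sub$end[k_cds], ph)
    }
    chrom <- as.character(genes$seqid[i])
    subg <- if (grepl("^[1-7][ABD]$", chrom)) sub("^[1-7]", "", chrom) else NA_character_
    models[[gid]] <- gene_model(gid, chrom, strand, exons, cds, subgenome = subg)
  }
  structure(models, class = "gene_model_list")
}

#' @export
print.gene_model_list <- function(x, ...) {
  cat(sprintf("gene_model_list: %d gene(s) on %d sequence(s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "chromosome")))))
  invisible(x)
}

#' Count placed genes per chromosome
#' @param models a `gene_model_list`
#' @param unplaced_prefix chromosome-name prefix marking unplaced scaffolds
#' @return list with `counts` (named integer vector, chromosome order) and
#'   `unplaced` (integer)
#' @export
chromosome_distribution <- function(models, unplaced_prefix = "scaffold") {
  chroms <- vapply(models, `[[`, "", "chromosome")
  unpl <- startsWith(chroms, unplaced_prefix)
  counts <- table(chroms[!unpl])
  list(counts = stats::setNames(as.integer(counts), names(counts)),
       unplaced = sum(unpl))
}
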