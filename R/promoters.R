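#' Extract the promoter window upstream of the initiation codon
#'
#' For a plus-strand gene the window is `[cds_start - window, cds_start - 1]`
#' on the chromosome; for a minus-strand gene it is the reverse complement
#' of `[cds_end + 1, cds_end + window]` (so the returned sequence always
#' reads 5' to 3' toward the initiation codon). Windows running off the
#' chromosome start/end are truncated and flagged.
#'
#' @param model a [gene_model] with CDS segments
#' @param genome a dna [tlp_seqs] collection keyed by chromosome name
#' @param window window size in bp (default 1500)
#' @return single-record dna [tlp_seqs] named after the gene, with
#'   attributes `truncated` (logical) and `window_bp` (realized size)
#' @export
extract_promoter <- function(model, genome, window = 1500L) {
  chrom <- model$chromosome
  if (!chrom %in% names(genome)) stop_tlp("chromosome '", chrom, "' not in genome")
  seq <- unclass(genome)[[chrom]]
  rng <- cds_genomic_range(model)
  truncated <- FALSE
  if (model$strand == "+") {
    lo <- rng[1] - window; hi <- rng[1] - 1L
    if (lo < 1L) { lo <- 1L; truncated <- TRUE }
    if (hi < lo) stop_tlp(model$gene_id, ": no upstream sequence")
    s <- substr(seq, lo, hi)
  } else {
    lo <- rng[2] + 1L; hi <- rng[2] + window
    if (hi > nchar(seq)) { hi <- nchar(seq); truncated <- TRUE }
    if (hi < lo) stop_tlp(model$gene_id, ": no upstream sequence")
    s <- revcomp(substr(seq, lo, hi))
  }
  out <- tlp_seqs(s, model$gene_id, "dna")
  attr(out, "truncated") <- truncated
  attr(out, "window_bp") <- nchar(s)
  out
}

#' Read a cis-regulatory element table
#'
#' TSV with columns `name`, `iupac_pattern`, `category` (one of
#' `growth_development`, `light`, `hormone`, `stress`) and optional
#' `hormone_subclass`. Patterns must be at least 4 bases of valid IUPAC
#' nucleotide codes.
#'
#' @param path TSV path; default: the table bundled with the package (a
#'   small, user-replaceable set of published consensus elements)
#' @return data.frame of elements
#' @export
read_element_table <- function(path = system.file("extdata", "cis_elements.tsv",
                                                  package = "tlpfam")) {
  el <- read_tsv(path)
  need <- c("name", "iupac_pattern", "category")
  if (!all(need %in% names(el))) stop_tlp("element table needs columns: ",
                                          paste(need, collapse = ", "))
  el$iupac_pattern <- toupper(el$iupac_pattern)
  bad <- regexpr("[^ACGTRYWSKMBDHVN]", el$iupac_pattern)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_tlp("invalid IUPAC code in pattern for element ", el$name[i])
  }
  if (any(nchar(el$iupac_pattern) < 4)) stop_tlp("element patterns must be >= 4 bases")
  okcat <- c("growth_development", "light", "hormone", "stress")
  if (!all(el$category %in% okcat)) {
    stop_tlp("unknown element category: ",
             setdiff(el$category, okcat)[1])
  }
  if (anyDuplicated(el$name)) stop_tlp("duplicate element name in table")
  el
}

#' Scan a promoter for degenerate cis-regulatory elements
#'
#' IUPAC-degenerate matching on both strands (via
#' [Biostrings::matchPattern()] with `fixed = FALSE`); overlapping hits are
#' reported. A minus-strand hit's coordinates refer to the promoter's plus
#' strand and its `matched_seq` is the reverse complement of that slice
#' (i.e. the sequence that actually matches the pattern).
#'
#' @param promoter single-record dna [tlp_seqs] (or plain string)
#' @param elements element table from [read_element_table()]
#' @param both_strands scan the minus strand too (default TRUE)
#' @return data.frame: `gene_id`, `element_name`, `strand`, `start`, `end`,
#'   `matched_seq`
#' @export
scan_elements <- function(promoter, elements, both_strands = TRUE) {
  s <- if (inherits(promoter, "tlp_seqs")) unclass(promoter)[[1]] else toupper(promoter)
  gid <- if (inherits(promoter, "tlp_seqs")) names(promoter)[1] else NA_character_
  subj <- Biostrings::DNAString(s)
  rows <- list()
  for (i in seq_len(nrow(elements))) {
    pat <- Biostrings::DNAString(elements$iupac_pattern[i])
    m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
    if (length(m) > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, element_name = elements$name[i], strand = "+",
        start = Biostrings::start(m), end = Biostrings::end(m),
        matched_seq = as.character(m), stringsAsFactors = FALSE)
    }
    if (both_strands) {
      mr <- Biostrings::matchPattern(Biostrings::reverseComplement(pat), subj,
                                     fixed = FALSE)
      if (length(mr) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gid, element_name = elements$name[i], strand = "-",
          start = Biostrings::start(mr), end = Biostrings::end(mr),
          matched_seq = vapply(as.character(mr), revcomp, character(1),
                               USE.NAMES = FALSE),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(gene_id = character(0), element_name = character(0),
                      strand = character(0), start = integer(0), end = integer(0),
                      matched_seq = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$element_name, out$strand), , drop = FALSE]
}

#' Count element hits per gene and functional category
#'
#' Each hit is counted under its element's category; the four categories
#' are growth and development, light, hormone, and stress response.
#'
#' @param hits data.frame of hits (from [scan_elements()], possibly several
#'   genes row-bound)
#' @param elements element table
#' @return data.frame: `gene_id`, `growth_development`, `light`, `hormone`,
#'   `stress`
#' @export
categorize_hits <- function(hits, elements) {
  cats <- c("growth_development", "light", "hormone", "stress")
  cat_of <- stats::setNames(elements$category, elements$name)
  genes <- unique(hits$gene_id)
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (cc in cats) out[[cc]] <- integer(length(genes))
  for (i in seq_len(nrow(hits))) {
    cc <- cat_of[[hits$element_name[i]]]
    r <- match(hits$gene_id[i], genes)
    out[r, cc] <- out[r, cc] + 1L
  }
  out
}
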