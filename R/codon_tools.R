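# Codon-level utilities shared by the Ka/Ks estimator and the simulator.
# The standard genetic code is taken from Biostrings::GENETIC_CODE.

genetic_code <- function() {
  gc <- .tlpfam_cache$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE
    .tlpfam_cache$genetic_code <- gc
  }
  gc
}

is_stop_codon <- function(codon) genetic_code()[codon] == "*"

#' Translate a CDS under the standard genetic code
#' @param cds nucleotide string, length a multiple of 3
#' @param strip_terminal_stop drop a trailing stop codon before translating
#' @return protein string (`*` would indicate an internal stop; an error is
#'   raised instead)
#' @export
translate_cds <- function(cds, strip_terminal_stop = TRUE) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3 != 0) stop_tlp("CDS length not a multiple of 3")
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  aa <- genetic_code()[codons]
  if (anyNA(aa)) {
    # codons containing N translate to X
    aa[is.na(aa)] <- "X"
  }
  if (strip_terminal_stop && length(aa) > 0 && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
  }
  if (any(aa == "*")) {
    stop_tlp("internal stop codon at codon ", which(aa == "*")[1])
  }
  paste(aa, collapse = "")
}

split_codons <- function(cds) {
  substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
}

#' Back-translate a protein alignment to a codon alignment
#'
#' Each aligned protein column maps to one codon column; protein gaps become
#' `---` gap codons (PAL2NAL-style). Every CDS must translate exactly to its
#' degapped protein under the standard code (a trailing stop codon is
#' stripped first).
#'
#' @param protein_alignment aligned protein [tlp_seqs] (gaps as `-`)
#' @param cds_records unaligned CDS [tlp_seqs] with matching ids
#' @return a `codon_alignment`: list with `ids` and `codon_columns` (a
#'   character matrix, sequences x columns, entries are codons or `---`)
#' @export
backtranslate <- function(protein_alignment, cds_records) {
  ids <- names(protein_alignment)
  if (!all(ids %in% names(cds_records))) {
    stop_tlp("CDS missing for: ",
             paste(setdiff(ids, names(cds_records)), collapse = ", "))
  }
  ncol_aln <- unique(nchar(unclass(protein_alignment)))
  if (length(ncol_aln) != 1) stop_tlp("protein alignment rows differ in length")
  mat <- matrix("---", nrow = length(ids), ncol = ncol_aln,
                dimnames = list(ids, NULL))
  for (id in ids) {
    prot_aln <- unclass(protein_alignment)[[id]]
    prot <- gsub("-", "", prot_aln, fixed = TRUE)
    cds <- toupper(unclass(cds_records)[[id]])
    if (nchar(cds) == 3 * nchar(prot) + 3) {
      last <- substr(cds, nchar(cds) - 2, nchar(cds))
      if (!isTRUE(is_stop_codon(last))) {
        stop_tlp(id, ": CDS length suggests a trailing stop codon but '",
                 last, "' is not one")
      }
      cds <- substr(cds, 1, nchar(cds) - 3)
    }
    if (nchar(cds) != 3 * nchar(prot)) {
      stop_tlp(id, ": CDS length ", nchar(cds), " does not match protein length ",
               nchar(prot))
    }
    codons <- split_codons(cds)
    aa <- genetic_code()[codons]
    aa[is.na(aa)] <- "X"
    mism <- which(aa != chars(prot) & chars(prot) != "X" & aa != "X")
    if (any(aa == "*")) stop_tlp(id, ": internal stop codon at codon ", which(aa == "*")[1])
    if (length(mism) > 0) {
      stop_tlp(id, ": translation mismatch at codon ", mism[1],
               " (", codons[mism[1]], " -> ", aa[mism[1]], ", protein has ",
               substr(prot, mism[1], mism[1]), ")")
    }
    cols <- which(chars(prot_aln) != "-")
    mat[id, cols] <- codons
  }
  structure(list(ids = ids, codon_columns = mat), class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("codon_alignment: %d sequence(s) x %d codon column(s)\n",
              length(x$ids), ncol(x$codon_columns)))
  invisible(x)
}

#' Degap one sequence of a codon alignment back to its CDS
#' @param alignment a `codon_alignment`
#' @param id sequence id
#' @return CDS string without gaps
#' @export
degap_codons <- function(alignment, id) {
  row <- alignment$codon_columns[id, ]
  paste(row[row != "---"], collapse = "")
}
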