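# Reference-anchored three-way protein alignment.
#
# Full multiple alignment is delegated to external aligners in real
# analyses; for the relative-rate test over one duplicate pair plus an
# outgroup, two global pairwise alignments (A-B and A-outgroup, both via
# Biostrings::pairwiseAlignment with BLOSUM62/affine gaps) are merged on
# the shared coordinate system of A. Columns where A is gapped in one
# pairwise alignment are interleaved as gap columns for the third sequence.

.aligned_pair_chars <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  list(a = chars(as.character(Biostrings::alignedPattern(aln))),
       b = chars(as.character(Biostrings::alignedSubject(aln))))
}

#' Align a protein pair plus outgroup through a shared reference
#'
#' @param a,b,outgroup protein strings (or single-record [tlp_seqs])
#' @return named character vector of three equal-length aligned sequences
#'   (`a`, `b`, `outgroup`)
#' @export
align_triple <- function(a, b, outgroup) {
  get1 <- function(x) if (inherits(x, "tlp_seqs")) unclass(x)[[1]] else toupper(x)
  sa <- get1(a); sb <- get1(b); so <- get1(outgroup)
  ab <- .aligned_pair_chars(sa, sb)
  ao <- .aligned_pair_chars(sa, so)
  # walk both alignments in step over positions of A
  i <- 1L; j <- 1L
  col_a <- character(0); col_b <- character(0); col_o <- character(0)
  na_ab <- length(ab$a); na_ao <- length(ao$a)
  while (i <= na_ab || j <= na_ao) {
    gap_ab <- i <= na_ab && ab$a[i] == "-"
    gap_ao <- j <= na_ao && ao$a[j] == "-"
    if (gap_ab) {            # B has residues against a gap in A
      col_a <- c(col_a, "-"); col_b <- c(col_b, ab$b[i]); col_o <- c(col_o, "-")
      i <- i + 1L
    } else if (gap_ao) {     # outgroup has residues against a gap in A
      col_a <- c(col_a, "-"); col_b <- c(col_b, "-"); col_o <- c(col_o, ao$b[j])
      j <- j + 1L
    } else {                 # both alignments sit on the same A residue
      col_a <- c(col_a, ab$a[i]); col_b <- c(col_b, ab$b[i]); col_o <- c(col_o, ao$b[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  c(a = paste(col_a, collapse = ""), b = paste(col_b, collapse = ""),
    outgroup = paste(col_o, collapse = ""))
}
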