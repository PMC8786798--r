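# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a DNA string
#' @param x character scalar over A,C,G,T,N (IUPAC codes allowed).
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# split a string into single characters
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

stop_tlp <- function(...) stop(..., call. = FALSE)

# round-half-up at d decimals (report parity with tables printed by spreadsheet
# software, which round 0.125 -> 0.13 rather than to even)
round_half_up <- function(x, d = 0) floor(x * 10^d + 0.5) / 10^d

#' Write a data.frame as a UTF-8 TSV with header
#' @param df data.frame
#' @param path output path
#' @return invisibly, `path`
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a UTF-8 TSV with header
#' @param path input path
#' @return data.frame
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}
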