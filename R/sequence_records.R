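#' Sequence record collections
#'
#' A `tlp_seqs` object is a named character vector of uppercase residues with
#' an `alphabet` attribute (`"protein"` or `"dna"`) and a parallel
#' `descriptions` attribute. Protein records may use the 20 standard amino
#' acids plus `X` (unknown); DNA records use `ACGT` plus `N`. Aligned
#' sequences may additionally contain `-` gaps when created with
#' `aligned = TRUE`.
#'
#' @param residues character vector of sequences
#' @param ids unique record identifiers
#' @param alphabet `"protein"` or `"dna"`
#' @param descriptions optional FASTA description strings (sans id)
#' @param aligned allow `-` gap characters
#' @return a `tlp_seqs` object
#' @export
tlp_seqs <- function(residues, ids = names(residues), alphabet = c("protein", "dna"),
                     descriptions = NULL, aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (is.null(ids)) stop_tlp("sequence records need ids")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop_tlp("duplicate sequence id: ", ids[duplicated(ids)][1])
  }
  residues <- toupper(as.character(residues))
  if (any(!nzchar(residues))) stop_tlp("empty sequence for id ", ids[!nzchar(residues)][1])
  legal <- if (alphabet == "protein") "ACDEFGHIKLMNPQRSTVWYX" else "ACGTN"
  if (aligned) legal <- paste0(legal, "-")
  bad <- regexpr(sprintf("[^%s]", legal), residues)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    stop_tlp("illegal ", alphabet, " character '",
             substr(residues[i], bad[i], bad[i]), "' in '", ids[i],
             "' at position ", bad[i])
  }
  if (is.null(descriptions)) descriptions <- rep("", length(residues))
  structure(stats::setNames(residues, ids), class = "tlp_seqs",
            alphabet = alphabet,
            descriptions = stats::setNames(as.character(descriptions), ids))
}

#' @export
print.tlp_seqs <- function(x, ...) {
  cat(sprintf("tlp_seqs: %d %s record(s)\n", length(x), attr(x, "alphabet")))
  n <- min(length(x), 6L)
  for (i in seq_len(n)) {
    s <- unclass(x)[[i]]
    cat(sprintf("  %-20s %5d aa/nt  %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > n) cat("  ...\n")
  invisible(x)
}

#' @export
`[.tlp_seqs` <- function(x, i) {
  out <- unclass(x)[i]
  if (anyNA(names(out))) stop_tlp("unknown sequence id")
  structure(out, class = "tlp_seqs", alphabet = attr(x, "alphabet"),
            descriptions = attr(x, "descriptions")[names(out)])
}

#' Read a FASTA file into a `tlp_seqs` collection
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; records are
#' validated against the declared alphabet, uppercased, and must have unique
#' ids (the first whitespace-delimited token of each header).
#'
#' @param path FASTA file
#' @param alphabet `"protein"` or `"dna"`
#' @param aligned allow gap characters (aligned FASTA)
#' @return a [tlp_seqs] object (empty file gives a zero-length collection)
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"), aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_tlp("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    return(tlp_seqs(character(0), character(0), alphabet))
  }
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  tlp_seqs(as.character(set), ids, alphabet, descriptions = desc, aligned = aligned)
}

#' Write a `tlp_seqs` collection as FASTA (wrapped at 60 columns)
#' @param seqs a [tlp_seqs] object
#' @param path output path
#' @return invisibly, `path`
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  desc <- attr(seqs, "descriptions")
  for (id in names(seqs)) {
    hdr <- if (nzchar(desc[[id]])) paste(id, desc[[id]]) else id
    writeLines(paste0(">", hdr), con)
    s <- unclass(seqs)[[id]]
    starts <- seq(1, nchar(s), by = 60)
    writeLines(substring(s, starts, pmin(starts + 59, nchar(s))), con)
  }
  invisible(path)
}
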