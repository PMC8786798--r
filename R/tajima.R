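#' Upper-tail probability of the chi-square distribution
#'
#' Thin wrapper over [stats::pchisq()] (`lower.tail = FALSE`); for one
#' degree of freedom this equals `erfc(sqrt(x/2))`.
#'
#' @param x non-negative statistic
#' @param df degrees of freedom (default 1)
#' @return upper-tail probability
#' @export
chi2_sf <- function(x, df = 1) {
  if (any(x < 0)) stop_tlp("chi-square statistic must be non-negative")
  stats::pchisq(x, df = df, lower.tail = FALSE)
}

#' Tajima's relative-rate test
#'
#' Compares the substitution rates of two lineages A and B against an
#' outgroup. Alignment columns are classified as: identical in all three
#' (`nt`); A differs while B equals the outgroup (`na`); B differs while A
#' equals the outgroup (`nb`); columns where all three differ, or where
#' A = B differ from the outgroup, count toward none (Tajima 1993
#' convention). The statistic is `chi2 = (na - nb)^2 / (na + nb)` on 1 df;
#' `p = 1` when `na + nb = 0`. Non-rejection is consistent with a molecular
#' clock. Columns containing a gap, `N` (nucleotide mode) or `X`
#' (amino-acid mode) in any sequence are skipped.
#'
#' @param a,b,outgroup aligned sequences of equal length (strings or
#'   single-record [tlp_seqs]); either nucleotide or protein, per `mode`
#' @param mode `"nucleotide"` or `"amino_acid"` (controls which ambiguity
#'   letter is skipped)
#' @return a `tajima_result` list: `nt`, `na`, `nb`, `chi2`, `p`,
#'   `sites_used`
#' @export
tajima_relative_rate <- function(a, b, outgroup, mode = c("nucleotide", "amino_acid")) {
  mode <- match.arg(mode)
  get1 <- function(x) if (inherits(x, "tlp_seqs")) unclass(x)[[1]] else toupper(x)
  sa <- get1(a); sb <- get1(b); so <- get1(outgroup)
  if (length(unique(nchar(c(sa, sb, so)))) != 1) {
    stop_tlp("sequences must be aligned to equal lengths")
  }
  va <- chars(sa); vb <- chars(sb); vo <- chars(so)
  amb <- if (mode == "nucleotide") c("-", "N") else c("-", "X")
  keep <- !(va %in% amb | vb %in% amb | vo %in% amb)
  va <- va[keep]; vb <- vb[keep]; vo <- vo[keep]
  nt <- sum(va == vb & vb == vo)
  na_ <- sum(va != vb & vb == vo)
  nb_ <- sum(vb != va & va == vo)
  chi2 <- if (na_ + nb_ > 0) (na_ - nb_)^2 / (na_ + nb_) else 0
  p <- if (na_ + nb_ == 0 || chi2 == 0) 1 else chi2_sf(chi2, df = 1)
  structure(list(nt = nt, na = na_, nb = nb_, chi2 = chi2, p = p,
                 sites_used = length(va)),
            class = "tajima_result")
}

#' @export
print.tajima_result <- function(x, ...) {
  cat(sprintf("Tajima relative-rate test: Nt=%d Na=%d Nb=%d  chi2=%.2f  P=%.5f\n",
              x$nt, x$na, x$nb, x$chi2, x$p))
  invisible(x)
}

#' Flatten a codon alignment to aligned nucleotide strings
#' @param alignment a `codon_alignment`
#' @return named character vector of aligned nucleotide sequences
#' @export
flatten_codon_alignment <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  vapply(alignment$ids, function(id) {
    paste(alignment$codon_columns[id, ], collapse = "")
  }, character(1))
}
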