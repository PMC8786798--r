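# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction.
#
# Synonymous site fractions: at each codon position the three alternative
# nucleotides are examined; alternatives creating a stop codon are excluded
# from both numerator and denominator (PAML convention), and the position's
# synonymous fraction is (#synonymous)/(#non-stop alternatives). A codon's
# synonymous site count S is the sum of its three fractions; N = 3 - S.
#
# Observed differences: for codons differing at 1-3 positions, all minimal
# mutational pathways (orderings of the differing positions) are averaged
# with equal weight; pathways passing through a stop codon are excluded.
# In the degenerate case where every pathway passes through a stop, all
# pathways are used (so the codon still contributes its differences).

.nt <- c("A", "C", "G", "T")

.codon_site_table <- function() {
  tab <- .tlpfam_cache$site_table
  if (!is.null(tab)) return(tab)
  gc <- genetic_code()
  codons <- names(gc)[gc != "*"]
  syn <- vapply(codons, function(cd) {
    s <- 0
    for (pos in 1:3) {
      alts <- setdiff(.nt, substr(cd, pos, pos))
      alt_cd <- vapply(alts, function(n) {
        x <- cd; substr(x, pos, pos) <- n; x
      }, character(1))
      valid <- gc[alt_cd] != "*"
      if (any(valid)) s <- s + sum(gc[alt_cd[valid]] == gc[cd]) / sum(valid)
    }
    s
  }, numeric(1))
  tab <- cbind(S = syn, N = 3 - syn)
  rownames(tab) <- codons
  .tlpfam_cache$site_table <- tab
  tab
}

# average (syn, nonsyn) differences between two codons over minimal pathways
.codon_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(0, 0))
  key <- paste(sort(c(c1, c2)), collapse = "|")
  memo <- .tlpfam_cache$pair_memo
  if (is.null(memo)) {
    memo <- new.env(parent = emptyenv())
    .tlpfam_cache$pair_memo <- memo
  }
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  pos_diff <- which(chars(c1) != chars(c2))
  orders <- if (length(pos_diff) == 1) list(pos_diff) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
      }
      out
    }
    perms(pos_diff)
  }
  path_counts <- list(); path_valid <- logical(0)
  for (ord in orders) {
    cur <- c1; sd <- 0; nd <- 0; valid <- TRUE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (gc[nxt] == "*" && nxt != c2) valid <- FALSE  # stop intermediate
      if (identical(gc[[cur]], gc[[nxt]])) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1L]] <- c(sd, nd)
    path_valid <- c(path_valid, valid)
  }
  use <- if (any(path_valid)) path_counts[path_valid] else path_counts
  res <- Reduce(`+`, use) / length(use)
  memo[[key]] <- res
  res
}

#' Nei-Gojobori (1986) Ka/Ks for a pairwise codon alignment
#'
#' Synonymous (Ks) and non-synonymous (Ka) substitutions per respective
#' site, with equal-weight averaging over all minimal mutational pathways
#' (stop-codon pathways excluded) and Jukes-Cantor multiple-hit correction
#' `d = -(3/4) ln(1 - (4/3) p)`. Codon columns containing a gap, `N`, or a
#' stop codon in either sequence are skipped and do not count as usable.
#'
#' @param alignment a `codon_alignment` with exactly two sequences (from
#'   [backtranslate()]), or `NULL` if `cds_a`/`cds_b` are given
#' @param cds_a,cds_b alternatively, two equal-length gap-free CDS strings
#'   already aligned codon-by-codon
#' @return a `kaks_result` list: `ka`, `ks` (NA when saturated), `omega`
#'   (NA when `ks` is 0 or saturated), `selection`, `usable_codons`,
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `saturated_ka`, `saturated_ks`
#' @export
ng86_kaks <- function(alignment = NULL, cds_a = NULL, cds_b = NULL) {
  if (!is.null(alignment)) {
    stopifnot(inherits(alignment, "codon_alignment"))
    if (length(alignment$ids) != 2) stop_tlp("pairwise alignment required")
    ca <- alignment$codon_columns[1, ]
    cb <- alignment$codon_columns[2, ]
  } else {
    if (nchar(cds_a) != nchar(cds_b)) stop_tlp("aligned CDS must have equal length")
    ca <- split_codons(toupper(cds_a))
    cb <- split_codons(toupper(cds_b))
  }
  gc <- genetic_code()
  usable <- ca %in% rownames(.codon_site_table()) & cb %in% rownames(.codon_site_table())
  ca <- ca[usable]; cb <- cb[usable]
  if (length(ca) == 0) stop_tlp("zero usable codons")
  st <- .codon_site_table()
  S <- (sum(st[ca, "S"]) + sum(st[cb, "S"])) / 2
  N <- (sum(st[ca, "N"]) + sum(st[cb, "N"])) / 2
  d <- vapply(seq_along(ca), function(i) .codon_pair_diffs(ca[i], cb[i]), numeric(2))
  sd_ <- sum(d[1, ]); nd_ <- sum(d[2, ])
  ps <- if (S > 0) sd_ / S else 0
  pn <- if (N > 0) nd_ / N else 0
  jc <- function(p) if (p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  structure(list(
    ka = ka, ks = ks, omega = omega,
    selection = if (is.na(omega)) NA_character_ else classify_selection(omega),
    usable_codons = length(ca),
    syn_sites = S, nonsyn_sites = N, syn_diffs = sd_, nonsyn_diffs = nd_,
    saturated_ks = ps >= 3 / 4, saturated_ka = pn >= 3 / 4
  ), class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("NG86: Ka = %s, Ks = %s, Ka/Ks = %s (%s), %d usable codons\n",
              format(x$ka, digits = 4), format(x$ks, digits = 4),
              format(x$omega, digits = 4),
              ifelse(is.na(x$selection), "undefined", x$selection),
              x$usable_codons))
  if (x$saturated_ks || x$saturated_ka) cat("  [saturated: JC correction undefined]\n")
  invisible(x)
}

#' Selection-pressure call from omega
#' @param omega Ka/Ks ratio
#' @return `"purifying"` (< 1), `"neutral"` (= 1) or `"positive"` (> 1)
#' @export
classify_selection <- function(omega) {
  stopifnot(is.finite(omega))
  if (omega < 1) "purifying" else if (omega > 1) "positive" else "neutral"
}

#' Divergence time from the synonymous clock
#'
#' `T = Ks / (2 r)`, with the grass synonymous substitution rate of
#' 6.5e-9 substitutions/site/year by default, reported in million years
#' (MYA).
#'
#' @param ks synonymous substitutions per synonymous site
#' @param rate_r substitution rate per site per year
#' @return list: `t_mya` (full precision), `t_mya_1dp` (report rounding),
#'   `rate_r`
#' @export
divergence_time <- function(ks, rate_r = 6.5e-9) {
  if (is.na(ks)) stop_tlp("ks is undefined (saturated?)")
  if (ks < 0) stop_tlp("negative ks")
  t <- ks / (2 * rate_r) / 1e6
  list(t_mya = t, t_mya_1dp = round_half_up(t, 1), rate_r = rate_r)
}
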