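# Average (isotope-averaged) residue masses in Da, ExPASy-style, i.e. the
# amino acid mass minus one water; a peptide's mass is the residue sum plus
# one water (18.0153 Da).
.residue_mass <- c(
  G = 57.0519,  A = 71.0788,  S = 87.0782,  P = 97.1167,  V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.water_mass <- 18.0153

# Bjellqvist/"ExPASy-style" pKa set
.pka <- list(nterm = 7.5, cterm = 3.55,
             D = 4.05, E = 4.45, C = 9.0, Y = 10.0,   # acidic side chains
             H = 5.98, K = 10.0, R = 12.0)            # basic side chains

#' Molecular weight of a protein (kDa)
#'
#' Sum of average residue masses plus one water, divided by 1000. Unknown
#' residues (`X`) contribute the mean residue mass of the 20 standard amino
#' acids and raise a warning.
#'
#' @param protein single-record protein [tlp_seqs] or plain string
#' @return molecular weight in kDa
#' @export
compute_mw <- function(protein) {
  s <- if (inherits(protein, "tlp_seqs")) unclass(protein)[[1]] else toupper(protein)
  if (!nzchar(s)) stop_tlp("empty sequence")
  aa <- chars(s)
  nx <- sum(aa == "X")
  if (nx > 0) {
    warning("sequence contains ", nx, " unknown residue(s); mean residue mass used")
  }
  masses <- .residue_mass[aa]
  masses[is.na(masses)] <- mean(.residue_mass)
  (sum(masses) + .water_mass) / 1000
}

# net charge at a given pH under Henderson-Hasselbalch
.net_charge <- function(counts, pH) {
  pos <- c(nterm = 1, K = counts[["K"]], R = counts[["R"]], H = counts[["H"]])
  pka_pos <- c(.pka$nterm, .pka$K, .pka$R, .pka$H)
  neg <- c(cterm = 1, D = counts[["D"]], E = counts[["E"]],
           C = counts[["C"]], Y = counts[["Y"]])
  pka_neg <- c(.pka$cterm, .pka$D, .pka$E, .pka$C, .pka$Y)
  sum(pos / (1 + 10^(pH - pka_pos))) - sum(neg / (1 + 10^(pka_neg - pH)))
}

#' Isoelectric point of a protein
#'
#' The pH at which the Henderson-Hasselbalch net charge vanishes, using the
#' Bjellqvist ("ExPASy-style") pKa set (N-terminus 7.5, C-terminus 3.55;
#' D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0), found by
#' bisection on \[0, 14\] to |charge| < 1e-4.
#'
#' @param protein single-record protein [tlp_seqs] or plain string
#' @return pI (pH units)
#' @export
compute_pi <- function(protein) {
  s <- if (inherits(protein, "tlp_seqs")) unclass(protein)[[1]] else toupper(protein)
  if (!nzchar(s)) stop_tlp("empty sequence")
  aa <- chars(s)
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(aa == a), numeric(1))
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- .net_charge(as.list(counts), mid)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Physicochemical profile of a protein
#' @param protein single-record protein [tlp_seqs] or plain string
#' @param id optional identifier for the report row
#' @return data.frame row: `id`, `length_aa`, `mw_kda`, `pi`, `cysteine_count`
#' @export
physicochemical_profile <- function(protein, id = NULL) {
  s <- if (inherits(protein, "tlp_seqs")) unclass(protein)[[1]] else toupper(protein)
  if (is.null(id)) id <- if (inherits(protein, "tlp_seqs")) names(protein)[1] else NA_character_
  data.frame(id = id, length_aa = nchar(s),
             mw_kda = suppressWarnings(compute_mw(s)),
             pi = compute_pi(s),
             cysteine_count = sum(chars(s) == "C"),
             stringsAsFactors = FALSE)
}

#' Classify a TLP as long or small
#'
#' Long (L-type) and small (S-type) TLPs have disjoint thaumatin-domain
#' length ranges (roughly 202-217 vs 134-154 residues), whereas their mature
#' vs full-protein molecular weights overlap once signal peptides are
#' counted. Classification is therefore primarily on domain length
#' (>= 180 aa: long) with molecular weight as a secondary guard for the
#' small class (< 180 aa AND < 22 kDa: small); anything else is flagged
#' `ambiguous` rather than silently assigned.
#'
#' @param mw_kda full-protein molecular weight (kDa)
#' @param domain_len_aa thaumatin-domain length (aa)
#' @return list: `size_class` (`"long"`, `"small"`, `"ambiguous"`),
#'   `basis_mw_kda`, `basis_domain_len_aa`
#' @export
classify_size <- function(mw_kda, domain_len_aa) {
  if (domain_len_aa <= 0) stop_tlp("domain length must be positive")
  cls <- if (domain_len_aa >= 180) "long"
         else if (mw_kda < 22) "small"
         else "ambiguous"
  list(size_class = cls, basis_mw_kda = mw_kda,
       basis_domain_len_aa = as.integer(domain_len_aa))
}

#' Check the REDDD motif against a reference alignment
#'
#' The REDDD motif is five acidic-cleft residues (R, E, D, D, D) conserved in
#' most TLPs and implicated in receptor binding/antifungal action. Given an
#' alignment containing both the query and a reference thaumatin for which
#' the five REDDD columns are annotated, the query's residues at those
#' columns are reported; the motif is `present` iff they read exactly
#' R, E, D, D, D, otherwise the substitutions (expected, observed; `-` for a
#' gapped column) are listed.
#'
#' @param query_id id of the query in the alignment
#' @param alignment an aligned protein [tlp_seqs] (gaps as `-`)
#' @param reddd_columns integer vector of 5 alignment columns
#' @return list: `present`, `residues_found` (data.frame column/residue),
#'   `substitutions` (data.frame expected/observed)
#' @export
check_reddd <- function(query_id, alignment, reddd_columns) {
  stopifnot(length(reddd_columns) == 5L)
  if (!query_id %in% names(alignment)) {
    stop_tlp("query '", query_id, "' missing from alignment")
  }
  s <- unclass(alignment)[[query_id]]
  expected <- c("R", "E", "D", "D", "D")
  observed <- vapply(reddd_columns, function(cl) substr(s, cl, cl), character(1))
  subs <- data.frame(expected = expected[observed != expected],
                     observed = observed[observed != expected],
                     stringsAsFactors = FALSE)
  list(present = all(observed == expected),
       residues_found = data.frame(alignment_column = as.integer(reddd_columns),
                                   residue = observed, stringsAsFactors = FALSE),
       substitutions = subs)
}
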