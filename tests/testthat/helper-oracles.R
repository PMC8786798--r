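# Independent oracles, deliberately written with different strategies than
# the package implementations they check.

# ---- PROSITE-style motif scan: exhaustive run-length enumeration ----------

# the thaumatin signature, hard-coded as position predicates; run lengths
# enumerated exhaustively in the same (run1, run2) priority order the
# matcher documents (earlier runs take shorter expansions first)
oracle_scan_signature <- function(s) {
  n <- nchar(s)
  ch <- strsplit(s, "")[[1]]
  fixed_ok <- function(c, spec) {
    if (spec == ".") c != "X" else c %in% strsplit(spec, "")[[1]]
  }
  head_spec <- c("G", ".", "GF", ".", "C", ".", "T", "GA", "D", "C")
  hits <- NULL
  for (start in seq_len(n)) {
    found_end <- NA
    for (r1 in 1:2) {
      for (r2 in 2:3) {
        len <- 10 + r1 + 1 + r2 + 1
        if (start + len - 1 > n) next
        w <- ch[start:(start + len - 1)]
        ok <- TRUE
        for (i in 1:10) if (!fixed_ok(w[i], head_spec[i])) { ok <- FALSE; break }
        if (ok) {
          run1 <- w[11:(10 + r1)]
          gpos <- 10 + r1 + 1
          run2 <- w[(gpos + 1):(gpos + r2)]
          ok <- all(run1 != "X") && w[gpos] == "G" && all(run2 != "X") &&
            w[len] == "C"
        }
        if (ok) { found_end <- start + len - 1; break }
      }
      if (!is.na(found_end)) break
    }
    if (!is.na(found_end)) {
      hits <- rbind(hits, data.frame(start = start, end = found_end))
    }
  }
  hits
}

# ---- IUPAC element scan: per-position set membership ----------------------

iupac_sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                   Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
                   K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                   D = c("A", "G", "T"), H = c("A", "C", "T"),
                   V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracle_iupac_hits <- function(seq, pattern) {
  s <- strsplit(seq, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  w <- length(p)
  starts <- integer(0)
  for (i in seq_len(nchar(seq) - w + 1)) {
    ok <- TRUE
    for (j in seq_len(w)) {
      if (!(s[i + j - 1] %in% iupac_sets[[p[j]]])) { ok <- FALSE; break }
    }
    if (ok) starts <- c(starts, i)
  }
  starts
}

oracle_revcomp <- function(x) {
  paste(rev(chartr("ACGTRYWSKMBDHVN", "TGCAYRWSMKVHDBN",
                   strsplit(x, "")[[1]])), collapse = "")
}

# ---- global alignment: Gotoh affine-gap DP (score only) -------------------

oracle_nw_score <- function(a, b, gap_open = 10, gap_ext = 0.5) {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  sub <- BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - gap_ext * (i - 1)
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - gap_ext * (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_ext, X[i - 1, j] - gap_ext)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_ext, Y[i, j - 1] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# ---- NG86: slow explicit pathway enumeration ------------------------------

oracle_ng86 <- function(cds_a, cds_b) {
  code <- as.list(Biostrings::GENETIC_CODE)
  codons_a <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  codons_b <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  nts <- c("A", "C", "G", "T")
  site_count <- function(cd) {
    s <- 0
    for (pos in 1:3) {
      orig <- substr(cd, pos, pos)
      n_syn <- 0; n_valid <- 0
      for (nt in setdiff(nts, orig)) {
        alt <- cd; substr(alt, pos, pos) <- nt
        if (code[[alt]] == "*") next
        n_valid <- n_valid + 1
        if (code[[alt]] == code[[cd]]) n_syn <- n_syn + 1
      }
      if (n_valid > 0) s <- s + n_syn / n_valid
    }
    c(S = s, N = 3 - s)
  }
  # all mutational pathways by recursive graph walk (not permutation lists)
  walk_paths <- function(cur, target) {
    if (cur == target) return(list(c(syn = 0, non = 0, stop = 0)))
    out <- list()
    for (pos in 1:3) {
      if (substr(cur, pos, pos) != substr(target, pos, pos)) {
        nxt <- cur; substr(nxt, pos, pos) <- substr(target, pos, pos)
        step_syn <- identical(code[[cur]], code[[nxt]])
        for (tail in walk_paths(nxt, target)) {
          out[[length(out) + 1L]] <- c(
            syn = tail[["syn"]] + as.numeric(step_syn),
            non = tail[["non"]] + as.numeric(!step_syn),
            stop = (code[[nxt]] == "*" && nxt != target) ||
              isTRUE(tail[["stop"]] > 0))
        }
      }
    }
    out
  }
  S <- 0; N <- 0; sd <- 0; nd <- 0; usable <- 0
  for (k in seq_along(codons_a)) {
    ca <- codons_a[k]; cb <- codons_b[k]
    skip <- grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb) ||
      code[[ca]] == "*" || code[[cb]] == "*"
    if (skip) next
    usable <- usable + 1
    S <- S + (site_count(ca)[["S"]] + site_count(cb)[["S"]]) / 2
    N <- N + (site_count(ca)[["N"]] + site_count(cb)[["N"]]) / 2
    if (ca != cb) {
      paths <- walk_paths(ca, cb)
      good <- Filter(function(p) !(p[["stop"]] > 0), paths)
      if (length(good) == 0) good <- paths
      sd <- sd + mean(vapply(good, `[[`, 0, "syn"))
      nd <- nd + mean(vapply(good, `[[`, 0, "non"))
    }
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(nd / N), ks = jc(sd / S), usable = usable,
       S = S, N = N, sd = sd, nd = nd)
}

# ---- molecular weight: independently re-typed mass table ------------------

oracle_mw_kda <- function(s) {
  mass <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
            E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
            L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
            S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  (sum(mass[strsplit(s, "")[[1]]]) + 18.0153) / 1000
}

# ---- equal-variance two-sample t-test: textbook formula -------------------

oracle_ttest_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tstat), df = nx + ny - 2)
}

# ---- shared fixtures ------------------------------------------------------

random_protein <- function(n, with_x = FALSE) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (with_x) aa <- c(aa, "X")
  paste(sample(aa, n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

write_fasta_text <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id)
    c(paste0(">", id), records[[id]]))), path)
  path
}
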