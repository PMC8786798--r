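#' Motif definitions in PROSITE-like syntax
#'
#' A pattern is a dash-separated list of position specifications:
#' a fixed residue (`G`), the wildcard `X`, a residue set (`[GF]`), or a
#' variable-length wildcard run (`X(1,2)`; `X(2)` means exactly two). At
#' least one fixed position is required.
#'
#' @param pattern PROSITE-like pattern string,
#'   e.g. `"G-X-[GF]-X-C-X-T-[GA]-D-C-X(1,2)-G-X(2,3)-C"`
#' @param name motif name
#' @return a `motif_definition` object
#' @export
motif_definition <- function(pattern, name = "motif") {
  toks <- strsplit(gsub("\\s", "", pattern), "-", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0) stop_tlp("empty motif pattern")
  elems <- lapply(toks, function(t) {
    if (grepl("^[A-WY]$", t)) {
      list(type = "fixed", residue = t)
    } else if (t == "X") {
      list(type = "any")
    } else if (grepl("^\\[[A-Y]+\\]$", t)) {
      list(type = "set", residues = chars(gsub("\\[|\\]", "", t)))
    } else if (grepl("^X\\([0-9]+(,[0-9]+)?\\)$", t)) {
      nums <- as.integer(strsplit(gsub("X\\(|\\)", "", t), ",")[[1]])
      mn <- nums[1]; mx <- if (length(nums) == 2) nums[2] else nums[1]
      if (mn > mx) stop_tlp("variable run with min > max: ", t)
      list(type = "run", min = mn, max = mx)
    } else {
      stop_tlp("cannot parse motif element: '", t, "'")
    }
  })
  if (!any(vapply(elems, function(e) e$type %in% c("fixed", "set"), TRUE))) {
    stop_tlp("motif needs at least one fixed position")
  }
  structure(list(name = name, pattern = pattern, elements = elems),
            class = "motif_definition")
}

#' The thaumatin family signature motif
#'
#' The PROSITE-style consensus diagnostic of thaumatin-like proteins:
#' `G-X-[GF]-X-C-X-T-[GA]-D-C-X(1,2)-G-X(2,3)-C`.
#' @return a [motif_definition]
#' @export
thaumatin_signature <- function() {
  motif_definition("G-X-[GF]-X-C-X-T-[GA]-D-C-X(1,2)-G-X(2,3)-C",
                   name = "thaumatin_signature")
}

# try to match `elems` starting at `pos`; variable runs take the SHORTEST
# satisfying expansion (non-greedy, tried in increasing length with
# backtracking). Returns end position or NA.
.match_from <- function(s, n, elems, i, pos) {
  if (i > length(elems)) return(pos - 1L)
  e <- elems[[i]]
  if (e$type == "run") {
    for (len in e$min:e$max) {
      if (pos + len - 1L > n) break
      if (len > 0 && grepl("X", substr(s, pos, pos + len - 1L), fixed = TRUE)) break
      r <- .match_from(s, n, elems, i + 1L, pos + len)
      if (!is.na(r)) return(r)
    }
    return(NA_integer_)
  }
  if (pos > n) return(NA_integer_)
  ch <- substr(s, pos, pos)
  ok <- switch(e$type,
               fixed = ch == e$residue,
               any   = ch != "X",       # unknown residues satisfy no position
               set   = ch %in% e$residues)
  if (!ok) return(NA_integer_)
  .match_from(s, n, elems, i + 1L, pos + 1L)
}

#' Scan a protein for a signature motif
#'
#' Every start position admitting a complete match is reported; at each
#' start, variable-length runs take their shortest satisfying expansion
#' (non-greedy PROSITE semantics), which fixes the reported end coordinate
#' but not hit existence. Overlapping hits at distinct starts are allowed.
#' Unknown residues (`X`) never satisfy any pattern position, including
#' wildcards.
#'
#' @param protein a single-record protein [tlp_seqs] or a plain string
#' @param motif a [motif_definition] (default: [thaumatin_signature()])
#' @return data.frame with columns `motif_name`, `start`, `end`,
#'   `matched_substring` (zero rows when there is no match)
#' @export
scan_signature <- function(protein, motif = thaumatin_signature()) {
  s <- if (inherits(protein, "tlp_seqs")) unclass(protein)[[1]] else toupper(protein)
  n <- nchar(s)
  hits <- list()
  for (pos in seq_len(n)) {
    end <- .match_from(s, n, motif$elements, 1L, pos)
    if (!is.na(end)) {
      hits[[length(hits) + 1L]] <- data.frame(
        motif_name = motif$name, start = pos, end = end,
        matched_substring = substr(s, pos, end), stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(motif_name = character(0), start = integer(0),
                      end = integer(0), matched_substring = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Screen candidate proteins for the thaumatin signature
#'
#' A candidate is accepted iff it carries at least one complete signature
#' match anywhere in the sequence; rejected candidates carry a reason.
#'
#' @param proteins a protein [tlp_seqs] collection
#' @param motif a [motif_definition]
#' @return list with `accepted` (tlp_seqs), `rejected` (data.frame
#'   `id`, `reason`) and `hits` (data.frame of all signature hits with an
#'   `id` column)
#' @export
screen_candidates <- function(proteins, motif = thaumatin_signature()) {
  acc <- character(0); rej <- list(); allhits <- list()
  for (id in names(proteins)) {
    h <- scan_signature(proteins[id], motif)
    if (nrow(h) > 0) {
      acc <- c(acc, id)
      allhits[[id]] <- cbind(id = id, h, stringsAsFactors = FALSE)
    } else {
      rej[[length(rej) + 1L]] <- data.frame(
        id = id, reason = "no complete thaumatin signature motif",
        stringsAsFactors = FALSE)
    }
  }
  list(
    accepted = if (length(acc)) proteins[acc] else
      tlp_seqs(character(0), character(0), attr(proteins, "alphabet") %||% "protein"),
    rejected = if (length(rej)) do.call(rbind, rej) else
      data.frame(id = character(0), reason = character(0), stringsAsFactors = FALSE),
    hits = if (length(allhits)) do.call(rbind, c(allhits, make.row.names = FALSE)) else
      data.frame(id = character(0), motif_name = character(0), start = integer(0),
                 end = integer(0), matched_substring = character(0),
                 stringsAsFactors = FALSE)
  )
}
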