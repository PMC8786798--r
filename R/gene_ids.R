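#' Parse a TLP gene symbol
#'
#' Family members are named `<Prefix>TLP<k>` in diploid species (e.g.
#' `BdTLP1`) and `<Prefix>TLP<k>-<S><copy?>` in hexaploid wheat, where `<S>`
#' is the subgenome (A/B/D) and an optional numeric suffix distinguishes
#' multiple copies on one subgenome (e.g. `TaTLP15-B2`). Homeolog candidates
#' share the family index and differ only in the subgenome tag.
#'
#' A small alias table absorbs known typographic variants without loosening
#' the grammar (by default `BdTLPK1`/`BdTLPK2`, which appear alongside
#' `BdTLP1`/`BdTLP2` in published tables for the same genes).
#'
#' @param id_string gene symbol
#' @param aliases named character vector mapping variant spellings to
#'   canonical symbols
#' @return a `gene_identity` list: `species_prefix`, `family_index`,
#'   `subgenome_tag` (`NA` for diploid-style names), `subgenome`, `copy`
#' @export
parse_gene_id <- function(id_string,
                          aliases = c(BdTLPK1 = "BdTLP1", BdTLPK2 = "BdTLP2")) {
  stopifnot(length(id_string) == 1L)
  raw <- id_string
  if (id_string %in% names(aliases)) id_string <- aliases[[id_string]]
  m <- regmatches(id_string,
                  regexec("^([A-Z][a-z])TLP([0-9]+)(?:-([ABD])([0-9]+)?)?$", id_string))[[1]]
  if (length(m) == 0) stop_tlp("unparseable gene id: '", raw, "'")
  idx <- as.integer(m[3])
  if (idx < 1) stop_tlp("family index must be >= 1 in '", raw, "'")
  structure(list(
    species_prefix = m[2],
    family_index   = idx,
    subgenome_tag  = if (nzchar(m[4])) paste0(m[4], m[5]) else NA_character_,
    subgenome      = if (nzchar(m[4])) m[4] else NA_character_,
    copy           = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_
  ), class = "gene_identity")
}

#' Format a `gene_identity` back to its symbol
#' @param identity a `gene_identity` (from [parse_gene_id()])
#' @return character scalar
#' @export
format_gene_id <- function(identity) {
  stopifnot(inherits(identity, "gene_identity"))
  base <- paste0(identity$species_prefix, "TLP", identity$family_index)
  if (is.na(identity$subgenome_tag)) base else paste0(base, "-", identity$subgenome_tag)
}

#' @export
print.gene_identity <- function(x, ...) {
  cat("gene_identity:", format_gene_id(x),
      sprintf("(prefix=%s, family=%d, subgenome=%s)\n",
              x$species_prefix, x$family_index,
              ifelse(is.na(x$subgenome_tag), "none", x$subgenome_tag)))
  invisible(x)
}
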