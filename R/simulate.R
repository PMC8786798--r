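# Synthetic TLP family generator.
#
# Every generator is a deterministic function of its spec and an integer
# seed; each generator sets its own named RNG stream (set.seed at entry) so
# sub-generators are independently reproducible. Ground truth for every
# planted feature is recorded and serialized alongside the emitted files.

.aa_nocys <- strsplit("ADEFGHIKLMNPQRSTVWY", "")[[1]]  # standard residues minus C

# background residue frequencies (typical plant-proteome composition,
# renormalized without cysteine); uniform sampling would average ~119 Da
# per residue and push small TLPs past their published 17-19 kDa range
.aa_freq <- c(A = 0.080, D = 0.053, E = 0.062, F = 0.040, G = 0.071,
              H = 0.022, I = 0.053, K = 0.058, L = 0.092, M = 0.022,
              N = 0.042, P = 0.048, Q = 0.038, R = 0.051, S = 0.081,
              T = 0.056, V = 0.069, W = 0.011, Y = 0.029)

.sample_aa <- function(n) {
  sample(.aa_nocys, n, replace = TRUE, prob = .aa_freq[.aa_nocys])
}

.codons_of <- function() {
  by_aa <- .tlpfam_cache$codons_by_aa
  if (is.null(by_aa)) {
    gc <- genetic_code()
    by_aa <- split(names(gc), gc)
    .tlpfam_cache$codons_by_aa <- by_aa
  }
  by_aa
}

# uniform random CDS encoding a protein
.encode_protein <- function(protein) {
  by_aa <- .codons_of()
  paste(vapply(chars(protein), function(a) {
    cods <- by_aa[[a]]
    cods[sample.int(length(cods), 1)]
  }, character(1)), collapse = "")
}

# concrete instance of the thaumatin signature motif; returns the string and
# the offsets of its cysteines
.instantiate_signature <- function() {
  x <- function() sample(.aa_nocys, 1)
  run1 <- sample(1:2, 1); run2 <- sample(2:3, 1)
  s <- c("G", x(), sample(c("G", "F"), 1), x(), "C", x(), "T",
         sample(c("G", "A"), 1), "D", "C",
         replicate(run1, x()), "G", replicate(run2, x()), "C")
  paste(s, collapse = "")
}

#' Specification for a synthetic TLP family
#'
#' The defaults emulate the scale of the hexaploid wheat family: 93 genes
#' of which 81 form 27 complete A/B/D homeolog triplets (7 of the triplets
#' small-type, the rest long-type), plus 6 duplicate gene pairs (1 tandem,
#' 5 segmental, mirroring the wheat tandem/segmental split) evolved at
#' purifying-selection Ka/Ks with synonymous divergences inside the
#' non-saturated range of the family's published pairs.
#'
#' @param n_homeolog_groups number of homeolog groups (hexaploid mode)
#' @param n_small_groups how many of those groups are small-type TLPs
#' @param duplicate_specs data.frame with columns `kind`
#'   (`tandem`/`segmental`), `target_omega`, `target_ks`
#' @param ploidy_mode `"hexaploid"` or `"diploid"`
#' @param n_genes diploid mode: number of genes (hexaploid mode derives the
#'   count from groups and pairs)
#' @param motif_plant_rate fraction of genes carrying a complete signature
#' @param seed integer seed
#' @return a `family_spec` list
#' @export
family_spec <- function(n_homeolog_groups = 27, n_small_groups = 7,
                        duplicate_specs = data.frame(
                          kind = c("tandem", rep("segmental", 5)),
                          target_omega = c(0.10, 0.12, 0.10, 0.15, 0.10, 0.12),
                          target_ks = c(0.30, 0.45, 0.55, 0.65, 0.75, 0.80)),
                        ploidy_mode = c("hexaploid", "diploid"),
                        n_genes = NULL, motif_plant_rate = 1, seed = 101) {
  ploidy_mode <- match.arg(ploidy_mode)
  if (!is.null(duplicate_specs) && nrow(duplicate_specs) > 0) {
    stopifnot(all(duplicate_specs$kind %in% c("tandem", "segmental")),
              all(duplicate_specs$target_ks < 2.0))
  }
  if (ploidy_mode == "hexaploid") {
    n_genes_total <- 3 * n_homeolog_groups +
      2 * (if (is.null(duplicate_specs)) 0 else nrow(duplicate_specs))
    if (!is.null(n_genes) && n_genes < 3 * n_homeolog_groups) {
      stop_tlp("infeasible spec: 3 * n_homeolog_groups exceeds n_genes")
    }
  } else {
    n_genes_total <- n_genes %||% 26
  }
  structure(list(ploidy_mode = ploidy_mode,
                 n_homeolog_groups = if (ploidy_mode == "hexaploid") n_homeolog_groups else 0L,
                 n_small_groups = n_small_groups,
                 duplicate_specs = duplicate_specs,
                 n_genes = n_genes_total,
                 motif_plant_rate = motif_plant_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# build one protein with a planted signature and an exact cysteine census;
# small: domain 134-154 aa, 10 Cys; long: domain 202-217 aa, 16 Cys.
# Flanks are cysteine-free so the domain census is exact.
.make_tlp_protein <- function(size_class, plant_motif = TRUE) {
  dlen <- if (size_class == "long") sample(202:217, 1) else sample(134:154, 1)
  ncys <- if (size_class == "long") 16L else 10L
  # flanks sized so totals mirror the published ranges: small TLPs stay at
  # ~175-185 aa (17-19 kDa, under the 22 kDa small-class guard), long TLPs
  # carry a fuller signal-peptide-like leader
  nflank <- if (size_class == "long") sample(22:30, 1) else sample(22:26, 1)
  cflank <- if (size_class == "long") sample(3:8, 1) else sample(3:5, 1)
  dom <- .sample_aa(dlen)
  sig <- .instantiate_signature()
  sig_at <- NA_integer_
  if (plant_motif) {
    sig_at <- sample(seq(10, dlen - nchar(sig) - 5), 1)
    dom[sig_at:(sig_at + nchar(sig) - 1)] <- chars(sig)
  }
  # top up cysteines outside the signature footprint to the planted census
  have <- sum(dom == "C")
  free <- setdiff(which(dom != "C"),
                  if (plant_motif) sig_at:(sig_at + nchar(sig) - 1) else integer(0))
  add <- ncys - have
  if (add > 0) dom[sample(free, add)] <- "C"
  prot <- paste(c("M", .sample_aa(nflank - 1), dom,
                  .sample_aa(cflank)), collapse = "")
  list(protein = prot,
       domain_start = nflank + 1L,
       domain_end = nflank + dlen,
       motif_start = if (plant_motif) nflank + sig_at else NA_integer_,
       motif_end = if (plant_motif) nflank + sig_at + nchar(sig) - 1L else NA_integer_,
       cysteine_count = ncys)
}

# substitution-only divergence of a CDS: nsyn synonymous codon swaps and
# nnon amino-acid changes at unprotected, non-cysteine codons
.mutate_copy <- function(cds, nsyn, nnon, protect_codons = integer(0)) {
  by_aa <- .codons_of()
  cods <- split_codons(cds)
  aa <- genetic_code()[cods]
  swappable <- setdiff(which(lengths(by_aa[aa]) > 1), protect_codons)
  for (i in sample(swappable, min(nsyn, length(swappable)))) {
    alt <- setdiff(by_aa[[aa[i]]], cods[i])
    cods[i] <- alt[sample.int(length(alt), 1)]
  }
  mutable <- setdiff(which(!aa %in% c("C", "M", "W")), protect_codons)
  for (i in sample(mutable, min(nnon, length(mutable)))) {
    new_aa <- sample(setdiff(.aa_nocys, aa[i]), 1)
    alt <- by_aa[[new_aa]]
    cods[i] <- alt[sample.int(length(alt), 1)]
    aa[i] <- new_aa
  }
  paste(cods, collapse = "")
}

#' Evolve a duplicate gene pair by codon substitution
#'
#' Two descendants of `cds` are produced by simulating substitutions along
#' two independent branches of `target_ks / 2` synonymous substitutions per
#' synonymous site each. Proposals pick a codon position and a non-stop
#' alternative nucleotide uniformly; synonymous proposals are accepted with
#' probability `1/q` and non-synonymous with `omega/q` (`q = max(1,
#' omega)`), so the expected synonymous divergence is `target_ks` and the
#' expected Ka/Ks is `target_omega`. `target_ks` is therefore an
#' expectation, not an exact realization; realized substitution counts are
#' returned for tolerance-free downstream tests. No stop codons are ever
#' introduced, and optionally a set of codons can be protected from
#' amino-acid change (used by [generate_family()] to preserve planted
#' signature motifs and the cysteine census).
#'
#' @param cds ancestor CDS (internally stop-free)
#' @param target_omega expected Ka/Ks
#' @param target_ks expected synonymous substitutions per synonymous site
#'   (must stay below the Jukes-Cantor saturation range, < 2)
#' @param seed integer seed
#' @param protect_codons codon indices shielded from amino-acid change
#' @param forbid_gain amino acids that substitutions may never create
#'   (used by [generate_family()] with `"C"` so the planted cysteine
#'   census stays exact)
#' @return list: `cds_a`, `cds_b`, `realized` (per-branch accepted
#'   synonymous/non-synonymous substitution counts)
#' @export
evolve_pair <- function(cds, target_omega, target_ks, seed,
                        protect_codons = integer(0), forbid_gain = character(0)) {
  if (target_ks >= 2) stop_tlp("target_ks too high for reliable JC inversion")
  if (target_ks < 0 || target_omega < 0) stop_tlp("negative evolution target")
  set.seed(as.integer(seed))
  gc <- genetic_code()
  evolve_branch <- function(cds) {
    cods <- split_codons(cds)
    L <- length(cods)
    q <- max(1, target_omega)
    n_prop <- stats::rpois(1, (target_ks / 2) * 3 * L * q)
    syn_acc <- 0L; non_acc <- 0L
    for (k in seq_len(n_prop)) {
      ci <- sample.int(L, 1)
      pos <- sample.int(3, 1)
      cur <- cods[ci]
      alts <- setdiff(.nt, substr(cur, pos, pos))
      cand <- vapply(alts, function(n) { x <- cur; substr(x, pos, pos) <- n; x },
                     character(1))
      cand <- cand[gc[cand] != "*"]
      if (length(cand) == 0) next
      nxt <- cand[sample.int(length(cand), 1)]
      syn <- identical(gc[[nxt]], gc[[cur]])
      if (!syn && ci %in% protect_codons) next
      if (!syn && gc[[nxt]] %in% forbid_gain) next
      p_acc <- if (syn) 1 / q else target_omega / q
      if (stats::runif(1) <= p_acc) {
        cods[ci] <- nxt
        if (syn) syn_acc <- syn_acc + 1L else non_acc <- non_acc + 1L
      }
    }
    list(cds = paste(cods, collapse = ""), syn = syn_acc, non = non_acc)
  }
  a <- evolve_branch(cds)
  b <- evolve_branch(cds)
  list(cds_a = a$cds, cds_b = b$cds,
       realized = data.frame(branch = c("a", "b"),
                             syn_substitutions = c(a$syn, b$syn),
                             nonsyn_substitutions = c(a$non, b$non)))
}

# ---- family generation -----------------------------------------------------

.next_gene_slot <- function(state, chrom, gap = NULL) {
  cur <- state$cursor[[chrom]] %||% 500000L
  if (!is.null(gap)) start <- cur + gap else
    start <- cur + sample(250000:400000, 1)
  state$cursor[[chrom]] <- start
  list(state = state, start = start)
}

# emit a gene model for a CDS: small TLPs intronless, long TLPs 1-3 exons
.layout_gene <- function(gene_id, chrom, subgenome, start, cds_len, size_class) {
  strand <- sample(c("+", "-"), 1)
  n_ex <- if (size_class == "small") 1L else sample(1:3, 1)
  if (n_ex == 1L) {
    seg_len <- cds_len
  } else {
    cuts <- sort(sample(seq(30, cds_len - 30, by = 1), n_ex - 1))
    seg_len <- diff(c(0, cuts, cds_len))
  }
  introns <- if (n_ex > 1) sample(100:500, n_ex - 1, replace = TRUE) else integer(0)
  # genomic layout 5'->3' on the + strand of the genome
  lens5to3 <- if (strand == "+") seg_len else rev(seg_len)
  intr5to3 <- if (strand == "+") introns else rev(introns)
  starts <- integer(n_ex); ends <- integer(n_ex)
  cur <- start
  for (i in seq_len(n_ex)) {
    starts[i] <- cur; ends[i] <- cur + lens5to3[i] - 1L
    cur <- ends[i] + 1L + (if (i < n_ex) intr5to3[i] else 0L)
  }
  exons <- cbind(starts, ends)
  # GFF phase: number of bases to skip to reach the next codon start
  tx_lens <- seg_len
  cum <- c(0, cumsum(tx_lens))[seq_len(n_ex)]
  phase_tx <- (3 - (cum %% 3)) %% 3
  phase5to3 <- if (strand == "+") phase_tx else rev(phase_tx)
  list(gene_id = gene_id, chrom = chrom, subgenome = subgenome, strand = strand,
       exons = exons, phases = phase5to3, start = min(exons), end = max(exons))
}

.gff3_lines <- function(layout) {
  g <- layout
  attr_of <- function(id, parent = NULL) {
    if (is.null(parent)) paste0("ID=", id) else paste0("ID=", id, ";Parent=", parent)
  }
  tid <- paste0(g$gene_id, ".1")
  rows <- c(
    paste(g$chrom, "tlpfam_sim", "gene", g$start, g$end, ".", g$strand, ".",
          attr_of(g$gene_id), sep = "\t"),
    paste(g$chrom, "tlpfam_sim", "mRNA", g$start, g$end, ".", g$strand, ".",
          attr_of(tid, g$gene_id), sep = "\t"))
  for (i in seq_len(nrow(g$exons))) {
    rows <- c(rows,
              paste(g$chrom, "tlpfam_sim", "exon", g$exons[i, 1], g$exons[i, 2],
                    ".", g$strand, ".", paste0("Parent=", tid), sep = "\t"),
              paste(g$chrom, "tlpfam_sim", "CDS", g$exons[i, 1], g$exons[i, 2],
                    ".", g$strand, g$phases[i], paste0("Parent=", tid), sep = "\t"))
  }
  rows
}

#' Generate a synthetic TLP family with ground truth
#'
#' Emits protein FASTA, CDS FASTA, GFF3 gene models, a thaumatin-domain
#' annotation table, and a ground-truth record. Proteins carry a planted
#' thaumatin signature (per `motif_plant_rate`) and exactly 16 (long) or 10
#' (small) cysteines inside the domain; the CDS translates exactly to the
#' protein; homeolog triplets sit on the A/B/D copies of one chromosome
#' number at >= 90% identity; duplicate pairs honor their tandem
#' (same chromosome, < 100 kb) or segmental (different chromosomes) kind.
#' Deterministic per seed.
#'
#' @param spec a [family_spec]
#' @param dir optional output directory; when given, writes
#'   `proteins.fasta`, `cds.fasta`, `genes.gff3`, `domains.tsv`,
#'   `ground_truth.json`
#' @return list: `proteins`, `cds` ([tlp_seqs]), `models`
#'   (`gene_model_list`), `domains` (data.frame), `truth` (ground-truth
#'   list)
#' @export
generate_family <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  hex <- spec$ploidy_mode == "hexaploid"
  prefix <- if (hex) "Ta" else "Bd"
  proteins <- character(0); cds <- character(0)
  layouts <- list(); truth_genes <- list(); truth_groups <- list()
  truth_pairs <- list()
  state <- list(cursor = list())
  fam_idx <- 0L

  add_gene <- function(gene_id, prot_info, cds_seq, chrom, subgenome, group_id,
                       gap = NULL) {
    slot <- .next_gene_slot(state, chrom, gap)
    state <<- slot$state
    size_class <- if (prot_info$domain_end - prot_info$domain_start + 1 >= 180)
      "long" else "small"
    lay <- .layout_gene(gene_id, chrom, subgenome, slot$start,
                        nchar(cds_seq), size_class)
    proteins[gene_id] <<- prot_info$protein
    cds[gene_id] <<- cds_seq
    layouts[[gene_id]] <<- lay
    truth_genes[[gene_id]] <<- data.frame(
      gene_id = gene_id, size_class = size_class, chromosome = chrom,
      subgenome = subgenome %||% NA_character_,
      group_id = group_id %||% NA_integer_,
      domain_start = prot_info$domain_start, domain_end = prot_info$domain_end,
      motif_start = prot_info$motif_start, motif_end = prot_info$motif_end,
      cysteine_count = prot_info$cysteine_count, stringsAsFactors = FALSE)
  }

  n_groups <- spec$n_homeolog_groups
  if (hex && n_groups > 0) {
    for (g in seq_len(n_groups)) {
      fam_idx <- fam_idx + 1L
      size_class <- if (g <= spec$n_small_groups) "small" else "long"
      plant <- stats::runif(1) <= spec$motif_plant_rate
      base <- .make_tlp_protein(size_class, plant_motif = plant)
      base_cds <- .encode_protein(base$protein)
      L <- nchar(base$protein)
      protect <- unique(c(
        if (plant) seq(base$motif_start, base$motif_end) else integer(0),
        which(chars(base$protein) == "C")))
      chrom_num <- ((g - 1) %% 7) + 1
      members <- character(0)
      for (sg in c("A", "B", "D")) {
        gid <- sprintf("%sTLP%d-%s", prefix, fam_idx, sg)
        members <- c(members, gid)
        copy_cds <- .mutate_copy(base_cds,
                                 nsyn = max(1L, round(0.04 * L)),
                                 nnon = max(1L, round(0.02 * L)),
                                 protect_codons = protect)
        info <- base
        info$protein <- translate_cds(copy_cds, strip_terminal_stop = FALSE)
        add_gene(gid, info, copy_cds, paste0(chrom_num, sg), sg, g)
      }
      truth_groups[[g]] <- sort(members)
    }
  } else if (!hex) {
    for (g in seq_len(spec$n_genes -
                      2 * (if (is.null(spec$duplicate_specs)) 0 else nrow(spec$duplicate_specs)))) {
      fam_idx <- fam_idx + 1L
      size_class <- if (g %% 6 == 0) "small" else "long"
      plant <- stats::runif(1) <= spec$motif_plant_rate
      base <- .make_tlp_protein(size_class, plant_motif = plant)
      gid <- sprintf("%sTLP%d", prefix, fam_idx)
      add_gene(gid, base, .encode_protein(base$protein),
               paste0(prefix, ((g - 1) %% 5) + 1), NA_character_, NA_integer_)
    }
  }

  dspecs <- spec$duplicate_specs
  if (!is.null(dspecs) && nrow(dspecs) > 0) {
    for (i in seq_len(nrow(dspecs))) {
      base <- .make_tlp_protein("long", plant_motif = TRUE)
      base_cds <- .encode_protein(base$protein)
      protect <- unique(c(seq(base$motif_start, base$motif_end),
                          which(chars(base$protein) == "C")))
      # a DuplicatePair must satisfy its detection invariant (supporting
      # edge identity >= 80); the evolved realization is stochastic, so
      # draws violating the invariant are rejected and re-evolved on a
      # derived seed. Realized substitution counts reflect the accepted draw.
      for (attempt in seq_len(25L)) {
        ev <- evolve_pair(base_cds, dspecs$target_omega[i], dspecs$target_ks[i],
                          seed = spec$seed + 7919L * i + 101L * (attempt - 1L),
                          protect_codons = protect, forbid_gain = "C")
        idn <- pairwise_identity(translate_cds(ev$cds_a, FALSE),
                                 translate_cds(ev$cds_b, FALSE))
        if (idn >= 81) break
      }
      if (idn < 81) {
        stop_tlp("infeasible duplicate spec ", i,
                 ": target_ks/target_omega too divergent for a detectable pair")
      }
      ids <- character(2)
      for (j in 1:2) {
        fam_idx <- fam_idx + 1L
        ids[j] <- if (hex) sprintf("%sTLP%d-A", prefix, fam_idx) else
          sprintf("%sTLP%d", prefix, fam_idx)
      }
      kind <- dspecs$kind[i]
      if (kind == "tandem") {
        chrom <- if (hex) paste0(((i - 1) %% 7) + 1, "A") else
          paste0(prefix, ((i - 1) %% 5) + 1)
        chroms <- c(chrom, chrom)
        gaps <- list(NULL, sample(30000:60000, 1))
      } else {
        if (hex) {
          cn <- ((i - 1) %% 7) + 1
          chroms <- paste0(c(cn, (cn %% 7) + 1), c("A", "D"))
        } else {
          cn <- ((i - 1) %% 5) + 1
          chroms <- paste0(prefix, c(cn, (cn %% 5) + 1))
        }
        gaps <- list(NULL, NULL)
      }
      for (j in 1:2) {
        cds_j <- if (j == 1) ev$cds_a else ev$cds_b
        info <- base
        info$protein <- translate_cds(cds_j, strip_terminal_stop = FALSE)
        add_gene(ids[j], info, cds_j, chroms[j],
                 if (hex) sub("^[0-9]+", "", chroms[j]) else NA_character_,
                 NA_integer_, gap = gaps[[j]])
      }
      truth_pairs[[i]] <- data.frame(
        gene_a = ids[1], gene_b = ids[2], kind = kind,
        target_omega = dspecs$target_omega[i], target_ks = dspecs$target_ks[i],
        realized_syn = sum(ev$realized$syn_substitutions),
        realized_nonsyn = sum(ev$realized$nonsyn_substitutions),
        stringsAsFactors = FALSE)
    }
  }

  prot_set <- tlp_seqs(proteins, names(proteins), "protein")
  cds_set <- tlp_seqs(cds, names(cds), "dna")
  models <- structure(lapply(layouts, function(l) {
    gene_model(l$gene_id, l$chrom, l$strand, l$exons,
               cds = cbind(l$exons, l$phases), subgenome = l$subgenome)
  }), class = "gene_model_list")
  genes_df <- do.call(rbind, c(truth_genes, make.row.names = FALSE))
  domains <- genes_df[, c("gene_id", "domain_start", "domain_end")]
  truth <- list(genes = genes_df,
                groups = truth_groups,
                pairs = if (length(truth_pairs))
                  do.call(rbind, c(truth_pairs, make.row.names = FALSE)) else NULL,
                spec_seed = spec$seed)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(prot_set, file.path(dir, "proteins.fasta"))
    write_fasta(cds_set, file.path(dir, "cds.fasta"))
    lines <- c("##gff-version 3",
               unlist(lapply(layouts, .gff3_lines), use.names = FALSE))
    writeLines(lines, file.path(dir, "genes.gff3"))
    write_tsv(domains, file.path(dir, "domains.tsv"))
    jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  list(proteins = prot_set, cds = cds_set, models = models,
       domains = domains, truth = truth)
}

#' Generate synthetic promoters with planted cis-elements
#'
#' 1.5 kb random-background sequences with concrete instances of IUPAC
#' elements planted at recorded, non-overlapping positions and strands.
#'
#' @param gene_ids promoter names
#' @param elements element table (see [read_element_table()])
#' @param plant_plan data.frame `gene_id`, `element_name`, `count`; absent
#'   genes get background only
#' @param seed integer seed
#' @param window promoter length in bp (default 1500)
#' @return list: `promoters` (dna [tlp_seqs]) and `truth` (data.frame
#'   `gene_id`, `element_name`, `strand`, `start`, `end`)
#' @export
generate_promoters <- function(gene_ids, elements, plant_plan = NULL, seed = 1,
                               window = 1500L) {
  set.seed(as.integer(seed))
  iupac_expand <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                       Y = c("C", "T"), W = c("A", "T"), S = c("C", "G"),
                       K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                       D = c("A", "G", "T"), H = c("A", "C", "T"),
                       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  seqs <- character(0); truth <- list()
  for (g in gene_ids) {
    s <- sample(c("A", "C", "G", "T"), window, replace = TRUE,
                prob = c(0.275, 0.225, 0.225, 0.275))
    occupied <- rep(FALSE, window)
    if (!is.null(plant_plan)) {
      plan_g <- plant_plan[plant_plan$gene_id == g, , drop = FALSE]
      for (i in seq_len(nrow(plan_g))) {
        pat <- elements$iupac_pattern[elements$name == plan_g$element_name[i]]
        if (length(pat) == 0) stop_tlp("unknown element: ", plan_g$element_name[i])
        for (k in seq_len(plan_g$count[i])) {
          inst <- vapply(chars(pat), function(code) sample(iupac_expand[[code]], 1),
                         character(1))
          strand <- sample(c("+", "-"), 1)
          planted <- if (strand == "+") inst else chars(revcomp(paste(inst, collapse = "")))
          w <- length(planted)
          ok_starts <- which(!vapply(seq_len(window - w + 1), function(p)
            any(occupied[p:(p + w - 1)]), logical(1)))
          if (length(ok_starts) == 0) stop_tlp("promoter too crowded for plan")
          p <- ok_starts[sample.int(length(ok_starts), 1)]
          s[p:(p + w - 1)] <- planted
          occupied[p:(p + w - 1)] <- TRUE
          truth[[length(truth) + 1L]] <- data.frame(
            gene_id = g, element_name = plan_g$element_name[i], strand = strand,
            start = p, end = p + w - 1L, stringsAsFactors = FALSE)
        }
      }
    }
    seqs[g] <- paste(s, collapse = "")
  }
  list(promoters = tlp_seqs(seqs, names(seqs), "dna"),
       truth = if (length(truth)) do.call(rbind, c(truth, make.row.names = FALSE)) else
         data.frame(gene_id = character(0), element_name = character(0),
                    strand = character(0), start = integer(0), end = integer(0),
                    stringsAsFactors = FALSE))
}

#' Default expression archetypes
#'
#' Mean log2-FPKM profiles over a control plus four stress time points,
#' emulating the group structure seen in stress-series heat maps:
#' flat (not differential), early-up, late-up, and down-regulated. The
#' differential archetypes are planted at 2.5-fold or stronger so they
#' clear a 2-fold filter even with the ratio pseudocount.
#'
#' @param conditions condition names (first is the control)
#' @return named list of per-condition mean log2-FPKM vectors
#' @export
expression_archetypes <- function(conditions = c("control", "t6h", "t12h",
                                                 "t24h", "t48h")) {
  n <- length(conditions)
  lapply(list(
    flat       = rep(4, n),
    early_up   = c(4, 4 + log2(2.5), 4 + log2(1.4), rep(4, n - 3)),
    late_up    = c(rep(4, n - 2), 4 + log2(1.4), 4 + log2(3)),
    down       = c(4, rep(4 - log2(2.5), n - 1))
  ), function(v) stats::setNames(v[seq_len(n)], conditions))
}

#' Generate a synthetic expression matrix with archetype structure
#'
#' Each gene is assigned an archetype mean profile on the log2 scale;
#' fragment counts are derived from the implied FPKM with lognormal noise
#' of standard deviation `noise_sd` (log2 units) and `replicates` columns
#' per condition. At `noise_sd = 0` the realized FPKM equals the archetype
#' exactly (counts are expected fragment counts and may be fractional).
#'
#' @param gene_ids genes
#' @param archetypes named list of per-condition mean log2-FPKM vectors
#'   (default [expression_archetypes()]); genes are assigned round-robin
#' @param replicates replicate columns per condition (default 1)
#' @param noise_sd lognormal noise SD in log2 units (default 0)
#' @param seed integer seed
#' @param gene_lengths per-gene exonic length in bp (default 750)
#' @param library_total mapped fragments per sample (default 2e7)
#' @return list: `counts` (gene x sample), `lengths`, `totals`,
#'   `replicate_map` (sample -> condition), `truth` (data.frame `gene_id`,
#'   `archetype`, `differential`)
#' @export
generate_expression <- function(gene_ids, archetypes = expression_archetypes(),
                                replicates = 1L, noise_sd = 0, seed = 1,
                                gene_lengths = NULL, library_total = 2e7) {
  set.seed(as.integer(seed))
  conds <- names(archetypes[[1]])
  if (is.null(gene_lengths)) {
    gene_lengths <- stats::setNames(rep(750L, length(gene_ids)), gene_ids)
  }
  arch_names <- names(archetypes)
  assign <- arch_names[((seq_along(gene_ids) - 1) %% length(arch_names)) + 1]
  samples <- as.vector(t(outer(conds, seq_len(replicates),
                               function(c, r) paste0(c, "_r", r))))
  if (replicates == 1L) samples <- conds
  counts <- matrix(0, nrow = length(gene_ids), ncol = length(samples),
                   dimnames = list(gene_ids, samples))
  rep_map <- stats::setNames(rep(conds, each = replicates), samples)
  for (gi in seq_along(gene_ids)) {
    mu <- archetypes[[assign[gi]]]
    for (si in seq_along(samples)) {
      lg <- mu[[rep_map[[samples[si]]]]] +
        (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
      fp <- 2^lg
      counts[gi, si] <- fp * gene_lengths[[gene_ids[gi]]] * library_total / 1e9
    }
  }
  diffg <- vapply(assign, function(a) {
    mu <- archetypes[[a]]
    any(abs(mu[-1] - mu[1]) >= log2(2.5) - 1e-12)
  }, logical(1))
  list(counts = counts,
       lengths = gene_lengths,
       totals = stats::setNames(rep(library_total, length(samples)), samples),
       replicate_map = rep_map,
       truth = data.frame(gene_id = gene_ids, archetype = assign,
                          differential = diffg, stringsAsFactors = FALSE))
}

#' Generate a synthetic qPCR Ct table with known fold changes
#'
#' The reference-gene Ct is constant (the internal-control assumption);
#' treated-condition target Cts are shifted by `-log2(fold)` relative to
#' control so the planted 2^-ddCt fold change is exact at `noise_sd = 0`.
#'
#' @param gene_ids genes to assay
#' @param fold_plan data.frame `gene_id`, `condition`, `fold`; conditions
#'   absent for a gene default to fold 1
#' @param conditions condition names (first is the control)
#' @param replicates biological replicates per condition (default 3)
#' @param noise_sd Ct noise SD in cycles (default 0)
#' @param seed integer seed
#' @return list: `qpcr` (data.frame gene_id/condition/replicate/ct_target/
#'   ct_reference), `truth` (= `fold_plan`)
#' @export
generate_qpcr <- function(gene_ids, fold_plan,
                          conditions = c("control", "t6h", "t12h"),
                          replicates = 3L, noise_sd = 0, seed = 1) {
  set.seed(as.integer(seed))
  rows <- list()
  for (g in gene_ids) {
    for (cond in conditions) {
      fold <- 1
      k <- fold_plan$gene_id == g & fold_plan$condition == cond
      if (any(k)) fold <- fold_plan$fold[k][1]
      for (r in seq_len(replicates)) {
        ct_t <- 25 - log2(fold) + (if (noise_sd > 0) stats::rnorm(1, 0, noise_sd) else 0)
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, condition = cond, replicate = r,
          ct_target = ct_t, ct_reference = 20, stringsAsFactors = FALSE)
      }
    }
  }
  list(qpcr = do.call(rbind, rows), truth = fold_plan)
}

#' Generate a complete synthetic analysis bundle
#'
#' One call producing every input [run_pipeline()] consumes — family
#' sequences and gene models, promoters with planted elements, an
#' expression matrix with archetype structure, and a qPCR table — plus the
#' combined ground truth. All files are written under `dir`.
#'
#' @param dir output directory
#' @param seed integer seed; sub-generators use documented offsets of this
#'   seed so each stream is independently reproducible
#' @param spec a [family_spec] (default: [family_spec()] with this seed)
#' @param noise_sd expression noise SD in log2 units (default 0)
#' @return list: `paths` (named file paths), `truth` (family, promoter,
#'   expression and qPCR ground truth)
#' @export
simulate_tlp_bundle <- function(dir, seed = 101, spec = NULL, noise_sd = 0) {
  if (is.null(spec)) spec <- family_spec(seed = seed)
  fam <- generate_family(spec, dir = dir)
  gene_ids <- names(fam$proteins)
  elements <- read_element_table()
  set.seed(seed + 1L)
  plan <- do.call(rbind, lapply(gene_ids, function(g) {
    els <- sample(elements$name, sample(1:3, 1))
    data.frame(gene_id = g, element_name = els,
               count = sample(1:2, length(els), replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  prom <- generate_promoters(gene_ids, elements, plan, seed = seed + 2L)
  write_fasta(prom$promoters, file.path(dir, "promoters.fasta"))
  write_tsv(prom$truth, file.path(dir, "promoter_truth.tsv"))
  expr <- generate_expression(gene_ids, noise_sd = noise_sd, seed = seed + 3L)
  write_tsv(data.frame(gene_id = rownames(expr$counts), expr$counts,
                       check.names = FALSE),
            file.path(dir, "counts.tsv"))
  write_tsv(data.frame(gene_id = names(expr$lengths), length_bp = expr$lengths),
            file.path(dir, "lengths.tsv"))
  write_tsv(data.frame(sample = names(expr$totals), total = expr$totals),
            file.path(dir, "totals.tsv"))
  qp_genes <- utils::head(gene_ids, 8)
  qplan <- data.frame(gene_id = rep(qp_genes, each = 2),
                      condition = rep(c("t6h", "t12h"), length(qp_genes)),
                      fold = rep(c(2.5, 0.5), length(qp_genes)),
                      stringsAsFactors = FALSE)
  qp <- generate_qpcr(qp_genes, qplan, seed = seed + 4L, noise_sd = 0.05)
  write_tsv(qp$qpcr, file.path(dir, "qpcr.tsv"))
  paths <- list(
    proteins = file.path(dir, "proteins.fasta"),
    cds = file.path(dir, "cds.fasta"),
    gff3 = file.path(dir, "genes.gff3"),
    domains = file.path(dir, "domains.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    expression_counts = file.path(dir, "counts.tsv"),
    expression_lengths = file.path(dir, "lengths.tsv"),
    expression_totals = file.path(dir, "totals.tsv"),
    qpcr = file.path(dir, "qpcr.tsv"))
  list(paths = paths,
       truth = list(family = fam$truth, promoters = prom$truth,
                    expression = expr$truth, qpcr = qp$truth))
}

#' Simulate an equal-rate sequence triple for relative-rate calibration
#'
#' An ancestral nucleotide sequence accumulates substitutions independently
#' along the two ingroup lineages at the SAME per-site rate (the molecular
#' clock null) and along the outgroup lineage at `div_out`. Each site
#' mutates to a uniformly chosen different base with the given probability.
#'
#' @param n_sites alignment length (default 500)
#' @param div_ab expected per-site divergence on each ingroup branch
#' @param div_out expected per-site divergence on the outgroup branch
#' @param seed integer seed
#' @return list of three aligned sequences: `a`, `b`, `outgroup`
#' @export
generate_clock_triple <- function(n_sites = 500, div_ab = 0.05, div_out = 0.15,
                                  seed = 1) {
  set.seed(as.integer(seed))
  nts <- c("A", "C", "G", "T")
  anc <- sample(nts, n_sites, replace = TRUE)
  mutate <- function(s, p) {
    hit <- stats::runif(n_sites) < p
    s[hit] <- vapply(s[hit], function(x) sample(setdiff(nts, x), 1),
                     character(1))
    s
  }
  list(a = paste(mutate(anc, div_ab), collapse = ""),
       b = paste(mutate(anc, div_ab), collapse = ""),
       outgroup = paste(mutate(anc, div_out), collapse = ""))
}
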