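#' Pipeline configuration
#'
#' Collects input paths, thresholds and stage toggles for [run_pipeline()].
#' Thresholds default to the values conventional for this family analysis:
#' homeolog identity >= 90%, duplicate identity >= 80%, tandem gap
#' <= 100 kb (or <= 5 intervening family genes), >= 2-fold differential
#' expression, synonymous clock rate 6.5e-9/site/year, 1.5 kb promoter
#' windows. A configuration can also be read from a YAML file holding the
#' same fields.
#'
#' @param proteins,cds,gff3,domains,promoters,element_table paths to the
#'   protein FASTA, CDS FASTA, GFF3 gene models, thaumatin-domain table
#'   (TSV gene_id/domain_start/domain_end), promoter FASTA and cis-element
#'   table; `NULL` disables the stages needing them
#' @param expression_counts,expression_lengths,expression_totals TSV paths
#'   for the count matrix (genes x samples), gene lengths and per-sample
#'   mapped totals
#' @param qpcr path to a qPCR Ct table (TSV)
#' @param control_cond control condition name for expression/qPCR stages
#' @param out_dir output directory for stage TSVs
#' @param stages character vector of stages to run (subset of
#'   `c("identify", "structure", "evolution", "promoters", "expression")`)
#' @param homeolog_identity,duplicate_identity,tandem_gap_kb,max_intervening,min_fold,fold_pseudo,rate_r,promoter_window,expression_floor,r_min,cluster_k
#'   thresholds (see Details above)
#' @param seed integer seed recorded in the report
#' @return a validated `tlp_config` list
#' @export
tlp_config <- function(proteins = NULL, cds = NULL, gff3 = NULL, domains = NULL,
                       promoters = NULL, element_table = NULL,
                       expression_counts = NULL, expression_lengths = NULL,
                       expression_totals = NULL, qpcr = NULL,
                       control_cond = "control",
                       out_dir = tempfile("tlpfam_run_"),
                       stages = c("identify", "structure", "evolution",
                                  "promoters", "expression"),
                       homeolog_identity = 90, duplicate_identity = 80,
                       tandem_gap_kb = 100, max_intervening = 5,
                       min_fold = 2, fold_pseudo = 0.01, rate_r = 6.5e-9,
                       promoter_window = 1500, expression_floor = 1,
                       r_min = 0.6, cluster_k = 4, seed = 1L) {
  cfg <- as.list(environment())
  thresholds <- c("homeolog_identity", "duplicate_identity", "tandem_gap_kb",
                  "max_intervening", "min_fold", "fold_pseudo", "rate_r",
                  "promoter_window", "expression_floor", "r_min", "cluster_k")
  for (th in thresholds) {
    if (!is.numeric(cfg[[th]]) || length(cfg[[th]]) != 1 || cfg[[th]] <= 0) {
      stop_tlp("threshold '", th, "' must be a positive number")
    }
  }
  bad <- setdiff(stages, c("identify", "structure", "evolution", "promoters",
                           "expression"))
  if (length(bad)) stop_tlp("unknown stage: ", bad[1])
  needs <- list(identify = "proteins", structure = c("proteins", "gff3"),
                evolution = c("proteins", "cds"),
                promoters = "promoters",
                expression = c("expression_counts", "expression_lengths",
                               "expression_totals"))
  for (st in stages) {
    for (field in needs[[st]]) {
      if (is.null(cfg[[field]])) {
        stop_tlp("stage '", st, "' enabled but input '", field, "' missing")
      }
      if (!file.exists(cfg[[field]])) {
        stop_tlp("input file not found: ", cfg[[field]])
      }
    }
  }
  structure(cfg, class = "tlp_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys are [tlp_config()] arguments
#' @return a `tlp_config`
#' @export
read_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_tlp("the 'yaml' package is required to read YAML configs")
  }
  do.call(tlp_config, yaml::read_yaml(path))
}

#' Run the family-characterization pipeline
#'
#' Executes the enabled stages in dependency order (identify, structure,
#' evolution, promoters, expression), writes each stage's TSVs into
#' `config$out_dir`, and returns a `tlp_report` summarizing counts in/out
#' of every filter together with the thresholds actually used.
#'
#' @param config a [tlp_config()]
#' @return a `tlp_report` list (also serialized as `report.json` in the
#'   output directory)
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tlp_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  rep <- list(thresholds = config[c("homeolog_identity", "duplicate_identity",
                                    "tandem_gap_kb", "max_intervening",
                                    "min_fold", "fold_pseudo", "rate_r",
                                    "promoter_window", "expression_floor",
                                    "r_min", "cluster_k")],
              seed = config$seed, stages = list())
  st <- config$stages
  proteins <- NULL; accepted <- NULL; models <- NULL; edges <- NULL
  groups <- list(); dup_pairs <- NULL

  if ("identify" %in% st) {
    proteins <- read_fasta(config$proteins, "protein")
    scr <- screen_candidates(proteins)
    accepted <- scr$accepted
    prof <- do.call(rbind, lapply(names(accepted), function(id)
      physicochemical_profile(accepted[id])))
    dom <- if (!is.null(config$domains)) read_tsv(config$domains) else NULL
    size <- vapply(names(accepted), function(id) {
      if (!is.null(dom) && id %in% dom$gene_id) {
        d <- dom[dom$gene_id == id, ]
        dl <- d$domain_end - d$domain_start + 1
      } else {
        h <- scr$hits[scr$hits$id == id, ][1, ]   # proxy: signature +/- 60 aa
        dl <- min(nchar(unclass(accepted)[[id]]), h$end + 60) - max(1, h$start - 60) + 1
      }
      classify_size(prof$mw_kda[prof$id == id], dl)$size_class
    }, character(1))
    prof$size_class <- size
    sig <- scr$hits[!duplicated(scr$hits$id), c("id", "start", "end")]
    names(sig) <- c("id", "signature_start", "signature_end")
    prof <- merge(prof, sig, by = "id", sort = FALSE)
    write_tsv(prof, file.path(config$out_dir, "identification.tsv"))
    write_tsv(scr$rejected, file.path(config$out_dir, "rejected.tsv"))
    rep$stages$identify <- list(candidates_in = length(proteins),
                                accepted = length(accepted),
                                rejected = nrow(scr$rejected),
                                size_classes = as.list(table(size)))
  }

  if ("structure" %in% st) {
    models <- read_gff3(config$gff3)
    if (is.null(accepted)) accepted <- read_fasta(config$proteins, "protein")
    edges <- similarity_edges(accepted)
    groups <- group_homeologs(edges, models,
                              identity_min = config$homeolog_identity)
    dup <- find_duplicates(edges, identity_min = config$duplicate_identity,
                           exclude_groups = groups)
    dup_pairs <- if (nrow(dup) > 0) do.call(rbind, lapply(seq_len(nrow(dup)),
      function(i) {
        cd <- classify_duplication(dup$gene_a[i], dup$gene_b[i], models,
                                   tandem_gap_bp = config$tandem_gap_kb * 1000,
                                   max_intervening = config$max_intervening)
        cd$identity_pct <- dup$identity_pct[i]
        cd
      })) else NULL
    arch <- do.call(rbind, lapply(models, function(m) {
      a <- intron_phases(m)
      data.frame(gene_id = a$gene_id, exon_count = a$exon_count,
                 intron_phases = paste(a$intron_phases, collapse = ","),
                 intronless = a$intronless, stringsAsFactors = FALSE)
    }))
    grp_df <- if (length(groups)) data.frame(
      group_id = rep(seq_along(groups), lengths(groups)),
      gene_id = unlist(groups), stringsAsFactors = FALSE) else
      data.frame(group_id = integer(0), gene_id = character(0))
    chd <- chromosome_distribution(models)
    write_tsv(grp_df, file.path(config$out_dir, "homeolog_groups.tsv"))
    if (!is.null(dup_pairs))
      write_tsv(dup_pairs, file.path(config$out_dir, "duplicate_pairs.tsv"))
    write_tsv(arch, file.path(config$out_dir, "gene_architecture.tsv"))
    write_tsv(data.frame(chromosome = names(chd$counts), genes = chd$counts),
              file.path(config$out_dir, "chromosome_distribution.tsv"))
    rep$stages$structure <- list(
      genes_located = length(models), homeolog_groups = length(groups),
      duplicate_pairs = if (is.null(dup_pairs)) 0L else nrow(dup_pairs),
      tandem = if (is.null(dup_pairs)) 0L else sum(dup_pairs$kind == "tandem",
                                                   na.rm = TRUE),
      segmental = if (is.null(dup_pairs)) 0L else sum(dup_pairs$kind == "segmental",
                                                      na.rm = TRUE),
      intronless = sum(arch$intronless))
  }

  if ("evolution" %in% st && !is.null(dup_pairs) && nrow(dup_pairs) > 0) {
    cds <- read_fasta(config$cds, "dna")
    if (is.null(accepted)) accepted <- read_fasta(config$proteins, "protein")
    grp_of <- unlist(lapply(seq_along(groups), function(i)
      stats::setNames(rep(i, length(groups[[i]])), groups[[i]])))
    t1 <- list(); t2 <- list()
    for (i in seq_len(nrow(dup_pairs))) {
      ga <- dup_pairs$gene_a[i]; gb <- dup_pairs$gene_b[i]
      pr <- .aligned_pair_chars(unclass(accepted)[[ga]], unclass(accepted)[[gb]])
      aln <- tlp_seqs(c(paste(pr$a, collapse = ""), paste(pr$b, collapse = "")),
                      c(ga, gb), "protein", aligned = TRUE)
      ca <- backtranslate(aln, cds)
      kk <- ng86_kaks(ca)
      tm <- if (!is.na(kk$ks)) divergence_time(kk$ks, config$rate_r) else
        list(t_mya_1dp = NA_real_)
      t1[[i]] <- data.frame(
        gene_a = ga, gene_b = gb,
        ka = round_half_up(kk$ka, 4), ks = round_half_up(kk$ks, 4),
        ratio = round_half_up(kk$omega, 4),
        selection = kk$selection %||% NA_character_,
        t_mya = tm$t_mya_1dp, stringsAsFactors = FALSE)
      # outgroup: closest accepted gene outside the pair and their homeolog
      # groups (a related but external sequence maximizes comparable sites)
      excl <- c(ga, gb)
      for (g in c(ga, gb)) if (!is.na(grp_of[g] %||% NA))
        excl <- c(excl, groups[[grp_of[[g]]]])
      cand <- edges[xor(edges$gene_a %in% c(ga, gb), edges$gene_b %in% c(ga, gb)), ]
      cand$other <- ifelse(cand$gene_a %in% c(ga, gb), cand$gene_b, cand$gene_a)
      cand <- cand[!cand$other %in% excl, ]
      if (nrow(cand) > 0) {
        sc <- tapply(cand$identity_pct, cand$other, mean)
        og <- names(sc)[order(-sc, names(sc))][1]
        tri <- align_triple(unclass(accepted)[[ga]], unclass(accepted)[[gb]],
                            unclass(accepted)[[og]])
        caln <- backtranslate(tlp_seqs(tri, c(ga, gb, og), "protein",
                                       aligned = TRUE), cds)
        nuc <- flatten_codon_alignment(caln)
        tj <- tajima_relative_rate(nuc[[1]], nuc[[2]], nuc[[3]])
        t2[[length(t2) + 1L]] <- data.frame(
          group_a = ga, group_b = gb, outgroup = og, nt = tj$nt, na = tj$na,
          nb = tj$nb, chi2 = round_half_up(tj$chi2, 2),
          p = round_half_up(tj$p, 5), stringsAsFactors = FALSE)
      }
    }
    t1 <- do.call(rbind, t1)
    write_tsv(t1, file.path(config$out_dir, "kaks_divergence.tsv"))
    if (length(t2))
      write_tsv(do.call(rbind, t2), file.path(config$out_dir, "relative_rate.tsv"))
    rep$stages$evolution <- list(
      pairs_analyzed = nrow(t1),
      purifying = sum(t1$selection == "purifying", na.rm = TRUE),
      mean_t_mya = mean(t1$t_mya, na.rm = TRUE))
  }

  if ("promoters" %in% st) {
    promoters <- read_fasta(config$promoters, "dna")
    elements <- read_element_table(config$element_table %||%
                                     system.file("extdata", "cis_elements.tsv",
                                                 package = "tlpfam"))
    hits <- do.call(rbind, lapply(names(promoters), function(g)
      scan_elements(promoters[g], elements)))
    cats <- categorize_hits(hits, elements)
    write_tsv(hits, file.path(config$out_dir, "element_hits.tsv"))
    write_tsv(cats, file.path(config$out_dir, "element_categories.tsv"))
    rep$stages$promoters <- list(promoters_scanned = length(promoters),
                                 total_hits = nrow(hits),
                                 hits_per_category =
                                   as.list(colSums(cats[, -1, drop = FALSE])))
  }

  if ("expression" %in% st) {
    counts <- as.matrix(read_tsv(config$expression_counts)[, -1, drop = FALSE])
    cdf <- read_tsv(config$expression_counts)
    rownames(counts) <- cdf[[1]]
    lens <- read_tsv(config$expression_lengths)
    lengths <- stats::setNames(lens[[2]], lens[[1]])
    tot <- read_tsv(config$expression_totals)
    totals <- stats::setNames(tot[[2]], tot[[1]])
    m <- fpkm(counts, lengths, totals)
    treated <- setdiff(colnames(m), config$control_cond)
    de <- differential_filter(m, config$control_cond, treated,
                              min_fold = config$min_fold,
                              pseudo = config$fold_pseudo)
    k <- min(config$cluster_k, max(2, length(de$flagged)))
    cl <- if (length(de$flagged) >= 2)
      cluster_genes(m[de$flagged, , drop = FALSE], k = k) else NULL
    fpkm_df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    write_tsv(fpkm_df, file.path(config$out_dir, "fpkm.tsv"))
    de_df <- data.frame(gene_id = rownames(m),
                        differential = rownames(m) %in% de$flagged,
                        de$folds, check.names = FALSE)
    write_tsv(de_df, file.path(config$out_dir, "differential.tsv"))
    if (!is.null(cl))
      write_tsv(data.frame(gene_id = names(cl$groups), cluster = cl$groups),
                file.path(config$out_dir, "expression_clusters.tsv"))
    fates <- NULL
    if (!is.null(dup_pairs) && nrow(dup_pairs) > 0) {
      fates <- do.call(rbind, lapply(seq_len(nrow(dup_pairs)), function(i) {
        if (!all(c(dup_pairs$gene_a[i], dup_pairs$gene_b[i]) %in% rownames(m)))
          return(NULL)
        f <- duplicate_fate(m, dup_pairs$gene_a[i], dup_pairs$gene_b[i],
                            floor = config$expression_floor,
                            r_min = config$r_min)
        data.frame(gene_a = f$gene_a, gene_b = f$gene_b, fate = f$fate,
                   correlation = f$correlation, stringsAsFactors = FALSE)
      }))
      if (!is.null(fates))
        write_tsv(fates, file.path(config$out_dir, "duplicate_fates.tsv"))
    }
    qp <- NULL
    if (!is.null(config$qpcr)) {
      qp <- ddct_fold(read_tsv(config$qpcr), config$control_cond)
      write_tsv(qp, file.path(config$out_dir, "qpcr_folds.tsv"))
    }
    rep$stages$expression <- list(
      genes = nrow(m), differential = length(de$flagged),
      clusters = if (is.null(cl)) 0L else max(cl$groups),
      fates = if (is.null(fates)) NULL else as.list(table(fates$fate)),
      qpcr_rows = if (is.null(qp)) 0L else nrow(qp))
  }

  rep <- structure(rep, class = "tlp_report")
  jsonlite::write_json(unclass(rep), file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  rep
}

#' @export
print.tlp_report <- function(x, ...) {
  cat("tlpfam pipeline report\n")
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-10s %s\n", nm,
                paste(names(s), vapply(s, function(v)
                  paste(format(unlist(v)), collapse = "/"), ""), sep = "=",
                  collapse = ", ")))
  }
  invisible(x)
}
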