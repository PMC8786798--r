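test_that("promoter windows follow strand and truncate at chromosome ends", {
  set.seed(71)
  chrom <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  genome <- tlp_seqs(c(chr1 = chrom), alphabet = "dna")
  plus <- gene_model("gp", "chr1", "+", cbind(2001, 4000),
                     cds = cbind(2001, 4000, 0))
  pp <- extract_promoter(plus, genome)
  expect_equal(unname(unclass(pp)[[1]]), substr(chrom, 501, 2000))
  expect_false(attr(pp, "truncated"))

  minus <- gene_model("gm", "chr1", "-", cbind(2001, 4000),
                      cds = cbind(2001, 4000, 0))
  pm <- extract_promoter(minus, genome)
  expect_equal(unname(unclass(pm)[[1]]),
               oracle_revcomp(substr(chrom, 4001, 5500)))

  near <- gene_model("gn", "chr1", "+", cbind(800, 2000),
                     cds = cbind(800, 2000, 0))
  pn <- extract_promoter(near, genome)
  expect_true(attr(pn, "truncated"))
  expect_equal(attr(pn, "window_bp"), 799)

  lost <- gene_model("gl", "chrX", "+", cbind(2001, 4000),
                     cds = cbind(2001, 4000, 0))
  expect_error(extract_promoter(lost, genome), "chrX")
})

test_that("a motif planted on the minus strand is found after extraction", {
  set.seed(72)
  chrom <- paste(sample(c("A", "C"), 8000, TRUE), collapse = "")
  # plant the reverse complement of TGTCTC upstream (genomically downstream)
  # of a minus-strand gene; extraction should expose the motif on +
  motif <- "TGTCTC"
  substr(chrom, 4100, 4105) <- oracle_revcomp(motif)
  genome <- tlp_seqs(c(chr1 = chrom), alphabet = "dna")
  gm <- gene_model("g", "chr1", "-", cbind(2001, 4000), cds = cbind(2001, 4000, 0))
  prom <- extract_promoter(gm, genome)
  el <- data.frame(name = "ARFAT", iupac_pattern = motif, category = "hormone")
  hits <- scan_elements(prom, el)
  expect_true(any(hits$strand == "+" & hits$matched_seq == motif))
})

test_that("IUPAC element scanning handles degeneracy and both strands", {
  el <- function(name, pat, cat = "light") {
    data.frame(name = name, iupac_pattern = pat, category = cat,
               stringsAsFactors = FALSE)
  }
  h <- scan_elements("AAGATAAA", el("GATABOX", "GATA"))
  expect_true(any(h$strand == "+" & h$start == 3 & h$end == 6))

  hw <- scan_elements("CCTAAAGCC", el("POLLEN", "WAAAG"))
  expect_true(any(hw$strand == "+" & hw$start == 3))  # W matches T

  # minus-strand hit coordinates mirror and matched_seq satisfies pattern
  hm <- scan_elements("CCGAGACACC", el("ARFAT", "TGTCTC", "hormone"))
  expect_true(any(hm$strand == "-"))
  expect_equal(hm$matched_seq[hm$strand == "-"], "TGTCTC")
})

test_that("element scanning equals the sliding-window oracle", {
  elements <- read_element_table()
  set.seed(73)
  for (i in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    hits <- scan_elements(tlp_seqs(c(p = s), alphabet = "dna"), elements)
    for (j in seq_len(nrow(elements))) {
      pat <- elements$iupac_pattern[j]
      plus <- oracle_iupac_hits(s, pat)
      minus <- oracle_iupac_hits(s, oracle_revcomp(pat))
      got <- hits[hits$element_name == elements$name[j], ]
      expect_setequal(got$start[got$strand == "+"], plus)
      expect_setequal(got$start[got$strand == "-"], minus)
    }
  }
})

test_that("scanning a promoter and its reverse complement mirrors hits", {
  elements <- read_element_table()
  set.seed(74)
  s <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  h_fwd <- scan_elements(s, elements)
  h_rev <- scan_elements(oracle_revcomp(s), elements)
  n <- nchar(s)
  mirrored <- data.frame(element_name = h_rev$element_name,
                         strand = ifelse(h_rev$strand == "+", "-", "+"),
                         start = n - h_rev$end + 1, end = n - h_rev$start + 1)
  key <- function(d) sort(paste(d$element_name, d$strand, d$start, d$end))
  expect_equal(key(h_fwd[, c("element_name", "strand", "start", "end")]),
               key(mirrored))
})

test_that("category counts aggregate per gene and ignore table order", {
  elements <- read_element_table()
  hits <- data.frame(gene_id = c("g1", "g1", "g1", "g2"),
                     element_name = c("GATABOX", "IBOXCORE", "CBFHV", "ARFAT"),
                     strand = "+", start = 1:4, end = 5:8,
                     matched_seq = "X", stringsAsFactors = FALSE)
  cc <- categorize_hits(hits, elements)
  g1 <- cc[cc$gene_id == "g1", ]
  expect_equal(unlist(g1[, c("growth_development", "light", "hormone", "stress")],
                      use.names = FALSE), c(0L, 2L, 0L, 1L))
  cc2 <- categorize_hits(hits, elements[rev(seq_len(nrow(elements))), ])
  expect_equal(cc, cc2)
  # no hits: zero rows, not an error
  none <- categorize_hits(hits[0, ], elements)
  expect_equal(nrow(none), 0)
})

test_that("the element table loader rejects malformed tables", {
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("name\tiupac_pattern\tcategory", "EL1\tGAZA\tlight"), bad)
  expect_error(read_element_table(bad), "IUPAC")
  short <- tempfile(fileext = ".tsv")
  writeLines(c("name\tiupac_pattern\tcategory", "EL1\tGAT\tlight"), short)
  expect_error(read_element_table(short), ">= 4")
  wrongcat <- tempfile(fileext = ".tsv")
  writeLines(c("name\tiupac_pattern\tcategory", "EL1\tGATA\tcolor"), wrongcat)
  expect_error(read_element_table(wrongcat), "category")
})
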