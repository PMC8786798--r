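---
title: "Characterizing a thaumatin-like protein gene family: models, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing a thaumatin-like protein gene family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlpfam)
```

This vignette is the package's account of the science it implements: the
models and rules behind each stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was genuinely
open.

## The analysis

Thaumatin-like proteins (TLPs, PR-5 family) form mid-sized gene families in
cereal genomes. A family characterization proceeds through five stages, each
of which this package implements as standalone functions orchestrated by
`run_pipeline()`:

1. **Screening.** A candidate protein belongs to the family iff it carries a
   complete thaumatin signature motif,
   `G-X-[GF]-X-C-X-T-[GA]-D-C-X(1,2)-G-X(2,3)-C`. The matcher reports every
   start position with a complete match; at each start, variable-length
   wildcard runs take their *shortest* satisfying expansion (non-greedy
   PROSITE semantics). This changes the reported end coordinate, never hit
   existence. Unknown residues (`X`) satisfy no pattern position, including
   wildcards, so a signature interrupted by sequencing ambiguity does not
   count as complete. The screen accepts a signature anywhere in the
   protein, and records where; restricting it to an annotated domain is a
   caller-side filter.

2. **Long vs small classes.** Published mature-protein weight ranges
   (~21–26 vs ~16–17 kDa) conflict with full-protein averages once signal
   peptides are included (~29–35 vs ~17–19 kDa), but the thaumatin-domain
   length ranges are disjoint: ~202–217 aa (long) vs ~134–154 aa (small).
   Classification is therefore primarily by domain length (≥ 180 aa →
   long), with molecular weight as a secondary guard for the small class
   (< 180 aa **and** < 22 kDa → small); everything else is `ambiguous`,
   never silently assigned. Domain boundaries come from an annotation table
   (domain search tools are external); without one, the signature footprint
   ± 60 aa is used as a proxy and flagged — the proxy underestimates long
   domains, so a real annotation is strongly preferred.

3. **Family structure.** "Sequence similarity" is implemented as percent
   identity over global-alignment columns (BLOSUM62, gap opening 10,
   extension 0.5, via `Biostrings::pairwiseAlignment`), with terminal gap
   overhangs excluded so length differences do not dilute identity.
   Identity, unlike BLOSUM positives, has unambiguous threshold semantics.
   Homeolog groups are maximal cliques (not connected components, which
   would chain through promiscuous members) over ≥ 90%-identity edges
   restricted to same-chromosome-number, distinct-subgenome gene pairs.
   Duplicate pairs are bidirectional best hits at ≥ 80% identity, made
   disjoint greedily by descending identity because published families
   report disjoint pairs. Homeologous pairs are excluded from duplicate
   detection: inter-subgenome copies are products of polyploidization, not
   of the within-genome duplication events being classified. Tandem vs
   segmental uses thresholds the literature leaves implicit; we adopt the
   common conventions of ≤ 100 kb gap or ≤ 5 intervening family genes on
   one chromosome (both configurable).

4. **Molecular evolution.** Codon alignments are built by back-translating
   a protein alignment against the CDS (PAL2NAL-style; each CDS must
   translate exactly to its protein, trailing stops stripped). Ka and Ks
   follow Nei–Gojobori (1986): per-codon synonymous site fractions from the
   standard code averaged over both sequences; observed differences
   averaged with equal weight over all minimal mutational pathways, paths
   through stop codons excluded (PAML convention — this shifts Ks slightly
   on codons adjacent to stops; if every pathway is blocked, all are used
   so the codon still contributes); Jukes–Cantor correction
   `d = -(3/4) ln(1 - (4/3)p)`, flagged saturated at `p ≥ 3/4` rather than
   returning a number. Divergence time is `T = Ks/(2r)` with the grass
   synonymous clock `r = 6.5e-9` per site per year. Tajima's relative-rate
   test counts, per alignment column, sites identical in all three
   sequences (`nt`), unique differences in A (`na`) and in B (`nb`);
   columns where all three differ, or where A = B ≠ outgroup, count toward
   none (Tajima 1993). `χ² = (na − nb)²/(na + nb)` on 1 df; `p = 1` when
   `na + nb = 0`. Published tables of this kind are ambiguous about whether
   counts are nucleotide or amino-acid sites, so both modes exist
   (`mode = "nucleotide"` is the default, applied to the codon alignment
   flattened to nucleotides) and neither is asserted as "the" published
   mode. Report rounding follows the published precision: Ka/Ks to 4
   decimals, T to 1, χ² to 2, P to 5 — with half-up rounding, matching
   spreadsheet-style output rather than banker's rounding.

5. **Promoters and expression.** Promoter windows are 1.5 kb upstream of
   the initiation codon (reverse-complemented for minus-strand genes,
   truncated and flagged at chromosome edges). Elements are scanned as
   IUPAC-degenerate patterns on both strands — the convention of classical
   promoter-database scans; published analyses rarely state their strand
   handling, so both-strand is the default with a flag to restrict — with
   overlaps allowed and a bundled ~27-element table (published consensus
   motifs, user-replaceable). FPKM is `counts·10⁹/(length·total)` with
   annotated exonic length (no effective-length correction). Differential
   calls use raw FPKM ratios with a 0.01-FPKM pseudocount (zero handling is
   unstated in the published analyses; the pseudocount is configurable) and
   flag any gene ≥ 2-fold up or down in at least one treated condition.
   Clustering is hierarchical on `log2(FPKM + 1)` with Euclidean distance
   and average (UPGMA) linkage — the clustering tool used in the published
   analyses does not document its default linkage, so this choice is
   explicit and configurable. qPCR fold change is `2^-ΔΔCt` with replicate
   SD and a two-tailed equal-variance t-test on replicate ΔCt values
   (degenerate zero-variance replicates give `NA` rather than a fabricated
   p). Duplicate fates: a gene is expressed if its max FPKM ≥ 1; exactly
   one expressed → pseudo-functionalization; both expressed → retention if
   Pearson r ≥ 0.6 across conditions, else neo-functionalization. The
   floor and correlation threshold are artifact decisions — the literature
   gives categories, not cutoffs.

## The synthetic-data generator

Real analyses of this kind consume reference genomes and RNA-seq archives.
The generator stands in for those inputs with known ground truth, so that
recovery can be asserted exactly rather than approximately.

The default `family_spec()` *is* the study condition: 93 genes emulating the
hexaploid wheat family — 27 complete A/B/D homeolog triplets (81 genes; 7
triplets small-type, giving 21 small TLPs, matching the ~20/93 published
split) plus 6 duplicate pairs (1 tandem, 5 segmental, the wheat
tandem/segmental split) evolved at ω = 0.10–0.15 and Ks = 0.30–0.80 —
purifying selection inside the non-saturated part of the published Ks range.
Homeolog copies diverge by ~2% amino-acid substitutions from their group
ancestor (pairwise ~96% identity, comfortably above the 90% threshold);
distinct families are unrelated random sequences (~10% identity,
comfortably below 80%).

Design points worth knowing:

- **Exact censuses by construction.** Proteins carry a planted signature
  instance and exactly 16 (long) or 10 (small) cysteines inside the domain;
  flanks are cysteine-free; substitutions never create or destroy a
  cysteine and never touch the signature footprint. This is what makes
  "cysteine census recovered exactly" a meaningful test.
- **Residue composition.** Background residues are drawn from a typical
  plant-proteome composition rather than uniformly. Uniform sampling
  averages ~119 Da per residue and pushes 185-aa small TLPs against the
  22 kDa class guard; real small TLPs weigh 17–19 kDa, and the weighted
  composition reproduces that.
- **Codon evolution.** `evolve_pair()` runs two independent branches of
  expected `Ks/2` synonymous substitutions per synonymous site. Proposals
  pick a codon position and a non-stop alternative uniformly; synonymous
  proposals are accepted with probability `1/q`, non-synonymous with
  `ω/q` (`q = max(1, ω)`). Targets are therefore *expectations*; realized
  substitution counts are recorded for tolerance-free tests. The
  per-site rate calibration is consistent with the NG86 site definition
  used by the estimator, which is why parameter recovery is unbiased to
  within simulation noise.
- **Pair detectability is an invariant, not luck.** A planted duplicate
  pair must satisfy the ≥ 80%-identity detection rule; realizations that
  fall below it (possible at Ks ≈ 0.8) are rejected and re-evolved on a
  derived seed.
- **Expression.** Genes are assigned archetype mean profiles (flat,
  early-up, late-up, down) on the log2 scale; differential archetypes are
  planted at ≥ 2.5-fold so they clear a 2-fold filter even with the
  pseudocount. At `noise_sd = 0` counts are expected (possibly fractional)
  fragment counts and realized FPKM equals the archetype exactly, making
  end-to-end differential recovery an equality, not a tolerance, test.
- **Determinism.** Every generator is a deterministic function of its seed;
  `simulate_tlp_bundle()` derives sub-generator seeds at fixed offsets so
  each stream is independently reproducible.

What the generator does **not** emulate: codon-usage bias, indels (all
divergence is substitution-only, so alignments are trivially correct),
read-level noise, batch effects, genome-scale intergenic sequence, or
realistic promoter background composition beyond a mild AT bias.
Consequently, passing recovery tests demonstrates the correctness of the
implemented rules under their stated assumptions — not robustness to
alignment error, annotation noise, or expression normalization artifacts in
real data.

## Numerical choices and degenerate inputs

- Percent identity excludes terminal gap overhang columns; two sequences
  with no aligned overlap get identity 0.
- The all-vs-all similarity step applies a BLAST-like 6-mer word prefilter:
  pairs sharing < 2% of 6-mer words are not globally aligned (they cannot
  approach the 80–90% thresholds — at 80% identity roughly a quarter of all
  6-mers survive) and carry the word-sharing fraction, capped at 50, as a
  surrogate. `kmer_prefilter = FALSE` aligns every pair.
- pI is found by bisection of the Henderson–Hasselbalch net charge on
  [0, 14] to |charge| < 1e-4, with the Bjellqvist pKa set (N-term 7.5,
  C-term 3.55, D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0).
- Ties in best-hit ranking and greedy pairing break by lexicographic id;
  clique selection prefers larger cliques, then smaller first member.
  Both make results invariant to input order.
- Intron phases are cumulative CDS length 5' of each intron mod 3, in
  transcription order; UTR introns get phase 0; a CDS total that is not a
  multiple of 3 warns but still reports phases.
- The relative-rate pipeline stage aligns pair + outgroup by merging the
  two pairwise alignments on the shared coordinate system of the first
  pair member — adequate for counting shared/unique differences among
  closely related sequences; full multiple alignment is delegated to
  external tools in real analyses.
- `verify_tables()` uses interval-consistency checks: printed derived
  columns were computed upstream from *unrounded* inputs, so the test asks
  whether the printed value is consistent with any inputs that round to
  the printed inputs. Five rows of the bundled Ka/Ks table fail even this
  (two look like a column shift across adjacent rows; three divergence
  times are off by one in the last decimal) and are flagged, not matched.

## Problem sizes

The shipped tests and the acceptance script use: the default 93-gene bundle
for end-to-end recovery; 50 random 100-codon pairs for estimator-vs-oracle
equivalence at 1e-9; 100 replicates of 500 codons per ω setting for
parameter recovery; and 1,000 clock-true triples of 500 sites for the
relative-rate type-I error. These sizes give stable Monte-Carlo estimates
(SE of the type-I rate ≈ 0.007; SE of mean ω̂ ≈ 1–2% of ω) while keeping a
full run in the minutes range on one core.

## Known limitations

- NG86 with JC correction underestimates rates under strong
  transition/transversion bias or codon-usage bias; the estimator is
  deliberately swappable behind `ng86_kaks()`'s result contract.
- The ±60 aa signature-footprint domain proxy misclassifies long TLPs;
  supply a domain table.
- Homeolog grouping assumes wheat-style `<number><subgenome>` chromosome
  names for subgenome inference; other naming schemes need explicit
  subgenome tags on the gene models.
- The qPCR SD propagates replicate ΔCt variation of the treated group
  around the control mean; error in the control mean itself is reflected
  in the t-test, not the SD bar.
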