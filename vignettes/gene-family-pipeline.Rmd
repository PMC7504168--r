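---
title: "Methods: the gene-family characterization pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gene-family characterization pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`genefamr` re-implements, as one coherent and testable pipeline, the standard
genome-wide survey of a plant gene family: who the members are, what their
proteins look like, how the family expanded (tandem vs segmental
duplication), what selection pressure it evolved under, how it responds to
nutrient stress, which members are coexpression hubs, and what regulatory
elements sit in its promoters. This vignette documents the models and the
design decisions; the README shows a worked example.

## Family identification

Candidates are aligned to a labelled reference protein set (one or more
reference proteins per subfamily, FASTA headers `<ref>|<subfamily>`) with
affine-gap Smith–Waterman under BLOSUM62 (gap open 10, extension 0.5; the
unknown residue X scores 0). A candidate joins the family iff its
best-scoring reference hit exceeds **both** 75% similarity and 75%
coverage-of-the-longer-sequence, strictly. "Similarity" is not defined in
most survey papers; here it is the percentage of aligned columns with a
positive BLOSUM62 score, reported next to plain identity. Manual redundancy
removal is formalized as the only reproducible rule: candidates with
byte-identical protein sequences collapse to the lexicographically smallest
id. Systematic names follow
`<Species><Chr>.<Reference><suffix>` with suffix letters assigned in
(chromosome, start) order inside each reference group, singletons unsuffixed.

No pre-filter (e.g. an E-value screen) precedes the 75/75 criteria: they are
the sole membership rule, applied to the best hit per candidate.

## Protein characterization

* **MW**: sum of average residue masses minus one water per peptide bond.
* **Theoretical pI**: Henderson–Hasselbalch net charge with the EMBOSS pKa
  set (N-term 8.6, C-term 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5,
  Y 10.1), root found by bisection on pH 0–14 to 0.001. Exact parity with
  ProtParam's unpublished internals is not promised; the charge identity is
  what the tests assert, against a 10,000-point grid oracle.
* **GRAVY**: mean per-residue Kyte–Doolittle hydropathy; GRAVY > 0 is
  classified hydrophobic. The scale is a configuration table.
* **TMD counts**: a 19-residue centered hydropathy window at cutoff 1.6
  (both configurable); qualifying window extents are merged and each merged
  run is one predicted TMD. This is the classic window method, not an HMM:
  counts on real transporters will differ from TMHMM, and on synthetic data
  the planted count is the recovery target.

## Selection pressure and phylogeny

Member/reference protein pairs are globally aligned, back-translated through
their CDS (mismatching translations are an error naming the residue), and
passed to a Nei–Gojobori (1986) estimator: per-codon synonymous site
fractions averaged over the two sequences; observed differences averaged
over all minimal mutational pathways with equal weights; Jukes–Cantor
correction d = −(3/4)·ln(1 − 4p/3). Two conventions the method's common
descriptions leave open are fixed as follows and exercised by the test
oracle: changes
that create a stop codon count as nonsynonymous in the site fractions, and
pathways passing through a stop codon are excluded (all pathways are used,
with stop steps nonsynonymous, only if every pathway is blocked). Saturation
(p ≥ 3/4) gives an undefined rate; Ks = 0 an undefined ratio. Ratios map to
purifying (< 1), neutral (= 1) and positive (> 1) selection.

Trees are neighbor-joining on protein p-distances (the common MEGA default),
with ties broken by the smallest index pair and negative branch estimates
clamped to zero with the deficit moved to the sister branch. Bootstrap
(default 1000 column resamples) maps support onto the original tree's
bipartitions, as MEGA annotates, rather than building a consensus tree. A
center-star progressive aligner is provided for desk-scale multiple
alignments; any external alignment can be supplied instead.

## Duplication and synteny

Homologous pairs (same strict 75/75 filter) are classified:

* **tandem** — same chromosome and an inter-gene gap (downstream start minus
  upstream end, floored at 0) of at most 200 kb;
* **segmental** — membership in a collinear block: per chromosome pair,
  chains of pairs monotone in rank order on both sides (either orientation),
  found by dynamic programming with both rank gaps ≤ 10, reported at ≥ 5
  pairs, each pair assigned greedily to its best chain. A pair matching both
  definitions resolves to tandem, the more specific claim.

`min_block = 5` and `max_gap = 10` follow common collinearity-scanner
defaults; unlike a whole-genome scanner, chains are built over the supplied
homolog pairs only, which is sufficient for planted-truth recovery and keeps
the module desk-scale. Cross-species synteny reuses the same chaining across
two genomes and partitions family pairs by the target-side subgenome letter.

## Expression, networks, qPCR

DEGs are called per (tissue, contrast vs CK) with a Welch t-test on
log2(FPKM + 1) and BH adjustment within the contrast; a gene is a DEG iff
|log2FC| ≥ 1 (log2 ratio of group mean FPKM + 1) and FDR < 0.05.
Family-survey reports rarely state DEG thresholds; these defaults live in
the run configuration and are echoed to the log. Venn partitions and universal
responders (the intersection over all condition sets) are set operations on
the called sets.

The coexpression network is Pearson correlation over the samples of the
N-sufficient and N-free treatments (CK, LN; replicates as individual
samples), an edge wherever |r| > 0.6 — the cutoff is applied to |r| since
the study phrasing does not sign it; a signed mode is a flag. Hubs are the
top 10 nodes by degree, ties lexicographic. qPCR fold changes follow
2^−ΔΔCt against a housekeeping reference and a calibrator condition, with
two-sided Welch tests on replicate ΔCt values flagged at P < 0.05 and
P < 0.01.

## The synthetic study and what it shows

`simulate_corpus()` generates four chromosomes (two per subgenome), 40
family members derived from 24 reference proteins (8 subfamilies × 3) by
amino-acid substitution at rate 0.15 — high enough divergence to be
realistic, low enough to clear the 75/75 filter — plus 60 unrelated decoys
that cannot clear it. Planted structure: one tandem pair 6.5 kb apart; two
cross-subgenome collinear blocks of five consecutive gene pairs (copies at
substitution rate 0.03), one in inverted orientation; intron counts drawn
mostly from 2–5 (mode 3 at 45.6%); CDSs derived with synonymous codon swaps
(rate 0.3 vs references, 0.05 for copies) so Ks exceeds Ka and within-family
ratios come out purifying without saturating. Same-reference "independent"
members are never placed on one chromosome or on a planted block's
chromosome pair, so stray homolog pairs cannot create false tandems or
corrupt exact block recovery.

Expression: log2-FPKM baselines ~ N(6, 1.2) — moderately expressed
transporters, FPKM roughly 8–500 — with i.i.d. N(0, 0.25) log-scale noise.
That baseline matters: genes near FPKM 1 would make a planted twofold-change
invisible to the pseudocount-protected fold-change rule, defeating the
generator's purpose of detectable planted effects at n = 3. Each of the 8
(tissue, contrast) sets plants 28 DEGs (27 at |log2FC| = 2 plus one
universal responder at log2FC 4 present in every set): with n = 3 the Welch
statistic has an unstable denominator and the BH step only reaches the
planted genes' p-value tail when a set carries paper-scale signal (a quarter
of the genes), which simulation shows gives recall ≈ 0.96 and a
false-positive rate ≈ 0. The nitrogen-contrast responders are drawn from
the decoys (the network is computed among family genes only, matching the
family-wise network of the study design), so the CK/LN samples carry no
family-side DE clique that could out-degree the planted hub. The hub module
is 12 family genes sharing a latent factor at target r = 0.85 to the hub
(r² ≈ 0.72 between members); the factor is replicate-linked and balanced
within every treatment group — it cannot shift group means (no false DEGs)
and always has spread in any sample subset, so the planted correlation
materializes in every draw rather than only in lucky ones.

Promoters are 2,000 bp. Family promoters are scrubbed of chance catalog
matches (any residual match is mutated away) before literature-consensus
elements are inserted at recorded positions and strands; a promoter is
re-drawn if an insertion junction creates an extra match. The recorded truth
is the full expected hit set — including the mirror hits of palindromic
motifs (G-box, MYC) and strand-twin motifs (TGACG/CGTCA) — so scanning
recovers it exactly, not approximately. Ct tables satisfy
Ct_target = Ct_ref + offset − log2(fold) + N(0, 0.2²), so zero-noise tables
invert exactly.

What passing these tests does **not** show: performance on real genomes
(fragmented assemblies, alternative splicing, tandem arrays larger than
two, overdispersed counts, batch effects) and agreement with the specific
external tools a study may have used (BLASTP E-values, TMHMM, PlantCARE
matrices, MCScanX block definitions). The synthetic corpus validates the
logic and the planted-parameter recovery, not those tool equivalences.

## Problem sizes and numerics

The shipped tests and the acceptance script run the default corpus (100
genes, 30 samples), 100 expression redraws for hub recovery, ≥ 200 random
codon pairs against the Ka/Ks pathway oracle, and ≥ 100 random 5–8-leaf
additive trees for NJ — sizes chosen so the whole suite completes in
minutes on one core while keeping every estimator's oracle comparison
exhaustive at small n. Bisection tolerance for pI is 0.001 pH; JC saturation
is reported as undefined rather than clamped; all randomness flows from a
single integer seed per run, with stage seeds derived by fixed offsets.
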