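# genefamr

Genome-wide characterization of a plant gene family, as one tested, reusable
R pipeline. The package targets the common "family survey" study design used
for transporter families such as the nitrate/peptide NPF family: starting
from a genome annotation, protein and CDS sequences, a labelled reference
protein set, an FPKM expression matrix and a qPCR Ct table, it

- identifies family members by local-alignment homology to the reference set
  (strict > 75% similarity and > 75% coverage-of-longer, with redundancy
  collapse), assigns subfamilies and systematic names such as
  `BnaA03.NPF4;1a`, and tabulates copy numbers and intron structure;
- characterizes the proteins: molecular weight, theoretical pI
  (Henderson–Hasselbalch bisection), GRAVY (mean Kyte–Doolittle hydropathy;
  GRAVY > 0 = hydrophobic) and hydropathy-window transmembrane-domain counts;
- quantifies selection pressure with Nei–Gojobori (1986) Ka/Ks
  (pathway-averaged counts, Jukes–Cantor correction; Ka/Ks < 1 purifying,
  = 1 neutral, > 1 positive) and builds neighbor-joining trees with
  bootstrap support;
- classifies duplication events: tandem (homologous pair within 200 kb on
  one chromosome) versus segmental (pair inside a collinear block of ≥ 5
  ordered homologous pairs, chained by dynamic programming on gene ranks),
  plus cross-species synteny per subgenome;
- calls differentially expressed genes per tissue × nutrient contrast
  (Welch t-test on log2(FPKM+1), BH FDR < 0.05, |log2FC| ≥ 1), partitions
  them into Venn regions, finds universal responders, builds the Pearson
  coexpression network (|r| > 0.6) and ranks hub genes by degree;
- scans 2.0-kb promoters against an editable IUPAC consensus catalog of
  cis-regulatory elements (G-box, ABRE, MYB, MYC, GATA-box, ...);
- computes relative qPCR expression by the 2^−ΔΔCt method with significance
  flags (* P < 0.05, ** P < 0.01).

Because real survey inputs (genome releases, in-house RNA-seq) are not
reproducible at desk scale, the package ships a synthetic-study
generator, `simulate_corpus()`, that emits a complete corpus — genome FASTA,
GFF3, proteins, CDS, promoters, expression matrix, Ct table — with a
machine-readable truth record (planted family members, one tandem pair 6.5 kb
apart, two cross-subgenome collinear blocks, planted DEG sets, a correlated
hub module, planted promoter elements, known qPCR fold changes). Every
analysis stage is validated by recovering that planted truth.

## Worked example

```r
library(genefamr)

cfg <- default_config()
corpus <- simulate_corpus(tempfile("corpus"), cfg)

# family identification against the labelled reference set
refs <- setNames(corpus$sim$ref_proteins,
                 paste0(names(corpus$sim$ref_proteins), "|",
                        corpus$sim$ref_subfamily))
members <- identify_family(corpus$sim$proteins, refs)
nrow(members)
#> [1] 40
all(members$gene_id %in% corpus$truth$family_members$gene_id)
#> [1] TRUE

# duplication classification
pairs  <- filter_homolog_pairs(pairwise_hits(
            corpus$sim$proteins[members$gene_id]))
tand   <- detect_tandem(pairs, corpus$sim$genes)
tand$separation_bp
#> [1] 6500
blocks <- chain_collinear_blocks(pairs, corpus$sim$genes, corpus$sim$genes)
vapply(blocks, `[[`, 0L, "size")
#> [1] 5 5

# nutrient-stress DEGs and the coexpression hub
expr <- corpus$expression
degs <- call_all_degs(expr$matrix, expr$samples)
net  <- build_network(expr$matrix[members$gene_id, ], expr$samples)
head(hub_genes(net), 3)
#>      gene_id degree
#> 1 SynC01g100     14
#> 2 SynA01g100     13
#> 3 SynA02g150     12
```

The 40 identified members are exactly the planted family (precision =
recall = 1); the single recovered tandem pair sits at the planted 6,500 bp
separation; the two recovered blocks of five gene pairs match the planted
collinear blocks, one in the same orientation and one inverted; the
top-ranked hub, `SynC01g100` with 14 coexpression partners, is the planted
hub gene.

## Package layout

- `R/` — implementation: io, simulation, family catalog, protein
  characterization, evolution (Ka/Ks, NJ, bootstrap), duplication/synteny,
  expression/networks, promoter scanning.
- `inst/extdata/cre_catalog.tsv` — literature IUPAC consensus catalog
  (editable TSV: name, consensus, category).
- `vignettes/gene-family-pipeline.Rmd` — methods vignette: the models,
  parameter choices, generator design and limitations.
- `tests/testthat/` — unit, property and acceptance tests with independent
  brute-force oracles.
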