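# codonscape

Comparative codon-level selection and conservation analysis for bacterial
gene families.

`codonscape` is built for the kind of question asked of bacterial
membrane-protein families such as TatC, the substrate-recognition component
of the twin-arginine (Tat) translocase: across hundreds of homologues, which
lineages are maintaining the gene under purifying-dominated pressure and
which are diversifying? Which residues and membrane-spanning regions carry
the conservation signal, and which genes travel with the locus in its operon
neighborhood?

The package implements the full desk-side pipeline around those questions:

* **Codon alignments** — back-translation of a protein multiple alignment
  onto unaligned coding sequences (`backtranslateAlignment()`), with strict
  register validation, terminal-stop stripping, and explicit (never
  automated) column removal.
* **Synonymous/non-synonymous substitution statistics** — Nei–Gojobori
  (1986)-style counting as popularised by SNAP. Per codon, the synonymous
  site count is

  `S(codon) = Σ_pos (# synonymous single-nucleotide neighbors / # non-stop neighbors)`,

  with `N = 3 − S`. Observed differences between two codons are averaged
  over all `d!` minimal mutational pathways, excluding pathways through stop
  codons (`pathwayCounts()`). Proportions `pS = Sd/S`, `pN = Nd/N` are
  corrected with the Jukes–Cantor transformation
  `d = −(3/4)·ln(1 − (4/3)p)`, which is undefined at `p ≥ 0.75`; such pairs
  are flagged saturated and excluded from means (`pairwiseDsDn()`,
  `allPairsDsDn()`, `perSequenceMeanDsDn()`). Per-codon mean synonymous
  substitution profiles come from `perCodonSd()`.
* **Conservation profiling** — per-column consensus residue and % identity
  (all-rows denominator), high/low classification at 75 % / 25 %, and
  comparison of sub-group consensus (e.g. two isoform clades) against the
  overall profile (`conservationProfile()`, `classifyColumns()`,
  `compareGroupProfiles()`).
* **Transmembrane consensus** — per-residue intersection of several TM
  predictions into consensus membrane-spanning regions, with a built-in
  Kyte–Doolittle hydropathy predictor so the rule is testable offline
  (`hydropathyPredict()`, `consensusTM()`, `tmAgreement()`).
* **Operon context** — ±10-gene neighborhoods around focal loci from GFF3 or
  TSV annotation, per-gene association frequency `freq = n_gene / O`
  (fraction of neighborhoods containing the gene), and conservation classes
  moderate (50–80 %) / high (≥80 %) (`extractNeighborhood()`,
  `geneAssociationFrequency()`, `classifyGeneConservation()`).
* **Summaries** — Tukey boxplot statistics (type-7 quantiles, 1.5×IQR
  fences) per group and selection-regime classes with the neutral cutoff at
  dS/dN = 1 (`boxplotStats()`, `selectionClass()`).
* **Synthetic data** — generators for codon alignments evolved at a
  controlled dN/dS (ω) along a tree, annotation tables with planted
  neighborhood gene frequencies, and 6-TM membrane proteins with known
  intervals (`simulateCodonAlignment()`, `simulateOperonTables()`,
  `simulateTmProtein()`), so every stage of the pipeline can be validated
  against planted truth.

A command-line front-end (`runCli()`, installed as `inst/exec/codonscape`)
exposes the stages as subcommands: `backtranslate`, `dsdn`, `sd-profile`,
`consensus`, `compare-consensus`, `tm-consensus`, `operon`, `summarize`,
`simulate`.

## Worked example

```r
library(codonscape)

prot <- c(eco = "MKLVTAGSERLIW", bsu = "MKLVTAGSERLIW", vdi = "MKLVTAGSDRLIW")
cds  <- c(eco = "ATGAAACTGGTTACCGCTGGCAGCGAACGTCTGATTTGG",
          bsu = "ATGAAACTGGTAACCGCAGGCAGCGAACGTCTGATTTGG",
          vdi = "ATGAAACTGGTTACCGCTGGCAGCGATCGTCTGATCTGG")
aln <- backtranslateAlignment(prot, cds)
aln
#> CodonAlignment with 3 sequences x 13 codons
#>   ids: eco, bsu, vdi

pairs <- allPairsDsDn(aln)
pairs[, c("id_a", "id_b", "Sd", "Nd", "pS", "pN", "dS", "dN", "ratio")]
#>   id_a id_b Sd Nd    pS     pN    dS     dN ratio
#> 1  eco  bsu  2  0 0.214 0.0000 0.252 0.0000    NA
#> 2  eco  vdi  1  1 0.107 0.0337 0.116 0.0345  3.35
#> 3  bsu  vdi  3  1 0.321 0.0337 0.420 0.0345 12.17
```

The eco–bsu pair has only synonymous differences, so `dN = 0` and the ratio
is left missing rather than infinite. The other two pairs have
`dS/dN > 1`: synonymous divergence outpaces non-synonymous divergence per
site, the signature of a maintained (purifying-dominated) coding sequence.

```r
m <- perSequenceMeanDsDn(pairs)
m$perSequence
#>    id mean_ratio pairs_computable pairs_total
#> 1 eco       3.35                1           2
#> 2 bsu      12.17                1           2
#> 3 vdi       7.76                2           2
m$computableFraction
#> [1] 0.667
selectionClass(m$perSequence$mean_ratio)
#> [1] "maintained" "maintained" "maintained"
```

Each sequence's mean dS/dN is averaged over its computable pairs only;
`computableFraction` reports how many pairwise comparisons survived the
saturation guard. A neutral-simulation sanity check:

```r
sim <- simulateCodonAlignment(starTree(8, 0.3), nCodons = 500, omega = 1, seed = 42)
p <- allPairsDsDn(sim$alignment)
mean(p$ratio[p$computable])
#> [1] 0.997
```

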