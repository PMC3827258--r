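---
title: "codonscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{codonscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`codonscape` packages the comparative-evolution toolkit used to study
bacterial membrane-protein gene families — the motivating case being TatC,
the six-transmembrane substrate-recognition component of the twin-arginine
translocase, whose homologues differ strongly in how much synonymous-site
conservation they retain. This vignette documents the statistical machinery,
the tunable parameters, the synthetic-data generators used for validation,
and the design decisions taken where conventions genuinely differ between
tools.

## Codon alignments

All substitution statistics operate on a `CodonAlignment`: a nucleotide
alignment whose columns come in triplets mirroring a protein alignment.
`backtranslateAlignment()` constructs one by threading each unaligned CDS
through its row of the protein alignment (residue column → codon triple,
gap → `---`). The contract is strict: after stripping a single terminal stop
codon, the CDS translation must equal the ungapped protein row exactly;
internal stops and ambiguous codons are errors (ambiguity can be relaxed to
`X` in `translateCds()`). Validity of the class guarantees equal row widths,
width divisible by three, and gaps only as whole codons, so downstream code
never needs to re-check register.

Removal of unreliably aligned columns is deliberately **not** automated:
there is no published algorithmic rule for which columns were "confidently
aligned" in this kind of analysis, so `dropAlignmentColumns()` (and the
`dropColumns` argument of the back-translator) take an explicit 1-based
column list and apply it identically to protein and codon alignments. All
user-facing coordinates are 1-based inclusive, the sequence-biology
convention; internal code indexes however is convenient.

## Synonymous/non-synonymous substitution statistics

The estimator is the Nei–Gojobori (1986) counting method as popularised by
the SNAP package.

**Sites.** For a sense codon, each position contributes a synonymous
fraction equal to (number of synonymous single-nucleotide neighbors) /
(number of non-stop single-nucleotide neighbors); `S` is the sum over the
three positions and `N = 3 − S`. Excluding mutations to stop codons from
the denominator is the standard NG86 convention. The identity
`S + N = 3` holds to 1e-9 for all 61 sense codons (tested exhaustively).

**Differences.** Between two codons differing at `d` positions, all `d!`
orderings of the single-nucleotide steps are enumerated; each step is
synonymous iff it preserves the encoded amino acid. Pathways that pass
through a stop codon are excluded; if every pathway does, the average falls
back to all pathways (a rare corner also present in common NG86
implementations — it affects no pair's `Sd + Nd = d` identity). The
pairwise `Sd`, `Nd` are sums over compared codons; the 64×64 pathway tables
are computed once and cached. An exhaustive-permutation brute-force oracle
over all 3721 sense-codon pairs backs this in the test suite.

**Pair handling.** Codon positions where either row carries a gap,
ambiguity, or stop are skipped *pairwise*, so every pair is compared over
its own maximal comparable codon set (rather than dropping columns
alignment-wide). `S` and `N` for a pair are the arithmetic means of the two
rows' summed site counts — the usual pairwise NG86 convention; the source
analyses do not state theirs, so this is declared rather than inferred.

**Correction and saturation.** `pS = Sd/S` and `pN = Nd/N` are transformed
with the one-parameter Jukes–Cantor correction
`d = −(3/4)·ln(1 − (4/3)p)`, defined only for `p < 0.75`. At `p ≥ 0.75` the
pair is flagged `saturated`, its distance left missing, and it is excluded
from all means (counted in `pairs_total` but not `pairs_computable`). The
ratio is reported as `dS/dN` — values above 1 indicate maintained
(purifying-dominated) sequences — and is left missing with reason
`"dN_zero"` when `dN = 0`, keeping group means finite instead of
propagating infinities. One degenerate case is worth noting: a pair can
have zero synonymous *opportunity* (e.g. rows of Met/Trp codons), making
`pS = 0/0`; since no synonymous difference can exist there either, the
proportion is defined as 0.

`perCodonSd()` profiles the mean pathway-averaged synonymous difference
count per codon column over all comparable pairs. The mean (not the sum) is
reported, with `pairs_used` alongside so a sum is recoverable — published
per-codon "mean Sd" tracks do not state which was plotted.

## Conservation profiling

`columnConsensus()` reports the modal non-gap residue of a column and its
percent identity with **all rows in the denominator**, so gap-rich columns
score low; a gap is never the consensus character. Ties break
lexicographically and are flagged. Classification defaults to the
conventions used for structure-mapped conservation figures: high means
`% identity ≥ 75`, low means `≤ 25` (the published captions say "greater
than"/"less than"; the inclusive variant is the documented default with an
`inclusive = FALSE` switch). `compareGroupProfiles()` flags a column for a
sub-group when its consensus residue differs from the overall consensus or
when identity shifts by at least 20 percentage points (tunable) — the kind
of signal that separates isoform sub-families at otherwise-conserved loop
positions.

## Transmembrane consensus

`consensusTM()` interprets "the overlap of all predictors" strictly: the
per-residue intersection of every input mask, decomposed into maximal
intervals, dropping intervals shorter than 8 residues (a guard against
spurious 1–2 residue intersections; configurable). A majority-vote mode is
available behind a flag, and `tmAgreement()` exposes the per-residue
agreement count for graded-confidence displays. The expected TM count for a
six-spanning architecture is a reported check, never enforced.

Because the external predictors (TMHMM, DAS, MEMSAT) are consumed as
interval files rather than run, the package ships a self-contained
stand-in: `hydropathyPredict()`, mean Kyte–Doolittle hydropathy over a
19-residue window (a typical TM helix span) thresholded at 1.6, maximal
runs of qualifying window centers extended to window extent. It exists so
the consensus rule is testable offline, not as a replacement for dedicated
topology predictors.

## Operon context

`extractNeighborhood()` takes up to 10 genes (default) each side of a focal
locus in genomic order, truncating at contig ends and never crossing
contigs. `geneAssociationFrequency()` counts each gene name at most once
per neighborhood (presence/absence, since multi-copy windows carry no extra
information for a presence map) and reports `freq = n_gene / O`, the
fraction of examined neighborhoods containing the gene. The literal printed
equation from the motivating analysis, `(n_gene/n_locus) × O`, is
dimensionally a count rather than a frequency; it is preserved as an
optional `paper_formula` column, while the fraction-of-neighborhoods form is
what reproduces the published conservation classes — moderate for
`0.50 ≤ freq < 0.80`, high for `freq ≥ 0.80`. Gene identity is matched on
normalized name tokens (lower-cased, version suffixes stripped, product
tokens as fallback for unnamed genes) with a user-extensible synonym table
(e.g. `efeB = ywbN`); strand context is summarised as a relation to the
focal gene (`same`/`opposite`/`mixed`) rather than by separate per-frame
counting.

## Distribution summaries

`boxplotStats()` uses type-7 quantiles (linear interpolation between order
statistics — the default of the plotting environment these figures are
conventionally drawn in), 1.5×IQR fences, whiskers at the most extreme
values within fences. Groups that are empty after removing missing ratios
are reported with `n = 0` rather than dropped. `selectionClass()` cuts at
the neutral boundary dS/dN = 1 (tolerance 1e-9): below → diversifying,
above → maintained.

## Synthetic-data generators

The generators define the validation conditions for the whole pipeline;
their defaults are fixed once and are not tuning knobs.

**Codon alignments** (`simulateCodonAlignment()`): along each branch, each
codon receives a Poisson number of proposal events with mean equal to the
branch length (branch lengths are therefore *pre-selection* expected events
per codon). A proposal is a uniform single-nucleotide change; proposals
creating stops are rejected; selection enters through acceptance
probabilities `min(1, ω)` for non-synonymous and `min(1, 1/ω)` for
synonymous proposals, making the realized non-synonymous:synonymous rate
ratio per opportunity equal ω. This is an event-rejection process, not a
full GY94 rate matrix: the validation target is NG86-estimator recovery,
not model realism. It deliberately omits indels, codon-usage bias,
transition/transversion bias, rate heterogeneity and recombination — so
passing recovery tests says the *estimator* is right, not that real data
are this clean. At ω = 1 the realized process is uniform over non-stop
neighbors, exactly the neutral model NG86 site counting assumes, and the
estimated mean pairwise dS/dN over 20 replicates (500 codons, 8-leaf star
tree, branch length 0.3) falls in [0.8, 1.2] — an interval fixed from a
pilot run before the recovery tests were frozen; estimated dS/dN is
monotone decreasing in generating ω across {0.2, 1, 5}.

**Operon tables** (`simulateOperonTables()`): per genome, one contig of
`2×window + 1` gene slots with the focal gene centered; each planted gene
present independently with its configured probability at a random free slot
and strand, unique-named fillers elsewhere. Planted presence probabilities
are recovered by `geneAssociationFrequency()` within the exact binomial
99 % interval (tested at p = 0.8, 50 genomes).

**TM proteins** (`simulateTmProtein()`): alternating hydrophilic linkers
(20 residues from R/K/D/E/S/T/N/Q/G/P) and hydrophobic TM segments (21
residues from I/L/V/F/A/M), six TMs by default — a caricature of a 6-TM
α-helical membrane protein with maximal hydropathy contrast. Pseudo-
predictions jitter the true interval ends by ±2 residues. Real TM helices
have far weaker contrast; recovery here validates the interval algebra, not
predictor accuracy.

All three generators draw from separate RNG streams derived from the master
seed, so adding one simulation never perturbs another, and fixed seeds give
byte-identical serialized outputs (tested per subcommand).

## Command-line interface

`runCli()` (and the installed `codonscape` script) exposes nine
subcommands covering the pipeline. Configuration precedence is
command-line flag > config file (flat `key = value` dialect, unknown keys
are errors) > defaults; the defaults equal the documented analysis settings
(window 10, saturation 0.75, identity classes 75/25, operon classes
0.50/0.80, TM min length 8, 1.5×IQR fences) so a bare invocation mirrors
the reference analysis. Every run writes a `manifest.json` with inputs,
merged parameters, package version and seed; logging goes to stderr so data
outputs stay pipeable. Primary outputs are deterministic given inputs and
seed.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: 500-codon, 8-leaf
simulations with 20 replicates per ω for recovery; 50 genomes for
frequency recovery; 1000 random columns for the consensus oracle; the full
3721-pair pathway oracle. Tolerances: 1e-9 for site-count identities and
the neutral-boundary cut, 1e-12 for quantile oracle agreement, exact
equality for pathway counts and consensus recounts.

## Known limitations

- The dS/dN estimator is the counting method: no maximum-likelihood codon
  model, no transition/transversion or codon-frequency correction, no
  sliding windows. Saturated pairs are excluded rather than modelled.
- Conservation is purely positional identity; no physicochemical similarity
  scoring.
- The operon module maps associations by annotation name matching; it does
  not predict operon boundaries from intergenic distances.
- The hydropathy predictor is intentionally simple; use real topology
  predictors for real proteins and feed their intervals to `consensusTM()`.
- Alignment construction, tree inference, and homologue retrieval are out
  of scope: the package consumes alignments and annotations.
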