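---
title: "Methods: a tested pipeline for plant kinome annotation, duplication, selection and expression analysis"
author: "plantKinome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plant kinome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantKinome)
```

# Scope

plantKinome re-implements, as tested and reusable functions, the analysis
chain of a genome-wide protein kinase (kinome) study in a plant genome:

1. **Catalog construction** — kinase candidates from Pfam-domain hit tables,
   family assignment from family-HMM hit tables, a neighbor-joining (NJ) tree
   with bootstrap support, and a tree-concordance filter that splits the
   catalog into *bona fide* and *UNK* (unknown) entries.
2. **Gene structure and protein properties** — the twelve per-gene structural
   features (transcript length, exon/intron/CDS/UTR counts and lengths,
   kinase-domain count) plus protein molecular weight and isoelectric point.
3. **Duplication and synteny** — the MCScanX-style duplication-origin
   classifier (singleton/dispersed/proximal/tandem/WGD-segmental) and
   collinear-block detection within and between genomes.
4. **Selection** — pairwise Ka/Ks by Nei–Gojobori (1986) counting with
   Jukes–Cantor correction and the usual selection-regime interpretation.
5. **Promoter cis-elements** — 1-kb promoter extraction, PWM scanning against
   JASPAR-format matrices, and per-family hypergeometric motif enrichment.
6. **Expression statistics** — the differential-expression filter,
   family/group tallies, cross-assay crosstalk, hypergeometric GO enrichment
   with Benjamini–Hochberg FDR, and efficiency-corrected qPCR relative
   expression with a label-reallocation randomization test.
7. **Synthetic data** — a seeded generator that emits a miniature annotated
   genome and expression datasets with machine-readable ground truth, so all
   of the above is testable offline.

Heavy upstream steps are deliberately **inputs**, not code: HMM searches
arrive as tabular hit files, multiple sequence alignments as aligned FASTA,
differential-expression results as tables with `log2FC`, `p` and `fdr`.
This keeps the package's claims checkable end to end.

# The catalog rules

A protein is a **kinase candidate** when at least one hit to a kinase-domain
model (PF00069, PF07714 or PF00481) covers at least 50% of the model, i.e.
`(model_to − model_from + 1) / model_length ≥ 0.5`; the candidate's number of
kinase domains is the count of qualifying hits. **Families** come from the
best family-HMM hit with e-value strictly below `1e-5`; ties break by lower
e-value, then higher bit score, then lexicographic model id, so results are
order-independent. The **group** is the family prefix before the first
underscore (`RLK-Pelle_DLSV` → `RLK-Pelle`).

The second, phenetic validation step builds a p-distance NJ tree of the
candidates and asks whether each member "groups with its peers". That phrase
is not a formal rule, so the package offers two explicit interpretations and
documents the default:

* `method = "nearest"` (default): a protein is *bona fide* iff at least one
  of its `neighbor_depth` (default 1) nearest other leaves, by patristic
  distance with lexicographic tie-breaks, shares its family.
* `method = "clade"`: the smallest non-trivial clade containing the leaf must
  be at least half same-family.

Singleton families are *bona fide* by default — a lone member has no peers to
group with, and discarding it would conflate "unvalidatable" with
"contradicted". Bootstrap support is reported but does not influence the
decision; whether the original analysis used it is unstated, and coupling the
two would make the filter depend on a Monte-Carlo quantity.

NJ itself is the standard Saitou–Nei agglomeration with two determinism
guarantees the tests rely on: Q-criterion ties break by the lexicographically
smallest pair of cluster labels, and negative branch-length estimates are
clamped to zero before any patristic computation (nearest-leaf logic needs
metric-like distances). On distances that are exactly additive the recovered
topology and branch lengths are exact, which the test suite verifies against
random trees with an independent Robinson–Foulds check.

# Gene features and protein properties

Features are computed on the **primary transcript**, the mRNA with the
largest total exon length (ties: lexicographic id). "Transcript length" is
reported as the mature length (sum of exon lengths); the genomic span (exons
plus introns) is emitted alongside, since the original tooling does not say
which it used. Introns are the gaps between sorted exons; UTRs come from
annotated `five_prime_UTR`/`three_prime_UTR` records when present and are
otherwise derived as exon minus CDS on the appropriate side of the CDS span,
strand-aware. Overlapping exons and CDS outside exons are hard errors:
silently "fixing" a malformed model would corrupt the feature statistics.
Coordinates are handled as 1-based inclusive throughout, matching GFF3.

Molecular weight is the sum of average residue masses plus one water
(18.0153 Da). The isoelectric point solves `net_charge(pH) = 0` with
Henderson–Hasselbalch terms for the termini and K/R/H/D/E/C/Y side chains,
by bisection on (0, 14); the charge is strictly decreasing in pH so the root
is unique, and the returned pH satisfies `|charge| < 1e-4`. The pKa table
(N-term 9.69, C-term 2.34, K 10.5, R 12.4, H 6.0, D 3.9, E 4.1, C 8.3,
Y 10.1) is a documented default and an explicit argument: the online tool the
original study used does not publish its table, so exact per-protein
agreement with any specific tool is not a claim this package makes.

# Duplication classes and collinearity

Gene **ranks** are 1-based positions among *all* annotated genes of a
chromosome ordered by start (ties: end, then id) — not only kinases; rank
gaps are meaningless otherwise. The classifier then applies the standard
priority ladder: every gene starts as a singleton; any retained similarity
hit makes it dispersed; a same-chromosome partner at rank gap 2–19 makes it
proximal; rank gap exactly 1 makes it tandem; anchoring a collinear block
makes it WGD/segmental; the highest label wins
(WGD/segmental > tandem > proximal > dispersed > singleton). Two readings
fixed here: "rank difference < 20" means gaps 2–19 (gap 1 is tandem), and
tandem/proximal require the same chromosome — cross-chromosome hits can only
yield dispersed. Each gene is classified from its own top-5 partners by bit
score (configurable, `Inf` disables), mirroring the usual BLAST pre-filter
that stops promiscuous hub genes linking everything.

Collinear blocks are chains of matches, within a chromosome pair, whose
ranks are strictly monotone on both sides (the B side may run either way:
`same` vs `inverted` orientation) with per-step gaps of at most 25 ranks on
each side. Chains are found by dynamic programming and extracted greedily by
descending size, each match used once; only chains of **at least five** anchor
pairs are reported. The rank-gap cap of 25 is a configurable default in line
with common collinearity practice — the original study ran its tool with
unstated defaults. Dual-genome synteny computes ranks per genome, chains the
inter-genome hits, emits a dot-plot table of anchor coordinates, and counts
blocks containing at least one kinase locus.

# Ka/Ks

Coding pairs are codon-aligned through their protein alignment; columns
gapped in either protein, and codons that are ambiguous or stops, are dropped
pairwise and counted (pairwise deletion — whether the original run used
complete or pairwise deletion is unstated, and this default is documented).
Synonymous site fractions are computed per codon over the three positions,
with changes to stop codons counted as nonsynonymous; S and N are averaged
over the two sequences, so `S + N = 3 ×` retained codons exactly. Differences
per differing codon are averaged with equal weights over all minimal
mutational pathways, excluding pathways through stop codons (weights
renormalized; in the degenerate case where every pathway is blocked, the
unweighted average is used so `Sd + Nd` still equals the number of differing
positions). Then `Ks = JC(pS)` and `Ka = JC(pN)` with
`JC(p) = −¾ ln(1 − 4p/3)`, undefined at `p ≥ ¾` and *signaled*, never a
silent NaN. The ratio is Ka/Ks with nonsynonymous in the numerator — the
interpretation (< 1 purifying, = 1 neutral within `1e-9`, > 1 positive)
only makes sense that way, and the package follows it even though one results
passage of the source literature writes the ratio upside down. A worked
single-codon-family example: ten lysine codons with one AAA→AAG change give
`S = 10/3`, `Sd = 1`, `pS = 0.3`, `Ks = 0.38312`, `Ka = 0`.

# Promoters and motif enrichment

Promoters are the 1000 bp immediately upstream of the annotated gene start
(strand-aware; minus-strand promoters are reverse-complemented so sequences
always read 5'→3' towards the gene), clipped and flagged at chromosome ends.
They are anchored at the gene, not a transcription start site, because that
is what is reproducible from a genome annotation alone. De novo motif
discovery is out of scope; instead, promoters are scanned with supplied
position frequency matrices in JASPAR text format. Counts become
probabilities with a pseudocount (default 0.5) and log2-odds against a
uniform background; a window on either strand is a hit at
`score ≥ 0.8 × maximum attainable score` (a common PWM convention, absent
from the source literature, and configurable). Enrichment per family is an
upper-tail hypergeometric test on promoters-with-a-hit, foreground versus
background, BH-corrected across motifs, with strict cutoffs `p < 1e-2` and
`q < 1e-2`. The "maximum of 10 motifs per promoter" of the original MEME run
is a search setting with no analog in scanning and is deliberately not
implemented.

# Expression, GO and qPCR

The DE filter reads the literature's "−1 > log2FC > 1" as the only coherent
disjunction, `|log2FC| > 1`, with `p < 0.05` and `FDR < 0.05`, all strict: a
transcript at exactly the threshold is never called. Family tallies count
distinct up-regulated transcripts per family per treatment; crosstalk is the
intersection of up-sets across assays. GO enrichment is the same
hypergeometric machinery with BH across tested terms, using the whole assay
transcriptome as background; annotations are taken as given, with no
ontology-graph propagation.

qPCR relative expression follows the Pfaffl model:
`ratio = E_t^ΔCt_t / geomean_g(E_g^ΔCt_g)` with
`ΔCt = mean(control) − mean(treated)` and efficiencies as fold per cycle
(2.0 = 100%; percent efficiencies convert as `E = 1 + pct/100`).
Significance uses a fixed-reallocation randomization test: control/treated
labels are reshuffled jointly across target and reference genes when the
replicate structure is shared (independently per gene otherwise), and the
two-sided p-value is the fraction of reallocations at least as far from a
ratio of 1 on the log scale as the observed one. All reallocations are
enumerated exhaustively when there are at most `n_permutations` of them;
sampled otherwise (with the add-one correction). The exact reallocation
scheme of the original tool is not published; this scheme is documented here
and oracle-tested, with no claim of bit-for-bit agreement with that tool.

# The synthetic-data generator

`simConfig()`/`genGenome()` build a miniature genome whose defaults are the
package's test conditions: 2 chromosomes of 260 kb, 60 genes with 1–4 exons,
UTRs and introns, four kinase families of sizes 6/5/4/3 with a common founder
length of 240 codons, three tandem, three proximal and three dispersed
duplicate pairs, one six-pair inter-chromosomal collinear block, a promoter
motif planted in 80% of one family's promoters versus 5% elsewhere, and
expression plans with planted up-regulated members. These sizes keep a full
pipeline run around a second while leaving every class of planted signal
recoverable; they are choices of this package, stated here once.

Choices that matter for interpreting test results:

* **Common founder length.** All kinase founders share one CDS length and
  members diverge by substitutions only, so the raw member proteins already
  form a gap-free alignment. Real kinase alignments have indels and require
  an aligner (an input to this package); the tree/concordance tests therefore
  validate the tree and filter logic, not alignment quality.
* **Duplicate divergence under selection.** Duplicate and family copies
  diverge by `0.02 ×` length accepted substitutions through the same
  proposal–acceptance process as `evolveCdsPair()`, at selection intensity
  `duplication_omega = 0.2`. Retained duplicates in real genomes are mostly
  under purifying selection, and this makes the simulated tandem pairs'
  Ka/Ks biologically sensible rather than neutral.
* **The evolver's acceptance rule.** Proposals are accepted with
  probabilities in the ratio 1 : ω (synonymous : nonsynonymous): for ω ≤ 1
  synonymous changes are always accepted and nonsynonymous ones with
  probability ω; for ω > 1 the roles invert (nonsynonymous always, synonymous
  with probability 1/ω). The literal "nonsynonymous accepted with probability
  ω" cannot represent diversifying selection, and parameter recovery at ω = 5
  requires it; for ω ≤ 1 the two rules coincide. Proposals creating stop
  codons are always rejected.
* **Non-overlapping genes, uniform strands, ≥ 2.3 kb intergenic spacing.**
  This keeps gene ranks unambiguous and guarantees that no two 1-kb promoter
  windows overlap, so planted motif counts are exact.
* **Dispersed pairs avoid block extensions.** A planted "dispersed" pair is
  placed so it cannot prepend or append to any planted collinear chain;
  otherwise the block finder would (correctly) absorb it as an anchor and the
  planted class would be wrong by construction, not by defect.
* **Truth tables as TSV.** Every planted fact (family, duplication class,
  block chains, per-gene structure, motif placements, selection intensities,
  DE directions, expression ratios) is emitted as plain TSV beside the
  FASTA/GFF3, so any implementation — not just this one — can be checked
  against the same ground truth.

What the generator does **not** emulate: indels, transposable elements,
read-level RNA-seq, alternative isoforms (one mRNA per gene; multi-isoform
primary-transcript selection is exercised by hand-built annotations in the
unit tests), and base-composition biases. Passing tests on this generator
therefore demonstrate correctness of the implemented rules on clean inputs,
not robustness to the full messiness of real genomes.

# Numerical choices

* Hypergeometric tails via `phyper`, exact to enumeration within `1e-12` for
  all tested `N ≤ 60`; BH via `p.adjust` after validating inputs to [0, 1].
* pI bisection: ≤ 100 iterations, tolerance `1e-4` pH units; invariant to the
  starting bracket because the charge is strictly monotone.
* Neutrality tolerance on Ka/Ks: `1e-9` (exact equality is measure-zero).
* NJ Q-ties and patristic ties: lexicographic by label; permuting input order
  never changes any catalog decision (tested).
* The randomization p-value for the null-uniformity study uses 5v5
  replicates (252 exhaustive reallocations). With 3v3 the p-value support has
  only ten atoms and a Kolmogorov–Smirnov test against the continuous
  uniform rejects on discreteness alone — a property of the test, not of the
  statistic; 3v3 is still checked separately against full enumeration.

# A short end-to-end run

```{r pipeline, eval = FALSE}
cfg <- simConfig(seed = 7)
sim <- genGenome(cfg)

cand <- identifyKinases(sim$domain_hits)
fams <- assignFamilies(
  sim$domain_hits[!sim$domain_hits$model_id %in% KINASE_MODELS, ])
catalog <- buildCatalog(cand, fams)

tree <- njTree(pDistanceMatrix(sim$proteins[catalogTable(catalog)$protein_id]))
catalog <- setCatalogStatus(catalog,
                            concordanceFilter(tree, catalogFamilies(catalog)))
catalog

ranks <- geneRanks(sim$annotation)
ia <- match(sim$similarity$query, ranks$gene_id)
ib <- match(sim$similarity$subject, ranks$gene_id)
pairs <- data.frame(geneA = sim$similarity$query,
                    chromA = ranks$chromosome[ia], rankA = ranks$rank[ia],
                    geneB = sim$similarity$subject,
                    chromB = ranks$chromosome[ib], rankB = ranks$rank[ib])
blocks <- findCollinearBlocks(pairs)
classifyDuplicates(ranks, sim$similarity, blocks)
```

# Known limitations

* The concordance rule is an interpretation (two are provided); real studies
  may have applied manual judgment that no rule reproduces exactly.
* p-distance NJ is the only tree method; no maximum likelihood, no rate
  models. That matches the validation role the tree plays here.
* NG86 without transition/transversion weighting; saturated pairs
  (`p ≥ 3/4`) are reported as undefined rather than extrapolated.
* PWM scanning finds occurrences of known motifs; it cannot discover motifs,
  and its threshold convention (fraction of maximum score) is one of several
  reasonable ones.
* The qPCR randomization scheme is one defensible formalization of
  fixed-reallocation testing, validated against exhaustive enumeration, not
  against the original closed-source tool.
* Problem sizes in the test suite (60-gene genomes, 600-codon pairs, 100–200
  replicate studies) are the package's chosen study conditions for fast,
  deterministic verification; scaling the generator up is a matter of
  configuration, not code.
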