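---
title: "Phylogeny-based AMF community profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogeny-based AMF community profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amfphylo)
```

## Why phylogenetic placement for AMF

Arbuscular mycorrhizal fungi (Glomeromycota) lack an actively curated 18S
reference database, and the ITS barcode used for other fungi does not
resolve AMF taxa.  Identification therefore proceeds by building a tree
from query amplicon sequence variants (ASVs) together with a curated set
of reference 18S sequences and reading taxonomy off the tree's
monophyletic groups.  `amfphylo` packages every step that follows the
externally produced alignment and tree — reference curation, alignment
trimming, rooting, monophyly-based annotation, community normalisation
and ANOSIM — plus a neighbor-joining fallback and a synthetic-data
generator so that the whole chain is exercisable without external data or
tools.

## The annotation model

Given a rooted tree whose tips are reference sequences (with four-rank
lineages: order, family, genus, species) and query ASVs, each query is
annotated from its *housing clade*: walking from the query's parent
toward the root, the housing clade is the first node whose descendants
include at least one reference (and, when a support threshold is set,
whose support meets it; nodes without a support value pass, since absence
of evidence is not evidence of low support).  Because clades containing a
given tip are totally ordered by nesting, this is exactly the smallest
monophyletic group housing the query with references.

The references inside the housing clade vote by rank, and the assignment
is the deepest unanimous rank, species > genus > family > order.
References recorded only to genus (empty species field) vote from genus
upward; they neither grant nor veto a species call.  If the housed
references disagree even at order level the ASV is reported as
`unclassified` / `"unknown"` — the treatment given to well-supported
query-only groups of unknown identity.  Two consequences worth noting:

* an ASV sister to a single reference inherits that reference's species;
* an ASV basal to several species of one genus (its housing clade holds
  references of two or more species) is annotated to the genus only.

Maximal clades consisting purely of queries (size ≥ 2 by default) are
reported as candidate novel lineages.  Two diagnostics attach to the
assignment table: tips whose terminal branch exceeds `factor` (default 5)
times the median tip branch length are flagged as long branches, and for
each novel clade the alignment columns where ≥ 50% of clade members carry
a residue while every outside row has a gap are counted as
clade-exclusive insertions — the alignment signature that explains long
branches in divergent AMF lineages.

Queries on the outgroup side of the root (the root child that carries the
outgroup and no ingroup reference) or attached to the root edge itself
are classified off-target and removed before abundance analysis, along
with ASVs whose dataset-wide total is ≤ 2 (singletons and doubletons).
We interpret the singleton/doubleton rule as a dataset-wide total, not
per-sample, since the edit is applied once to the ASV table before any
per-sample computation.

## Alignment operations

Alignments are consumed, never computed; columns are indexed 1-based with
closed `[start, end]` windows, the native R convention.  The amplicon
window is located by Hamming-matching the forward primer and the
reverse-complemented reverse primer on each ungapped row (default
tolerance 2 mismatches; no indels inside a primer site), mapping match
offsets through the row's gap pattern, and taking the median start/end
column over matching rows (at least half the rows must match).  The
window includes both primer-binding sites.

Gap-stringency trimming removes every column whose gap fraction is
`>= t` for a threshold `t > 0`, and every column containing any gap at
`t = 0`; this makes the removed-column sets nested as `t` decreases and
makes the 0% setting the exact limiting case of the 90/50/10% sweep.  Gap
fractions are computed over all alignment rows (references and queries
alike).  Rows left without residues after any trim are dropped with a
warning.

## Trees, distances, rooting

Trees come from external maximum-likelihood inference (consumed as newick
with bootstrap supports on internal-node labels; supports in [0, 1] are
rescaled to [0, 100] with a warning) or from the built-in fallback:
Jukes–Cantor distances, d = −(3/4)·ln(1 − (4/3)p) with p the mismatch
fraction over columns where both rows carry residues, pairs at p ≥ 0.75
set to a ceiling of 5 substitutions/site, followed by standard neighbor
joining (`ape::nj`).  Rooting places the root on the edge separating the
designated outgroup (for Glomeromycota, *Paraglomus*) from the ingroup;
a non-monophyletic outgroup triggers a warning and rooting at its
smallest enclosing clade (or, when that clade is the entire tree, at the
first outgroup tip's edge).  Multifurcations are accepted and monophyly
is evaluated on the polytomy as-is.

## Community tables and statistics

Relative abundance is computed per sample after all filtering, so every
retained row sums to 1; replicate means within each
(genotype, treatment) group are unweighted, so deeper-sequenced
replicates do not dominate; clade-level profiles sum member ASVs, with an
ASV's clade label being its novel-clade id when present and its assigned
taxon otherwise.  Sum-to-one is asserted at 1e-9 throughout.  The
relative-to-absolute conversion multiplies qPCR-measured total fungal DNA
by the Glomeromycota read fraction, per sample.

ANOSIM ranks all M = n(n−1)/2 Bray–Curtis dissimilarities (average ranks
on ties) and uses R = (r̄_between − r̄_within)/(M/2).  The null permutes
group labels; the one-sided p-value follows the add-one rule
p = (1 + #{R\* ≥ R}) / (1 + n_permutations), so p is never 0 and never
below 1/(1 + n_permutations).  On small designs an exhaustive mode
enumerates all distinct relabelings and returns the exact proportion with
R\* ≥ R.  The permutation seed is an explicit argument; the default
permutation count is 9,999.  Pairwise group comparisons report raw
p-values — no multiple-testing correction is applied, because the choice
of correction (if any) belongs to the caller; `p.adjust()` composes
directly with the returned table.

## What the synthetic generator emulates

The generator's defaults encode the study conditions: ~800 bp amplicons
carrying the AML1/AML2 primer sites at their ends, a curated reference
world of 174 sequences covering 91 species in 24 genera (split 146/28
across two source sets, 21 type cultures), species represented by 1–30
intragenomic variants at 0.5% divergence with rare geometric-length
indels (rate 5 × 10⁻⁴ per site, mean length 3), a design of 4 rootstock
genotypes × 3 treatment states (pre-planting, control, inoculated) × 5
replicates, and exactly 10,000 reads per sample.  Where the study fixes
no value we chose once: the four-rank taxonomy follows real
Glomeromycota genera nested as orders > families > genera > species with
per-tier divergence scales of 0.10/0.06/0.04/0.02 substitutions/site
(reference sequences sit 0.002 from their species sequence), per-genotype
base compositions are Dirichlet-distributed, and replicates are tied to
their group composition by a Dirichlet with concentration 200 —
within-group variability comparable to between-replicate scatter in real
amplicon data.  Substitutions are uniform over alternative bases
(JC-like), deliberately matching the JC distances of the fallback tree
builder so the tree-recovery property is honest.

Planted effects mirror the study's observed dynamics: dropout of a genus
in inoculated samples, enrichment of a distantly related clade, a
query-only novel lineage (default 6 variants, 8% divergence) carrying a
12-column clade-exclusive insertion, and off-target sequences branching
on the outgroup side.  The off-target clade is attached inside the basal
(outgroup) side of the root and the manifest's `outgroup_tips` lists that
whole basal clade, so rooting is clean and off-target removal has
unambiguous ground truth.  The outgroup genus itself contributes no query
variants — as in root samples, where the basal order appears only among
references.

The generator writes a true alignment (master coordinates plus tracked
insertion events) and the true tree, so no aligner or tree program is
required; an externally computed alignment can be substituted at any
point.  It does **not** emulate read-level error, chimeras, CCS quality
profiles, primer-amplification bias, or alignment error: recovery rates
measured on these data show that the annotation logic is correct given a
faithful tree, not that upstream denoising or alignment will be accurate
on real reads.

## Numerical and testing choices

Ties in ANOSIM ranks take average ranks; the NJ builder inherits `ape`'s
deterministic tie handling; assignment output order follows tree tip
order, making repeated runs byte-identical.  Brute-force oracles (clade
enumeration, per-column scans, exhaustive relabeling) back the unit tests
on hundreds of random small instances (trees ≤ 25 tips, alignments
≤ 20 × 50), and the ANOSIM type-I error is checked empirically at
α = 0.05 over 2,000 null data sets (n = 8, two groups of four, 199
permutations each).  Synthetic recovery is measured at the full study
scale for one replicate (~1,400 variants) and across 50 seeded
scaled-down replicates (12 species, 300 bp, 1,000 reads/sample) for the
novel-clade detection rate — sizes chosen to keep the whole suite
comfortably under a minute while leaving every property at its stated
threshold.

## Known limitations

* Assignment consumes one fixed tree; there is no likelihood-weighted or
  multi-placement uncertainty.
* A query basal to the ingroup but above all reference clades is reported
  `unclassified` rather than guessed.
* The generator's indel model is simple (geometric lengths, no
  heterogeneity in rate along the sequence) and primer sites are held
  invariant, so primer-mismatch dropout cannot be simulated.
* Bray–Curtis/ANOSIM inherit the usual caveats of rank-based one-way
  designs; there is no two-way ANOSIM or PERMANOVA here.
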