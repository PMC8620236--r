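---
title: "Models and methods behind retropop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retropop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retropop)
```

`retropop` analyzes transposable-element (TE) insertion polymorphisms called
from population-scale short-read data. Its study system is the giraffe
(*Giraffa*), one of the few mammal groups carrying two potentially active
autonomous non-LTR retrotransposon clades — LINE1 and the horizontally
transferred RTE/BovB — plus their dependent SINEs. This vignette explains the
models the package implements, the defaults it fixes and why, and what the
synthetic-data generator does and does not emulate.

## The data model

Every analysis runs off a `geno_matrix`: loci × individuals insertion-allele
dosages (0 = no insertion allele, 1 = heterozygous, 2 = homozygous, `NA` =
missing), with per-locus metadata (position, TE family, element length) and a
species/subspecies assignment per individual. Upstream of it sit two call
classes produced by split-read callers:

* **REF− calls**: insertions present in an individual but absent from the
  reference assembly.
* **REF+ calls**: deletion-style records of insertions the reference carries.
  Their genotypes describe the *absence* of the element, so
  `invert_deletion_calls()` maps deletion dosage $d$ to insertion dosage
  $2-d$ before the two sets are merged. A flag prevents double inversion.

### The cascade filter

`cascade_filter()` removes calls that (1) failed the caller's internal
filters, (2) have fewer than 5 supporting read pairs on *each* side, or
(3) are shorter than 100 bp. Thresholds are inclusive-retain (a call with
exactly 5/5 support and 100 bp survives) because removal is defined for
values *below* the threshold. Removed calls are attributed to the first
criterion they fail, in the order internal → support → length, which makes
the filter report reproducible. Support fields missing from a VCF record are
read as 0 so that malformed records are filtered out rather than silently
retained (fail-closed).

## Consensus curation and divergence

`majority_consensus()` computes the per-column majority of a copy alignment
(gap wins a column only when gapped in more than half of the rows), then
restores ancestral CpG dinucleotides: methylated CpG decays to TpG/CpA an
order of magnitude faster than the background substitution rate, so a
consensus TG or CA pair is rewritten to CG when at least `cpg_fraction`
(default 0.10) of rows still show CG there and the decayed state plus CG form
the row majority. The 10% default and the exact rule are this package's
reproducible stand-in for manual curation of TE libraries; both are exposed
as parameters.

Pairwise identity (`seq_identity()`) uses a deterministic end-gap-free global
alignment (match +1, mismatch −1, gap −2). `N` never matches anything,
including `N` — conservative for the 100%-identity clustering below. The
identity denominator is never smaller than the shorter sequence, so a short
incidental perfect overlap between unrelated sequences cannot masquerade as
high identity; free end gaps only absorb terminal overhangs (truncated copies,
contig ends).

`k2p()` implements the Kimura 2-parameter distance
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with transitions $P$ and
transversions $Q$ counted over gap- and N-free columns; saturated pairs
($1-2P-Q \le 0$ or $1-2Q \le 0$) are flagged rather than given an arbitrary
value. `repeat_landscape()` bins copies into half-open divergence bins and
reports genome percentage per family and bin; the bins sum exactly to each
family's total genomic share, a conservation property the tests assert.

## SINE activity

Active SINE families leave clusters of 100%-identical copies. The pipeline
is: `full_length_filter()` (termini truncated by < 15 bp relative to the
consensus, measured from an end-gap-free alignment) →
`identity_cluster()` → `classify_cluster()`.

The published clustering used a heuristic search engine with
`min-seq-id = 1.0, c = 0.98, cov-mode = 0`. Rather than reimplement a search
heuristic, `identity_cluster()` interprets those parameters exactly: two
copies are linked iff one is an exact substring of the other *and* the
shorter covers ≥ 98% of the longer (bidirectional coverage); clusters are
connected components of that relation. This dialect is deterministic and is
verified against an independent all-pairs + union–find oracle in the tests.
The representative is the longest member with lexicographic tie-break, making
the output invariant to input order.

Identical copies can also arise from **segmental duplication**, which copies
the element *together with its flanks*. A cluster is a duplication
pseudocluster when any member pair reaches ≥ 0.98 identity on *both* 350 bp
flanks — both, because a duplication copies contiguous sequence spanning the
element. The 0.98/350 bp rule reuses the consensus-curation deduplication
threshold; the published description of pseudocluster flanks is qualitative,
so the threshold is exposed as a parameter. `date_insertions()` places a copy
on the stem branch above the MRCA of the assemblies that carry it, provided
no assembly inside that clade lacks it; scattered presence is labeled
homoplastic.

## Irreversible parsimony

TE insertions are essentially irreversible, rarely excised characters, so
tree scoring permits only 0 → 1 changes from an absence root state
(Camin–Sokal parsimony). For one locus on a rooted tree the minimum number of
gains equals the number of *maximal pure clades*: maximal subtrees whose
non-missing leaves are all carriers. `camin_sokal_length()` computes this in
one post-order pass vectorized over loci; the tests verify it against
exhaustive enumeration over all subsets of gain branches on every rooted
topology with up to 6 leaves (213,600 tree × character combinations).

Missing codes (`?`) impose no constraint — they neither force nor forbid a
gain. The artificial outgroup is coded 0 at every locus and only fixes the
root; scoring is identical with or without its tip in the tree.

* **CI/HI**: consistency index = (one gain per variable locus) / realized
  length; homoplasy index = 1 − CI. They satisfy CI + HI = 1 identically.
* **Search**: `parsimony_search()` enumerates all rooted ingroup topologies
  exhaustively for ≤ 8 taxa (collapse individuals to populations first for
  more) and returns *all* minima; downstream consumers can take their strict
  consensus. The heuristic alternative does random-addition stepwise
  insertion followed by SPR hill climbing. SPR (a superset of NNI) stands in
  for TBR: it is tractable to implement exactly, and the exhaustive search
  guards its correctness at small sizes — on random 6-taxon matrices the two
  agree on the optimum in ≥ 95% of seeds.
* **Bootstrap**: loci resampled with replacement, each replicate re-searched;
  support = % of replicates whose best tree contains the clade.
* **Branch mapping**: a locus whose carriers form exactly one clade maps to
  that clade's stem; its age is the stem midpoint depth in the tree's
  branch-length units. Loci whose carriers span several clades are flagged
  conflicting rather than forced onto a branch.
* **Node heterozygosity**: for loci mapped to a branch, the heterozygous
  fraction among carrier genotype calls. Because insertions drift toward
  fixation, this fraction decays with insertion age, and differences between
  clades reflect ancestral population sizes.

## Population genetics on TE markers

TE presence/absence behaves as a biallelic co-dominant locus, so the
classical SNP estimators apply to dosage matrices directly:

* individual heterozygosity $n_1/(n_0+n_1+n_2)$ over all markers
  (`mode = "all"`, MLH) or only population-segregating markers
  (`mode = "seg"`); the heterozygote count is invariant to allele
  polarization, and `seg` ≥ `all` always since it removes only
  zero-contribution loci;
* Nei's (1972) standard distance $D=-\ln(J_{xy}/\sqrt{J_xJ_y})$;
* Wright's $F_{st}=1-H_S/H_T$;
* Weir & Cockerham's (1984) $\hat\theta$ from the a/b/c variance components,
  combined across loci as a ratio of sums (ratio-of-averages), which corrects
  for sample size and can be slightly negative under panmixia;
* PCA on dosages centered by $2\hat p$ and scaled by $\sqrt{\hat p(1-\hat p)}$
  (scaling exposed as a flag), with mean imputation of missing cells;
  classical PCoA via double-centering;
* `concordance()`: Pearson correlation of pairwise-population vectors
  between TE- and SNP-derived statistics.

Missing genotypes are excluded per locus and population throughout.

## The synthetic-data generator

The generator produces data with the *structure* the analysis assumes, under
the study conditions, so every stage is testable without external data. It is
a stand-in: the source study analyzed real resequencing data and specifies no
generative model, so all distributions here are explicit modeling choices.

* **Demography**: 48 individuals, 4 species, 7 subspecies (plus the
  reticulated giraffe as its own population unit), on the topology
  ((northern, reticulated), (southern, Masai)) with crown age 1.2 Myr and a
  10.3 Myr stem to the okapi split — the tree `giraffe_species_tree()`.
  Within-species sample splits (5/5/5, 10, 5/6, 6/6) are fixed once; the
  study reports species-level counts (15/10/11/12), which these match.
* **Insertion gains**: Poisson along branches with per-family rates 40 and
  6 per Myr (≈ 6.6:1, the observed LINE1:RTE ratio of 86.9%:13.1%), giving
  ~700 loci per run — matrices the same shape as the study's phylogenetic
  marker set, at desk scale.
* **Heterozygosity**: among carriers, a locus of age $a$ (midpoint depth of
  its branch) is heterozygous with probability $h(a)=e^{-\lambda a}$, with
  $\lambda$ calibrated so that root-stem insertions are 40% heterozygous
  (the observed value at the species MRCA is 39.9%). Branch age as midpoint
  depth keeps $h$ a function of a single scalar.
* **Tip segregation**: branch-tip loci segregate within their taxon at a
  carrier frequency ~ Uniform(1/(2n), 1) per locus — covering singletons
  through near-fixed variants with one simple law.
* **Lengths**: point mass at the full consensus length (7997 bp / 3872 bp)
  with probabilities 5.3% / 0.32% (the observed full-length fractions), and
  a uniform 5′-truncation tail down to 100 bp with a minimum truncation of
  50 bp — truncations smaller than that are not realistically
  distinguishable from full-length copies.
* **Call emission**: loci carried by a designated reference individual (the
  first Kordofan sample, mirroring the reference assembly's position nested
  inside the population) are emitted as REF+ deletion-style calls; per-side
  support is Poisson with mean 19 (the data's mean coverage); injected noise
  calls violate the internal-filter or length criterion at configurable
  rates.
* **SNP comparator**: ancestral frequency 0.5 diffused along branches with
  Gaussian increments (variance 0.05 per Myr, clamped away from fixation),
  binomial sampling within taxa — the same demography as the TE simulation,
  for concordance checks.

What the generator does **not** emulate: linkage, reference-alignment
artifacts, genotyping error beyond the injected noise classes, coalescent
variance within populations, migration or hybridization, and selection.
Passing recovery tests on this generator therefore demonstrates correctness
of the estimators and algorithms under the assumed structure — not robustness
to every property of real resequencing data.

All generators are pure functions of their configuration and seed; identical
seeds give bit-identical output.

## Numerical choices and degenerate inputs

* Parsimony ties: all minimum trees are returned, canonically ordered, so
  results are independent of enumeration order.
* Cluster representatives: longest member, then smallest ID — input-order
  invariant.
* A single-taxon ingroup degenerates to one gain per locus present.
* `k2p` errors on zero valid columns rather than returning 0.
* Nei's D returns `Inf` with a warning when $J_{xy}=0$.
* Individuals with no usable loci get `NA` heterozygosity plus a warning.
* Genotype conflicts when merging REF−/REF+ records at the same locus
  (same family, within 50 bp) become missing cells, logged.

## Problem sizes

The test suite and the acceptance script run everything at desk scale: the
parsimony oracle covers all 1,068 rooted topologies on 3–6 leaves × 200
random characters; topology recovery uses 100 simulated data sets of ~180
loci; heterozygosity recovery uses 30 runs of the full ~700-locus default
configuration; estimator null/limit checks use 2 × 500 individuals × 2,000
loci. These sizes make every result reproducible in minutes on one CPU while
keeping the statistical checks well-powered.

## Known limitations

* The heuristic search approximates TBR by SPR; for very large taxon sets
  PAUP-style searches may find shorter trees.
* The exact-substring clustering dialect will not link copies differing by a
  single internal indel, where a search-engine aligner might; at 100%
  identity this is the stricter, more reproducible choice.
* Nexus support covers the STANDARD binary dialect this pipeline emits and
  consumes, not arbitrary Nexus files.
* Insertion dating and branch mapping assume the guide tree is correct;
  conflicting loci are reported, not resolved.
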