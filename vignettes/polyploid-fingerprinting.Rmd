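---
title: "Dosage-unaware genotype analysis and the polysomic self-incompatibility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dosage-unaware genotype analysis and the polysomic self-incompatibility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polySSR)
```

## The observability problem

Polyploid *Prunus* species — tetraploid blackthorn (*P. spinosa*, 2n = 4x =
32), hexaploid *P. domestica* subsp. *insititia* (2n = 6x = 48) and their
pentaploid hybrids (2n = 5x = 40) — are routinely fingerprinted with SSR
markers and S-RNase intron-length polymorphism. A capillary trace reveals
*which* allele sizes an accession carries at a locus, but not *how many* of
its genome copies carry each: a tetraploid showing three bands may be
1+1+2 in any arrangement, or carry a null allele. Every method in this
package is therefore defined on the **set** of distinct alleles per
accession and locus (`PolyGenotypes`), with failed amplifications recorded
as *missing* — a different state from an empty set, because a locus that
fails in some samples must be maskable pairwise rather than scored as
absence.

## Presence-based diversity statistics

Allele frequencies are estimated by presence: each accession contributes
one count per distinct allele it carries, and the denominator is the total
number of allele-in-accession occurrences at the locus. This is not an
unbiased estimator of gene (copy) frequencies — common alleles are
undercounted because extra copies are invisible — but it is the only
estimator available without dosage, and it is the convention under which
published PIC values for such panels are computed. Accessions missing a
locus are excluded from its spectrum entirely rather than imputed as
null-allele carriers.

PIC uses the full form

$$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2\, p_i^2 p_j^2 ,$$

not the plain expected heterozygosity $1-\sum p_i^2$. On the packaged
17-accession S-genotype panel the two differ visibly (0.9324 vs 0.9360,
i.e. 0.93 vs 0.94 at two decimals); the full form is what published marker
tables for this material report, and `pic()` exposes both so the choice is
auditable. Report tables round half *up* to two decimals
(`roundHalfUp()`), matching how such tables are conventionally printed;
`round()`'s half-to-even rule would disagree on exact halves.

Clone detection groups accessions with identical profiles across a marker
subset; accessions missing any marker of the subset are excluded and
reported, never silently dropped. The minimal-discriminating-set search is
an exhaustive scan over subsets of size 1, 2, ..., returning *all* subsets
of the first size that separates every pair — clonal groups are collapsed
first, since no marker can split true clones. Exhaustiveness is affordable
because fingerprinting panels have ~10 loci; the search is not intended
for hundreds of markers.

## Distance analysis

Presence/absence encoding produces one binary marker per observed
(locus, allele); S-alleles can be appended as an extra pseudo-locus to form
the merged dataset. Dice similarity is used because, for binary marker
data, shared absences carry no information (an allele absent from both
accessions says nothing about relatedness). Loci missing in either member
of a pair are deleted pairwise before computing the coefficient.

UPGMA is implemented in-package rather than delegated to
`stats::hclust` for one reason: determinism under ties. Equal minimal
distances are resolved toward the lexicographically smallest pair of
cluster representatives, so output is independent of input row order;
`hclust`'s index-order tie-breaking is order-sensitive. On tie-free input
the two agree exactly (this is asserted in the tests against random
matrices). Heights are merge distances and are monotone non-decreasing —
checked on every run in the property tests — and conversion to `phylo`
halves them, giving ultrametric branch lengths.

Bootstrap supports resample **allele columns** with replacement by
default. The resampling unit is genuinely a design choice for binary
multilocus data; column resampling is the standard for presence/absence
fingerprints and is what we adopt, with `unit = "locus"` resampling whole
loci for users who prefer to respect linkage within a locus. Support for a
node is the percentage of replicate trees containing the same leaf
bipartition. Duplicated accessions always receive support 100 (their
similarity is 1 under any column resample) — a useful self-check that the
tests rely on.

The cophenetic correlation is the Pearson correlation between input
distances and tree-implied distances. Its significance is computed by
permuting the dendrogram's leaf labels and recomputing the correlation,
one-sided, with the add-one estimator $p = (1 + \#\{r_\pi \ge r\})/(B+1)$.
This label-permutation null is an approximation chosen for transparency —
the literature contains several variants of dendrogram-fit tests, and the
exact published procedure is not fully specified for this material; at
$n = 4$ the sampled p matches full enumeration of all $4! = 24$
relabelings (tested).

PCA operates on the column-centered binary matrix (covariance mode) by
default; correlation mode is available behind a flag but inflates the
weight of rare alleles, which is rarely wanted for 0/1 markers. Axis signs
follow the convention that each axis's largest-magnitude loading is
positive, making score plots reproducible across platforms.

## S-locus genotyping

Fragment-to-allele assignment is single-linkage clustering in one
dimension: sorted lengths split where the gap between neighbours exceeds
the tolerance. The default tolerance is ±10 bp below 1000 bp and 3% above,
reflecting that small fragments are sequencer-called (±1–2 bp accuracy)
while larger ones are estimated from agarose gels (several-percent error).
Alleles whose fragments are nearly identical in size (e.g. 713 vs 716 bp)
are genuinely inseparable on a gel: they are kept apart only when
observations carry a `sequence_label` (sequence-confirmed identity), and
otherwise merge with a warning whenever a single accession contributes
multiple fragments to one bin — the signature of two alleles hiding under
one band. Labels are assigned in descending carrier count, then ascending
size. First-intron observations are accepted and stored but do not enter
genotype calls: the second intron is the informative region, and
first-intron amplification is too unreliable to call from.

Functionality scanning translates a cloned in-frame CDS and reports the
first stop codon before the expected protein end. A premature stop
upstream of the catalytic region implies a non-functional S-RNase; the
resulting flag feeds directly into the mating model. Peptide divergence is
the p-distance under complete deletion (columns containing any gap or
missing symbol removed for all pairs alike) with Poisson correction
$d = -\ln(1-p)$, reported at three decimals.

## The polysomic mating model

Under polysomic inheritance with equal chance for all chromosome pairings,
each of the $\binom{2m}{m}$ subsets of a $2m$-ploid parent's S-locus
copies is an equally likely gamete. Pollen is rejected iff it carries at
least one *functional* allele matching a *functional* pistil S-RNase — the
one-allele-match rule; non-functional alleles on either side never cause
rejection. For fully assigned genotypes with all alleles distinct and
functional, the compatible fraction is hypergeometric,
$\binom{n-s}{m}/\binom{n}{m}$, and the enumeration is tested against this
closed form for all $n \le 6$, $s \le n$. The canonical case — two
tetraploids sharing two of four functional alleles — gives $1/6 \approx
16.7\%$, which is what limits fruit set when such cultivars are
co-planted.

Three boundary decisions deserve explanation:

- **Odd ploidy.** Pentaploids have no balanced meiosis model, so they are
  refused as pollen parents with an explanatory error but accepted as
  pistil parents (the pistil side only needs the genotype's functional
  allele set). Panel compatibility matrices show `NA` columns for them.
- **Unassigned genome copies.** When fewer alleles than genome copies were
  detected, the point estimate fills the gap with placeholder alleles that
  match nothing — the no-hidden-match assumption. Because hidden copies
  could equally be pistil-matching alleles, `interval = TRUE` reports the
  exact range of the fraction over all completions consistent with the
  rule that functional alleles are single-copy (duplicated alleles are
  only possible when non-functional, since matching functional
  specificities could not have met in one zygote under a working
  self-incompatibility system).
- **No pollen competition.** Rejection is per-gamete and per-matching
  allele; heteroallelic-pollen interactions (as discussed for other
  allopolyploids) are deliberately out of scope.

A consequence worth knowing: self-compatibility requires *at least two*
non-functional haplotypes — a genotype with a single non-functional allele
still rejects every self-gamete, because each gamete carries at least one
functional self-allele. The packaged panel contains exactly this
configuration (the 'Zempléni' cultivar, field-observed to set selfed
fruit, carries one non-functional allele), and the model accordingly
predicts full self-incompatibility for it: the model and the field
observation disagree, which the package reports as-is rather than
patching — resolving it needs pollen-side (SFB) data.

## What the simulator emulates — and what it does not

`simulationConfig()` defaults mirror the composition of the packaged
panel: 10 tetraploids, 4 hexaploids, 3 pentaploid hybrids, nine SSR loci
with pool sizes spanning 5–26 alleles (the observed range), symmetric
Dirichlet pool frequencies, one clone pair, and a 23-label S-allele pool
with one non-functional member. Dosage is simulated (copies drawn with
replacement) and then discarded, so tests can quantify exactly what
presence/absence coding loses. Hybrids are formed by uniting one gamete
from each parent, with the pollen gamete resampled until it passes the
seed parent's pistil screen — so simulated pedigrees are always crosses
that could have set seed, and hybrid S-genotypes share alleles with both
parents as real pedigrees do.

The simulator does **not** model mutation, linkage between SSR loci and
the S-locus, null alleles, stutter or allele-calling error, population
structure within a species class, or selection. Passing tests on simulated
data therefore demonstrate algorithmic correctness under the stated
sampling model, not robustness to genotyping artifacts.

Presence-frequency estimates converge to pool frequencies only when the
pool is close to uniform (the presence transform $1-(1-q)^k$ is nonlinear
in the pool frequency $q$); the convergence test uses a high Dirichlet
concentration and $n = 500$ accessions at tolerance 0.03 for this reason.

## Numerical choices and problem sizes

Ties in UPGMA are broken lexicographically; tie detection uses a $10^{-12}$
absolute tolerance. Bootstrap and permutation procedures take an explicit
integer seed and are byte-reproducible. Default replicate counts follow
published practice for such panels (2000 bootstrap replicates, 999
permutations); the test-suite uses 50–200 replicates, which is ample for
the planted-structure assertions it makes (clone clades are
sampling-invariant, and the planted-bipartition checks allow the expected
Monte-Carlo spread). Property tests run tens of seeded replicates per
invariant; gamete enumeration is exercised through ploidy 8
($\binom{8}{4} = 70$ subsets), far above the panel's maximum of 6.

## Known limitations

- Dice with extensive missingness deletes pairwise, so different pairs are
  compared over different marker sets; a dendrogram over such a matrix is
  not guaranteed to reflect a single consistent geometry.
- The minimal-marker-set search is exponential in the subset size cap and
  meant for panels of ~10 loci.
- Fragment binning assumes per-locus allele pools are separable by size
  gaps at the stated tolerance; heavily saturated allele series require
  sequence confirmation, as the warning indicates.
- The mating model predicts *pollen acceptance*, not fruit set; fertility
  costs of unbalanced gametes in odd-ploidy or aneuploid material are
  outside the model.
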