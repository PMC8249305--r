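# polySSR

Genetic characterization of polyploid *Prunus* germplasm (blackthorn,
damson-type plums and their interspecific hybrids) from **dosage-unaware**
marker data. In tetra-, penta- and hexaploid accessions a capillary trace
shows which allele sizes are present at an SSR locus but not how many genome
copies carry each, so every statistic in this package is built on
presence/absence of alleles rather than on gene counts. The package covers
the full analysis a breeder or curator runs on such a panel:

- **Diversity**: per-locus allele counts, unique alleles, distinct genotype
  profiles, and polymorphic information content from presence-based
  frequencies

  `PIC = 1 − Σᵢ pᵢ² − Σ_{i<j} 2 pᵢ² pⱼ²`,

  with each accession contributing one count per distinct allele it carries;
  clone detection and exhaustive search for the smallest marker subsets that
  distinguish every non-clonal accession.
- **Distance analysis**: presence/absence encoding (optionally merging SSR
  and S-locus markers), Dice similarity `D = 2|A∩B| / (|A|+|B|)` with
  pairwise deletion of failed loci, UPGMA with deterministic tie-breaking,
  column-resampling bootstrap supports, cophenetic correlation with a
  permutation test, PCA, Newick export.
- **S-locus genotyping**: single-linkage binning of S-RNase intron PCR
  fragment lengths into an allele catalog (sequence-confirmed identities
  honored), occurrence tables by species class, premature-stop-codon
  scanning of cloned CDS, and Poisson-corrected peptide divergence
  `d = −ln(1 − p)` under complete deletion.
- **Mating model**: polysomic gametophytic self-incompatibility. With equal
  chance for all chromosome pairings, every `m`-subset of a `2m`-ploid
  parent's S-locus copies is an equally likely pollen gamete; a gamete is
  rejected iff it carries a functional S-allele matching a functional pistil
  S-RNase (one-allele-match rule). For fully assigned genotypes the
  compatible-pollen fraction has the closed form `C(n−s, m) / C(n, m)` for
  `n` pollen alleles sharing `s` with the pistil.
- **Simulator**: seeded generator of polyploid SSR + S-locus panels with
  planted clones, interploidy hybrids (gamete unions screened for
  self-incompatibility) and known allele pools, used throughout the tests.

The package ships the S-genotypes of a published 17-accession Central
European panel (10 tetraploid *P. spinosa*, 4 hexaploid *P. domestica*
subsp. *insititia*, 3 pentaploid hybrids) as a fixture, together with its
per-locus SSR summary table and S-RNase allele catalog.

## Worked example

```r
library(polySSR)

sg <- loadFixture("table1_sgenotypes")   # the 17-accession panel
locusSummary(sg, "S")[, c("n_scored", "n_alleles", "n_unique_alleles",
                          "n_genotypes", "pic")]
#>   n_scored n_alleles n_unique_alleles n_genotypes       pic
#> 1       17        23                6          16 0.9324158
```

23 S-RNase alleles across 17 accessions, six carried by a single accession,
and 16 distinct S-genotypes — the missing 17th is the clone pair T1/T4,
which `findClonalGroups(sg)` returns. The PIC of 0.93 makes the S-locus as
informative as the best SSR markers on the same panel.

The mating model for two tetraploids sharing two of their four functional
S-alleles (D2 × D5, pollen parent D5 = {S_3-1, S_M, S_O, S_P}):

```r
cc <- crossCompatibility("D2", "D5", sgenotypes = sg)
cc$gametes
#>      gamete      prob accepted
#> 1 S_3-1/S_M 0.1666667    FALSE
#> 2 S_3-1/S_O 0.1666667    FALSE
#> 3 S_3-1/S_P 0.1666667    FALSE
#> 4   S_M/S_O 0.1666667    FALSE
#> 5   S_M/S_P 0.1666667    FALSE
#> 6   S_O/S_P 0.1666667     TRUE
cc$fraction
#> [1] 0.1666667
```

Only the one gamete in six avoiding both shared alleles can grow in the
pistil: such crosses are *partially* compatible, with under 20% of pollen
effective — a real agronomic constraint when co-planting pollinizers.

A command-line wrapper over the same functions is at
`inst/scripts/polySSR.R` (`summarize`, `cluster`, `pca`, `slocus`,
`mating`, `simulate` subcommands); `runPipeline()` is the programmatic
equivalent.

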