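#' Configuration for the polyploid dataset simulator
#'
#' Defaults emulate the composition of a Central European polyploid plum
#' panel: 17 accessions (10 tetraploid, 4 hexaploid, 3 pentaploid
#' interspecific hybrids formed by gamete union of a tetraploid and a
#' hexaploid parent), nine SSR loci with allele-pool sizes spanning the
#' 5-26 range observed in such panels, one clonal pair, and an S-allele
#' pool of 23 labels of which one is non-functional.
#'
#' @param nTetra,nHexa,nHybrid accession counts per ploidy class (hybrids
#'   are pentaploid, built from one tetraploid and one hexaploid parent
#'   drawn from the simulated panel)
#' @param lociPoolSizes named integer vector: allele pool size per SSR
#'   locus
#' @param dirichletConcentration concentration of the symmetric Dirichlet
#'   from which pool allele frequencies are drawn (1 = uniform prior;
#'   smaller values give more skewed frequency spectra)
#' @param clonePairs number of accessions duplicated as clones (appended as
#'   `<id>_clone`)
#' @param sAllelePool character vector of S-allele labels
#' @param sNonFunctional labels of the pool flagged non-functional
#' @return a `SimulationConfig` list
#' @seealso [simulateAccessions()]
#' @export
simulationConfig <- function(nTetra = 10, nHexa = 4, nHybrid = 3,
                             lociPoolSizes = c(
                               SSR01 = 17L, SSR02 = 24L, SSR03 = 5L,
                               SSR04 = 6L, SSR05 = 7L, SSR06 = 12L,
                               SSR07 = 24L, SSR08 = 26L, SSR09 = 8L),
                             dirichletConcentration = 1,
                             clonePairs = 1,
                             sAllelePool = paste0("S", 1:23),
                             sNonFunctional = "S23") {
  stopifnot(nTetra >= 0, nHexa >= 0, nHybrid >= 0,
            all(lociPoolSizes >= 2), dirichletConcentration > 0,
            all(sNonFunctional %in% sAllelePool))
  if (nHybrid > 0 && (nTetra < 1 || nHexa < 1))
    stop("hybrids need at least one tetraploid and one hexaploid parent")
  if (length(sAllelePool) < 6)
    stop("S-allele pool smaller than the distinct functional alleles a ",
         "hexaploid needs")
  structure(list(nTetra = nTetra, nHexa = nHexa, nHybrid = nHybrid,
                 lociPoolSizes = lociPoolSizes,
                 dirichletConcentration = dirichletConcentration,
                 clonePairs = clonePairs, sAllelePool = sAllelePool,
                 sNonFunctional = sNonFunctional),
            class = "SimulationConfig")
}

.rdirichlet <- function(k, conc) {
  g <- stats::rgamma(k, shape = conc)
  g / sum(g)
}

#' Simulate a polyploid SSR + S-locus dataset with known truth
#'
#' Each accession draws `ploidy` allele copies per locus from the locus
#' pool with replacement; the observed call is the *set* of distinct sizes,
#' so dosage is simulated and then discarded, reproducing the central
#' observability constraint of presence/absence genotyping. S-genotypes are
#' drawn without duplicated functional alleles. Hybrids are formed by
#' uniting one gamete from a tetraploid and one from a hexaploid parent
#' (see [simulateHybrid()]); clones are exact copies of existing
#' accessions.
#'
#' @param config a [simulationConfig()] object
#' @param seed integer seed (mandatory: the generator is fully
#'   reproducible)
#' @return list with `genotypes` ([PolyGenotypes-class]), `sgenotypes`
#'   ([SGenotypes-class]), `truth` (list: `clones` — pairs of ids,
#'   `hybridParents` — named list of parent-id pairs, `pools` — per-locus
#'   allele frequencies) ready for recovery tests
#' @export
simulateAccessions <- function(config, seed) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)

  pools <- lapply(config$lociPoolSizes, function(k) {
    sizes <- sort(sample(seq(100, 100 + 2 * (k + 20), by = 2), k))
    stats::setNames(.rdirichlet(k, config$dirichletConcentration), sizes)
  })
  sFun <- stats::setNames(!(config$sAllelePool %in% config$sNonFunctional),
                          config$sAllelePool)

  ids <- c(sprintf("TET%02d", seq_len(config$nTetra)),
           sprintf("HEX%02d", seq_len(config$nHexa)))
  ploidy <- c(rep(4L, config$nTetra), rep(6L, config$nHexa))
  species <- c(rep("P_spinosa", config$nTetra),
               rep("P_insititia", config$nHexa))

  drawAccession <- function(k) {
    calls <- lapply(pools, function(p) {
      copies <- sample(as.integer(names(p)), k, replace = TRUE, prob = p)
      sort(unique(copies))
    })
    # S-genotype: distinct functional alleles; the non-functional label may
    # duplicate but a plain draw without replacement always satisfies GSI
    s <- sample(config$sAllelePool, k, replace = FALSE)
    list(calls = calls, s = s)
  }

  base <- lapply(ploidy, drawAccession)
  names(base) <- ids

  hybrids <- list(); hybridParents <- list()
  if (config$nHybrid > 0) {
    for (h in seq_len(config$nHybrid)) {
      pa <- sample(ids[ploidy == 4L], 1)
      pb <- sample(ids[ploidy == 6L], 1)
      id <- sprintf("HYB%02d", h)
      hybrids[[id]] <- .hybridFromDraws(base[[pa]], 4L, base[[pb]], 6L, sFun)
      hybridParents[[id]] <- c(pa, pb)
    }
  }

  all <- c(base, hybrids)
  ids2 <- names(all)
  ploidy2 <- c(ploidy, rep(5L, length(hybrids)))
  species2 <- c(species, rep("hybrid", length(hybrids)))

  clones <- list()
  if (config$clonePairs > 0) {
    src <- sample(ids2, config$clonePairs)
    for (s in src) {
      id <- paste0(s, "_clone")
      all[[id]] <- all[[s]]
      ids2 <- c(ids2, id)
      ploidy2 <- c(ploidy2, ploidy2[match(s, names(all))])
      species2 <- c(species2, species2[match(s, names(all))])
      clones[[length(clones) + 1L]] <- sort(c(s, id))
    }
  }

  acc <- data.frame(id = ids2, species = species2, ploidy = ploidy2,
                    origin = "simulated")
  pg <- PolyGenotypes(lapply(all, `[[`, "calls"), acc)
  sg <- SGenotypes(lapply(all, `[[`, "s"), sFun, acc)
  list(genotypes = pg, sgenotypes = sg,
       truth = list(clones = clones, hybridParents = hybridParents,
                    pools = pools, sFunctional = sFun))
}

.hybridFromDraws <- function(a, ploidyA, b, ploidyB, sFun, maxTries = 1000) {
  # SSR loci: union of one random gamete from each parent; the parental
  # dosage is unknown (sets only), so gametes sample ploidy/2 copies from
  # the observed set with replacement -- consistent with any dosage
  gamCalls <- function(p, m) lapply(p$calls, function(s)
    s[sample.int(length(s), m, replace = TRUE)])
  # S-locus honors GSI: the pollen gamete must carry no functional allele
  # matching the seed parent's functional S-RNases
  pistil <- a$s
  for (t in seq_len(maxTries)) {
    gb <- sample(b$s, ploidyB / 2)
    if (pollenAccepted(gb, pistil, sFun)) {
      ga <- sample(a$s, ploidyA / 2)
      ca <- gamCalls(a, ploidyA / 2); cb <- gamCalls(b, ploidyB / 2)
      calls <- stats::setNames(lapply(names(ca), function(l)
        sort(unique(c(ca[[l]], cb[[l]])))), names(ca))
      s <- c(ga, gb)
      # duplicated functional alleles cannot coexist; drop extra copies
      dup <- duplicated(s) & sFun[s]
      return(list(calls = calls, s = sort(s[!dup])))
    }
  }
  stop("no compatible gamete found: cross is fully incompatible")
}

#' Simulate one interploidy hybrid from two parents
#'
#' Unites a random `ploidyA/2` gamete of parent A (seed parent) with a
#' random `ploidyB/2` gamete of parent B (pollen parent); a 4x by 6x cross
#' yields a pentaploid. The pollen gamete is resampled until it passes the
#' pistil's gametophytic self-incompatibility screen ([pollenAccepted()]),
#' so the simulated hybrid is always a cross that could actually set seed.
#'
#' @param parentA,parentB lists with elements `calls` (named list of
#'   per-locus allele sets) and `s` (S-allele labels) — the format stored
#'   in [simulateAccessions()] output; alternatively accession ids together
#'   with `data` (the full simulation output)
#' @param ploidyA,ploidyB even parental ploidies
#' @param functional named logical over S-allele labels
#' @return list with `calls`, `s`, and `ploidy` (= `(ploidyA+ploidyB)/2`)
#' @export
simulateHybrid <- function(parentA, parentB, ploidyA, ploidyB,
                           functional = NULL) {
  if (ploidyA %% 2 != 0 || ploidyB %% 2 != 0)
    stop("parental ploidies must be even")
  if (is.null(functional)) {
    labs <- unique(c(parentA$s, parentB$s))
    functional <- stats::setNames(rep(TRUE, length(labs)), labs)
  }
  out <- .hybridFromDraws(parentA, ploidyA, parentB, ploidyB, functional)
  out$ploidy <- as.integer((ploidyA + ploidyB) / 2)
  out
}

#' Write a simulated dataset to disk
#'
#' Emits the same long-format genotype CSV read by [readGenotypeTable()],
#' an S-genotype CSV, and a JSON truth record.
#'
#' @param sim output of [simulateAccessions()]
#' @param dir output directory (created if needed)
#' @return character vector of the files written, invisibly
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fGeno <- file.path(dir, "genotypes.csv")
  writeGenotypeTable(sim$genotypes, fGeno)
  fS <- file.path(dir, "sgenotypes.csv")
  sg <- sim$sgenotypes
  utils::write.csv(data.frame(
    accession = accessionIds(sg),
    s_alleles = vapply(sAlleles(sg), paste, character(1), collapse = ";")),
    fS, row.names = FALSE, quote = FALSE)
  fT <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, fT, auto_unbox = TRUE, digits = NA)
  fM <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(accessions = accessionInfo(sim$genotypes)), fM,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(fGeno, fS, fT, fM))
}
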