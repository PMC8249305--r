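#' Enumerate gametes of a polysomic polyploid at the S-locus
#'
#' Under polysomic inheritance with equal chance for all possible
#' chromosome pairings at meiosis, every subset of `ploidy/2` of the
#' parent's `ploidy` S-locus chromosome copies is an equally likely gamete.
#' Gametes are aggregated by allele multiset, summing probabilities.
#'
#' When fewer distinct alleles than genome copies were detected, the
#' unassigned copies must be placed before enumeration. Under a functional
#' gametophytic self-incompatibility system a *functional* allele cannot be
#' present in more than one copy, so with `fill = "nonfunctional"`
#' (the strict default) unassigned copies are filled by duplicating
#' non-functional alleles only, and an error is raised when none exist.
#' `fill = "phantom"` instead fills with unique placeholder alleles
#' (`"?1"`, `"?2"`, ...) that are treated as never matching any pistil
#' specificity — the no-hidden-match point assumption used by
#' [crossCompatibility()].
#'
#' Odd-ploidy parents (e.g. pentaploid hybrids) have no balanced gamete
#' model and are rejected.
#'
#' @param alleles character vector of S-allele labels (a multiset:
#'   duplicates allowed for non-functional alleles)
#' @param ploidy even integer >= 2
#' @param functional named logical over all labels; defaults to all
#'   functional
#' @param fill how to place unassigned genome copies (see Details)
#' @return `data.frame` with columns `gamete` (slash-joined sorted allele
#'   multiset) and `prob`; probabilities sum to 1. The per-chromosome
#'   subsets number `choose(ploidy, ploidy/2)`.
#' @examples
#' enumerateGametes(c("S1", "S2", "S3", "S4"), 4)
#' @export
enumerateGametes <- function(alleles, ploidy, functional = NULL,
                             fill = c("nonfunctional", "phantom")) {
  fill <- match.arg(fill)
  if (ploidy %% 2 != 0)
    stop("odd ploidy (", ploidy, "): no balanced gamete model; ",
         "odd-ploidy parents can act only as pistil parents")
  if (length(alleles) > ploidy)
    stop("more alleles (", length(alleles), ") than genome copies (", ploidy, ")")
  if (is.null(functional))
    functional <- stats::setNames(rep(TRUE, length(unique(alleles))),
                                  unique(alleles))
  dupFun <- unique(alleles[duplicated(alleles)])
  dupFun <- dupFun[functional[dupFun]]
  if (length(dupFun))
    stop("functional allele(s) duplicated: ", paste(dupFun, collapse = ","))

  chrom <- as.character(alleles)
  nFill <- ploidy - length(chrom)
  if (nFill > 0) {
    if (fill == "phantom") {
      chrom <- c(chrom, paste0("?", seq_len(nFill)))
    } else {
      nonfun <- unique(chrom[!functional[chrom]])
      if (!length(nonfun))
        stop(nFill, " genome copies unassigned and no non-functional allele ",
             "to duplicate: copy number of functional alleles is ambiguous ",
             "(use fill = \"phantom\" for a no-hidden-match point estimate)")
      chrom <- c(chrom, rep_len(nonfun, nFill))
    }
  }
  m <- ploidy / 2
  subsets <- utils::combn(seq_along(chrom), m, simplify = FALSE)
  gam <- vapply(subsets, function(ix)
    paste(sort(chrom[ix]), collapse = "/"), character(1))
  tab <- table(gam)
  data.frame(gamete = names(tab),
             prob = as.vector(tab) / length(subsets))
}

#' Is a pollen gamete accepted by a pistil?
#'
#' One-allele-match rule of gametophytic self-incompatibility in
#' polyploids: a pollen grain is rejected if and only if it carries at
#' least one *functional* S-allele whose specificity matches a
#' *functional* S-RNase of the pistil. Non-functional alleles on either
#' side never cause rejection; placeholder alleles (`"?..."`) match
#' nothing.
#'
#' @param gamete character vector of allele labels (or a slash-joined
#'   string as produced by [enumerateGametes()])
#' @param pistil character vector of the pistil genotype's allele labels
#' @param functional named logical over all real labels involved
#' @return `TRUE` when the gamete can fertilize
#' @export
pollenAccepted <- function(gamete, pistil, functional = NULL) {
  if (length(gamete) == 1 && grepl("/", gamete, fixed = TRUE))
    gamete <- strsplit(gamete, "/", fixed = TRUE)[[1]]
  labs <- unique(c(gamete, pistil))
  real <- labs[!startsWith(labs, "?")]
  if (is.null(functional))
    functional <- stats::setNames(rep(TRUE, length(real)), real)
  if (!all(real %in% names(functional)))
    stop("unknown allele label(s): ",
         paste(setdiff(real, names(functional)), collapse = ","))
  gamFun <- gamete[!startsWith(gamete, "?")]
  gamFun <- gamFun[functional[gamFun]]
  pisFun <- pistil[!startsWith(pistil, "?")]
  pisFun <- pisFun[functional[pisFun]]
  !any(gamFun %in% pisFun)
}

#' Compatible-pollen fraction of a cross
#'
#' Enumerates the pollen parent's gametes under the polysomic model and
#' sums the probability of those accepted by the seed parent's pistil under
#' the one-allele-match rule. For two parents with all alleles distinct,
#' functional and fully assigned, the fraction has the closed
#' hypergeometric form `choose(n - s, m) / choose(n, m)` for a pollen
#' parent with `n` alleles sharing `s` with the pistil and gamete size `m`.
#'
#' The point estimate places unassigned pollen genome copies as phantom
#' alleles that match no pistil specificity (no hidden matches). With
#' `interval = TRUE` the function also reports the range of the fraction
#' over all completions consistent with the self-incompatibility constraint
#' that functional alleles are single-copy: the lower bound fills copies
#' with pistil-matching functional alleles not yet in the pollen genotype,
#' the upper bound with novel non-matching ones.
#'
#' @param seedParent,pollenParent character vectors of S-allele labels, or
#'   accession ids when `sgenotypes` is given
#' @param sgenotypes optional [SGenotypes-class] supplying genotypes,
#'   ploidies and functionality flags by accession id
#' @param seedPloidy,pollenPloidy genome copy numbers (defaulting to
#'   metadata in `sgenotypes`, else the smallest even ploidy holding the
#'   alleles)
#' @param functional named logical over allele labels (ignored when
#'   `sgenotypes` is given)
#' @param interval also compute `[min, max]` over consistent completions
#' @return list with `fraction`, `category` (`"incompatible"` iff 0,
#'   `"fully_compatible"` iff 1, else `"partially_compatible"`), `gametes`
#'   (the acceptance-annotated gamete table) and, when requested,
#'   `fractionMin`/`fractionMax`
#' @examples
#' # two tetraploids sharing two of four functional S-alleles
#' crossCompatibility(c("S1","S2","S3","S4"), c("S1","S2","S5","S6"))$fraction
#' @export
crossCompatibility <- function(seedParent, pollenParent, sgenotypes = NULL,
                               seedPloidy = NULL, pollenPloidy = NULL,
                               functional = NULL, interval = FALSE) {
  if (!is.null(sgenotypes)) {
    acc <- accessionInfo(sgenotypes)
    getG <- function(x) if (length(x) == 1 && x %in% acc$id)
      sAlleles(sgenotypes)[[x]] else x
    getP <- function(x, p) if (!is.null(p)) p else
      if (length(x) == 1 && x %in% acc$id) acc$ploidy[match(x, acc$id)] else NULL
    seedPloidy <- getP(seedParent, seedPloidy)
    pollenPloidy <- getP(pollenParent, pollenPloidy)
    seedParent <- getG(seedParent); pollenParent <- getG(pollenParent)
    if (is.null(functional)) functional <- functionalFlags(sgenotypes)
  }
  evenUp <- function(g) max(2L, as.integer(2 * ceiling(length(g) / 2)))
  if (is.null(pollenPloidy)) pollenPloidy <- evenUp(pollenParent)
  if (is.null(seedPloidy)) seedPloidy <- evenUp(seedParent)
  labs <- unique(c(seedParent, pollenParent))
  if (is.null(functional))
    functional <- stats::setNames(rep(TRUE, length(labs)), labs)

  gam <- enumerateGametes(pollenParent, pollenPloidy, functional,
                          fill = "phantom")
  gam$accepted <- vapply(gam$gamete, pollenAccepted, logical(1),
                         pistil = seedParent, functional = functional)
  fraction <- sum(gam$prob[gam$accepted])
  out <- list(fraction = fraction,
              category = if (fraction == 0) "incompatible"
                         else if (fraction == 1) "fully_compatible"
                         else "partially_compatible",
              gametes = gam)
  if (interval) {
    nFill <- pollenPloidy - length(pollenParent)
    out$fractionMax <- fraction  # phantom fill: no hidden matches
    if (nFill > 0) {
      extra <- setdiff(seedParent[functional[seedParent]], pollenParent)
      low <- c(pollenParent, utils::head(extra, nFill))
      pad <- nFill - min(nFill, length(extra))
      if (pad > 0) low <- c(low, paste0("?", seq_len(pad)))
      gl <- enumerateGametes(low, pollenPloidy, functional, fill = "phantom")
      acc_ <- vapply(gl$gamete, pollenAccepted, logical(1),
                     pistil = seedParent, functional = functional)
      out$fractionMin <- sum(gl$prob[acc_])
    } else out$fractionMin <- fraction
  }
  out
}

#' Cross-compatibility matrix for an accession panel
#'
#' Computes the compatible-pollen fraction for every ordered (seed, pollen)
#' pair of the panel. Pollen-side computation for odd-ploidy accessions is
#' undefined under the balanced polysomic model; those columns are `NA`.
#'
#' @param sgenotypes an [SGenotypes-class] object
#' @return numeric matrix, rows = seed (pistil) parents, columns = pollen
#'   parents; diagonal = predicted self-compatibility
#' @export
compatibilityMatrix <- function(sgenotypes) {
  acc <- accessionInfo(sgenotypes)
  n <- nrow(acc)
  out <- matrix(NA_real_, n, n, dimnames = list(seed = acc$id, pollen = acc$id))
  for (j in seq_len(n)) {
    if (acc$ploidy[j] %% 2 != 0) next
    for (i in seq_len(n))
      out[i, j] <- crossCompatibility(acc$id[i], acc$id[j],
                                      sgenotypes = sgenotypes)$fraction
  }
  out
}

#' Partition accessions into cross-incompatibility groups
#'
#' Accessions with identical sets of *functional* S-alleles reject all of
#' each other's functional pollen and cannot fertilize one another; such
#' accessions must not be co-planted as mutual pollinizers.
#'
#' @param sgenotypes an [SGenotypes-class] object
#' @return list of sorted accession-id vectors (the full partition);
#'   attribute `"multi"` lists groups of size >= 2
#' @export
incompatibilityGroups <- function(sgenotypes) {
  fun <- functionalFlags(sgenotypes)
  key <- vapply(sAlleles(sgenotypes), function(g) {
    g <- unique(g); paste(sort(g[fun[g]]), collapse = "/")
  }, character(1))
  part <- lapply(split(names(key), unname(key)), sort)
  part <- unname(part[order(vapply(part, `[`, character(1), 1))])
  attr(part, "multi") <- part[vapply(part, length, integer(1)) >= 2L]
  part
}

#' Predicted fraction of self-pollen accepted
#'
#' Self-compatibility under the one-allele-match model: the genotype is
#' crossed with itself, so only gametes composed entirely of non-functional
#' (or unassigned) alleles escape rejection. Genotypes whose alleles are
#' all functional are predicted fully self-incompatible; accumulating two
#' or more non-functional haplotypes opens a compatible gamete class.
#'
#' @inheritParams crossCompatibility
#' @param sgenotype character vector of allele labels, or an accession id
#'   when `sgenotypes` is given
#' @param ploidy genome copy number
#' @return list as from [crossCompatibility()]
#' @export
predictSelfCompatibility <- function(sgenotype, sgenotypes = NULL,
                                     ploidy = NULL, functional = NULL) {
  crossCompatibility(sgenotype, sgenotype, sgenotypes = sgenotypes,
                     seedPloidy = ploidy, pollenPloidy = ploidy,
                     functional = functional)
}
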