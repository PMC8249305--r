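#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' Polyploid genotypes with dosage-unaware allele calls
#'
#' Container for multilocus SSR genotypes of polyploid accessions where only
#' the *set* of distinct allele sizes per locus is observable: allele copy
#' number (dosage) is unknown, so a tetraploid showing three bands may carry
#' any of several underlying dosage configurations.
#'
#' @slot calls Named list, one element per accession. Each element is a named
#'   list mapping locus name to a sorted integer vector of observed allele
#'   sizes (bp). A locus absent from an accession's list is *missing*
#'   (amplification failure), which is distinct from an empty set; empty sets
#'   never occur in valid objects.
#' @slot accessions `data.frame` with columns `id`, `species`
#'   (`"P_spinosa"`, `"P_insititia"` or `"hybrid"`), `ploidy` (integer
#'   >= 2) and `origin` (free text). `id` values are unique and match
#'   `names(calls)`.
#' @slot missing `data.frame` with columns `accession`, `locus`: loci that
#'   were attempted but failed to amplify.
#'
#' @seealso [readGenotypeTable()], [locusSummary()], [encodeBinary()]
#' @export
setClass("PolyGenotypes",
  slots = c(calls = "list", accessions = "data.frame", missing = "data.frame"))

setValidity("PolyGenotypes", function(object) {
  msg <- character()
  acc <- object@accessions
  need <- c("id", "species", "ploidy", "origin")
  if (!all(need %in% names(acc)))
    return(paste("accessions must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(acc$id))
    msg <- c(msg, "accession ids must be unique")
  if (any(acc$ploidy < 2))
    msg <- c(msg, "ploidy must be >= 2")
  if (!setequal(names(object@calls), acc$id))
    msg <- c(msg, "names(calls) must match accession ids")
  for (a in names(object@calls)) {
    cl <- object@calls[[a]]
    k <- acc$ploidy[match(a, acc$id)]
    for (loc in names(cl)) {
      sizes <- cl[[loc]]
      if (length(sizes) < 1L)
        msg <- c(msg, sprintf("%s/%s: empty allele set (use missing instead)", a, loc))
      if (anyDuplicated(sizes))
        msg <- c(msg, sprintf("%s/%s: duplicated allele sizes", a, loc))
      if (any(sizes <= 0) || any(sizes != round(sizes)))
        msg <- c(msg, sprintf("%s/%s: allele sizes must be positive integers", a, loc))
      if (length(sizes) > k)
        msg <- c(msg, sprintf(
          "%s/%s: %d alleles exceed declared ploidy %d", a, loc, length(sizes), k))
    }
  }
  if (length(msg)) msg else TRUE
})

#' S-locus genotypes with functionality annotation
#'
#' Per-accession sets of S-RNase allele labels for a gametophytic
#' self-incompatibility locus. Because a functional self-incompatibility
#' system forbids matching functional specificities on homologous
#' chromosomes, a label may appear more than once in a genotype only when the
#' allele is annotated non-functional.
#'
#' @slot genotypes Named list mapping accession id to a character vector of
#'   S-allele labels (duplicates allowed only for non-functional alleles).
#' @slot functional Named logical vector over all labels used; `TRUE` means
#'   the allele encodes an active S-RNase.
#' @slot accessions `data.frame` as in [PolyGenotypes-class].
#'
#' @seealso [loadFixture()], [enumerateGametes()], [crossCompatibility()]
#' @export
setClass("SGenotypes",
  slots = c(genotypes = "list", functional = "logical", accessions = "data.frame"))

setValidity("SGenotypes", function(object) {
  msg <- character()
  acc <- object@accessions
  if (anyDuplicated(acc$id))
    msg <- c(msg, "accession ids must be unique")
  if (!setequal(names(object@genotypes), acc$id))
    msg <- c(msg, "names(genotypes) must match accession ids")
  labs <- unique(unlist(object@genotypes, use.names = FALSE))
  if (!all(labs %in% names(object@functional)))
    msg <- c(msg, "every allele label needs a functionality flag")
  for (a in names(object@genotypes)) {
    g <- object@genotypes[[a]]
    k <- acc$ploidy[match(a, acc$id)]
    if (length(g) > k)
      msg <- c(msg, sprintf("%s: %d S-alleles exceed ploidy %d", a, length(g), k))
    dup <- unique(g[duplicated(g)])
    bad <- dup[object@functional[dup]]
    if (length(bad))
      msg <- c(msg, sprintf("%s: duplicated functional allele(s) %s",
                            a, paste(bad, collapse = ",")))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PolyGenotypes", function(object) {
  nl <- length(unique(unlist(lapply(object@calls, names))))
  cat(sprintf("PolyGenotypes: %d accessions, %d loci\n",
              nrow(object@accessions), nl))
  cat(sprintf("  ploidies: %s\n",
              paste(sort(unique(object@accessions$ploidy)), collapse = "/")))
  if (nrow(object@missing))
    cat(sprintf("  %d missing accession x locus combinations\n", nrow(object@missing)))
})

setMethod("show", "SGenotypes", function(object) {
  nf <- sum(!object@functional)
  cat(sprintf("SGenotypes: %d accessions, %d S-allele labels (%d non-functional)\n",
              nrow(object@accessions), length(object@functional), nf))
})

#' @describeIn PolyGenotypes-class construct from a list of per-accession calls
#' @param calls,accessions,missing see slot documentation
#' @export
PolyGenotypes <- function(calls, accessions,
                          missing = data.frame(accession = character(),
                                               locus = character())) {
  accessions$id <- as.character(accessions$id)
  calls <- lapply(calls, function(cl) lapply(cl, function(x) sort(unique(as.integer(x)))))
  new("PolyGenotypes", calls = calls[accessions$id], accessions = accessions,
      missing = missing)
}

#' @describeIn SGenotypes-class construct from a list of label vectors
#' @param genotypes,functional,accessions see slot documentation
#' @export
SGenotypes <- function(genotypes, functional = NULL, accessions) {
  accessions$id <- as.character(accessions$id)
  labs <- sort(unique(unlist(genotypes, use.names = FALSE)))
  if (is.null(functional)) {
    functional <- stats::setNames(rep(TRUE, length(labs)), labs)
  } else if (is.null(names(functional)) || !all(labs %in% names(functional))) {
    stop("'functional' must be a named logical covering all allele labels")
  }
  genotypes <- lapply(genotypes, function(g) sort(as.character(g)))
  new("SGenotypes", genotypes = genotypes[accessions$id],
      functional = functional, accessions = accessions)
}

# ---- accessors ----

#' @rdname PolyGenotypes-class
#' @param object,x a `PolyGenotypes` or `SGenotypes` object
#' @export
setGeneric("accessionInfo", function(object) standardGeneric("accessionInfo"))
#' @rdname PolyGenotypes-class
#' @export
setMethod("accessionInfo", "PolyGenotypes", function(object) object@accessions)
#' @rdname SGenotypes-class
#' @export
setMethod("accessionInfo", "SGenotypes", function(object) object@accessions)

#' @rdname PolyGenotypes-class
#' @export
accessionIds <- function(object) accessionInfo(object)$id

#' @rdname PolyGenotypes-class
#' @export
setGeneric("genotypeCalls", function(object) standardGeneric("genotypeCalls"))
#' @rdname PolyGenotypes-class
#' @export
setMethod("genotypeCalls", "PolyGenotypes", function(object) object@calls)

#' @rdname SGenotypes-class
#' @export
setGeneric("sAlleles", function(object) standardGeneric("sAlleles"))
#' @rdname SGenotypes-class
#' @export
setMethod("sAlleles", "SGenotypes", function(object) object@genotypes)

#' @rdname SGenotypes-class
#' @export
setGeneric("functionalFlags", function(object) standardGeneric("functionalFlags"))
#' @rdname SGenotypes-class
#' @export
setMethod("functionalFlags", "SGenotypes", function(object) object@functional)

#' Locus names observed in a genotype set
#' @param object a `PolyGenotypes` object
#' @return character vector of locus names, sorted
#' @export
locusNames <- function(object) {
  sort(unique(c(unlist(lapply(object@calls, names), use.names = FALSE),
                object@missing$locus)))
}

#' Missing accession-by-locus combinations
#' @param object a `PolyGenotypes` object
#' @return `data.frame` with columns `accession`, `locus`
#' @export
missingLoci <- function(object) object@missing
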