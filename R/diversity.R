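#' Presence-based allele frequencies at a locus
#'
#' In a dosage-unaware polyploid dataset the copy number of each allele is
#' unobservable, so gene frequencies cannot be estimated in the diploid
#' sense. Instead each accession contributes one count per *distinct* allele
#' it carries, and frequencies are counts over the total number of
#' allele-in-accession occurrences at the locus. Accessions whose locus is
#' missing (failed amplification) are excluded entirely rather than treated
#' as null-allele carriers.
#'
#' @param genotypes a [PolyGenotypes-class] object, or a plain list of
#'   per-accession allele vectors for a single marker
#' @param locus locus name (ignored for a plain list)
#' @return `data.frame` with columns `allele`, `count`, `freq`
#'   (`sum(freq) == 1`), ordered by decreasing count then allele
#' @seealso [pic()]
#' @export
presenceFrequencies <- function(genotypes, locus = NULL) {
  sets <- .locusSets(genotypes, locus)
  if (!length(sets)) stop("no accession scored at locus ", locus)
  occ <- unlist(lapply(sets, unique), use.names = FALSE)
  cnt <- table(occ)
  out <- data.frame(allele = names(cnt), count = as.integer(cnt),
                    freq = as.integer(cnt) / sum(cnt))
  out[order(-out$count, out$allele), , drop = FALSE]
}

.locusSets <- function(genotypes, locus) {
  if (is(genotypes, "PolyGenotypes")) {
    sets <- lapply(genotypes@calls, function(cl) cl[[locus]])
    Filter(Negate(is.null), sets)
  } else if (is(genotypes, "SGenotypes")) {
    Filter(function(x) length(x) > 0, genotypes@genotypes)
  } else {
    Filter(function(x) length(x) > 0, genotypes)
  }
}

#' Polymorphic information content
#'
#' The marker-informativeness statistic
#' \deqn{PIC = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2,}
#' where \eqn{p_i} are allele frequencies. The second sum corrects expected
#' heterozygosity for the chance that a random cross is uninformative
#' because both parents share the same heterozygous genotype. The simpler
#' expected heterozygosity \eqn{1 - \sum_i p_i^2} is available via
#' `method = "heterozygosity"`; the full formula is the default because it
#' is the standard for marker-informativeness reporting.
#'
#' @param freqs numeric vector of allele frequencies summing to 1, or the
#'   `data.frame` returned by [presenceFrequencies()]
#' @param method `"botstein"` (full formula, default) or `"heterozygosity"`
#' @return a value in `[0, 1)`
#' @examples
#' pic(c(0.5, 0.5))         # 0.375
#' pic(c(0.5, 0.5), "heterozygosity")  # 0.5
#' @export
pic <- function(freqs, method = c("botstein", "heterozygosity")) {
  method <- match.arg(method)
  p <- if (is.data.frame(freqs)) freqs$freq else as.numeric(freqs)
  if (any(p <= 0)) stop("frequencies must be positive")
  if (abs(sum(p) - 1) > 1e-8) stop("frequencies must sum to 1")
  het <- 1 - sum(p^2)
  if (method == "heterozygosity") return(het)
  p2 <- p^2
  cross <- (sum(p2)^2 - sum(p2^2)) / 2  # sum_{i<j} p_i^2 p_j^2
  het - 2 * cross
}

#' Per-locus diversity summary
#'
#' Computes, for one marker, the statistics conventionally reported for
#' germplasm fingerprinting panels: number of alleles, observed size range,
#' number of unique alleles (carried by exactly one accession), number of
#' distinct per-locus genotypes among scored accessions, and PIC (both
#' variants).
#'
#' @inheritParams presenceFrequencies
#' @return one-row `data.frame` with columns `locus`, `n_scored`,
#'   `n_alleles`, `size_min_bp`, `size_max_bp`, `n_unique_alleles`,
#'   `n_genotypes`, `pic`, `heterozygosity`
#' @export
locusSummary <- function(genotypes, locus) {
  sets <- .locusSets(genotypes, locus)
  if (!length(sets)) stop("no accession scored at locus ", locus)
  spec <- presenceFrequencies(genotypes, locus)
  sizes <- suppressWarnings(as.numeric(spec$allele))
  profiles <- unique(vapply(sets, function(x) paste(sort(x), collapse = "/"),
                            character(1)))
  data.frame(
    locus = if (is.null(locus)) NA_character_ else locus,
    n_scored = length(sets),
    n_alleles = nrow(spec),
    size_min_bp = if (anyNA(sizes)) NA_real_ else min(sizes),
    size_max_bp = if (anyNA(sizes)) NA_real_ else max(sizes),
    n_unique_alleles = sum(spec$count == 1L),
    n_genotypes = length(profiles),
    pic = pic(spec),
    heterozygosity = pic(spec, "heterozygosity"))
}

#' Diversity summary for every locus
#'
#' @param genotypes a [PolyGenotypes-class] object
#' @param digits rounding (half-up) applied to the PIC columns for
#'   reporting; `NULL` leaves full precision
#' @return `data.frame` with one row per locus, see [locusSummary()]
#' @export
diversityTable <- function(genotypes, digits = 2) {
  out <- do.call(rbind, lapply(locusNames(genotypes), function(loc)
    locusSummary(genotypes, loc)))
  if (!is.null(digits))
    for (col in c("pic", "heterozygosity"))
      out[[col]] <- roundHalfUp(out[[col]], digits)
  rownames(out) <- NULL
  out
}

#' Round half away from zero
#'
#' `round()` in R rounds half to even; published marker tables
#' conventionally round half up, so 0.925 prints as 0.93.
#' @param x numeric
#' @param digits decimal places
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Group accessions with identical multilocus profiles
#'
#' Accessions showing the same allele set at every marker of `markers` are
#' putative clones (or, for the S-locus, members of one cross-incompatibility
#' group). Accessions missing any of the markers are excluded and reported
#' in the `"excluded"` attribute.
#'
#' @param genotypes a [PolyGenotypes-class] or [SGenotypes-class] object
#' @param markers marker subset to compare on; default all loci
#'   (for `SGenotypes` the single S-locus is used)
#' @return list of character vectors (each sorted by accession id) of size
#'   >= 2 — the putative clonal groups, ordered by first member; attribute
#'   `"all_groups"` holds the full partition including singletons
#' @export
findClonalGroups <- function(genotypes, markers = NULL) {
  prof <- .profileStrings(genotypes, markers)
  part <- split(names(prof), unname(prof))
  part <- lapply(part, sort)
  part <- part[order(vapply(part, `[`, character(1), 1))]
  groups <- unname(part[vapply(part, length, integer(1)) >= 2L])
  attr(groups, "all_groups") <- unname(part)
  attr(groups, "excluded") <- attr(prof, "excluded")
  groups
}

.profileStrings <- function(genotypes, markers = NULL) {
  if (is(genotypes, "SGenotypes")) {
    prof <- vapply(genotypes@genotypes, function(g)
      paste(sort(g), collapse = "/"), character(1))
    attr(prof, "excluded") <- character()
    return(prof)
  }
  if (is.null(markers)) markers <- locusNames(genotypes)
  if (!length(markers)) stop("empty marker subset")
  ok <- vapply(accessionIds(genotypes), function(a)
    all(markers %in% names(genotypes@calls[[a]])), logical(1))
  prof <- vapply(accessionIds(genotypes)[ok], function(a)
    paste(vapply(markers, function(loc)
      paste(genotypes@calls[[a]][[loc]], collapse = "/"), character(1)),
      collapse = "|"), character(1))
  attr(prof, "excluded") <- accessionIds(genotypes)[!ok]
  prof
}

#' Smallest marker subsets that separate all distinct accessions
#'
#' Exhaustively searches subsets of loci of size 1, 2, ... `maxSize` and
#' returns *all* subsets of the first size at which at least one subset
#' distinguishes every pair of accessions that differ somewhere on the full
#' panel. Known clonal groups (identical on all markers) are collapsed to a
#' single representative first, since no marker can separate true clones.
#'
#' @param genotypes a [PolyGenotypes-class] object
#' @param maxSize largest subset size to try
#' @return list of character vectors (the minimal discriminating subsets);
#'   empty list with attribute `"unresolved_pairs"` when no subset of size
#'   <= `maxSize` works
#' @export
minimalDiscriminatingSets <- function(genotypes, maxSize = 3) {
  stopifnot(maxSize >= 1)
  loci <- locusNames(genotypes)
  full <- .profileStrings(genotypes, loci)
  reps <- names(full)[!duplicated(unname(full))]   # collapse clones
  perLocus <- lapply(loci, function(loc)
    vapply(reps, function(a)
      paste(genotypes@calls[[a]][[loc]], collapse = "/"), character(1)))
  names(perLocus) <- loci
  for (k in seq_len(min(maxSize, length(loci)))) {
    sets <- utils::combn(loci, k, simplify = FALSE)
    hits <- Filter(function(s) {
      key <- do.call(paste, c(perLocus[s], sep = "|"))
      !anyDuplicated(key)
    }, sets)
    if (length(hits)) return(hits)
  }
  # diagnostic: pairs not separated by the best subset of maxSize loci
  best <- NULL; bestDup <- Inf
  for (s in utils::combn(loci, min(maxSize, length(loci)), simplify = FALSE)) {
    key <- do.call(paste, c(perLocus[s], sep = "|"))
    d <- sum(duplicated(key))
    if (d < bestDup) { bestDup <- d; best <- key }
  }
  dupkeys <- unique(best[duplicated(best)])
  pairs <- lapply(dupkeys, function(kk) reps[best == kk])
  out <- list()
  attr(out, "unresolved_pairs") <- pairs
  out
}
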