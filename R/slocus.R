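#' Bin S-RNase intron fragment lengths into alleles
#'
#' Intron-length-polymorphism genotyping assigns each PCR fragment to an
#' S-allele by size. Fragments are clustered in one dimension by single
#' linkage: sorted lengths are split wherever the gap between neighbours
#' exceeds the tolerance. Sequencer-called sizes are precise while sizes
#' estimated from agarose gels are not, so the default tolerance is
#' absolute (+/- 10 bp) below 1000 bp and relative (3%) above, where gel
#' estimates dominate.
#'
#' Pairs of alleles with nearly identical fragment sizes cannot be
#' separated on a gel; they are kept apart only when observations carry a
#' `sequence_label` annotation (sequence-confirmed identity). Otherwise
#' they merge into one bin with a warning.
#'
#' @param observations `data.frame` with columns `accession`, `length_bp`,
#'   and optionally `approximate` (logical), `region` (`"first"`/`"second"`
#'   intron; only `"second"` fragments are used for genotype calls) and
#'   `sequence_label` (character, `NA` when not sequenced)
#' @param tolerance absolute gap tolerance in bp for fragments under
#'   `relativeAbove`, or `NULL` for the default 10 bp
#' @param relativeTolerance fractional tolerance used above `relativeAbove`
#' @param relativeAbove size threshold switching to relative tolerance
#' @return list with `catalog` (a `data.frame`: `label`, `size_bp`
#'   (representative = rounded median), `size_min`, `size_max`, `count`)
#'   and `genotypes` (an [SGenotypes-class]). Labels are assigned
#'   `S_A`, `S_B`, ... in descending carrier count, ties by ascending
#'   size; sequence-confirmed bins keep their supplied labels.
#' @export
binFragments <- function(observations, tolerance = NULL,
                         relativeTolerance = 0.03, relativeAbove = 1000) {
  if (!is.null(tolerance) && tolerance <= 0) stop("tolerance must be > 0")
  tol <- if (is.null(tolerance)) 10 else tolerance
  obs <- as.data.frame(observations)
  stopifnot(all(c("accession", "length_bp") %in% names(obs)))
  if (!nrow(obs)) stop("need at least one observation")
  if ("region" %in% names(obs)) obs <- obs[obs$region == "second", , drop = FALSE]
  if (!"sequence_label" %in% names(obs)) obs$sequence_label <- NA_character_
  obs <- obs[order(obs$length_bp), , drop = FALSE]

  gapTol <- function(x, y) {
    m <- (x + y) / 2
    if (m < relativeAbove) tol else relativeTolerance * m
  }
  bin <- cumsum(c(0, vapply(seq_len(nrow(obs) - 1), function(i)
    (obs$length_bp[i + 1] - obs$length_bp[i]) >
      gapTol(obs$length_bp[i], obs$length_bp[i + 1]), numeric(1))))
  obs$bin <- bin

  # split bins whose members carry distinct sequence-confirmed labels
  pieces <- list()
  for (b in unique(bin)) {
    sub <- obs[obs$bin == b, , drop = FALSE]
    labs <- unique(stats::na.omit(sub$sequence_label))
    if (length(labs) >= 2) {
      reps <- vapply(labs, function(l)
        stats::median(sub$length_bp[!is.na(sub$sequence_label) &
                                    sub$sequence_label == l]), numeric(1))
      assign_ <- ifelse(is.na(sub$sequence_label),
                        labs[apply(abs(outer(sub$length_bp, reps, `-`)), 1,
                                   which.min)],
                        sub$sequence_label)
      for (l in labs)
        pieces[[length(pieces) + 1L]] <- cbind(sub[assign_ == l, , drop = FALSE],
                                               fixed_label = l)
    } else {
      if (length(labs) == 0 && anyDuplicated(sub$accession) &&
          length(unique(sub$length_bp)) > 1)
        warning(sprintf(paste0(
          "bin at ~%d bp holds multiple fragments from one accession; ",
          "alleles this close need sequence confirmation to separate"),
          as.integer(round(stats::median(sub$length_bp)))))
      pieces[[length(pieces) + 1L]] <- cbind(
        sub, fixed_label = if (length(labs)) labs else NA_character_)
    }
  }
  obs <- do.call(rbind, pieces)

  key <- paste(obs$bin, obs$fixed_label)
  stats <- do.call(rbind, lapply(split(obs, key), function(sub) data.frame(
    fixed_label = sub$fixed_label[1],
    size_bp = as.integer(round(stats::median(sub$length_bp))),
    size_min = min(sub$length_bp), size_max = max(sub$length_bp),
    count = length(unique(sub$accession)))))
  stats <- stats[order(-stats$count, stats$size_bp), , drop = FALSE]
  pool <- paste0("S_", c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0)))))
  free <- setdiff(pool, stats::na.omit(stats$fixed_label))
  stats$label <- ifelse(is.na(stats$fixed_label),
                        free[cumsum(is.na(stats$fixed_label))],
                        stats$fixed_label)
  catalog <- stats[, c("label", "size_bp", "size_min", "size_max", "count")]
  rownames(catalog) <- NULL

  # map each observation to its catalog label
  obs$label <- stats$label[match(key, rownames(stats))]
  genos <- lapply(split(obs$label, obs$accession), function(x) sort(unique(x)))
  accs <- data.frame(id = names(genos), species = "unknown",
                     ploidy = vapply(genos, length, integer(1)) + 0L,
                     origin = "")
  accs$ploidy <- pmax(2L, as.integer(2 * ceiling(accs$ploidy / 2)))
  sg <- SGenotypes(genos, accessions = accs)
  list(catalog = catalog, genotypes = sg)
}

#' Occurrence table for S-alleles by species class
#'
#' Counts, for every S-allele label, the carriers in each species class and
#' in total, plus the presence-based frequency (total over the summed
#' totals). This recomputes the occurrence statistics from the genotypes
#' themselves.
#'
#' @param sgenotypes an [SGenotypes-class] object (species classes are read
#'   from its accession metadata)
#' @param catalogOrder optional character vector fixing the allele row
#'   order; default is label sort order
#' @return `data.frame` with one row per allele: `allele`, one count column
#'   per species class, `total`, `freq`
#' @export
occurrenceTable <- function(sgenotypes, catalogOrder = NULL) {
  acc <- accessionInfo(sgenotypes)
  genos <- sAlleles(sgenotypes)
  if (!length(genos))
    return(data.frame(allele = character(), total = integer(),
                      freq = numeric()))
  long <- do.call(rbind, lapply(names(genos), function(a) {
    if (!a %in% acc$id) stop("unknown accession id: ", a)
    g <- unique(genos[[a]])
    if (!length(g)) return(NULL)
    data.frame(allele = g, species = acc$species[match(a, acc$id)])
  }))
  tab <- as.data.frame.matrix(table(long$allele, long$species))
  out <- data.frame(allele = rownames(tab), tab, check.names = FALSE,
                    row.names = NULL)
  out$total <- rowSums(tab)
  out$freq <- out$total / sum(out$total)
  ord <- if (is.null(catalogOrder)) order(out$allele) else
    order(match(out$allele, catalogOrder))
  out[ord, , drop = FALSE]
}

#' S-alleles shared between two genotypes
#'
#' @param g1,g2 character vectors of S-allele labels (or single accession
#'   genotypes extracted with [sAlleles()])
#' @return sorted character vector of common labels
#' @export
sharedAlleles <- function(g1, g2) sort(intersect(unique(g1), unique(g2)))

#' Scan a coding sequence for a premature stop codon
#'
#' Translates the in-frame CDS and reports the first stop codon occurring
#' before the expected protein end. A premature stop truncates the S-RNase
#' (typically losing catalytic residues downstream), rendering the allele
#' non-functional for pollen rejection.
#'
#' @param cds a character string or [Biostrings::DNAString] holding the
#'   in-frame coding sequence (length divisible by 3)
#' @param expectedEnd expected protein length in codons (position of the
#'   natural stop); default the final codon of `cds`
#' @return list with `functional` (logical) and `stopCodon` (1-based codon
#'   index of the premature stop, or `NA`)
#' @export
scanPrematureStop <- function(cds, expectedEnd = NULL) {
  s <- toupper(as.character(cds))
  if (grepl("[^ACGTRYSWKMBDHVN]", s)) stop("non-IUPAC characters in sequence")
  if (nchar(s) %% 3 != 0) stop("sequence length not divisible by 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "solve"))
  nCodon <- nchar(aa)
  if (is.null(expectedEnd)) expectedEnd <- nCodon
  stops <- unlist(gregexpr("*", aa, fixed = TRUE))
  stops <- stops[stops > 0 & stops < expectedEnd]
  if (length(stops))
    list(functional = FALSE, stopCodon = stops[1])
  else
    list(functional = TRUE, stopCodon = NA_integer_)
}

#' Proportion of differing residues under complete deletion
#'
#' The p-distance between two sequences of a multiple alignment after
#' removing every column containing a gap or missing residue in *any*
#' sequence (complete deletion), so all pairs are compared over the same
#' positions.
#'
#' @param alignment an [Biostrings::AAStringSet] of equal-width aligned
#'   sequences (or a character vector)
#' @param i,j sequence indices or names
#' @return proportion of differing positions, in `[0, 1]`
#' @export
pDistance <- function(alignment, i, j) {
  mat <- .alignmentMatrix(alignment)
  keep <- .completeDeletionMask(mat)
  if (!any(keep)) stop("no columns left after complete deletion")
  mean(mat[i, keep] != mat[j, keep])
}

.alignmentMatrix <- function(alignment) {
  seqs <- if (is(alignment, "XStringSet")) as.character(alignment) else
    as.character(alignment)
  if (length(unique(nchar(seqs))) != 1) stop("aligned sequences must have equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  mat
}

.completeDeletionMask <- function(mat) {
  colSums(matrix(mat %in% c("-", ".", "?", "X", "*"), nrow = nrow(mat))) == 0
}

#' Poisson-corrected amino-acid distance
#'
#' Corrects an observed proportion of differing residues for multiple
#' substitutions at the same site: \eqn{d = -\ln(1 - p)}.
#'
#' @param p observed p-distance(s) in `[0, 1)`
#' @return corrected distance(s), `>= p`
#' @export
poissonCorrection <- function(p) {
  if (any(p < 0) || any(p >= 1))
    stop("p must be in [0, 1); p = 1 saturates the correction")
  -log(1 - p)
}

#' Pairwise Poisson-corrected divergence matrix
#'
#' @inheritParams pDistance
#' @param digits decimal places for the reported matrix (3 by convention);
#'   `NULL` for full precision
#' @return symmetric matrix of corrected distances
#' @export
divergenceMatrix <- function(alignment, digits = 3) {
  mat <- .alignmentMatrix(alignment)
  keep <- .completeDeletionMask(mat)
  if (!any(keep)) stop("no columns left after complete deletion")
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    d[i, j] <- d[j, i] <- poissonCorrection(mean(mat[i, keep] != mat[j, keep]))
  if (!is.null(digits)) d <- round(d, digits)
  d
}
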