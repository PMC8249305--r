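#' Encode genotypes as a presence/absence marker matrix
#'
#' Each observed (locus, allele) combination becomes one marker row scored 1
#' (present) or 0 (absent) per accession — the standard encoding for
#' dosage-unaware polyploid fingerprints. When an [SGenotypes-class] object
#' is supplied the S-alleles are appended as additional rows of a
#' pseudo-locus `"S"`, giving the merged SSR + S-locus dataset.
#'
#' @param genotypes a [PolyGenotypes-class] object, or `NULL` to encode the
#'   S-locus alone
#' @param sgenotypes optional [SGenotypes-class] over the same accessions
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `presence` (markers x accessions), `rowData` columns `locus` and
#'   `allele`, accession metadata as `colData`, and a logical
#'   loci-x-accessions missingness matrix in `metadata(x)$missing` used for
#'   pairwise deletion in [diceSimilarity()]
#' @export
encodeBinary <- function(genotypes, sgenotypes = NULL) {
  stopifnot(!is.null(genotypes) || !is.null(sgenotypes))
  long <- list()
  if (!is.null(genotypes)) {
    for (a in accessionIds(genotypes)) {
      cl <- genotypes@calls[[a]]
      for (loc in names(cl))
        long[[length(long) + 1L]] <- data.frame(
          accession = a, locus = loc, allele = as.character(cl[[loc]]))
    }
  }
  if (!is.null(sgenotypes)) {
    for (a in names(sgenotypes@genotypes)) {
      g <- unique(sgenotypes@genotypes[[a]])
      if (length(g))
        long[[length(long) + 1L]] <- data.frame(
          accession = a, locus = "S", allele = g)
    }
  }
  long <- do.call(rbind, long)
  accs <- if (!is.null(genotypes)) accessionIds(genotypes) else
    accessionIds(sgenotypes)
  loci <- unique(long$locus)
  # numeric alleles sorted numerically within locus, labels lexicographically
  rows <- do.call(rbind, lapply(loci, function(loc) {
    al <- unique(long$allele[long$locus == loc])
    num <- suppressWarnings(as.numeric(al))
    al <- if (anyNA(num)) sort(al) else al[order(num)]
    data.frame(locus = loc, allele = al)
  }))
  mkey <- paste(rows$locus, rows$allele, sep = ":")
  mat <- matrix(0L, nrow = nrow(rows), ncol = length(accs),
                dimnames = list(mkey, accs))
  mat[cbind(match(paste(long$locus, long$allele, sep = ":"), mkey),
            match(long$accession, accs))] <- 1L

  missing <- matrix(FALSE, nrow = length(loci), ncol = length(accs),
                    dimnames = list(loci, accs))
  if (!is.null(genotypes)) {
    m <- missingLoci(genotypes)
    keep <- m$locus %in% loci
    if (any(keep))
      missing[cbind(match(m$locus[keep], loci), match(m$accession[keep], accs))] <- TRUE
  }
  meta <- if (!is.null(genotypes)) accessionInfo(genotypes) else
    accessionInfo(sgenotypes)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = mat),
    rowData = S4Vectors::DataFrame(rows),
    colData = S4Vectors::DataFrame(meta[match(accs, meta$id), , drop = FALSE],
                                   row.names = accs),
    metadata = list(missing = missing))
}

#' Dice similarity between two presence/absence profiles
#'
#' \eqn{D = 2 a / (2a + b + c)} where `a` counts shared presences and `b`,
#' `c` the presences private to each profile. Equivalently
#' \eqn{2|A \cap B| / (|A| + |B|)} on the allele sets.
#'
#' @param a,b binary vectors of equal length
#' @return similarity in `[0, 1]`
#' @export
diceCoefficient <- function(a, b) {
  stopifnot(length(a) == length(b))
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) stop("Dice undefined: both profiles empty")
  2 * sum(a & b) / (sa + sb)
}

#' Pairwise Dice similarity matrix
#'
#' Marker rows belonging to loci missing (failed amplification) in either
#' accession of a pair are excluded pairwise before computing the
#' coefficient, so missingness never masquerades as allele absence.
#'
#' @param se the [SummarizedExperiment::SummarizedExperiment] from
#'   [encodeBinary()]
#' @return symmetric accession-x-accession matrix with unit diagonal
#' @export
diceSimilarity <- function(se) {
  .diceSim(SummarizedExperiment::assay(se, "presence"),
           as.character(SummarizedExperiment::rowData(se)$locus),
           S4Vectors::metadata(se)$missing)
}

.diceSim <- function(mat, loci, miss, emptyPair = c("error", "one")) {
  emptyPair <- match.arg(emptyPair)
  n <- ncol(mat)
  accs <- colnames(mat)
  anyMissing <- !is.null(miss) && any(miss)
  if (!anyMissing) {
    shared <- crossprod(mat)
    ones <- diag(shared)
    denom <- outer(ones, ones, `+`)
    if (any(denom == 0)) {
      if (emptyPair == "error") stop("Dice undefined: empty profile pair")
      denom[denom == 0] <- 1  # both empty: identical, resolved below
    }
    sim <- 2 * shared / denom
    sim[outer(ones == 0, ones == 0, `&`)] <- 1
    diag(sim) <- 1
    dimnames(sim) <- list(accs, accs)
    return(sim)
  }
  sim <- diag(1, n); dimnames(sim) <- list(accs, accs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    keep <- !(loci %in% rownames(miss)[miss[, i] | miss[, j]])
    a <- mat[keep, i]; b <- mat[keep, j]
    sim[i, j] <- sim[j, i] <- if (sum(a) + sum(b) == 0) {
      if (emptyPair == "error") stop("Dice undefined: empty profile pair") else 1
    } else diceCoefficient(a, b)
  }
  sim
}

#' Dice distance matrix (1 - similarity)
#' @inheritParams diceSimilarity
#' @return a `dist` object
#' @export
diceDistance <- function(se) stats::as.dist(1 - diceSimilarity(se))

#' UPGMA clustering with deterministic tie-breaking
#'
#' Agglomerative clustering with unweighted group-average linkage: at each
#' step the pair of clusters at minimal distance is merged and distances to
#' the merged cluster are the size-weighted average of the members'
#' distances. Equal-distance ties are broken by the lexicographically
#' smallest pair of cluster representatives (each cluster represented by its
#' smallest accession id), which makes the output independent of input
#' order. Heights are the merge distances and are non-decreasing (the tree
#' is ultrametric; leaf-to-ancestor branch length is height/2, the
#' convention used when converting to `phylo`).
#'
#' @param d a symmetric distance matrix or `dist` object (e.g. 1 - Dice)
#' @return an object of class `hclust` (usable with [stats::cophenetic()],
#'   [ape::as.phylo()], `plot()`, ...)
#' @export
upgma <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n < 2) stop("need at least two accessions")

  active <- seq_len(n)            # current cluster slots
  node <- -seq_len(n)             # hclust merge codes
  size <- rep(1L, n)
  rep_ <- labels                  # lexicographic representative
  D <- dm
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    k <- length(active)
    best <- NULL; bestd <- Inf; bestkey <- NULL
    for (ii in seq_len(k - 1)) for (jj in (ii + 1):k) {
      i <- active[ii]; j <- active[jj]
      dij <- D[i, j]
      key <- sort(c(rep_[i], rep_[j]))
      if (dij < bestd - 1e-12 ||
          (abs(dij - bestd) <= 1e-12 &&
           (is.null(bestkey) || key[1] < bestkey[1] ||
            (key[1] == bestkey[1] && key[2] < bestkey[2])))) {
        bestd <- dij; best <- c(i, j); bestkey <- key
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(node[i], node[j]))
    height[step] <- bestd
    # group-average update into slot i
    for (m in setdiff(active, c(i, j)))
      D[i, m] <- D[m, i] <- (size[i] * D[i, m] + size[j] * D[j, m]) /
        (size[i] + size[j])
    size[i] <- size[i] + size[j]
    rep_[i] <- min(rep_[i], rep_[j])
    node[i] <- step
    active <- setdiff(active, j)
  }
  out <- list(merge = merge, height = height, order = .hclustOrder(merge, n),
              labels = labels, method = "average",
              call = match.call(), dist.method = "user")
  class(out) <- "hclust"
  out
}

.hclustOrder <- function(merge, n) {
  walk <- function(k) {
    if (k < 0) return(-k)
    c(walk(merge[k, 1]), walk(merge[k, 2]))
  }
  walk(n - 1L)
}

# leaf-label sets under each internal node, as sorted key strings
.cladeKeys <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  for (k in seq_len(n - 1)) {
    kids <- tree$merge[k, ]
    sets[[k]] <- sort(c(
      if (kids[1] < 0) tree$labels[-kids[1]] else sets[[kids[1]]],
      if (kids[2] < 0) tree$labels[-kids[2]] else sets[[kids[2]]]))
  }
  vapply(sets, paste, character(1), collapse = "\r")
}

#' Bootstrap supports for UPGMA clades
#'
#' Resamples marker columns with replacement (`unit = "allele"`; the
#' conventional unit for binary multilocus fingerprints) or whole loci
#' (`unit = "locus"`), rebuilds the Dice + UPGMA tree, and reports for each
#' internal node of `tree` the percentage of replicates whose tree contains
#' the same leaf bipartition.
#'
#' @param se the encoded matrix from [encodeBinary()]
#' @param tree the `hclust` tree built from `se` (see [upgma()])
#' @param nReplicates number of bootstrap replicates (published practice for
#'   this kind of panel is 2000)
#' @param seed integer seed; required for reproducibility
#' @param unit resampling unit, `"allele"` (marker columns) or `"locus"`
#' @return numeric vector of supports in `[0, 100]`, one per merge
#'   (internal node) of `tree`, in `tree$merge` order; the root is always
#'   100 by construction
#' @export
bootstrapSupports <- function(se, tree, nReplicates = 2000, seed,
                              unit = c("allele", "locus")) {
  if (nReplicates < 1) stop("nReplicates must be >= 1")
  unit <- match.arg(unit)
  set.seed(seed)
  mat <- SummarizedExperiment::assay(se, "presence")
  loci <- as.character(SummarizedExperiment::rowData(se)$locus)
  miss <- S4Vectors::metadata(se)$missing
  refKeys <- .cladeKeys(tree)
  hits <- numeric(length(refKeys))
  uloci <- unique(loci)
  for (b in seq_len(nReplicates)) {
    idx <- if (unit == "allele") {
      sample.int(nrow(mat), nrow(mat), replace = TRUE)
    } else {
      picked <- sample(uloci, length(uloci), replace = TRUE)
      unlist(lapply(picked, function(l) which(loci == l)), use.names = FALSE)
    }
    btree <- upgma(1 - .diceSim(mat[idx, , drop = FALSE], loci[idx], miss,
                                emptyPair = "one"))
    hits <- hits + (refKeys %in% .cladeKeys(btree))
  }
  100 * hits / nReplicates
}

#' Cophenetic correlation with permutation significance
#'
#' The cophenetic correlation is the Pearson correlation between the input
#' pairwise distances and the ultrametric distances implied by the
#' dendrogram; it measures how faithfully the tree summarizes the distance
#' matrix. Significance is assessed by a one-sided (greater) permutation
#' test: leaf labels of the dendrogram are permuted `nPermutations` times
#' and the correlation recomputed, with
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) / (n + 1)}.
#'
#' @param tree an `hclust` tree over the same accessions as `d`
#' @param d distance matrix or `dist` used to build the tree
#' @param nPermutations permutation count for the null distribution
#' @param seed integer seed
#' @return list with elements `r` (`NA` if the input distances are
#'   constant) and `p`
#' @export
copheneticCorrelation <- function(tree, d, nPermutations = 999, seed = 1) {
  dm <- as.matrix(d)
  if (nrow(dm) < 3) stop("need at least 3 accessions")
  dm <- dm[tree$labels, tree$labels]
  coph <- as.matrix(stats::cophenetic(tree))[tree$labels, tree$labels]
  lt <- lower.tri(dm)
  x <- dm[lt]
  if (stats::sd(x) == 0 || stats::sd(coph[lt]) == 0)
    return(list(r = NA_real_, p = NA_real_))
  robs <- stats::cor(x, coph[lt])
  set.seed(seed)
  n <- nrow(dm)
  ge <- 0L
  for (b in seq_len(nPermutations)) {
    perm <- sample.int(n)
    rp <- stats::cor(x, coph[perm, perm][lt])
    if (rp >= robs - 1e-12) ge <- ge + 1L
  }
  list(r = robs, p = (1 + ge) / (nPermutations + 1))
}

#' Principal component analysis of the presence/absence matrix
#'
#' Column-centers the accessions-x-markers binary matrix and
#' eigendecomposes its covariance (correlation with `scale = TRUE`, in
#' which case constant markers are dropped first). Axis signs follow the
#' convention that the largest-magnitude loading on each axis is positive.
#'
#' @param se the encoded matrix from [encodeBinary()]
#' @param scale use the correlation matrix instead of the covariance
#' @return list with `scores` (accessions x axes), `varianceFraction`
#'   (sums to 1 over all axes) and `loadings`
#' @export
pcaBinary <- function(se, scale = FALSE) {
  X <- t(SummarizedExperiment::assay(se, "presence"))
  if (nrow(X) < 3 || ncol(X) < 2) stop("need >= 3 accessions and >= 2 markers")
  v <- apply(X, 2, stats::var)
  if (all(v == 0)) stop("matrix has no variance")
  if (scale) X <- X[, v > 0, drop = FALSE]
  fit <- stats::prcomp(X, center = TRUE, scale. = scale)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(k) {
    l <- fit$rotation[, k]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  list(scores = scores,
       varianceFraction = fit$sdev^2 / sum(fit$sdev^2),
       loadings = loadings)
}

#' Export a dendrogram (with optional supports) as Newick
#'
#' Branch lengths are ultrametric (node height = merge distance / 2);
#' bootstrap supports, if given, become internal node labels.
#'
#' @param tree `hclust` from [upgma()]
#' @param supports optional vector from [bootstrapSupports()]
#' @param path optional file; when `NULL` the Newick string is returned
#' @param digits support rounding for labels
#' @return the Newick string, invisibly when written to file
#' @export
dendrogramNewick <- function(tree, supports = NULL, path = NULL, digits = 0) {
  phy <- ape::as.phylo(tree)
  if (!is.null(supports)) {
    # ape node numbering: as.phylo.hclust maps merge rows to internal nodes
    keys <- .cladeKeys(tree)
    phyKeys <- vapply((length(tree$labels) + 1):(length(tree$labels) + phy$Nnode),
      function(nd) paste(sort(ape::extract.clade(phy, nd)$tip.label),
                         collapse = "\r"), character(1))
    phy$node.label <- as.character(roundHalfUp(supports[match(phyKeys, keys)],
                                               digits))
  }
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
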