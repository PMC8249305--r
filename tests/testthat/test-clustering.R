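test_that("binary encoding produces one marker per observed (locus, allele)", {
  pg <- makePG(list(A = list(L = c(100, 104)), B = list(L = 104)))
  se <- encodeBinary(pg)
  mat <- SummarizedExperiment::assay(se, "presence")
  expect_equal(rownames(mat), c("L:100", "L:104"))
  expect_equal(unname(mat[, "A"]), c(1L, 1L))
  expect_equal(unname(mat[, "B"]), c(0L, 1L))
  expect_true(all(rowSums(mat) >= 1))
})

test_that("merging the S-locus appends 23 marker rows carrying 68 presences", {
  sim <- simulateAccessions(simulationConfig(nTetra = 13, nHexa = 4,
                                             nHybrid = 0, clonePairs = 0), 5)
  pg <- sim$genotypes
  sg <- loadFixture("table1_sgenotypes")
  # rename simulated accessions onto the panel ids so the two marry up
  ids <- accessionIds(sg)
  names(pg@calls) <- ids
  pg@accessions <- accessionInfo(sg)
  plain <- encodeBinary(pg)
  merged <- encodeBinary(pg, sg)
  expect_equal(nrow(merged), nrow(plain) + 23L)
  sOnly <- SummarizedExperiment::assay(merged)[
    SummarizedExperiment::rowData(merged)$locus == "S", ]
  expect_equal(sum(sOnly), 68L)
  # no S input leaves the matrix unchanged
  expect_equal(SummarizedExperiment::assay(encodeBinary(pg, NULL)),
               SummarizedExperiment::assay(plain))
})

test_that("Dice follows the set formula and its boundary identities", {
  expect_equal(diceCoefficient(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(diceCoefficient(c(1, 0, 0), c(0, 1, 1)), 0)
  # {a,b,c} vs {b,c,d}: 2*2/(3+3)
  expect_equal(diceCoefficient(c(1, 1, 1, 0), c(0, 1, 1, 1)), 2 / 3)
  expect_error(diceCoefficient(c(0, 0), c(0, 0)), "undefined")

  # encoding + matrix route equals the set formula directly
  pg <- makePG(list(A = list(L = c(1, 2, 3)), B = list(L = c(2, 3, 4))))
  sim <- diceSimilarity(encodeBinary(pg))
  expect_equal(sim["A", "B"], 2 / 3)
  expect_equal(diag(sim), c(A = 1, B = 1))
  expect_equal(sim, t(sim))
})

test_that("pairwise deletion keeps failed loci out of the coefficient", {
  pg <- makePG(list(A = list(L1 = c(1, 2), L2 = c(5)),
                    B = list(L1 = c(1, 2)),
                    C = list(L1 = c(9), L2 = c(5))))
  pg@missing <- data.frame(accession = "B", locus = "L2")
  sim <- diceSimilarity(encodeBinary(pg))
  expect_equal(sim["A", "B"], 1)       # L2 masked for the pair
  expect_equal(sim["A", "C"], 2 * 1 / (3 + 2))  # all markers in play
})

test_that("UPGMA reproduces hand-worked merges and deterministic tie-breaking", {
  d2 <- matrix(c(0, .4, .4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma(d2)
  expect_equal(t2$height, .4)

  d3 <- matrix(c(0, .2, .6,
                 .2, 0, .4,
                 .6, .4, 0), 3, byrow = TRUE,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma(d3)
  expect_equal(t3$height, c(.2, .5))   # group-average: (0.6+0.4)/2
  expect_equal(t3$merge[1, ], c(-2L, -1L))

  # clone pair merges first at height 0
  d0 <- as.matrix(dist(c(A = 0, B = 5, B2 = 5)))
  expect_equal(upgma(d0)$height[1], 0)

  # tie: identical distances everywhere -> lexicographically smallest pair first
  dt <- matrix(.5, 3, 3, dimnames = list(c("C", "A", "B"), c("C", "A", "B")))
  diag(dt) <- 0
  tt <- upgma(dt)
  first <- sort(tt$labels[-tt$merge[1, ]])
  expect_equal(first, c("A", "B"))

  expect_error(upgma(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA matches hclust average linkage and is monotone on random matrices", {
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(4:8, 1)
    x <- matrix(rnorm(n * 3), n)
    rownames(x) <- paste0("G", seq_len(n))
    d <- dist(x)
    mine <- upgma(d)
    ref <- hclust(d, method = "average")
    expect_equal(sort(mine$height), sort(ref$height))
    expect_equal(as.matrix(cophenetic(mine))[rownames(x), rownames(x)],
                 as.matrix(cophenetic(ref))[rownames(x), rownames(x)])
    expect_false(is.unsorted(mine$height))
  }
})

test_that("bootstrap supports behave at the extremes and for planted structure", {
  pg <- makePG(list(A = list(L = c(1, 2)), A2 = list(L = c(1, 2)),
                    B = list(L = c(7, 8)), C = list(L = c(7, 9))))
  se <- encodeBinary(pg)
  tree <- upgma(1 - diceSimilarity(se))
  sup <- bootstrapSupports(se, tree, nReplicates = 50, seed = 2)
  keys <- polySSR:::.cladeKeys(tree)
  expect_equal(sup[keys == paste(c("A", "A2"), collapse = "\r")], 100)
  expect_equal(sup[length(sup)], 100)  # root bipartition always present

  one <- bootstrapSupports(se, tree, nReplicates = 1, seed = 3)
  expect_true(all(one %in% c(0, 100)))
  expect_error(bootstrapSupports(se, tree, nReplicates = 0, seed = 1),
               "nReplicates")
})

test_that("well-separated planted clusters get near-unanimous support", {
  # two groups drawing from disjoint allele pools at every locus
  set.seed(9)
  mk <- function(base, ids) {
    calls <- lapply(ids, function(i) {
      l <- lapply(1:6, function(l) sort(sample(base + seq(0, 18, 2), 3)))
      names(l) <- paste0("L", 1:6)
      l
    })
    names(calls) <- ids
    calls
  }
  pg <- makePG(c(mk(100, paste0("A", 1:4)), mk(300, paste0("B", 1:4))))
  se <- encodeBinary(pg)
  tree <- upgma(1 - diceSimilarity(se))
  sup <- bootstrapSupports(se, tree, nReplicates = 200, seed = 4)
  keys <- polySSR:::.cladeKeys(tree)
  planted <- paste(sort(paste0("A", 1:4)), collapse = "\r")
  expect_gte(sup[keys == planted], 95)
  # a second seed agrees closely on the planted clade
  sup2 <- bootstrapSupports(se, tree, nReplicates = 200, seed = 104)
  expect_lt(abs(sup[keys == planted] - sup2[keys == planted]), 5)
})

test_that("cophenetic correlation is exact for ultrametric input and matches an exhaustive permutation null", {
  # ultrametric distances: UPGMA reproduces them, r = 1
  d <- matrix(c(0, .2, .8, .8,
                .2, 0, .8, .8,
                .8, .8, 0, .4,
                .8, .8, .4, 0), 4, byrow = TRUE,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tree <- upgma(d)
  cc <- copheneticCorrelation(tree, d, nPermutations = 99, seed = 1)
  expect_equal(cc$r, 1)

  # constant distances: undefined, reported as NA
  dc <- matrix(.5, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(dc) <- 0
  expect_true(is.na(copheneticCorrelation(upgma(dc), dc, 99, 1)$r))

  # sampled permutation p approximates full enumeration over 4! relabelings
  set.seed(5)
  x <- matrix(rnorm(8), 4, dimnames = list(LETTERS[1:4], NULL))
  dr <- as.matrix(dist(x))
  tr <- upgma(dr)
  coph <- as.matrix(cophenetic(tr))[LETTERS[1:4], LETTERS[1:4]]
  lt <- lower.tri(dr)
  robs <- cor(dr[lt], coph[lt])
  perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
  rs <- apply(perms, 1, function(p) cor(dr[lt], coph[p, p][lt]))
  exact <- mean(rs >= robs - 1e-12)
  got <- copheneticCorrelation(tr, dr, nPermutations = 999, seed = 6)
  expect_equal(got$r, robs)
  expect_lt(abs(got$p - exact), 0.06)
})

test_that("PCA of the binary matrix has coherent variance, symmetry and geometry", {
  sim <- simulateAccessions(simulationConfig(nTetra = 6, nHexa = 2,
                                             nHybrid = 0, clonePairs = 1), 21)
  se <- encodeBinary(sim$genotypes)
  fit <- pcaBinary(se)
  expect_equal(sum(fit$varianceFraction), 1)
  expect_true(all(diff(fit$varianceFraction) <= 1e-12))

  # duplicated accessions (the clone pair) land on identical scores
  pair <- sim$truth$clones[[1]]
  expect_equal(fit$scores[pair[1], ], fit$scores[pair[2], ])

  # all axes retained reproduce centered Euclidean distances
  X <- t(SummarizedExperiment::assay(se, "presence"))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(fit$scores)), as.matrix(dist(Xc)),
               tolerance = 1e-8)

  # sign convention: dominant loading on each axis is positive
  lead <- apply(fit$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(lead >= 0))
})

test_that("axis 1 separates two planted clusters without overlap", {
  calls <- c(
    lapply(setNames(1:4, paste0("A", 1:4)), function(i)
      list(L1 = c(100, 102), L2 = c(100 + 2 * i))),
    lapply(setNames(1:4, paste0("B", 1:4)), function(i)
      list(L1 = c(300, 302), L2 = c(300 + 2 * i))))
  fit <- pcaBinary(encodeBinary(makePG(calls)))
  a <- fit$scores[paste0("A", 1:4), 1]
  b <- fit$scores[paste0("B", 1:4), 1]
  expect_true(max(a) < min(b) || max(b) < min(a))
})

test_that("Newick export carries supports as internal node labels", {
  pg <- makePG(list(A = list(L = c(1, 2)), B = list(L = c(1, 2)),
                    C = list(L = c(8, 9))))
  se <- encodeBinary(pg)
  tree <- upgma(1 - diceSimilarity(se))
  sup <- bootstrapSupports(se, tree, nReplicates = 20, seed = 1)
  nwk <- dendrogramNewick(tree, sup)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("A", "B", "C"))
  expect_true("100" %in% phy$node.label)
  # ultrametric branch lengths: root-to-tip depth = max height / 2
  depths <- ape::node.depth.edgelength(phy)
  expect_equal(max(depths[1:3]), max(tree$height) / 2)
})
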