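test_that("fragment binning splits on gaps and pools identical lengths", {
  obs <- data.frame(accession = c("A", "B", "C"),
                    length_bp = c(713, 715, 815))
  res <- binFragments(obs, tolerance = 5)
  expect_equal(nrow(res$catalog), 2L)
  expect_equal(res$catalog$count, c(2L, 1L))

  same <- data.frame(accession = c("A", "B"), length_bp = c(900, 900))
  res2 <- binFragments(same, tolerance = 5)
  expect_equal(nrow(res2$catalog), 1L)
  expect_equal(res2$catalog$count, 2L)
  expect_error(binFragments(obs, tolerance = 0), "tolerance")
})

test_that("labels run by descending carrier count then ascending size", {
  obs <- data.frame(accession = c("A", "B", "C", "A", "B", "C"),
                    length_bp = c(500, 500, 500, 800, 800, 1200))
  res <- binFragments(obs, tolerance = 5)
  expect_equal(res$catalog$label, c("S_A", "S_B", "S_C"))
  expect_equal(res$catalog$size_bp, c(500L, 800L, 1200L))
  expect_equal(res$catalog$count, c(3L, 2L, 1L))
})

test_that("the default tolerance keeps the 23 published fragment sizes distinct when sequence-confirmed", {
  t3 <- loadFixture("table3_salleles")
  # one observation per (allele, carrier): sizes repeated `total` times
  obs <- do.call(rbind, lapply(seq_len(nrow(t3)), function(i)
    data.frame(accession = paste0("acc", i, "_", seq_len(t3$total_printed[i])),
               length_bp = t3$size_bp[i],
               sequence_label = if (t3$sequenced[i]) t3$allele[i] else
                 NA_character_)))
  res <- binFragments(obs)
  expect_equal(nrow(res$catalog), 23L)
  # sequence-confirmed identities are preserved
  expect_true(all(c("S_3-1", "S_D", "S_12") %in% res$catalog$label))
  r31 <- res$catalog[res$catalog$label == "S_3-1", ]
  expect_equal(r31$size_bp, 713L)

  # without sequence confirmation the 713/716 pair collapses; an accession
  # carrying both (single band on a gel) triggers the ambiguity warning
  blind <- rbind(obs[, c("accession", "length_bp")],
                 data.frame(accession = "T1x", length_bp = c(713, 716)))
  expect_warning(res2 <- binFragments(blind), "sequence confirmation")
  expect_lt(nrow(res2$catalog), 23L)
})

test_that("binning is idempotent and invariant to input order", {
  set.seed(42)
  obs <- data.frame(accession = sample(LETTERS[1:6], 30, replace = TRUE),
                    length_bp = sample(c(500, 650, 820, 1500, 2600), 30,
                                       replace = TRUE) +
                      sample(-3:3, 30, replace = TRUE))
  # random multisets can put several fragments of one accession in a bin,
  # which legitimately warns; that is not what this test is about
  res <- suppressWarnings(binFragments(obs))
  # re-binning the catalog representatives returns the same catalog sizes
  rebin <- binFragments(data.frame(accession = res$catalog$label,
                                   length_bp = res$catalog$size_bp))
  expect_equal(sort(rebin$catalog$size_bp), sort(res$catalog$size_bp))

  shuf <- obs[sample(nrow(obs)), ]
  res3 <- suppressWarnings(binFragments(shuf))
  expect_equal(res3$catalog, res$catalog)
})

test_that("first-intron observations are stored but not used for genotype calls", {
  obs <- data.frame(accession = "A",
                    length_bp = c(300, 700),
                    region = c("first", "second"))
  res <- binFragments(obs, tolerance = 10)
  expect_equal(nrow(res$catalog), 1L)
  expect_equal(res$catalog$size_bp, 700L)
})

test_that("occurrence tables recount the panel text statistics", {
  sg <- loadFixture("table1_sgenotypes")
  occ <- occurrenceTable(sg)
  expect_equal(occ$total[occ$allele == "S_C"], 9L)
  expect_equal(occ$total[occ$allele == "S_3-1"], 5L)
  expect_equal(occ$total[occ$allele == "S_12"], 6L)
  expect_equal(occ$total[occ$allele == "S_B"], 6L)
  expect_equal(sum(occ$total), 68L)
  expect_setequal(occ$allele[occ$total == 1L],
                  c("S_E", "S_G", "S_N", "S_O", "S_Q", "S_T"))
  expect_equal(occ$freq, occ$total / 68)
  # species columns present and consistent
  expect_equal(sum(occ$P_spinosa) + sum(occ$P_insititia) + sum(occ$hybrid), 68L)

  empty <- makeSG(stats::setNames(list(), character()))
  expect_equal(nrow(occurrenceTable(empty)), 0L)
})

test_that("shared alleles are plain set intersections", {
  sg <- loadFixture("table1_sgenotypes")
  expect_equal(sharedAlleles(sAlleles(sg)$L5, sAlleles(sg)$L1),
               c("S_B", "S_M"))
  expect_equal(sharedAlleles(c("S1"), c("S2")), character())
  g <- c("S1", "S2", "S3")
  expect_equal(sharedAlleles(g, g), g)
})

test_that("premature stop codons are located in frame", {
  # ATG AAA TAA GGG TGA: stop at codon 3 of 5
  res <- scanPrematureStop("ATGAAATAAGGGTGA")
  expect_false(res$functional)
  expect_equal(res$stopCodon, 3L)

  # natural terminal stop only
  ok <- scanPrematureStop("ATGAAAGGGTGA")
  expect_true(ok$functional)
  expect_true(is.na(ok$stopCodon))

  expect_error(scanPrematureStop("ATGAA"), "divisible")
  expect_error(scanPrematureStop("ATGAAZ"), "IUPAC")
})

test_that("an AAA->TAA change in the last hypervariable codon kills function and mating honors it", {
  # toy S-RNase-like CDS; the RHV block ends at codon 8
  base <- c("ATG", "TTT", "GGG", "CAT", "CGT", "AAA", "GCC", "AAA",
            "CAC", "GGA", "TAA")
  functionalCds <- paste(base, collapse = "")
  mutant <- base; mutant[8] <- "TAA"   # AAA -> TAA at the last RHV codon
  truncatedCds <- paste(mutant, collapse = "")

  expect_true(scanPrematureStop(functionalCds)$functional)
  hit <- scanPrematureStop(truncatedCds)
  expect_false(hit$functional)
  expect_equal(hit$stopCodon, 8L)

  # the flag feeds the mating rule: a matching non-functional allele
  # no longer triggers rejection
  fun <- c(S_J = hit$functional, S_5 = TRUE, S_6 = TRUE, S_7 = TRUE)
  expect_true(pollenAccepted(c("S_J", "S_5"),
                             pistil = c("S_J", "S_6", "S_7"),
                             functional = fun))
})

test_that("p-distance uses complete deletion and the Poisson correction behaves analytically", {
  aln <- Biostrings::AAStringSet(c(s1 = "ACDE", s2 = "ACDF"))
  expect_equal(pDistance(aln, "s1", "s2"), 0.25)
  expect_equal(pDistance(aln, "s1", "s1"), 0)

  # gap column removed in every pair (complete deletion)
  aln2 <- Biostrings::AAStringSet(c(a = "AC-E", b = "ACDE", c = "GCDE"))
  expect_equal(pDistance(aln2, "a", "b"), 0)      # only 3 columns compared
  expect_equal(pDistance(aln2, "a", "c"), 1 / 3)
  expect_equal(pDistance(aln2, "b", "c"), pDistance(aln2, "c", "b"))
  expect_error(pDistance(Biostrings::AAStringSet(c(a = "--", b = "A-")),
                         "a", "b"), "complete deletion")

  expect_equal(poissonCorrection(0), 0)
  expect_equal(poissonCorrection(0.5), 0.6931, tolerance = 1e-4)
  expect_equal(poissonCorrection(0.25), 0.2877, tolerance = 1e-4)
  p <- seq(0, 0.9, by = 0.05)
  d <- poissonCorrection(p)
  expect_true(all(d >= p))
  expect_true(all(diff(d) > 0))            # strictly increasing
  expect_true(all(diff(diff(d)) > 0))      # convex
  expect_error(poissonCorrection(1), "saturates")

  dm <- divergenceMatrix(aln2)
  expect_equal(dm, t(dm))
  expect_equal(dm["a", "c"], round(-log(1 - 1 / 3), 3))
})
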