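#' Run one pipeline step end-to-end, writing artifacts to disk
#'
#' Programmatic entry point behind the command-line wrapper shipped in
#' `inst/scripts/polySSR.R`. Every step is deterministic given `seed`; a
#' `run.log` records the package version, parameters and input files.
#'
#' Steps:
#' \describe{
#'   \item{`summarize`}{per-locus diversity table (+ S-locus row when
#'     S-genotypes given) and clonal groups.}
#'   \item{`cluster`}{Dice + UPGMA on the (optionally merged) binary
#'     matrix; Newick tree with bootstrap supports, similarity CSV,
#'     cophenetic correlation.}
#'   \item{`pca`}{scores, variance fractions and loadings CSVs.}
#'   \item{`slocus`}{fragment binning into an allele catalog and
#'     occurrence table.}
#'   \item{`mating`}{panel cross-compatibility matrix and
#'     incompatibility groups.}
#'   \item{`simulate`}{seeded synthetic dataset + truth JSON.}
#' }
#'
#' @param step one of `"summarize"`, `"cluster"`, `"pca"`, `"slocus"`,
#'   `"mating"`, `"simulate"`
#' @param genotypes path to a long-format genotype CSV, or a
#'   [PolyGenotypes-class] object
#' @param sgenotypes optional [SGenotypes-class] object, or the string
#'   `"table1"` to use the packaged panel
#' @param fragments `data.frame` of fragment observations (`slocus` step)
#' @param outDir output directory
#' @param bootstrap bootstrap replicate count for `cluster` (0 disables
#'   supports)
#' @param permutations permutation count for the cophenetic test
#' @param tolerance binning tolerance in bp for `slocus`
#' @param seed integer seed for every stochastic step
#' @param config [simulationConfig()] for `simulate`
#' @param mergeSLocus include S-alleles as extra markers in
#'   `cluster`/`pca`
#' @return named character vector of files written, invisibly
#' @export
runPipeline <- function(step = c("summarize", "cluster", "pca", "slocus",
                                 "mating", "simulate"),
                        genotypes = NULL, sgenotypes = NULL, fragments = NULL,
                        outDir = ".", bootstrap = 2000, permutations = 999,
                        tolerance = NULL, seed = 1,
                        config = simulationConfig(), mergeSLocus = FALSE) {
  step <- match.arg(step)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(genotypes)) genotypes <- readGenotypeTable(genotypes)
  if (identical(sgenotypes, "table1")) sgenotypes <- loadFixture("table1_sgenotypes")
  files <- character()
  put <- function(name) { f <- file.path(outDir, name); files[[name]] <<- f; f }

  log <- c(sprintf("polySSR %s | step=%s | seed=%d",
                   as.character(utils::packageVersion("polySSR")), step, seed),
           sprintf("bootstrap=%d permutations=%d mergeSLocus=%s",
                   bootstrap, permutations, mergeSLocus))

  if (step == "summarize") {
    stopifnot(!is.null(genotypes) || !is.null(sgenotypes))
    tabs <- list()
    if (!is.null(genotypes)) tabs$ssr <- diversityTable(genotypes)
    if (!is.null(sgenotypes)) {
      row <- locusSummary(sgenotypes, "S")
      row$pic <- roundHalfUp(row$pic, 2)
      row$heterozygosity <- roundHalfUp(row$heterozygosity, 2)
      tabs$s <- row
    }
    out <- do.call(rbind, tabs)
    utils::write.csv(out, put("locus_summary.csv"), row.names = FALSE)
    groups <- findClonalGroups(if (!is.null(genotypes)) genotypes else sgenotypes)
    writeLines(vapply(groups, paste, character(1), collapse = ","),
               put("clonal_groups.txt"))
  } else if (step %in% c("cluster", "pca")) {
    stopifnot(!is.null(genotypes) || !is.null(sgenotypes))
    se <- encodeBinary(genotypes,
                       if (mergeSLocus || is.null(genotypes)) sgenotypes)
    if (step == "cluster") {
      sim <- diceSimilarity(se)
      utils::write.csv(sim, put("dice_similarity.csv"))
      tree <- upgma(1 - sim)
      sup <- if (bootstrap > 0)
        bootstrapSupports(se, tree, nReplicates = bootstrap, seed = seed)
      dendrogramNewick(tree, sup, put("upgma.nwk"))
      cc <- copheneticCorrelation(tree, 1 - sim, permutations, seed)
      writeLines(sprintf("cophenetic_r\t%.6f\np_value\t%.6g", cc$r, cc$p),
                 put("cophenetic.txt"))
    } else {
      fit <- pcaBinary(se)
      utils::write.csv(fit$scores, put("pca_scores.csv"))
      utils::write.csv(data.frame(axis = seq_along(fit$varianceFraction),
                                  variance_fraction = fit$varianceFraction),
                       put("pca_variance.csv"), row.names = FALSE)
      utils::write.csv(fit$loadings, put("pca_loadings.csv"))
    }
  } else if (step == "slocus") {
    stopifnot(!is.null(fragments))
    res <- binFragments(fragments, tolerance = tolerance)
    utils::write.csv(res$catalog, put("allele_catalog.csv"), row.names = FALSE)
    utils::write.csv(occurrenceTable(res$genotypes,
                                     catalogOrder = res$catalog$label),
                     put("occurrence_table.csv"), row.names = FALSE)
  } else if (step == "mating") {
    stopifnot(!is.null(sgenotypes))
    cm <- compatibilityMatrix(sgenotypes)
    utils::write.csv(cm, put("compatibility_matrix.csv"))
    grp <- incompatibilityGroups(sgenotypes)
    writeLines(vapply(grp, paste, character(1), collapse = ","),
               put("incompatibility_groups.txt"))
  } else if (step == "simulate") {
    sim <- simulateAccessions(config, seed)
    files <- c(files, writeSimulation(sim, outDir))
  }

  writeLines(c(log, paste("wrote:", basename(unlist(files)))),
             file.path(outDir, "run.log"))
  invisible(unlist(files))
}
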