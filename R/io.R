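#' Read a long-format polyploid genotype table
#'
#' The canonical input is long format: one row per observed allele, with
#' columns `accession`, `locus` and `allele_bp`. A wide dialect in which
#' `allele_bp` holds a semicolon-joined list (e.g. `"100;104"`) is accepted
#' on read but never written. Rows with an empty `allele_bp` field mark an
#' attempted locus that failed to amplify; these are recorded as missing,
#' which is distinct from a locus that simply was not attempted.
#'
#' Accession metadata (species, ploidy, origin) can be supplied either as
#' extra columns in the table or through a JSON manifest with an
#' `accessions` array. Without either, accessions default to unknown species
#' and the smallest even ploidy consistent with the data.
#'
#' @param path path to a CSV or TSV file (delimiter inferred from extension)
#' @param manifest optional path to a JSON manifest carrying accession
#'   metadata: `{"accessions": [{"id": ..., "species": ..., "ploidy": ...,
#'   "origin": ...}, ...]}`
#' @return a [PolyGenotypes-class] object
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("accession,locus,allele_bp",
#'              "A,L1,100", "A,L1,104", "B,L1,104"), tf)
#' pg <- readGenotypeTable(tf)
#' genotypeCalls(pg)$A$L1
#' @export
readGenotypeTable <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, quote = "\"")
  need <- c("accession", "locus", "allele_bp")
  if (!all(need %in% names(tab)))
    stop("genotype table needs columns ", paste(need, collapse = ", "))
  tab$accession <- trimws(tab$accession)
  tab$locus <- trimws(tab$locus)
  tab$allele_bp <- trimws(tab$allele_bp)

  accs <- unique(tab$accession)
  calls <- stats::setNames(vector("list", length(accs)), accs)
  miss <- list()
  for (r in seq_len(nrow(tab))) {
    a <- tab$accession[r]; loc <- tab$locus[r]; field <- tab$allele_bp[r]
    if (field == "" || toupper(field) == "NA") {
      miss[[length(miss) + 1L]] <- data.frame(accession = a, locus = loc)
      next
    }
    parts <- trimws(strsplit(field, ";", fixed = TRUE)[[1]])
    parts <- parts[parts != ""]
    num <- suppressWarnings(as.numeric(parts))
    if (any(is.na(num)) || any(num != round(num)))
      stop(sprintf("row %d: malformed allele size '%s' (accession %s, locus %s)",
                   r, field, a, loc))
    calls[[a]][[loc]] <- sort(unique(c(calls[[a]][[loc]], as.integer(num))))
  }
  missing <- if (length(miss)) unique(do.call(rbind, miss)) else
    data.frame(accession = character(), locus = character())
  # scored-and-missing is contradictory: a row group wins over an empty row
  if (nrow(missing)) {
    scored <- vapply(seq_len(nrow(missing)), function(i)
      !is.null(calls[[missing$accession[i]]][[missing$locus[i]]]), logical(1))
    missing <- missing[!scored, , drop = FALSE]
  }

  meta <- .accessionMeta(tab, accs, manifest, calls)
  PolyGenotypes(calls = calls, accessions = meta, missing = missing)
}

.accessionMeta <- function(tab, accs, manifest, calls) {
  meta <- data.frame(id = accs, species = "unknown", ploidy = NA_integer_,
                     origin = "", stringsAsFactors = FALSE)
  for (col in c("species", "ploidy", "origin")) {
    if (col %in% names(tab)) {
      first <- tab[[col]][match(accs, tab$accession)]
      meta[[col]] <- if (col == "ploidy") as.integer(first) else first
    }
  }
  if (!is.null(manifest)) {
    man <- jsonlite::fromJSON(manifest)$accessions
    idx <- match(meta$id, man$id)
    for (col in intersect(c("species", "ploidy", "origin"), names(man))) {
      got <- man[[col]][idx]
      meta[[col]] <- ifelse(is.na(idx), meta[[col]], got)
    }
    meta$ploidy <- as.integer(meta$ploidy)
  }
  if (anyNA(meta$ploidy)) {
    # smallest even ploidy covering the largest observed allele set
    maxset <- vapply(accs, function(a) {
      n <- vapply(calls[[a]], length, integer(1))
      if (length(n)) max(n) else 2L
    }, integer(1))
    guess <- pmax(2L, as.integer(2 * ceiling(maxset / 2)))
    meta$ploidy <- ifelse(is.na(meta$ploidy), guess, meta$ploidy)
  }
  meta
}

#' Write a genotype table in canonical long format
#'
#' One row per observed allele; loci recorded as missing are written as a
#' single row with an empty `allele_bp` field so that a round trip through
#' [readGenotypeTable()] reproduces the object exactly.
#'
#' @param object a [PolyGenotypes-class] object
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeGenotypeTable <- function(object, path) {
  rows <- list()
  for (a in accessionIds(object)) {
    cl <- object@calls[[a]]
    for (loc in names(cl))
      rows[[length(rows) + 1L]] <- data.frame(
        accession = a, locus = loc, allele_bp = as.character(cl[[loc]]))
  }
  m <- missingLoci(object)
  if (nrow(m))
    rows[[length(rows) + 1L]] <- data.frame(
      accession = m$accession, locus = m$locus, allele_bp = "")
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a packaged reference table
#'
#' Three small reference tables for the 17-accession Central European
#' polyploid plum panel ship with the package: the S-genotypes of the panel
#' (`table1_sgenotypes`), the published per-locus SSR summary statistics
#' (`table2_locus_stats`), and the S-RNase allele catalog with fragment
#' sizes and printed occurrence counts (`table3_salleles`).
#'
#' @param name one of `"table1_sgenotypes"`, `"table2_locus_stats"`,
#'   `"table3_salleles"`
#' @return for `table1_sgenotypes`, an [SGenotypes-class] object (S_J is
#'   flagged non-functional, reflecting its premature stop codon); for the
#'   others, a `data.frame`
#' @examples
#' sg <- loadFixture("table1_sgenotypes")
#' sAlleles(sg)$T1
#' @export
loadFixture <- function(name = c("table1_sgenotypes", "table2_locus_stats",
                                 "table3_salleles")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "polySSR",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (name == "table1_sgenotypes") {
    genotypes <- stats::setNames(
      lapply(strsplit(tab$s_alleles, ";", fixed = TRUE), trimws), tab$accession)
    labs <- sort(unique(unlist(genotypes)))
    functional <- stats::setNames(labs != "S_J", labs)
    acc <- data.frame(id = tab$accession, species = tab$species,
                      ploidy = as.integer(tab$ploidy), origin = tab$origin)
    sg <- SGenotypes(genotypes, functional, acc)
    attr(sg, "sequenced") <- stats::setNames(
      lapply(strsplit(tab$sequenced_alleles, ";", fixed = TRUE),
             function(x) x[nzchar(x)]), tab$accession)
    sg
  } else {
    tab
  }
}
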