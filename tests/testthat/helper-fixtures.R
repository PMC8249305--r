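# small in-code builders used across test files

makeAccessions <- function(ids, ploidy = 4L, species = "P_spinosa") {
  data.frame(id = ids,
             species = rep_len(species, length(ids)),
             ploidy = rep_len(as.integer(ploidy), length(ids)),
             origin = rep_len("test", length(ids)))
}

# calls: named list accession -> named list locus -> integer vector
makePG <- function(calls, ploidy = 4L, ...) {
  PolyGenotypes(calls, makeAccessions(names(calls), ploidy = ploidy), ...)
}

makeSG <- function(genotypes, functional = NULL, ploidy = NULL) {
  if (is.null(ploidy))
    ploidy <- vapply(genotypes, function(g)
      max(2L, as.integer(2 * ceiling(length(g) / 2))), integer(1))
  SGenotypes(genotypes, functional, makeAccessions(names(genotypes), ploidy))
}

# independent PIC oracle: literal double loop over the formula
picOracle <- function(p) {
  s <- 1 - sum(p^2)
  k <- length(p)
  if (k >= 2)
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      s <- s - 2 * p[i]^2 * p[j]^2
  s
}

# small deterministic genotype table on disk
writeTestCSV <- function(lines) {
  tf <- tempfile(fileext = ".csv")
  writeLines(lines, tf)
  tf
}
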