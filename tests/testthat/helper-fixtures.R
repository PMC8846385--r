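# Shared fixtures, built in code at test time.

# a small but fully structured cohort, cached per session
.fixtureEnv <- new.env(parent = emptyenv())
smallCohort <- function(seed = 5L) {
  key <- paste0("cohort", seed)
  if (is.null(.fixtureEnv[[key]]))
    .fixtureEnv[[key]] <- simulateM6ACohort(simulationConfig(
      nSamples = 90L, nGenes = 900L, nDegPerCluster = 20L, seed = seed))
  .fixtureEnv[[key]]
}

writeTsv <- function(df, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "table.tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeExprTsv <- function(m, geneCol = "gene",
                         dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "expr.tsv")
  df <- data.frame(g = rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- geneCol
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

writeGmtLines <- function(lines,
                          dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "sets.gmt")
  writeLines(lines, path)
  path
}

# six-subject survival fixture with hand-computable KM / log-rank
handSurvival <- function() {
  list(time = c(1, 2, 3, 4, 5, 6),
       event = c(1, 0, 1, 1, 0, 1),
       group = c("a", "a", "a", "b", "b", "b"))
}
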