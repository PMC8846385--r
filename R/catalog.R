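#' The 23 canonical m6A regulator genes
#'
#' Returns the built-in catalog of the 23 m6A RNA-methylation regulators
#' commonly profiled in tumour transcriptomes: 8 writers (the
#' methyltransferase complex), 2 erasers (demethylases) and 13 readers
#' (m6A-binding proteins). The alias map covers the alternate spellings that
#' circulate in the literature: `KIAA1429` for `VIRMA` and the frequent
#' `LRPPPRC` misspelling of `LRPPRC`.
#'
#' @return A [RegulatorCatalog-class] with 23 canonical entries.
#' @examples
#' cat23 <- defaultRegulatorCatalog()
#' length(regulatorSymbols(cat23))            # 23
#' regulatorSymbols(cat23, role = "eraser")   # FTO, ALKBH5
#' @export
defaultRegulatorCatalog <- function() {
  roles <- c(
    METTL3 = "writer", METTL14 = "writer", WTAP = "writer", VIRMA = "writer",
    RBM15 = "writer", RBM15B = "writer", ZC3H13 = "writer", CBLL1 = "writer",
    FTO = "eraser", ALKBH5 = "eraser",
    YTHDC1 = "reader", YTHDC2 = "reader", YTHDF1 = "reader",
    YTHDF2 = "reader", YTHDF3 = "reader", HNRNPA2B1 = "reader",
    HNRNPC = "reader", FMR1 = "reader", LRPPRC = "reader", RBMX = "reader",
    IGF2BP1 = "reader", IGF2BP2 = "reader", IGF2BP3 = "reader"
  )
  aliases <- c(KIAA1429 = "VIRMA", LRPPPRC = "LRPPRC")
  new("RegulatorCatalog", roles = roles, aliases = aliases)
}

#' Regulator symbols, optionally restricted to a role
#'
#' @param catalog a [RegulatorCatalog-class].
#' @param role optional, one of `"writer"`, `"eraser"`, `"reader"`.
#' @return character vector of canonical symbols.
#' @export
regulatorSymbols <- function(catalog, role = NULL) {
  stopifnot(is(catalog, "RegulatorCatalog"))
  syms <- names(catalog@roles)
  if (!is.null(role)) {
    role <- match.arg(role, c("writer", "eraser", "reader"))
    syms <- syms[catalog@roles == role]
  }
  syms
}

#' Role of each regulator
#'
#' @param catalog a [RegulatorCatalog-class].
#' @return named character vector symbol -> role.
#' @export
regulatorRoles <- function(catalog) {
  stopifnot(is(catalog, "RegulatorCatalog"))
  catalog@roles
}

#' Canonicalize gene symbols
#'
#' Uppercases, strips surrounding whitespace, and resolves catalog aliases
#' (e.g. `KIAA1429` to `VIRMA`). Symbols not in the alias map pass through
#' unchanged, so the function is safe on whole-transcriptome gene lists.
#'
#' @param symbols character vector of gene symbols.
#' @param catalog a [RegulatorCatalog-class] supplying the alias map;
#'   defaults to the built-in catalog.
#' @return character vector of the same length.
#' @examples
#' canonicalizeSymbols(c(" mettl3", "KIAA1429"))  # "METTL3" "VIRMA"
#' @export
canonicalizeSymbols <- function(symbols, catalog = defaultRegulatorCatalog()) {
  s <- toupper(trimws(as.character(symbols)))
  hit <- s %in% names(catalog@aliases)
  s[hit] <- unname(catalog@aliases[s[hit]])
  s
}

#' Look up one regulator
#'
#' @param catalog a [RegulatorCatalog-class].
#' @param symbol a single symbol (alias accepted).
#' @return list with elements `symbol` (canonical) and `role`, or an error
#'   when the symbol is not in the catalog.
#' @export
lookupRegulator <- function(catalog, symbol) {
  s <- canonicalizeSymbols(symbol, catalog)
  if (!s %in% names(catalog@roles))
    stop("symbol '", symbol, "' is not in the regulator catalog", call. = FALSE)
  list(symbol = s, role = unname(catalog@roles[s]))
}

#' @describeIn RegulatorCatalog-class compact printout
#' @param object a `RegulatorCatalog`
#' @export
setMethod("show", "RegulatorCatalog", function(object) {
  tab <- table(factor(object@roles, c("writer", "eraser", "reader")))
  cat("RegulatorCatalog with", length(object@roles), "genes (",
      paste(paste0(tab, " ", names(tab), "s"), collapse = ", "), ")\n")
  cat("aliases:", paste(names(object@aliases), "->", object@aliases,
                        collapse = ", "), "\n")
})

#' Packaged cohort accession manifest
#'
#' The analysis this package supports was designed around TCGA-BRCA plus six
#' public GEO breast-cancer series with complete overall-survival follow-up.
#' The manifest ships as a plain TSV under `inst/extdata` so that users
#' re-running the workflow on real data know exactly which accessions to
#' fetch; the package itself never downloads anything.
#'
#' @return data.frame with columns `accession`, `source`, `role`.
#' @examples
#' cohortManifest()
#' @export
cohortManifest <- function() {
  path <- system.file("extdata", "cohort-manifest.tsv", package = "m6Apattern",
                      mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
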