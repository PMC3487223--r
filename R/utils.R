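# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 31-bit sub-seed so independent stages of one run draw from
# independent, reproducible streams
subseed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 69069 + h * 7919) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

read_tsv <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = NA,
                    na.strings = c("NA", ""), ...)
}

write_tsv <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path to a packaged fixture file
#'
#' The package ships plain-text transcriptions of the published result
#' tables: `table2_genes.tsv` (per-gene fold changes across the five
#' dopaminergic treatments), `table2_homologs.tsv` (platform id to human
#' homolog map), `table3_relations.tsv` (regulator-target relation records
#' for sub-network enrichment) and `table3_seeds.tsv` (the published seed
#' groupings with their reported p-values).
#'
#' @param file Fixture file name; with no argument, lists available files.
#' @return Absolute path to the fixture (or a character vector of names).
#' @examples
#' dopanet_fixture()
#' head(read_tsv_fixture("table2_genes.tsv"))
#' @export
dopanet_fixture <- function(file = NULL) {
  dir <- system.file("extdata", package = "dopanet")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stopf("no packaged fixture '%s'", file)
  path
}

#' Read a packaged fixture as a data frame
#' @param file Fixture file name, see [dopanet_fixture()].
#' @return A data frame.
#' @export
read_tsv_fixture <- function(file) read_tsv(dopanet_fixture(file))
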