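.relation_types <- c("expression_target", "binding_partner",
                     "protein_modification_target")

#' Read a regulator-target relation database
#'
#' The relation table holds one record per (regulator, relation type,
#' target) triple: relation types are restricted to expression targets,
#' binding partners and protein (post-translational) modification
#' targets; `sign` is `+`, `-` or `0` (unknown).  Duplicated triples are
#' rejected with their line numbers.
#'
#' @param path TSV with columns `regulator`, `relation_type`, `target`,
#'   `sign`.
#' @return A `relation_db` data frame.
#' @export
read_relations <- function(path) {
  db <- read_tsv(path)
  need <- c("regulator", "relation_type", "target", "sign")
  if (!all(need %in% names(db)))
    stopf("relation table must have columns %s", paste(need, collapse = ", "))
  bad <- !db$relation_type %in% .relation_types
  if (any(bad))
    stopf("unknown relation type(s): %s",
          paste(unique(db$relation_type[bad]), collapse = ", "))
  db$sign <- as.character(db$sign)
  if (!all(db$sign %in% c("+", "-", "0")))
    stopf("relation sign must be one of +, -, 0")
  key <- paste(db$regulator, db$relation_type, db$target)
  if (anyDuplicated(key)) {
    lines <- which(duplicated(key) | duplicated(key, fromLast = TRUE)) + 1L
    stopf("duplicate relation triples at line(s) %s of %s",
          paste(lines, collapse = ", "), path)
  }
  class(db) <- c("relation_db", "data.frame")
  db
}

#' Read a platform-to-human homolog map
#'
#' @param path TSV with columns `gene_id`, `human_symbol`,
#'   `human_accession`; unmapped entries carry `no_homolog` or `unknown`
#'   in the symbol column.
#' @return A `homolog_map` data frame.
#' @export
read_homolog_map <- function(path) {
  map <- read_tsv(path)
  if (!all(c("gene_id", "human_symbol") %in% names(map)))
    stopf("homolog map must have columns gene_id, human_symbol")
  class(map) <- c("homolog_map", "data.frame")
  map
}

#' Map measured platform genes to human homologs
#'
#' Genes whose map entry is `no_homolog`, `unknown` or empty are counted
#' as unmapped and excluded from all downstream enrichment computation;
#' genes absent from the map entirely are reported as missing and
#' likewise treated as unmapped.
#'
#' @param genes Character vector of platform gene ids.
#' @param map A [read_homolog_map()] table (or data frame with the same
#'   columns).
#' @return List with `mapped` (data frame `gene_id`, `human_symbol`),
#'   `n_mapped`, `n_unmapped` and `missing` (ids absent from the map).
#' @export
map_to_human <- function(genes, map) {
  if (!length(genes))
    return(list(mapped = data.frame(gene_id = character(),
                                    human_symbol = character(),
                                    stringsAsFactors = FALSE),
                n_mapped = 0L, n_unmapped = 0L, missing = character()))
  i <- match(genes, map$gene_id)
  missing <- genes[is.na(i)]
  sym <- map$human_symbol[i]
  ok <- !is.na(sym) & !tolower(sym) %in% c("", "no_homolog", "no homolog",
                                           "unknown")
  mapped <- data.frame(gene_id = genes[ok], human_symbol = sym[ok],
                       stringsAsFactors = FALSE)
  list(mapped = mapped, n_mapped = sum(ok), n_unmapped = sum(!ok),
       missing = missing)
}

#' Seed-centered sub-networks of one relation type
#'
#' Every regulator with at least one target of the requested relation
#' type becomes a seed; its sub-network is the deduplicated set of its
#' targets.
#'
#' @param db A `relation_db`.
#' @param relation_type One of the closed relation-type set.
#' @return Named list: seed -> character vector of target symbols.
#' @export
build_subnetworks <- function(db, relation_type) {
  if (!relation_type %in% .relation_types)
    stopf("unknown relation type '%s'", relation_type)
  sub <- db[db$relation_type == relation_type, , drop = FALSE]
  lapply(split(sub$target, sub$regulator), unique)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples.  Exact mode enumerates the
#' permutation distribution of U (used automatically for small untied
#' samples); normal mode uses the tie-corrected normal approximation
#' with continuity correction.  When every value is tied across both
#' samples the test is uninformative and p = 1 is returned with a
#' warning.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param mode `"auto"` (exact when `min(|x|,|y|) <= 8` and untied),
#'   `"exact"` or `"normal"`.
#' @return List with `U` (statistic for `x`) and `p.value` (two-sided,
#'   in (0, 1]).
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (length(unique(c(x, y))) == 1) {
    warnf("all values tied across both samples; p = 1")
    return(list(U = length(x) * length(y) / 2, p.value = 1))
  }
  if (mode == "auto")
    mode <- if (min(length(x), length(y)) <= 8 && !ties) "exact" else "normal"
  if (mode == "exact" && ties) {
    warnf("ties present; falling back to the normal approximation")
    mode <- "normal"
  }
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = mode == "exact", correct = TRUE,
    alternative = "two.sided"))
  p <- min(max(wt$p.value, .Machine$double.xmin), 1)
  list(U = unname(wt$statistic), p.value = p)
}

#' Sub-network enrichment over a measured gene list
#'
#' For every seed, the overlap between its sub-network and the measured
#' (human-mapped) gene list is tested against the background of all
#' other measured genes by a two-sided Mann-Whitney U test on the
#' supplied expression values.  A seed is retained when p < `alpha` and
#' the overlap has more than `min_members` members (strictly greater).
#' Seeds with an empty overlap are skipped and logged.
#'
#' @param subnetworks Named list from [build_subnetworks()], or a
#'   `relation_db` (then all three relation types are scanned).
#' @param expression Named numeric vector: one value (signed log2 fold
#'   change of the chosen contrast) per measured mapped human symbol.
#' @param alpha Enrichment p-value threshold.
#' @param min_members Minimum overlap size, exceeded strictly.
#' @return An `enrichment_result` data frame sorted by ascending p:
#'   `seed`, `relation_type`, `n_overlap`, `entities`, `U`, `p`,
#'   `retained`; skipped seeds in `attr(, "skipped")`.
#' @export
snea_enrich <- function(subnetworks, expression, alpha = 0.05,
                        min_members = 5) {
  if (is.null(names(expression)) || !is.numeric(expression))
    stopf("expression must be a named numeric vector of measured symbols")
  if (inherits(subnetworks, "relation_db")) {
    sets <- list()
    for (rt in .relation_types) {
      s <- build_subnetworks(subnetworks, rt)
      names(s) <- paste(rt, names(s), sep = "\r")
      sets <- c(sets, s)
    }
    subnetworks <- sets
  } else if (is.null(names(subnetworks)) ||
             !all(nzchar(names(subnetworks)))) {
    stopf("subnetworks must be a named list")
  }
  measured <- names(expression)
  rows <- list(); skipped <- character()
  for (nm in names(subnetworks)) {
    parts <- strsplit(nm, "\r", fixed = TRUE)[[1]]
    rt <- if (length(parts) == 2) parts[1] else NA_character_
    seed <- parts[length(parts)]
    overlap <- intersect(subnetworks[[nm]], measured)
    if (!length(overlap)) {
      skipped <- c(skipped, seed)
      next
    }
    bg <- setdiff(measured, overlap)
    if (!length(bg)) {
      skipped <- c(skipped, seed)
      next
    }
    mw <- mann_whitney_u(expression[overlap], expression[bg])
    rows[[length(rows) + 1]] <- data.frame(
      seed = seed, relation_type = rt, n_overlap = length(overlap),
      entities = paste(sort(overlap), collapse = ","),
      U = mw$U, p = mw$p.value,
      retained = mw$p.value < alpha && length(overlap) > min_members,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = character(), relation_type = character(),
               n_overlap = integer(), entities = character(), U = numeric(),
               p = numeric(), retained = logical(), stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Write an enrichment report
#'
#' Columns: relation group, seed, comma-joined overlapping entities and
#' the p-value in scientific notation, ordered by ascending p.
#'
#' @param results An `enrichment_result`.
#' @param path Optional output TSV.
#' @param retained_only Restrict to retained seeds?
#' @return The report data frame, invisibly when written to `path`.
#' @export
snea_report <- function(results, path = NULL, retained_only = FALSE) {
  tab <- as.data.frame(results)
  if (retained_only) tab <- tab[tab$retained, , drop = FALSE]
  rep <- data.frame(group = tab$relation_type, seed = tab$seed,
                    entities = tab$entities,
                    p_value = sprintf("%.2e", tab$p),
                    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_tsv(rep, path)
    return(invisible(rep))
  }
  rep
}

#' Full SNEA run from platform genes to a report
#'
#' Maps the measured platform genes to human homologs, attaches one
#' expression value per symbol (values of platform genes sharing a
#' symbol are averaged), builds seed sub-networks for all three relation
#' types and tests each against the background.
#'
#' @param genes Platform gene ids of the measured (regulated) list.
#' @param values Numeric vector parallel to `genes` (signed log2 fold
#'   changes of the chosen contrast).
#' @param map Homolog map, see [read_homolog_map()].
#' @param relations A `relation_db`, see [read_relations()].
#' @param alpha,min_members Passed to [snea_enrich()].
#' @return List with `enrichment` (an `enrichment_result`), `mapping`
#'   (the [map_to_human()] result) and `expression` (the symbol-level
#'   vector used).
#' @export
snea <- function(genes, values, map, relations, alpha = 0.05,
                 min_members = 5) {
  stopifnot(length(genes) == length(values))
  mp <- map_to_human(genes, map)
  if (!nrow(mp$mapped)) stopf("no measured gene mapped to a human homolog")
  v <- values[match(mp$mapped$gene_id, genes)]
  expr <- tapply(v, mp$mapped$human_symbol, mean)
  expr <- stats::setNames(as.numeric(expr), names(expr))
  enr <- snea_enrich(relations, expr, alpha = alpha,
                     min_members = min_members)
  list(enrichment = enr, mapping = mp, expression = expr)
}
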