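#' Join per-treatment SAM results by gene
#'
#' Outer-joins the result tables of several treatments of one tissue on
#' gene id.  A fold-change cell is carried forward as significant only
#' when its q-value is below `q_threshold`; other cells stay empty (NA),
#' mirroring the sparse layout of the published gene table.
#'
#' @param results List of `sam_result`s (or data frames with columns
#'   `gene_id`, `q`, `fold_change` plus a `treatment` attribute), one per
#'   treatment, all from the same tissue.
#' @param tissue Tissue label recorded on the output.
#' @param q_threshold Per-treatment significance cutoff.
#' @return A `meta_join` data frame: `gene_id`, `tissue`, one signed
#'   fold-change column per treatment (NA where not significant), and
#'   matching `q_<treatment>` columns.
#' @export
join_by_gene <- function(results, tissue = NA_character_,
                         q_threshold = 0.05) {
  tabs <- lapply(results, function(r) {
    if (inherits(r, "sam_result")) {
      tr <- r$treatment
      tab <- r$table
    } else {
      tr <- attr(r, "treatment")
      tab <- as.data.frame(r)
    }
    if (is.null(tr) || is.na(tr)) stopf("each result needs a treatment label")
    if (!tr %in% da_treatments())
      stopf("unknown treatment '%s'", tr)
    if (anyDuplicated(tab$gene_id))
      stopf("duplicate gene ids within treatment '%s'", tr)
    list(treatment = tr, tab = tab)
  })
  trts <- vapply(tabs, `[[`, "", "treatment")
  if (anyDuplicated(trts)) stopf("duplicate treatment results supplied")
  genes <- sort(unique(unlist(lapply(tabs, function(x) x$tab$gene_id))))
  out <- data.frame(gene_id = genes, tissue = tissue,
                    stringsAsFactors = FALSE)
  for (x in tabs) {
    fc <- q <- rep(NA_real_, length(genes))
    i <- match(x$tab$gene_id, genes)
    q[i] <- x$tab$q
    keep <- x$tab$q < q_threshold
    fc[i[keep]] <- x$tab$fold_change[keep]
    out[[x$treatment]] <- fc
    out[[paste0("q_", x$treatment)]] <- q
  }
  class(out) <- c("meta_join", "data.frame")
  attr(out, "q_threshold") <- q_threshold
  out
}

# qualifying drug pairs for one gene given its significant signed fold
# changes (named vector, NA = not significant)
qualifying_pairs <- function(fc) {
  pairs <- list()
  sgn <- sign(fc)
  # x̄ = 0 (fold change +1.0) carries no direction and can join no pair
  sgn[!is.na(fc) & fc == 1] <- 0
  for (a in .agonists) for (b in .blockers) {
    if (is.na(fc[a]) || is.na(fc[b])) next
    if (sgn[a] * sgn[b] < 0)
      pairs[[length(pairs) + 1]] <- list(drug1 = a, drug2 = b,
                                         rule = "reciprocal")
  }
  for (ant in .antagonists) {
    if (is.na(fc["MPTP_aMPT"]) || is.na(fc[ant])) next
    if (sgn["MPTP_aMPT"] != 0 && sgn["MPTP_aMPT"] == sgn[ant])
      pairs[[length(pairs) + 1]] <- list(drug1 = "MPTP_aMPT", drug2 = ant,
                                         rule = "same-direction")
  }
  pairs
}

#' Receptor attribution from classification evidence
#'
#' Drugs are receptor-specific (SKF 38393 and SCH 23390 act on D1,
#' LY 171555 and sulpiride on D2) while MPTP + alphaMPT depletion is
#' nonspecific.  A gene is attributed to D1 when its qualifying pairs
#' involve only D1-specific drugs (beyond depletion), to D2 in the
#' mirror case, to `both` when drugs of both subtypes appear, and to
#' `indeterminate` in the (guarded, unreachable under the pair
#' definitions) case that no receptor-specific drug occurs at all.
#'
#' @param evidence List of qualifying pairs as produced by
#'   [classify_reciprocal()].
#' @return One of `"D1"`, `"D2"`, `"both"`, `"indeterminate"`.
#' @export
attribute_receptor <- function(evidence) {
  if (!length(evidence)) stopf("attribute_receptor needs non-empty evidence")
  drugs <- unique(unlist(lapply(evidence, function(p) c(p$drug1, p$drug2))))
  d1 <- any(drugs %in% .d1_drugs)
  d2 <- any(drugs %in% .d2_drugs)
  if (d1 && d2) "both" else if (d1) "D1" else if (d2) "D2" else "indeterminate"
}

#' Classify one joined gene row by the reciprocal selection rule
#'
#' A gene is kept as dopamine-regulated iff at least one qualifying pair
#' exists among its significant fold changes: a reciprocal pair joins an
#' agonist (SKF, LY) with a blocker (SCH, sulpiride, MPTP + alphaMPT)
#' whose fold changes have opposite signs; a same-direction pair joins
#' depletion with an antagonist whose fold changes share a sign.  Genes
#' with no qualifying pair are rejected with a machine-readable reason.
#'
#' @param fc Named vector of significant signed fold changes over the
#'   treatment set (NA where not significant).
#' @param gene_id,tissue Labels carried through.
#' @return A `reciprocal_gene` list (`gene_id`, `tissue`, `fold_changes`,
#'   `evidence`, `receptor`, `accepted = TRUE`) or a rejection list
#'   (`accepted = FALSE`, `reason` one of `"single-treatment"`,
#'   `"non-qualifying-pattern"`).
#' @export
classify_reciprocal <- function(fc, gene_id = NA_character_,
                                tissue = NA_character_) {
  fc <- fc[da_treatments()]
  names(fc) <- da_treatments()
  pairs <- qualifying_pairs(fc)
  if (!length(pairs)) {
    reason <- if (sum(!is.na(fc)) < 2) "single-treatment"
              else "non-qualifying-pattern"
    return(list(accepted = FALSE, gene_id = gene_id, tissue = tissue,
                fold_changes = fc, reason = reason))
  }
  structure(list(accepted = TRUE, gene_id = gene_id, tissue = tissue,
                 fold_changes = fc, evidence = pairs,
                 receptor = attribute_receptor(pairs)),
            class = "reciprocal_gene")
}

#' Apply the reciprocal filter to a joined table
#'
#' @param joined A `meta_join` from [join_by_gene()], or any data frame
#'   with `gene_id`, `tissue` and one fold-change column per treatment.
#' @return List with `accepted` (data frame: gene, tissue, per-treatment
#'   fold changes, receptor, evidence summary), `rejected` (gene, reason)
#'   and `evidence` (list of `reciprocal_gene` objects).
#' @export
classify_genes <- function(joined) {
  trts <- da_treatments()
  acc <- list(); rej <- list(); ev <- list()
  for (i in seq_len(nrow(joined))) {
    fc <- unlist(joined[i, intersect(trts, names(joined))])
    ti <- if (is.null(joined$tissue)) NA_character_ else joined$tissue[i]
    r <- classify_reciprocal(fc, joined$gene_id[i], ti)
    if (isTRUE(r$accepted)) {
      pairs <- vapply(r$evidence, function(p)
        sprintf("%s|%s|%s", p$drug1, p$drug2, p$rule), "")
      acc[[length(acc) + 1]] <- data.frame(
        gene_id = r$gene_id, tissue = r$tissue, t(r$fold_changes),
        receptor = r$receptor, evidence = paste(pairs, collapse = ";"),
        stringsAsFactors = FALSE)
      ev[[r$gene_id]] <- r
    } else {
      rej[[length(rej) + 1]] <- data.frame(gene_id = r$gene_id,
                                           reason = r$reason,
                                           stringsAsFactors = FALSE)
    }
  }
  accepted <- if (length(acc)) do.call(rbind, acc) else
    data.frame(gene_id = character(), tissue = character(),
               MPTP_aMPT = numeric(), SCH = numeric(), sulpiride = numeric(),
               SKF = numeric(), LY = numeric(), receptor = character(),
               evidence = character(), stringsAsFactors = FALSE)
  rejected <- if (length(rej)) do.call(rbind, rej) else
    data.frame(gene_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(accepted) <- rownames(rejected) <- NULL
  list(accepted = accepted, rejected = rejected, evidence = ev)
}

#' Assemble the dopamine-regulated gene report
#'
#' Produces the published table's layout: tissue, gene id, annotation
#' and human homolog (where an annotation table is supplied),
#' per-treatment signed fold changes with blanks for non-significant
#' cells, and the attributed receptor; plus summary counts per tissue
#' and receptor.
#'
#' @param classified Result of [classify_genes()].
#' @param annotation Optional data frame with `gene_id`, `annotation`,
#'   `homolog_symbol` columns.
#' @param path Optional output TSV path.
#' @return A `meta_report`: list with `table`, `rejected` and `summary`.
#' @export
build_report <- function(classified, annotation = NULL, path = NULL) {
  tab <- classified$accepted
  if (!is.null(annotation) && nrow(tab)) {
    i <- match(tab$gene_id, annotation$gene_id)
    tab$annotation <- annotation$annotation[i]
    tab$homolog <- annotation$homolog_symbol[i]
  }
  cols <- c("tissue", "gene_id",
            intersect(c("annotation", "homolog"), names(tab)),
            da_treatments(), "receptor")
  tab <- tab[, cols, drop = FALSE]
  summary <- list(
    n_accepted = nrow(tab),
    n_rejected = nrow(classified$rejected),
    by_tissue = table(tab$tissue),
    by_receptor = table(tab$receptor))
  if (!is.null(path)) {
    out <- tab
    for (tr in da_treatments())
      out[[tr]] <- ifelse(is.na(out[[tr]]), "",
                          sprintf("%.1f", out[[tr]]))
    write_tsv(out, path)
  }
  structure(list(table = tab, rejected = classified$rejected,
                 summary = summary),
            class = "meta_report")
}

#' @export
print.meta_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Dopamine-regulated gene report: %d accepted, %d rejected\n",
              s$n_accepted, s$n_rejected))
  if (s$n_accepted) {
    cat("  by receptor: ",
        paste(sprintf("%s=%d", names(s$by_receptor), s$by_receptor),
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' End-to-end reciprocal meta-analysis for one tissue
#'
#' @param sam_results List of per-treatment `sam_result`s (one tissue).
#' @param tissue Tissue label.
#' @param q_threshold Significance cutoff applied per treatment.
#' @param annotation,path Passed to [build_report()].
#' @return A `meta_report`.
#' @export
meta_reciprocal <- function(sam_results, tissue = NA_character_,
                            q_threshold = 0.05, annotation = NULL,
                            path = NULL) {
  joined <- join_by_gene(sam_results, tissue, q_threshold)
  build_report(classify_genes(joined), annotation = annotation, path = path)
}
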