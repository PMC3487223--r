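#' Configuration of an end-to-end run
#'
#' @param out_dir Output directory for all stage products.
#' @param mode `"simulate"` (synthetic arrays through the full pipeline)
#'   or `"fixtures"` (classification + enrichment on the packaged
#'   published-table fixtures, no simulation).
#' @param sim A [sim_config()] (simulate mode).
#' @param tissues Tissues to analyse.
#' @param q_threshold Per-treatment SAM q cutoff.
#' @param alpha,min_members SNEA thresholds.
#' @param snea_contrast Treatment whose signed fold changes feed the
#'   enrichment test (the agonist SKF by default, with a companion MPTP
#'   run available through `snea_second_contrast`).
#' @param snea_second_contrast Optional second contrast; seeds retained
#'   under both runs are reported as the intersection.
#' @param relations_path,homologs_path Relation DB / homolog map TSVs;
#'   default to the packaged fixtures.
#' @param stages Named logical vector toggling `normalize`, `sam`,
#'   `meta`, `snea`.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("dopanet_run_"),
                       mode = c("simulate", "fixtures"),
                       sim = sim_config(),
                       tissues = NULL,
                       q_threshold = 0.05, alpha = 0.05, min_members = 5,
                       snea_contrast = "SKF",
                       snea_second_contrast = NULL,
                       relations_path = dopanet_fixture("table3_relations.tsv"),
                       homologs_path = dopanet_fixture("table2_homologs.tsv"),
                       stages = c(normalize = TRUE, sam = TRUE, meta = TRUE,
                                  snea = TRUE)) {
  mode <- match.arg(mode)
  if (q_threshold <= 0 || q_threshold >= 1 || alpha <= 0 || alpha >= 1)
    stopf("thresholds must lie in (0, 1)")
  if (min_members < 1) stopf("min_members must be a positive integer")
  structure(list(out_dir = out_dir, mode = mode, sim = sim,
                 tissues = tissues %||% sim$tissues,
                 q_threshold = q_threshold, alpha = alpha,
                 min_members = min_members, snea_contrast = snea_contrast,
                 snea_second_contrast = snea_second_contrast,
                 relations_path = relations_path,
                 homologs_path = homologs_path, stages = stages),
            class = "run_config")
}

stage_on <- function(config, stage) {
  val <- config$stages[stage]
  is.na(val) || isTRUE(unname(val))
}

#' Run the pipeline end to end
#'
#' Simulate mode executes simulate -> normalize -> SAM (per
#' treatment-tissue) -> reciprocal meta-analysis, and, when relation and
#' homolog tables are available, sub-network enrichment on the accepted
#' hypothalamic genes.  Fixture mode applies the meta-analysis
#' classification and the enrichment stage directly to the packaged
#' published-table fixtures.  All stage outputs are written under
#' `config$out_dir` together with a checksum manifest and an echo of the
#' configuration; identical configurations reproduce identical files.
#'
#' @param config A [run_config()].
#' @return A report bundle: list with `reports` (per tissue
#'   `meta_report`s), `snea` (enrichment results or NULL), `sam`
#'   (per treatment-tissue `sam_result`s, simulate mode), `truth`
#'   (simulate mode), `manifest` (file checksums) and `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  bundle <- if (config$mode == "simulate") run_all_simulate(config)
            else run_all_fixtures(config)
  # config echo + checksum manifest
  echo <- vapply(config[c("mode", "q_threshold", "alpha", "min_members",
                          "snea_contrast")],
                 function(x) paste(format(x), collapse = " "), "")
  writeLines(paste0(names(echo), ": ", echo),
             file.path(config$out_dir, "config_echo.txt"))
  files <- sort(setdiff(list.files(config$out_dir, recursive = TRUE),
                        "run_manifest.tsv"))
  man <- data.frame(file = files,
                    md5 = unname(tools::md5sum(
                      file.path(config$out_dir, files))),
                    stringsAsFactors = FALSE)
  write_tsv(man, file.path(config$out_dir, "run_manifest.tsv"))
  bundle$manifest <- man
  bundle$out_dir <- config$out_dir
  bundle
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline failed in stage '%s': %s", name, conditionMessage(e)))
}

run_all_simulate <- function(config) {
  scfg <- config$sim
  truth <- run_stage("simulate", {
    generate_truth(scfg)
  })
  study <- run_stage("simulate", {
    s <- generate_study(scfg, truth, tissues = config$tissues)
    write_arrays(s$arrays, file.path(config$out_dir, "arrays"))
    s
  })
  reports <- list(); sams <- list(); ratios <- list()
  if (stage_on(config, "normalize")) {
    for (ti in config$tissues) {
      rm_ti <- run_stage("normalize", {
        sel <- vapply(study$arrays, function(a) a$tissue == ti, TRUE)
        r <- normalize_arrays(study$arrays[sel])
        write_tsv(data.frame(gene_id = rownames(r$ratios), r$ratios,
                             check.names = FALSE),
                  file.path(config$out_dir, sprintf("ratios_%s.tsv", ti)))
        r
      })
      ratios[[ti]] <- rm_ti
      if (!stage_on(config, "sam")) next
      fits <- run_stage("sam", {
        fits <- list()
        for (tr in unique(rm_ti$arrays$treatment)) {
          fit <- sam(rm_ti, tr,
                     sam_config(q_threshold = config$q_threshold,
                                rng_seed = subseed(scfg$rng_seed,
                                                   paste("sam", tr, ti))))
          fits[[tr]] <- fit
          write_tsv(fit$table,
                    file.path(config$out_dir,
                              sprintf("sam_%s_%s.tsv", ti, tr)))
        }
        fits
      })
      sams[[ti]] <- fits
      if (!stage_on(config, "meta")) next
      reports[[ti]] <- run_stage("meta", meta_reciprocal(
        fits, tissue = ti, q_threshold = config$q_threshold,
        path = file.path(config$out_dir, sprintf("regulated_%s.tsv", ti))))
    }
  }
  enr <- NULL
  if (stage_on(config, "snea") && length(reports) &&
      file.exists(config$relations_path) &&
      file.exists(config$homologs_path)) {
    enr <- run_stage("snea", snea_stage(config, reports))
  }
  list(reports = reports, snea = enr, sam = sams, ratios = ratios,
       truth = truth)
}

run_all_fixtures <- function(config) {
  t2 <- read_tsv_fixture("table2_genes.tsv")
  reports <- list()
  for (ti in intersect(config$tissues, unique(t2$tissue))) {
    rows <- t2[t2$tissue == ti, , drop = FALSE]
    joined <- data.frame(gene_id = rows$gene_id, tissue = ti,
                         rows[da_treatments()], stringsAsFactors = FALSE)
    cls <- classify_genes(joined)
    ann <- data.frame(gene_id = rows$gene_id, annotation = rows$annotation,
                      homolog_symbol = rows$homolog_symbol,
                      stringsAsFactors = FALSE)
    reports[[ti]] <- build_report(
      cls, annotation = ann,
      path = file.path(config$out_dir, sprintf("regulated_%s.tsv", ti)))
  }
  enr <- NULL
  if (stage_on(config, "snea") && length(reports))
    enr <- snea_stage(config, reports)
  list(reports = reports, snea = enr, sam = NULL, truth = NULL)
}

# enrichment stage shared by both modes: accepted genes of the first
# tissue with any, expression = signed log2 fold change of the contrast
snea_stage <- function(config, reports) {
  rel <- read_relations(config$relations_path)
  map <- read_homolog_map(config$homologs_path)
  run_one <- function(contrast) {
    for (ti in names(reports)) {
      tab <- reports[[ti]]$table
      keep <- !is.na(tab[[contrast]])
      if (!any(keep)) next
      genes <- tab$gene_id[keep]
      vals <- log2(abs(tab[[contrast]][keep])) * sign(tab[[contrast]][keep])
      res <- try(snea(genes, vals, map, rel, alpha = config$alpha,
                      min_members = config$min_members), silent = TRUE)
      if (!inherits(res, "try-error")) {
        res$tissue <- ti
        return(res)
      }
    }
    NULL
  }
  primary <- run_one(config$snea_contrast)
  if (is.null(primary)) return(NULL)
  snea_report(primary$enrichment,
              file.path(config$out_dir,
                        sprintf("snea_%s.tsv", config$snea_contrast)))
  out <- list(primary = primary, contrast = config$snea_contrast)
  if (!is.null(config$snea_second_contrast)) {
    second <- run_one(config$snea_second_contrast)
    if (!is.null(second)) {
      snea_report(second$enrichment,
                  file.path(config$out_dir,
                            sprintf("snea_%s.tsv",
                                    config$snea_second_contrast)))
      both <- intersect(
        primary$enrichment$seed[primary$enrichment$retained],
        second$enrichment$seed[second$enrichment$retained])
      writeLines(both, file.path(config$out_dir,
                                 "snea_intersection_seeds.txt"))
      out$second <- second
      out$intersection <- both
    }
  }
  out
}

#' Audit the packaged published-table fixture
#'
#' Re-applies the reciprocal classification rule to every row of the
#' packaged gene-table fixture, listing conforming rows with their
#' attributed receptor and flagging rows whose printed fold-change
#' pattern satisfies neither the reciprocal nor the same-direction rule
#' (one such row exists in the published table: same-sign agonist and
#' antagonist responses).  The fixture itself is never modified.
#'
#' @param path Fixture path; defaults to the packaged table.
#' @return An audit data frame: `gene_id`, `tissue`, `annotation`,
#'   `conforming`, `receptor` (conforming rows), `reason` (others).
#' @export
validate_fixtures <- function(path = dopanet_fixture("table2_genes.tsv")) {
  t2 <- read_tsv(path)
  need <- c("tissue", "gene_id", da_treatments())
  if (!all(need %in% names(t2)))
    stopf("malformed fixture: missing column(s) %s",
          paste(setdiff(need, names(t2)), collapse = ", "))
  if (!nrow(t2))
    return(data.frame(gene_id = character(), tissue = character(),
                      annotation = character(), conforming = logical(),
                      receptor = character(), reason = character(),
                      stringsAsFactors = FALSE))
  out <- lapply(seq_len(nrow(t2)), function(i) {
    fc <- unlist(t2[i, da_treatments()])
    r <- classify_reciprocal(fc, t2$gene_id[i], t2$tissue[i])
    ann <- if (is.null(t2$annotation)) NA_character_ else t2$annotation[i]
    data.frame(gene_id = t2$gene_id[i], tissue = t2$tissue[i],
               annotation = ann,
               conforming = isTRUE(r$accepted),
               receptor = if (isTRUE(r$accepted)) r$receptor
                          else NA_character_,
               reason = if (isTRUE(r$accepted)) NA_character_ else r$reason,
               stringsAsFactors = FALSE)
  })
  audit <- do.call(rbind, out)
  rownames(audit) <- NULL
  audit
}
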