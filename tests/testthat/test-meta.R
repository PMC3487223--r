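sam_stub <- function(treatment, gene_id, q, fc) {
  structure(list(table = data.frame(gene_id = gene_id, q = q,
                                    fold_change = fc,
                                    stringsAsFactors = FALSE),
                 treatment = treatment), class = "sam_result")
}

test_that("gene-wise join keeps only significant cells", {
  r1 <- sam_stub("SKF", c("a", "b", "c"), c(0.01, 0.2, 0.04), c(2, 1.5, -1.7))
  r2 <- sam_stub("MPTP_aMPT", c("a", "d"), c(0.03, 0.01), c(-1.4, 1.2))
  j <- join_by_gene(list(r1, r2), tissue = "Hyp")
  expect_identical(sort(j$gene_id), c("a", "b", "c", "d"))
  # gene present and significant in 2 of the treatments -> 2 filled cells
  row_a <- j[j$gene_id == "a", ]
  expect_equal(row_a$SKF, 2)
  expect_equal(row_a$MPTP_aMPT, -1.4)
  # non-significant cell left empty
  expect_true(is.na(j$SKF[j$gene_id == "b"]))
  # disjoint gene sets -> single filled cell per row
  expect_true(is.na(j$SKF[j$gene_id == "d"]))
  expect_false(is.na(j$MPTP_aMPT[j$gene_id == "d"]))

  dup <- sam_stub("SKF", c("a", "a"), c(0.01, 0.02), c(2, 2))
  expect_error(join_by_gene(list(dup), "Hyp"), "duplicate gene ids")
})

test_that("classification implements the reciprocal selection rule", {
  trts <- da_treatments()
  fc <- function(...) {
    v <- setNames(rep(NA_real_, 5), trts)
    args <- list(...)
    v[names(args)] <- unlist(args)
    v
  }
  # depletion up, agonist down: reciprocal, D1-attributed
  r <- classify_reciprocal(fc(MPTP_aMPT = 1.3, SKF = -1.7), "aromB", "Hyp")
  expect_true(r$accepted)
  expect_identical(r$receptor, "D1")
  rules <- vapply(r$evidence, `[[`, "", "rule")
  expect_true("reciprocal" %in% rules)

  # depletion and antagonist down, agonist up: both rule types fire
  r2 <- classify_reciprocal(fc(MPTP_aMPT = -1.3, SCH = -2.0, SKF = 2.3))
  expect_true(r2$accepted)
  rules2 <- vapply(r2$evidence, `[[`, "", "rule")
  expect_setequal(unique(rules2), c("reciprocal", "same-direction"))
  pairs2 <- vapply(r2$evidence, function(p) paste(p$drug1, p$drug2), "")
  expect_true("SKF MPTP_aMPT" %in% pairs2 || "MPTP_aMPT SKF" %in% pairs2)
  expect_identical(r2$receptor, "D1")

  # significant in a single treatment only: no pair
  r3 <- classify_reciprocal(fc(SKF = 2.0))
  expect_false(r3$accepted)
  expect_identical(r3$reason, "single-treatment")

  # same-sign agonist and antagonist satisfies neither rule
  r4 <- classify_reciprocal(fc(SCH = -1.5, SKF = -1.5))
  expect_false(r4$accepted)
  expect_identical(r4$reason, "non-qualifying-pattern")

  # a fold change of exactly +1.0 has no direction and joins no pair
  r5 <- classify_reciprocal(fc(SKF = 1.0, MPTP_aMPT = -1.4))
  expect_false(r5$accepted)
})

test_that("receptor attribution follows drug selectivity", {
  p <- function(d1, d2, rule = "reciprocal") list(drug1 = d1, drug2 = d2,
                                                  rule = rule)
  expect_identical(attribute_receptor(list(p("SKF", "MPTP_aMPT"))), "D1")
  expect_identical(attribute_receptor(list(p("LY", "sulpiride"))), "D2")
  expect_identical(attribute_receptor(list(p("SKF", "MPTP_aMPT"),
                                           p("LY", "MPTP_aMPT"))), "both")
  expect_error(attribute_receptor(list()), "non-empty")
})

test_that("classification is invariant to treatment and gene order", {
  joined <- data.frame(gene_id = c("g1", "g2", "g3"), tissue = "Hyp",
                       MPTP_aMPT = c(1.3, NA, -1.2),
                       SCH = c(NA, -1.5, NA), sulpiride = NA_real_,
                       SKF = c(-1.7, 1.6, NA), LY = c(NA, NA, 1.5),
                       stringsAsFactors = FALSE)
  a <- classify_genes(joined)
  b <- classify_genes(joined[c(3, 1, 2),
                             c("gene_id", "tissue", "LY", "SKF", "sulpiride",
                               "SCH", "MPTP_aMPT")])
  expect_identical(a$accepted[order(a$accepted$gene_id), ]$receptor,
                   b$accepted[order(b$accepted$gene_id), ]$receptor)
  expect_setequal(a$accepted$gene_id, b$accepted$gene_id)
})

test_that("accepted evidence re-checks against the raw fold-change signs", {
  set.seed(50)
  cfg <- small_config(n_genes = 300, seed = 50)
  study <- generate_study(cfg, tissues = "Hyp")
  rm <- normalize_arrays(study$arrays)
  fits <- lapply(setNames(da_treatments(), da_treatments()),
                 function(tr) sam(rm, tr))
  joined <- join_by_gene(fits, "Hyp")
  cls <- classify_genes(joined)
  for (g in cls$evidence) {
    for (pr in g$evidence) {
      f1 <- g$fold_changes[pr$drug1]
      f2 <- g$fold_changes[pr$drug2]
      expect_false(anyNA(c(f1, f2)))
      if (pr$rule == "reciprocal") {
        expect_true(pr$drug1 %in% c("SKF", "LY"))
        expect_true(pr$drug2 %in% c("SCH", "sulpiride", "MPTP_aMPT"))
        expect_lt(unname(sign(f1) * sign(f2)), 0)
      } else {
        expect_identical(pr$drug1, "MPTP_aMPT")
        expect_true(pr$drug2 %in% c("SCH", "sulpiride"))
        expect_equal(unname(sign(f1)), unname(sign(f2)))
      }
    }
  }
})

test_that("the report mirrors the published table layout", {
  empty <- classify_genes(data.frame(gene_id = character(), tissue = character(),
                                     MPTP_aMPT = numeric(), SCH = numeric(),
                                     sulpiride = numeric(), SKF = numeric(),
                                     LY = numeric(), stringsAsFactors = FALSE))
  path <- withr::local_tempfile(fileext = ".tsv")
  rep0 <- build_report(empty, path = path)
  expect_identical(rep0$summary$n_accepted, 0L)
  written <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_identical(nrow(written), 0L)

  t2 <- read_tsv_fixture("table2_genes.tsv")
  hyp <- t2[t2$tissue == "Hyp", ]
  joined <- data.frame(gene_id = hyp$gene_id, tissue = "Hyp",
                       hyp[da_treatments()], stringsAsFactors = FALSE)
  cls <- classify_genes(joined)
  rep1 <- build_report(cls, annotation = data.frame(
    gene_id = hyp$gene_id, annotation = hyp$annotation,
    homolog_symbol = hyp$homolog_symbol, stringsAsFactors = FALSE))
  # printed fold-change cells echo the fixture verbatim
  arom <- rep1$table[rep1$table$gene_id == "04a17", ]
  expect_equal(arom$MPTP_aMPT, 1.3)
  expect_equal(arom$SKF, -1.7)
  expect_identical(arom$homolog, "CYP19A1")
  expect_identical(arom$receptor, "D1")
  lect <- rep1$table[rep1$table$gene_id == "21l19", ]
  expect_equal(unname(unlist(lect[c("MPTP_aMPT", "SCH", "SKF")])),
               c(1.5, -1.7, -1.7))
})
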