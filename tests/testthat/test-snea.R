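test_that("homolog mapping separates mapped, unmapped and missing genes", {
  map <- data.frame(gene_id = c("a", "b", "c"),
                    human_symbol = c("TP53", "no_homolog", "MYC"),
                    stringsAsFactors = FALSE)
  r <- map_to_human(c("a", "b", "c"), map)
  expect_identical(r$n_mapped, 2L)
  expect_identical(r$n_unmapped, 1L)
  expect_identical(r$mapped$human_symbol, c("TP53", "MYC"))

  r0 <- map_to_human(character(), map)
  expect_identical(r0$n_mapped, 0L)
  expect_identical(nrow(r0$mapped), 0L)

  r2 <- map_to_human(c("a", "zz"), map)
  expect_identical(r2$missing, "zz")
  expect_identical(r2$n_unmapped, 1L)
})

test_that("fixture mapping counts agree with a direct tally of homolog cells", {
  t2 <- read_tsv_fixture("table2_genes.tsv")
  hyp <- t2[t2$tissue == "Hyp", ]
  map <- read_homolog_map(dopanet_fixture("table2_homologs.tsv"))
  r <- map_to_human(hyp$gene_id, map)
  direct <- sum(!is.na(hyp$homolog_symbol) & nzchar(hyp$homolog_symbol))
  expect_identical(r$n_mapped, direct)
  expect_identical(r$n_mapped + r$n_unmapped, nrow(hyp))
})

test_that("sub-network construction validates and deduplicates", {
  db <- data.frame(regulator = "INS", relation_type = "expression_target",
                   target = "AGT", sign = "0", stringsAsFactors = FALSE)
  class(db) <- c("relation_db", "data.frame")
  nets <- build_subnetworks(db, "expression_target")
  expect_identical(nets, list(INS = "AGT"))
  expect_error(build_subnetworks(db, "banana"), "relation type")

  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("regulator\trelation_type\ttarget\tsign",
               "INS\texpression_target\tAGT\t0",
               "INS\texpression_target\tAGT\t0"), path)
  expect_error(read_relations(path), "line")
})

test_that("the packaged relation fixture reproduces the printed seed sets", {
  rel <- read_relations(dopanet_fixture("table3_relations.tsv"))
  nets <- build_subnetworks(rel, "expression_target")
  expect_setequal(nets$INS,
                  c("AGT", "FN1", "MYC", "GAPDH", "GLUL", "GPX3", "APOE",
                    "TTR", "VIM", "C3", "APOA4", "A2M", "ACTB", "FTH1",
                    "CKM", "BCKDK"))
  bind <- build_subnetworks(rel, "binding_partner")
  expect_setequal(bind[["Vitamin D"]], c("C3", "APOA4", "CUBN", "ACTA1"))
  pmod <- build_subnetworks(rel, "protein_modification_target")
  expect_setequal(pmod$GST, c("VIM", "FKBP1A", "TALDO1", "NSUN2"))
})

test_that("exact Mann-Whitney p-values match full enumeration", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 1 / 3, tolerance = 1e-12)
  o <- oracle_mwu_exact(c(1, 2), c(3, 4))
  expect_equal(r$p.value, o$p.value, tolerance = 1e-12)

  set.seed(8)
  x <- rnorm(5); y <- rnorm(5) + 1
  r2 <- mann_whitney_u(x, y, mode = "exact")
  o2 <- oracle_mwu_exact(x, y)
  expect_equal(r2$U, o2$U)
  expect_equal(r2$p.value, o2$p.value, tolerance = 1e-12)
})

test_that("tied and degenerate samples are handled", {
  expect_warning(r <- mann_whitney_u(rep(2, 4), rep(2, 5)), "tied")
  expect_equal(r$p.value, 1)
  expect_equal(r$U, 10)
  x <- c(1, 2, 3)
  r2 <- mann_whitney_u(x, x)
  expect_equal(r2$U, length(x)^2 / 2)
  expect_equal(r2$p.value, 1)
  expect_error(mann_whitney_u(numeric(), 1:3), "non-empty")
})

test_that("the normal approximation tracks a Monte-Carlo oracle", {
  set.seed(12)
  x <- rnorm(20, 0.45)
  y <- rnorm(100)
  p_norm <- mann_whitney_u(x, y, mode = "normal")$p.value
  p_mc <- oracle_mwu_mc(x, y, B = 2e5)
  expect_lt(abs(p_norm - p_mc) / p_mc, 0.1)
})

test_that("enrichment retains seeds by the printed rule", {
  set.seed(9)
  bg_names <- sprintf("BG%03d", 1:100)
  expr <- setNames(rnorm(100), bg_names)
  # exactly 5 overlapping members never pass the strictly-greater rule
  nets <- list(seed5 = bg_names[1:5], seed6 = bg_names[6:11])
  expr[bg_names[1:5]] <- expr[bg_names[1:5]] + 50
  expr[bg_names[6:11]] <- expr[bg_names[6:11]] + 3 * sd(expr)
  res <- snea_enrich(nets, expr)
  r5 <- res[res$seed == "seed5", ]
  expect_lt(r5$p, 0.01)
  expect_false(r5$retained)
  r6 <- res[res$seed == "seed6", ]
  expect_true(r6$retained)
  # skipped seeds are logged
  res2 <- snea_enrich(list(gone = c("NOPE1", "NOPE2")), expr)
  expect_identical(attr(res2, "skipped"), "gone")
  expect_identical(nrow(res2), 0L)
})

test_that("enrichment p is invariant under monotone transforms of expression", {
  set.seed(10)
  expr <- setNames(rnorm(60), sprintf("G%02d", 1:60))
  nets <- list(s1 = sprintf("G%02d", 1:8), s2 = sprintf("G%02d", 20:31))
  a <- snea_enrich(nets, expr)
  b <- snea_enrich(nets, exp(expr) + 2)
  expect_equal(a[order(a$seed), ]$p, b[order(b$seed), ]$p, tolerance = 1e-12)
  expect_equal(a[order(a$seed), ]$U, b[order(b$seed), ]$U)
})

test_that("reports are ordered by ascending p and round-trip the fixture", {
  res <- structure(data.frame(seed = c("A", "B"),
                              relation_type = "expression_target",
                              n_overlap = c(6L, 7L), entities = c("X", "Y"),
                              U = c(1, 2), p = c(1e-2, 1e-6),
                              retained = c(TRUE, TRUE),
                              stringsAsFactors = FALSE),
                   class = c("enrichment_result", "data.frame"))
  rep <- snea_report(res[order(res$p), ])
  expect_identical(rep$seed, c("B", "A"))
  expect_match(rep$p_value[1], "e-06")
  rep0 <- snea_report(res[0, ])
  expect_identical(nrow(rep0), 0L)

  # full run on the packaged fixtures: the insulin seed's overlap is the
  # full printed entity list
  t2 <- read_tsv_fixture("table2_genes.tsv")
  hyp <- t2[t2$tissue == "Hyp" & !is.na(t2$SKF), ]
  map <- read_homolog_map(dopanet_fixture("table2_homologs.tsv"))
  rel <- read_relations(dopanet_fixture("table3_relations.tsv"))
  vals <- sign(hyp$SKF) * log2(abs(hyp$SKF))
  out <- snea(hyp$gene_id, vals, map, rel)
  ins <- out$enrichment[out$enrichment$seed == "INS" &
                          out$enrichment$relation_type ==
                            "expression_target", ]
  expect_identical(ins$n_overlap, 16L)
  expect_identical(ins$entities,
                   paste(sort(c("AGT", "FN1", "MYC", "GAPDH", "GLUL", "GPX3",
                                "APOE", "TTR", "VIM", "C3", "APOA4", "A2M",
                                "ACTB", "FTH1", "CKM", "BCKDK")),
                         collapse = ","))
})
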