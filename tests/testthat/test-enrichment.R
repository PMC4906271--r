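ann_fixture <- function() {
  annotation_table(
    list(g1 = "WING", g2 = "WING", g3 = "CYC", g11 = "WING", g12 = "CYC"),
    c(WING = "wing development", CYC = "cell cycle"))
}

test_that("category proportions count annotated members over the whole set", {
  ann <- ann_fixture()
  s <- gene_set(sprintf("g%d", 1:10), "ref")
  prof <- category_proportions(s, ann, c("WING", "CYC", "GROWTH"))
  expect_identical(prof$count, c(2L, 1L, 0L))
  expect_equal(prof$proportion, c(0.2, 0.1, 0))

  all_ann <- gene_set(c("g1", "g2"), "ref")
  expect_equal(
    category_proportions(all_ann, ann, "WING")$proportion, 1)

  expect_error(category_proportions(gene_set(character(0), "ref"), ann,
                                    "WING"), "empty")
})

test_that("fold over-representation is the ratio of proportions", {
  ann <- ann_fixture()
  a <- gene_set(sprintf("g%d", 1:10), "ref")     # 2/10 WING
  b <- gene_set(sprintf("g%d", 11:30), "ref")    # g11 WING -> 1/20
  res <- fold_overrepresentation(a, b, ann, "WING")
  expect_equal(res$fold, (2 / 10) / (1 / 20))
  expect_true(res$fold_defined)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  # cross-check significance against the canonical 2x2 exact test
  expect_equal(res$p_value,
               fisher.test(matrix(c(2, 8, 1, 19), nrow = 2))$p.value)

  eq <- fold_overrepresentation(a, a, ann, "WING")
  expect_equal(eq$fold, 1)

  none <- fold_overrepresentation(gene_set(c("g20", "g21"), "ref"),
                                  gene_set(c("g22", "g23"), "ref"),
                                  ann, "WING")
  expect_false(none$fold_defined)
  expect_identical(none$p_value, 1)

  undef <- fold_overrepresentation(a, gene_set(c("g20", "g21"), "ref"),
                                   ann, "WING")
  expect_false(undef$fold_defined)
  expect_identical(undef$fold, Inf)
  expect_true(undef$p_value <= 1)
})

test_that("enrichment against a universe uses the hypergeometric tail + BH", {
  universe <- gene_set(sprintf("u%02d", 1:8), "ref")
  # C4 marks u01..u04; FULL covers the whole universe
  ann <- annotation_table(lapply(stats::setNames(universe$ids, universe$ids),
                                 function(g) {
                                   if (g <= "u04") c("C4", "FULL") else "FULL"
                                 }))
  s <- gene_set(c("u01", "u02", "u05"), "ref")
  res <- enrichment_vs_universe(s, ann, universe, c("C4", "FULL"))
  # exact enumeration over all C(8,3) draws for the size-4 category
  draws <- combn(8, 3)
  k_obs <- 2
  want <- mean(colSums(draws <= 4) >= k_obs)
  expect_equal(res$p_value[res$category_id == "C4"], want, tolerance = 1e-12)
  expect_identical(res$p_value[res$category_id == "FULL"], 1)
  expect_equal(res$q_value, p.adjust(res$p_value, "BH")[order(order(
    res$q_value, res$p_value))], tolerance = 1e-12)

  expect_error(enrichment_vs_universe(gene_set("zz", "ref"), ann, universe,
                                      "C4"), "not a subset")
})

test_that("BH q-values are monotone and never below raw p after step-up", {
  set.seed(72)
  pool <- sprintf("u%03d", 1:40)
  cats <- sprintf("C%02d", 1:12)
  assignments <- lapply(stats::setNames(pool, pool), function(g) {
    sample(cats, sample.int(4, 1))
  })
  ann <- annotation_table(assignments)
  uni <- gene_set(pool, "ref")
  s <- gene_set(sample(pool, 12), "ref")
  res <- enrichment_vs_universe(s, ann, uni, cats)
  expect_true(all(diff(res$q_value) >= -1e-12))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
  expect_true(all(res$q_value <= 1))
})

test_that("expression filter keeps genes at or above the fold threshold", {
  expr <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                     value1 = c(10, 10, 8, 3), value2 = c(40, 10, 4, 5))
  kept <- fold_change_filter(expr, min_fold = 2, pseudocount = 0)
  expect_identical(kept$ids, c("gA", "gC"))

  all_kept <- fold_change_filter(expr, min_fold = 1, pseudocount = 0)
  expect_identical(length(all_kept), 4L)

  none <- fold_change_filter(expr[0, , drop = FALSE], 2, 0)
  expect_identical(length(none), 0L)

  # unsigned: swapping the condition columns changes nothing
  swapped <- data.frame(gene_id = expr$gene_id, value1 = expr$value2,
                        value2 = expr$value1)
  expect_identical(fold_change_filter(swapped, 2, 0)$ids, kept$ids)

  # zero/zero rows are skipped (with warning) only when pseudocount is 0
  withz <- rbind(expr, data.frame(gene_id = "gZ", value1 = 0, value2 = 0))
  expect_warning(res <- fold_change_filter(withz, 2, 0), "skipped")
  expect_identical(attr(res, "n_skipped"), 1L)
  expect_false("gZ" %in% res$ids)
  expect_silent(fold_change_filter(withz, 2, 1))
})

test_that("DE overlap reports count and proportion of targets", {
  targets <- gene_set(sprintf("g%d", 1:4), "moth")
  de <- gene_set(c("g2", "g9"), "moth")
  res <- de_overlap(targets, de)
  expect_identical(res$overlap_count, 1L)
  expect_equal(res$proportion_of_targets, 0.25)

  expect_equal(de_overlap(targets, gene_set("zz", "moth"))$overlap_count, 0L)
  expect_equal(de_overlap(targets, gene_set(targets$ids, "moth"))$
                 proportion_of_targets, 1)
  expect_error(de_overlap(gene_set(character(0), "moth"), de), "empty")
})
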