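test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_sim_config(seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(cfg, d1)
  s2 <- simulate_dataset(cfg, d2)
  for (k in names(s1$paths)) {
    expect_identical(readLines(s1$paths[[k]]), readLines(s2$paths[[k]]))
  }
})

test_that("infeasible gene placement fails with a diagnostic", {
  cfg <- small_sim_config(seed = 1)
  cfg$n_genes <- 500L
  cfg$n_peaks <- 10L
  expect_error(simulate_dataset(cfg, withr::local_tempdir()),
               "infeasible placement")
})

test_that("planted peaks recover their intended targets under the pipeline convention", {
  cfg <- small_sim_config(seed = 13)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  genes <- read_gff3(sim$paths$genes_a)
  reps <- list(read_bed(sim$paths$peaks_a_rep1, "rep1"),
               read_bed(sim$paths$peaks_a_rep2, "rep2"))
  peaks <- reconcile_replicates(reps)
  expect_identical(nrow(peaks), cfg$n_peaks)
  asg <- nearest_gene(peaks, genes, max_distance_bp = 10000)
  expect_false(any(asg$tie))
  expect_identical(attr(asg, "unassigned"), 0L)
  got <- target_gene_set(asg, "a")
  expect_identical(got$ids, sort(sim$truth$targets_a))
  # each reconciled peak maps to exactly the gene recorded in the truth
  truth_map <- sim$truth$peak_to_gene_a
  key <- paste(asg$scaffold, asg$peak_start, asg$peak_end)
  truth_key <- paste(truth_map$scaffold, truth_map$start, truth_map$end)
  expect_identical(asg$gene_id[match(truth_key, key)], truth_map$gene_id)
})

test_that("replicate peak pairs overlap by at least 90%", {
  cfg <- small_sim_config(seed = 17)
  sim <- simulate_dataset(cfg, withr::local_tempdir())
  r1 <- read_bed(sim$paths$peaks_b_rep1)
  r2 <- read_bed(sim$paths$peaks_b_rep2)
  ov <- pmin(r1$end, r2$end) - pmax(r1$start, r2$start)
  expect_true(all(ov >= 0.9 * (r1$end - r1$start)))
  expect_true(all(ov >= 0.9 * (r2$end - r2$start)))
})

test_that("shared/specific truth sets are disjoint and sized as configured", {
  for (f in c(0, 0.4, 1)) {
    cfg <- small_sim_config(seed = 19, shared_target_fraction = f)
    sim <- simulate_dataset(cfg, withr::local_tempdir())
    tr <- sim$truth
    expect_identical(tr$n_shared, as.integer(round(f * cfg$n_peaks)))
    expect_length(intersect(tr$shared_ref_ids, tr$a_specific_ref_ids), 0)
    expect_length(intersect(tr$shared_ref_ids, tr$b_specific_ref_ids), 0)
    expect_length(intersect(tr$a_specific_ref_ids, tr$b_specific_ref_ids), 0)
    # all targets carry ortholog entries
    expect_true(all(tr$targets_a %in% names(tr$ortholog_map)))
    expect_true(all(tr$targets_b %in% names(tr$ortholog_map)))
  }
})

test_that("expression generator plants exactly the configured DE fraction", {
  cfg <- synthetic_config(seed = 23, de_fraction_2fold = 0.1, n_genes = 1000L,
                          n_scaffolds = 16L, scaffold_length_bp = 600000L,
                          n_peaks = 10L)
  res <- simulate_expression(cfg)
  expect_length(res$de_gene_ids, 100)
  for (ps in c(0, 1)) {
    kept <- fold_change_filter(res$expr, min_fold = 2, pseudocount = ps)
    expect_identical(kept$ids, sort(res$de_gene_ids))
  }

  none <- simulate_expression(synthetic_config(seed = 24,
                                               de_fraction_2fold = 0))
  expect_length(fold_change_filter(none$expr, 2, 1), 0L)

  all_de <- simulate_expression(synthetic_config(seed = 25,
                                                 de_fraction_2fold = 1))
  expect_identical(length(fold_change_filter(all_de$expr, 2, 1)),
                   nrow(all_de$expr))
})

test_that("planted category folds are realized exactly up to rounding", {
  cats <- data.frame(category_id = "CAT-WING", label = "wing development",
                     base_rate = 0.05, fold_in_shared = 4,
                     stringsAsFactors = FALSE)
  shared <- sprintf("s%03d", 1:240)
  other <- sprintf("o%03d", 1:240)
  ann <- simulate_annotation(list(shared = shared, other = other), cats,
                             seed = 29)
  res <- fold_overrepresentation(gene_set(shared, "ref"),
                                 gene_set(other, "ref"), ann, "CAT-WING")
  expect_identical(res$count_a, 48L)
  expect_identical(res$count_b, 12L)
  expect_equal(res$fold, 4)
})
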