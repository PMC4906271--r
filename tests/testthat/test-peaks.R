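test_that("replicate reconciliation intersects intervals and averages scores", {
  r1 <- make_peaks("s1", 100, 300, score = 10, replicate_ids = "rep1")
  r2 <- make_peaks("s1", 250, 400, score = 20, replicate_ids = "rep2")

  one <- reconcile_replicates(list(r1))
  expect_identical(one$start, 100L)

  merged <- reconcile_replicates(list(r1, r2), min_overlap_bp = 1)
  expect_identical(nrow(merged), 1L)
  expect_identical(merged$start, 250L)
  expect_identical(merged$end, 300L)
  expect_identical(merged$score, 15)
  expect_identical(merged$replicate_ids, "rep1,rep2")

  disjoint <- reconcile_replicates(
    list(make_peaks("s1", 100, 200), make_peaks("s1", 300, 400)))
  expect_identical(nrow(disjoint), 0L)

  expect_error(reconcile_replicates(list()), "non-empty")

  # a 50 bp overlap is dropped under a 60 bp requirement
  strict <- reconcile_replicates(list(r1, r2), min_overlap_bp = 60)
  expect_identical(nrow(strict), 0L)
})

test_that("reconciliation is symmetric in replicate order", {
  set.seed(21)
  reps <- lapply(1:3, function(k) {
    start <- sort(sample.int(5000, 12)) * 10L
    make_peaks("s1", start + sample.int(30, 12), start + 400L,
               score = runif(12, 1, 10),
               replicate_ids = sprintf("rep%d", k))
  })
  a <- reconcile_replicates(reps)
  b <- reconcile_replicates(rev(reps))
  expect_identical(a[, c("scaffold", "start", "end")],
                   b[, c("scaffold", "start", "end")])
  expect_equal(a$score, b$score)
})

test_that("nearest_gene matches the worked examples", {
  genes <- make_genes(c("G1", "G2"), "s1", c(0, 2000), c(500, 2500))
  a <- nearest_gene(make_peaks("s1", 1000, 1200), genes)
  expect_identical(a$gene_id, "G1")
  expect_identical(a$distance_bp, 500L)
  expect_identical(a$relation, "downstream")
  expect_false(a$tie)

  inside <- nearest_gene(make_peaks("s1", 100, 200), genes)
  expect_identical(inside$gene_id, "G1")
  expect_identical(inside$distance_bp, 0L)
  expect_identical(inside$relation, "overlapping")

  tied <- nearest_gene(make_peaks("s1", 900, 1100),
                       make_genes(c("G2", "G1"), "s1", c(1200, 0),
                                  c(2000, 800)))
  expect_identical(tied$gene_id, c("G1", "G2"))
  expect_identical(tied$distance_bp, c(100L, 100L))
  expect_true(all(tied$tie))
  expect_identical(tied$relation, c("downstream", "upstream"))
})

test_that("peaks beyond max_distance_bp are left unassigned and counted", {
  genes <- make_genes("G1", "s1", 0, 500)
  peaks <- make_peaks(c("s1", "s1", "s2"), c(600, 20000, 100),
                      c(700, 20100, 200))
  a <- nearest_gene(peaks, genes, max_distance_bp = 1000)
  expect_identical(a$peak_index, 1L)
  expect_identical(attr(a, "unassigned"), 2L)
})

test_that("nearest_gene equals the brute-force scan on random instances", {
  set.seed(31)
  for (rep in 1:60) {
    n_genes <- sample(2:10, 1)
    n_peaks <- sample(1:8, 1)
    # coarse coordinate grid forces frequent exact ties
    gs <- sample.int(60, n_genes, replace = TRUE) * 100L
    genes <- make_genes(sprintf("g%02d", seq_len(n_genes)),
                        sample(c("s1", "s2"), n_genes, replace = TRUE),
                        gs, gs + sample.int(8, n_genes, replace = TRUE) * 100L)
    ps <- sample.int(60, n_peaks, replace = TRUE) * 100L
    peaks <- make_peaks(sample(c("s1", "s2"), n_peaks, replace = TRUE),
                        ps, ps + sample.int(4, n_peaks, replace = TRUE) * 100L)
    maxd <- sample(c(0L, 200L, 1000L, 10000L), 1)
    got <- nearest_gene(peaks, genes, maxd)
    want <- brute_nearest(peaks, genes, maxd)
    attr(got, "unassigned") <- NULL
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(got, want)
    }
  }
})

test_that("assignment is invariant under permutation of inputs", {
  set.seed(41)
  gs <- sample.int(500, 15) * 50L
  genes <- make_genes(sprintf("g%02d", 1:15), "s1", gs, gs + 600L)
  ps <- sample.int(500, 10) * 50L
  peaks <- make_peaks("s1", ps, ps + 300L)
  ref <- nearest_gene(peaks, genes)
  perm_g <- genes[sample.int(nrow(genes)), , drop = FALSE]
  perm <- nearest_gene(peaks, perm_g)
  attr(ref, "unassigned") <- NULL
  attr(perm, "unassigned") <- NULL
  expect_identical(ref, perm)
})

test_that("target sets deduplicate assigned genes", {
  asg <- data.frame(gene_id = c("g1", "g2", "g2"))
  s <- target_gene_set(asg, "beeA")
  expect_identical(s$ids, c("g1", "g2"))
  expect_identical(s$species_tag, "beeA")
  expect_identical(length(target_gene_set(asg[0, , drop = FALSE], "x")), 0L)
})
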