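test_that("consensus scanning reproduces the worked examples", {
  mad1 <- motif_model("MAD1_fly", "MAD1", iupac = "GCCGTCGC")
  adf1_site <- "TGGCTGCCGTCGCGAT"
  h <- scan_motif(mad1, adf1_site, both_strands = FALSE)
  expect_identical(h$position, 5L)
  expect_identical(h$strand, "+")

  core <- motif_model("UbxCore", "Ubx", iupac = "TAAT")
  h2 <- scan_motif(core, "ATAATTAAT")
  expect_identical(nrow(h2), 3L)
  expect_identical(h2$position[h2$strand == "+"], c(1L, 5L))
  expect_identical(h2$position[h2$strand == "-"], 3L)

  long <- motif_model("L", "L", iupac = strrep("A", 20))
  expect_identical(nrow(scan_motif(long, strrep("A", 10))), 0L)

  # degenerate code: ATAATS matches ATAATG and ATAATC only
  ubx <- motif_model("UbxSite", "Ubx", iupac = "ATAATS")
  expect_identical(scan_motif(ubx, "ATAATGATAATCATAATT",
                              both_strands = FALSE)$position, c(0L, 6L))
})

test_that("sequence N never matches, on either strand", {
  core <- motif_model("UbxCore", "Ubx", iupac = "TAAT")
  expect_identical(nrow(scan_motif(core, "TANT")), 0L)
  n_code <- motif_model("X", "X", iupac = "TNT")
  expect_identical(scan_motif(n_code, "TGTANA", both_strands = FALSE)$position,
                   0L)
  expect_identical(nrow(scan_motif(n_code, "TNT")), 0L)
})

test_that("scanner equals the brute-force oracle on random sequences", {
  set.seed(81)
  motifs <- c("TAAT", "ATAATS", "GCCGTCGC", "GAGAG", "RYSW", "TRAATK",
              "GCTGCCCGCCGC")
  for (rep in 1:25) {
    seq <- random_dna(400, p_n = 0.01)
    for (cons in motifs) {
      m <- motif_model("m", "tf", iupac = cons)
      got <- scan_motif(m, seq)[, c("position", "strand")]
      want <- brute_scan(cons, seq)
      rownames(got) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("both-strand hit counts are reverse-complement symmetric", {
  set.seed(82)
  for (rep in 1:20) {
    seq <- random_dna(300, p_n = 0.02)
    cons <- sample(c("TAAT", "ATAATS", "GAGAG", "GCCGTCGC"), 1)
    m <- motif_model("m", "tf", iupac = cons)
    n_fwd <- nrow(scan_motif(m, seq))
    n_rc <- nrow(scan_motif(m, revcomp(seq)))
    expect_identical(n_fwd, n_rc)
  }
})

test_that("matrix mode scores log-odds against a uniform background", {
  # strongly peaked ACGT matrix: only the exact word reaches the threshold
  mat <- rbind(c(97, 1, 1, 1), c(1, 97, 1, 1), c(1, 1, 97, 1),
               c(1, 1, 1, 97))
  m <- motif_model("pwm", "tf", matrix = mat)
  prob <- (mat + 0.01) / rowSums(mat + 0.01)
  max_score <- sum(log2(diag(prob) / 0.25))
  expect_equal(m$score_threshold, 0.8 * max_score)
  h <- scan_motif(m, "TTACGTTT", both_strands = FALSE)
  expect_identical(h$position, 2L)
  expect_equal(h$score, max_score)
  # reverse strand finds the reverse complement ACGT (self-complementary)
  h2 <- scan_motif(m, "TTACGTTT", both_strands = TRUE)
  expect_identical(h2$position, c(2L, 2L))
  # one mismatch falls below the 80% threshold for this sharp matrix
  expect_identical(nrow(scan_motif(m, "TTACCTTT", both_strands = FALSE)), 0L)
  # explicit low threshold readmits single-mismatch words
  loose <- motif_model("pwm", "tf", matrix = mat, score_threshold = 1)
  expect_true(nrow(scan_motif(loose, "TTACCTTT", both_strands = FALSE)) >= 1)
})

test_that("non-coding sampling avoids gene bodies, N runs, and is seeded", {
  set.seed(83)
  genome <- c(sc1 = random_dna(6000), sc2 = random_dna(4000))
  # poke an N run into sc1 so rejection has something to reject
  substr(genome[["sc1"]], 2001, 2050) <- strrep("N", 50)
  genes <- make_genes(c("g1", "g2"), c("sc1", "sc2"), c(1000, 500),
                      c(1800, 3800))
  draws <- sample_noncoding(genome, genes, 40, rep(120, 40), seed = 9)
  expect_length(draws, 40)
  expect_true(all(nchar(draws) == 120))
  expect_false(any(grepl("N", draws, fixed = TRUE)))
  again <- sample_noncoding(genome, genes, 40, rep(120, 40), seed = 9)
  expect_identical(draws, again)
  other <- sample_noncoding(genome, genes, 40, rep(120, 40), seed = 10)
  expect_false(identical(draws, other))

  # every draw really is non-coding: it must occur outside gene bodies
  space <- c(substr(genome[["sc1"]], 1, 1000),
             substr(genome[["sc1"]], 1801, 6000),
             substr(genome[["sc2"]], 1, 500),
             substr(genome[["sc2"]], 3801, 4000))
  expect_true(all(vapply(draws, function(d) {
    any(vapply(space, function(s) grepl(d, s, fixed = TRUE), logical(1)))
  }, logical(1))))

  covered <- make_genes("g1", "tiny", 0, 800)
  expect_error(sample_noncoding(c(tiny = random_dna(800)), covered, 2,
                                c(50, 50), seed = 1), "non-coding space")
})

test_that("fold enrichment is ~1 under the null and recovers planted ratios", {
  set.seed(84)
  genome <- c(sc1 = random_dna(150000))
  genes <- empty_genes()
  core <- motif_model("UbxCore", "Ubx", iupac = "TAAT")
  fg <- sample_noncoding(genome, genes, 25, rep(1000, 25), seed = 41)
  fe <- fold_enrichment(fg, core, genome, genes, n_draws = 30, seed = 42)
  expect_true(fe$fold > 0.75 && fe$fold < 1.3)
  expect_true(fe$empirical_p > 1 / 31 - 1e-9 && fe$empirical_p <= 1)

  # plant 2 extra sites per kb on top of the genome-wide base rate of 1/kb
  rare <- "GATCGGTACA"
  planted_genome <- plant_motif(unname(genome), rare, 150, seed = 43)$seqs
  names(planted_genome) <- names(genome)
  fg2 <- sample_noncoding(planted_genome, genes, 20, rep(1000, 20), seed = 44)
  fg2 <- plant_motif(fg2, rare, 40, seed = 45)$seqs
  m_rare <- motif_model("rare", "tf", iupac = rare)
  fe2 <- fold_enrichment(fg2, m_rare, planted_genome, genes, n_draws = 30,
                         seed = 46)
  expect_true(fe2$fold > 2 && fe2$fold < 4.2)
  expect_equal(fe2$empirical_p, 1 / 31, tolerance = 1e-9)

  absent <- motif_model("never", "tf", iupac = "ACGTACGTACGTACGT")
  fe3 <- fold_enrichment(fg, absent, genome, genes, n_draws = 20, seed = 47)
  expect_identical(fe3$fg_hits, 0L)
  expect_true(fe3$fold == 0)
  expect_identical(fe3$empirical_p, 1)
})

test_that("k-mer enrichment recovers a planted hexamer and validates k", {
  set.seed(85)
  bg <- replicate(40, random_dna(1500))
  fg <- plant_motif(replicate(20, random_dna(1500)), "TAATGG", 250,
                    seed = 51)$seqs
  res <- kmer_enrichment(fg, bg, k = 6, top_n = 5)
  canonical <- min("TAATGG", revcomp("TAATGG"))
  expect_identical(res$kmer[1], canonical)

  # null: no k-mer strays far from fold 1 on ~60 kb per side
  null_res <- kmer_enrichment(bg[1:20], bg[21:40], k = 4, top_n = Inf)
  expect_true(all(null_res$fold > 0.5 & null_res$fold < 2))

  expect_error(kmer_enrichment(fg, bg, k = 13), "between 4 and 12")
  expect_error(kmer_enrichment(fg, bg, k = 3), "between 4 and 12")
  expect_error(kmer_enrichment("ACGTAC", bg, k = 8), "shortest sequence")
})

test_that("anchored arrays report signed offsets sorted by position", {
  set.seed(86)
  seqc <- strsplit(random_dna(200), "")[[1]]
  anchor <- 100L
  seqc[(anchor - 30 + 1):(anchor - 30 + 5)] <- strsplit("GAGAG", "")[[1]]
  seqc[(anchor + 12 + 1):(anchor + 12 + 8)] <- strsplit("GCCGTCGC", "")[[1]]
  seq <- paste(seqc, collapse = "")
  lib <- list(motif_model("GAF", "GAF", iupac = "GAGAG"),
              motif_model("MAD1_fly", "MAD1", iupac = "GCCGTCGC"))
  arr <- anchor_array(seq, anchor, lib, window_bp = 50)
  got <- arr$hits[arr$hits$strand == "+", ]
  expect_true(all(c(-30L, 12L) %in% got$offset))
  expect_identical(got$tf_name[got$offset == -30L], "GAF")
  expect_identical(got$tf_name[got$offset == 12L], "MAD1")
  expect_true(!is.unsorted(arr$hits$offset))
  expect_true(all(abs(arr$hits$offset) <= 50))

  # window 0 keeps only hits starting exactly at the anchor
  seq0 <- paste0(strrep("C", 100), "TAAT", strrep("C", 96))
  arr0 <- anchor_array(seq0, 100L, list(motif_model("U", "Ubx",
                                                    iupac = "TAAT")),
                       window_bp = 0)
  expect_identical(arr0$hits$offset, 0L)
})

test_that("the nested MAD1 site sits 5 bp inside the Adf-1 sequence", {
  set.seed(87)
  flank <- random_dna(80)
  region <- paste0(flank, "TGGCTGCCGTCGCGAT", random_dna(80))
  lib <- list(motif_model("Adf1", "Adf-1", iupac = "TGGCTGCCGTCGCGAT"),
              motif_model("MAD1_fly", "MAD1", iupac = "GCCGTCGC"))
  arr <- anchor_array(region, 88L, lib, window_bp = 60)
  adf <- arr$hits[arr$hits$tf_name == "Adf-1" & arr$hits$strand == "+", ]
  mad <- arr$hits[arr$hits$tf_name == "MAD1" & arr$hits$strand == "+", ]
  expect_identical(nrow(adf), 1L)
  expect_identical(mad$offset, adf$offset + 5L)
})

test_that("array comparison partitions TFs into shared and exclusive", {
  mk_arr <- function(tfs, offsets) {
    structure(list(anchor_midpoint = 0L, window_bp = 100L,
                   hits = data.frame(tf_name = tfs, motif_id = tfs,
                                     offset = offsets,
                                     strand = "+")),
              class = "binding_site_array")
  }
  a <- mk_arr(c("GAF", "Adf-1", "MAD1"), c(-30L, 5L, 10L))
  b <- mk_arr(c("GAF", "MAD1"), c(-28L, 14L))
  cmp <- compare_arrays(a, b)
  expect_identical(cmp$a_only_tfs, "Adf-1")
  expect_identical(cmp$shared_tfs, c("GAF", "MAD1"))
  expect_identical(cmp$b_only_tfs, character(0))
  expect_identical(cmp$per_tf_offset_pairs[["GAF"]]$offset_b, -28)

  same <- compare_arrays(a, a)
  expect_identical(same$a_only_tfs, character(0))
  expect_identical(same$b_only_tfs, character(0))

  disjoint <- compare_arrays(mk_arr("GAF", 0L), mk_arr("MAD1", 0L))
  expect_identical(disjoint$shared_tfs, character(0))
})
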