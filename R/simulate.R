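# Seeded two-species synthetic data with known ground truth for every
# pipeline stage. Geometry guarantees that every planted peak's nearest gene
# (by the pipeline's own edge-to-edge convention) is its intended target:
# each gene sits in its own slot  [pad 3000][peak zone 2000][gene body],
# the peak lies 100-1500 bp upstream of the gene start inside the peak zone,
# and the pad keeps every other gene at least 3000 bp away.

.PAD_BP <- 3000L
.PEAK_ZONE_BP <- 2000L

#' Configuration for the synthetic-data generator
#'
#' Defaults emulate the shape of a two-species ChIP comparison scaled to desk
#' size: a few hundred genes per species, ~150 reproducible peaks each, a
#' fifth of the targets shared through orthologs, ~85% ortholog coverage,
#' a wing-development-like category planted at 4-fold over-representation in
#' shared targets, and a small minority of >=2-fold differentially expressed
#' genes.
#'
#' @param seed Integer master seed; every byte of output is a deterministic
#'   function of the configuration.
#' @param n_scaffolds,scaffold_length_bp Genome shape per species.
#' @param n_genes Genes per species.
#' @param gene_length_bp_range Length range for gene bodies.
#' @param n_peaks Reproducible peaks (= target genes) per species.
#' @param peak_length_bp_range Length range for peaks (max 1800).
#' @param shared_target_fraction Fraction of targets whose reference
#'   orthologs are shared between the two species, in [0, 1].
#' @param ortholog_coverage Fraction of non-target genes with an ortholog
#'   entry (target genes are always covered, so the planted shared/specific
#'   structure is exact).
#' @param planted_motifs `data.frame` with columns `motif_id`, `tf`,
#'   `consensus`, `fg_per_kb` (density planted inside peaks), `bg_per_kb`
#'   (density planted in non-coding background).
#' @param categories `data.frame` with columns `category_id`, `label`,
#'   `base_rate`, `fold_in_shared`.
#' @param de_fraction_2fold Fraction of genes planted with a >=2-fold
#'   expression difference between the two conditions.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_scaffolds = 4L,
                             scaffold_length_bp = 600000L,
                             n_genes = 300L,
                             gene_length_bp_range = c(1000L, 2000L),
                             n_peaks = 150L,
                             peak_length_bp_range = c(200L, 400L),
                             shared_target_fraction = 0.2,
                             ortholog_coverage = 0.85,
                             planted_motifs = data.frame(
                               motif_id = c("MAD1_fly", "Adf1", "UbxSite"),
                               tf = c("MAD1", "Adf-1", "Ubx"),
                               consensus = c("GCCGTCGC",
                                             "TGGCTGCCGTCGCGAT",
                                             "ATAATS"),
                               fg_per_kb = c(1.0, 0.5, 0.5),
                               bg_per_kb = c(0.2, 0.1, 0.5),
                               stringsAsFactors = FALSE),
                             categories = data.frame(
                               category_id = c("CAT-WING", "CAT-TXN",
                                               "CAT-CYCLE"),
                               label = c("wing development",
                                         "regulation of transcription",
                                         "cell cycle"),
                               base_rate = c(0.05, 0.10, 0.05),
                               fold_in_shared = c(4, 2, 1),
                               stringsAsFactors = FALSE),
                             de_fraction_2fold = 0.05) {
  cfg <- list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
              scaffold_length_bp = as.integer(scaffold_length_bp),
              n_genes = as.integer(n_genes),
              gene_length_bp_range = as.integer(gene_length_bp_range),
              n_peaks = as.integer(n_peaks),
              peak_length_bp_range = as.integer(peak_length_bp_range),
              shared_target_fraction = shared_target_fraction,
              ortholog_coverage = ortholog_coverage,
              planted_motifs = planted_motifs,
              categories = categories,
              de_fraction_2fold = de_fraction_2fold)
  stopifnot(cfg$n_scaffolds >= 1, cfg$scaffold_length_bp >= 10000,
            cfg$n_genes >= 1, cfg$n_peaks >= 1,
            cfg$n_peaks <= cfg$n_genes,
            cfg$shared_target_fraction >= 0, cfg$shared_target_fraction <= 1,
            cfg$ortholog_coverage >= 0, cfg$ortholog_coverage <= 1,
            cfg$de_fraction_2fold >= 0, cfg$de_fraction_2fold <= 1,
            all(cfg$gene_length_bp_range >= 1),
            diff(cfg$gene_length_bp_range) >= 0,
            all(cfg$peak_length_bp_range >= 20),
            cfg$peak_length_bp_range[2] <= .PEAK_ZONE_BP - 200L,
            all(cfg$planted_motifs$fg_per_kb >= 0),
            all(cfg$planted_motifs$bg_per_kb >= 0),
            all(cfg$categories$base_rate >= 0),
            all(cfg$categories$fold_in_shared >= 0))
  class(cfg) <- "synthetic_config"
  cfg
}

.random_scaffolds <- function(n_scaffolds, len, prefix) {
  seqs <- vapply(seq_len(n_scaffolds), function(i) {
    paste(c("A", "C", "G", "T")[sample.int(4L, len, replace = TRUE)],
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("%s_sc%02d", prefix, seq_len(n_scaffolds))
  seqs
}

# Place genes sequentially into per-scaffold slots; errors when they do not
# fit. Returns the gene table plus per-gene slot bookkeeping.
.place_genes <- function(cfg, prefix) {
  lens <- if (diff(cfg$gene_length_bp_range) == 0) {
    rep(cfg$gene_length_bp_range[1], cfg$n_genes)
  } else {
    sample(cfg$gene_length_bp_range[1]:cfg$gene_length_bp_range[2],
           cfg$n_genes, replace = TRUE)
  }
  sc <- 1L; cursor <- 0L
  rows <- vector("list", cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    need <- .PAD_BP + .PEAK_ZONE_BP + lens[i]
    while (cursor + need > cfg$scaffold_length_bp) {
      sc <- sc + 1L; cursor <- 0L
      if (sc > cfg$n_scaffolds) {
        stop("infeasible placement: ", cfg$n_genes, " genes of up to ",
             max(cfg$gene_length_bp_range), " bp (plus ",
             .PAD_BP + .PEAK_ZONE_BP, " bp of slot overhead each) do not fit ",
             cfg$n_scaffolds, " scaffolds of ", cfg$scaffold_length_bp, " bp")
      }
    }
    gstart <- cursor + .PAD_BP + .PEAK_ZONE_BP
    rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%04d", prefix, i),
      scaffold = sprintf("%s_sc%02d", prefix, sc),
      start = gstart, end = gstart + lens[i],
      strand = if (stats::runif(1) < 0.5) "+" else "-",
      name = NA_character_, stringsAsFactors = FALSE)
    cursor <- cursor + need
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

# Peaks for the chosen target genes: replicate 1 planted 100-1500 bp upstream
# of the gene start, replicate 2 jittered by at most 5% of the peak length so
# the replicates overlap by >= 90%.
.place_peaks <- function(cfg, genes, target_idx) {
  n <- length(target_idx)
  lens <- if (diff(cfg$peak_length_bp_range) == 0) {
    rep(cfg$peak_length_bp_range[1], n)
  } else {
    sample(cfg$peak_length_bp_range[1]:cfg$peak_length_bp_range[2], n,
           replace = TRUE)
  }
  gap_max <- pmin(1500L, .PEAK_ZONE_BP - lens - 100L)
  gaps <- 100L + vapply(gap_max - 100L, function(m) {
    sample.int(m + 1L, 1L) - 1L
  }, integer(1))
  end1 <- genes$start[target_idx] - gaps
  start1 <- end1 - lens
  jit_max <- pmax(1L, floor(0.05 * lens))
  jit <- vapply(jit_max, function(m) sample(seq(-m, m), 1L), integer(1))
  mk <- function(start, end, rep_id, score) {
    data.frame(scaffold = genes$scaffold[target_idx], start = start,
               end = end, name = sprintf("peak%04d", seq_len(n)),
               score = round(score, 3), strand = "*",
               summit_offset = NA_integer_, replicate_ids = rep_id,
               stringsAsFactors = FALSE)
  }
  s1 <- stats::runif(n, 5, 50)
  s2 <- pmax(0.5, s1 + stats::runif(n, -3, 3))
  list(rep1 = mk(start1, end1, "rep1", s1),
       rep2 = mk(start1 + jit, end1 + jit, "rep2", s2),
       core = data.frame(scaffold = genes$scaffold[target_idx],
                         start = start1 + pmax(0L, jit),
                         end = end1 + pmin(0L, jit),
                         gene_id = genes$gene_id[target_idx],
                         stringsAsFactors = FALSE))
}

# Plant motif instances into genome scaffolds (held as per-scaffold
# character vectors, so writes are O(motif length)) inside the given
# intervals, avoiding overlap with previously planted instances.
.plant_into_intervals <- function(genome_chars, intervals, consensus,
                                  n_sites, occupied) {
  L <- nchar(consensus)
  codes <- iupac_codes()
  chars <- strsplit(consensus, "", fixed = TRUE)[[1]]
  widths <- pmax(intervals$end - intervals$start - L + 1L, 0L)
  if (n_sites > 0 && sum(widths) == 0) {
    stop("no room to plant motif '", consensus, "'")
  }
  for (i in seq_len(n_sites)) {
    for (try in seq_len(200L)) {
      ii <- sample.int(nrow(intervals), 1L, prob = widths)
      pos <- intervals$start[ii] + sample.int(widths[ii], 1L) - 1L
      sc <- intervals$scaffold[ii]
      occ <- occupied[[sc]]
      if (!is.null(occ) && any(pos < occ$end & pos + L > occ$start)) {
        if (try == 200L) stop("could not place motif instance without overlap")
        next
      }
      inst <- vapply(chars, function(ch) {
        set <- codes[[ch]]
        set[sample.int(length(set), 1L)]
      }, character(1), USE.NAMES = FALSE)
      if (stats::runif(1) < 0.5) {
        inst <- rev(.iupac_complement[inst])
      }
      genome_chars[[sc]][(pos + 1L):(pos + L)] <- inst
      occupied[[sc]] <- list(start = c(occ$start, pos),
                             end = c(occ$end, pos + L))
      break
    }
  }
  list(genome_chars = genome_chars, occupied = occupied)
}

.simulate_species <- function(cfg, prefix) {
  genome <- .random_scaffolds(cfg$n_scaffolds, cfg$scaffold_length_bp, prefix)
  genes <- .place_genes(cfg, prefix)
  target_idx <- sort(sample.int(cfg$n_genes, cfg$n_peaks))
  pk <- .place_peaks(cfg, genes, target_idx)

  # planted motif densities: fg inside reconciled peak cores, bg in the rest
  # of the non-coding space (pads and tails)
  core_kb <- sum(pk$core$end - pk$core$start) / 1000
  noncoding <- .noncoding_space(genome, genes)
  noncoding_kb <- sum(noncoding$width) / 1000
  bg_iv <- .subtract_intervals(noncoding, pk$core)
  occupied <- list()
  genome_chars <- lapply(genome, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  for (m in seq_len(nrow(cfg$planted_motifs))) {
    pm <- cfg$planted_motifs[m, ]
    n_fg <- round(pm$fg_per_kb * core_kb)
    n_bg <- round(pm$bg_per_kb * noncoding_kb)
    if (n_fg > 0) {
      res <- .plant_into_intervals(genome_chars, pk$core, pm$consensus, n_fg,
                                   occupied)
      genome_chars <- res$genome_chars; occupied <- res$occupied
    }
    if (n_bg > 0) {
      res <- .plant_into_intervals(genome_chars, bg_iv, pm$consensus, n_bg,
                                   occupied)
      genome_chars <- res$genome_chars; occupied <- res$occupied
    }
  }
  genome <- vapply(genome_chars, paste, character(1), collapse = "")
  list(genome = genome, genes = genes, target_idx = target_idx,
       targets = genes$gene_id[target_idx], peaks = pk)
}

# set difference of 0-based half-open interval tables (same schema)
.subtract_intervals <- function(a, b) {
  ir_a <- GenomicRanges::GRanges(a$scaffold,
                                 IRanges::IRanges(a$start + 1L, a$end))
  ir_b <- GenomicRanges::GRanges(b$scaffold,
                                 IRanges::IRanges(b$start + 1L, b$end))
  d <- GenomicRanges::setdiff(ir_a, ir_b)
  data.frame(scaffold = as.character(GenomicRanges::seqnames(d)),
             start = GenomicRanges::start(d) - 1L,
             end = GenomicRanges::end(d), stringsAsFactors = FALSE)
}

#' Plant category annotations with exact per-subset counts
#'
#' Each disjoint gene subset is annotated at its configured rate with an
#' exact count (`round(rate * size)`), assigned to a random subset of its
#' members. The planted fold between two subsets is therefore realized
#' exactly up to integer rounding, independent of set size.
#'
#' @param subsets Named list of disjoint character vectors of gene ids; the
#'   subset named `"shared"` receives `base_rate * fold_in_shared`, all
#'   others `base_rate`.
#' @param categories `data.frame` with `category_id`, `base_rate`,
#'   `fold_in_shared` (see [synthetic_config()]).
#' @param seed Integer seed.
#' @return An `annotation_table` over the union of the subsets.
#' @export
simulate_annotation <- function(subsets, categories, seed) {
  stopifnot(anyDuplicated(unlist(subsets)) == 0)
  with_seed(seed, {
    assign_list <- list()
    for (ci in seq_len(nrow(categories))) {
      cat_row <- categories[ci, ]
      for (sub_name in names(subsets)) {
        ids <- subsets[[sub_name]]
        rate <- cat_row$base_rate *
          if (sub_name == "shared") cat_row$fold_in_shared else 1
        k <- round(rate * length(ids))
        k <- min(k, length(ids))
        if (k > 0) {
          chosen <- sample(ids, k)
          assign_list[[length(assign_list) + 1L]] <-
            data.frame(gene = chosen, cat = cat_row$category_id)
        }
      }
    }
    df <- do.call(rbind, assign_list)
    labels <- structure(
      if ("label" %in% names(categories)) categories$label else
        categories$category_id,
      names = categories$category_id)
    if (is.null(df)) {
      annotation_table(stats::setNames(list(), character(0)), labels)
    } else {
      annotation_table(split(df$cat, df$gene), labels)
    }
  })
}

#' Generate a two-condition expression table with planted fold changes
#'
#' Non-DE genes get condition ratios drawn in [1, 1.4]; DE genes in [2.2, 8]
#' with a random direction, on baselines of at least 50, so
#' [fold_change_filter()] at `min_fold = 2` recovers exactly the planted set
#' under pseudocounts 0 and 1.
#'
#' @param config A `synthetic_config` (fields `seed`, `n_genes`,
#'   `de_fraction_2fold` are used).
#' @param gene_ids Optional character vector of gene ids; defaults to
#'   `b_g0001 ...` matching the generated second species.
#' @return List with `expr` (`data.frame` gene_id/value1/value2) and
#'   `de_gene_ids` (character vector of the planted DE genes).
#' @export
simulate_expression <- function(config, gene_ids = NULL) {
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("b_g%04d", seq_len(config$n_genes))
  }
  n <- length(gene_ids)
  n_de <- round(config$de_fraction_2fold * n)
  with_seed(config$seed + 77L, {
    de_idx <- if (n_de > 0) sort(sample.int(n, n_de)) else integer(0)
    base <- pmax(50, round(stats::rlnorm(n, meanlog = log(150), sdlog = 0.4),
                           2))
    ratio <- stats::runif(n, 1, 1.4)
    ratio[de_idx] <- stats::runif(n_de, 2.2, 8)
    flip <- stats::runif(n) < 0.5
    v1 <- ifelse(flip, base, round(base * ratio, 2))
    v2 <- ifelse(flip, round(base * ratio, 2), base)
    list(expr = data.frame(gene_id = gene_ids, value1 = v1, value2 = v2,
                           stringsAsFactors = FALSE),
         de_gene_ids = gene_ids[de_idx])
  })
}

#' Generate a paired two-species synthetic dataset
#'
#' Writes, per species, a genome FASTA, a gene-model GFF3 and two replicate
#' peak BEDs; plus a cross-species ortholog TSV, a category-annotation TSV
#' over the reference gene space, a two-condition expression TSV for the
#' second species, the planted-motif library JSON and a ground-truth JSON.
#' Fully deterministic under the configuration seed.
#'
#' Exactly `round(shared_target_fraction * n_peaks)` target genes of the two
#' species map to shared reference ids; all target genes carry ortholog
#' entries while `ortholog_coverage` trims entries from non-target genes
#' only, so the planted Venn structure survives mapping exactly.
#'
#' @param config A `synthetic_config`.
#' @param out_dir Output directory (created if missing).
#' @return List with `paths` (named file paths) and `truth` (ground truth:
#'   per-species `peak_to_gene` and target ids, `ortholog_map`,
#'   `shared_ref_ids`, per-species specific ref ids, planted motif table,
#'   `de_gene_ids`, the annotation subsets and the configuration).
#' @export
simulate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- with_seed(config$seed, {
    sp_a <- .simulate_species(config, "a")
    sp_b <- .simulate_species(config, "b")

    n_shared <- round(config$shared_target_fraction * config$n_peaks)
    ref_id <- function(i) sprintf("ref_g%05d", i)
    next_ref <- 1L
    take_refs <- function(n) {
      out <- ref_id(seq(next_ref, length.out = n))
      next_ref <<- next_ref + n
      out
    }
    refs_a_targets <- take_refs(config$n_peaks)
    shared_b_pos <- sort(sample.int(config$n_peaks, n_shared))
    refs_b_targets <- character(config$n_peaks)
    refs_b_targets[shared_b_pos] <- refs_a_targets[seq_len(n_shared)]
    fresh <- setdiff(seq_len(config$n_peaks), shared_b_pos)
    refs_b_targets[fresh] <- take_refs(length(fresh))

    omap <- list()
    omap[sp_a$targets] <- as.list(refs_a_targets)
    omap[sp_b$targets] <- as.list(refs_b_targets)
    for (sp in list(sp_a, sp_b)) {
      non_targets <- setdiff(sp$genes$gene_id, sp$targets)
      n_cov <- round(config$ortholog_coverage * length(non_targets))
      covered <- if (n_cov > 0) sort(sample(non_targets, n_cov)) else character(0)
      if (length(covered) > 0) {
        omap[covered] <- as.list(take_refs(length(covered)))
      }
    }

    shared_refs <- refs_a_targets[seq_len(n_shared)]
    a_specific <- setdiff(refs_a_targets, shared_refs)
    b_specific <- setdiff(refs_b_targets, shared_refs)
    other_refs <- setdiff(unlist(omap, use.names = FALSE),
                          c(shared_refs, a_specific, b_specific))
    subsets <- list(shared = shared_refs, a_specific = a_specific,
                    b_specific = b_specific, other = other_refs)
    subsets <- subsets[lengths(subsets) > 0]
    annotation <- simulate_annotation(subsets, config$categories,
                                      seed = config$seed + 31L)
    expr <- simulate_expression(config, gene_ids = sp_b$genes$gene_id)
    list(sp_a = sp_a, sp_b = sp_b, omap = omap, subsets = subsets,
         shared_refs = shared_refs, a_specific = a_specific,
         b_specific = b_specific, annotation = annotation, expr = expr)
  })

  paths <- list(
    genome_a = file.path(out_dir, "a.genome.fasta"),
    genes_a = file.path(out_dir, "a.genes.gff3"),
    peaks_a_rep1 = file.path(out_dir, "a.hindwing.rep1.bed"),
    peaks_a_rep2 = file.path(out_dir, "a.hindwing.rep2.bed"),
    genome_b = file.path(out_dir, "b.genome.fasta"),
    genes_b = file.path(out_dir, "b.genes.gff3"),
    peaks_b_rep1 = file.path(out_dir, "b.hindwing.rep1.bed"),
    peaks_b_rep2 = file.path(out_dir, "b.hindwing.rep2.bed"),
    orthologs = file.path(out_dir, "orthologs.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    expression_b = file.path(out_dir, "b.expression.tsv"),
    motifs = file.path(out_dir, "motifs.json"),
    truth = file.path(out_dir, "truth.json"))

  write_fasta(res$sp_a$genome, paths$genome_a)
  write_gff3(res$sp_a$genes, paths$genes_a)
  write_bed(res$sp_a$peaks$rep1, paths$peaks_a_rep1)
  write_bed(res$sp_a$peaks$rep2, paths$peaks_a_rep2)
  write_fasta(res$sp_b$genome, paths$genome_b)
  write_gff3(res$sp_b$genes, paths$genes_b)
  write_bed(res$sp_b$peaks$rep1, paths$peaks_b_rep1)
  write_bed(res$sp_b$peaks$rep2, paths$peaks_b_rep2)
  write_ortholog_map(res$omap, paths$orthologs)
  write_annotation_table(res$annotation, paths$annotation)
  write_expression_table(res$expr$expr, paths$expression_b)
  jsonlite::write_json(
    lapply(seq_len(nrow(config$planted_motifs)), function(i) {
      list(id = config$planted_motifs$motif_id[i],
           tf = config$planted_motifs$tf[i],
           iupac = config$planted_motifs$consensus[i])
    }),
    paths$motifs, auto_unbox = TRUE, pretty = TRUE)

  truth <- list(
    peak_to_gene_a = res$sp_a$peaks$core[, c("scaffold", "start", "end",
                                             "gene_id")],
    peak_to_gene_b = res$sp_b$peaks$core[, c("scaffold", "start", "end",
                                             "gene_id")],
    targets_a = res$sp_a$targets,
    targets_b = res$sp_b$targets,
    ortholog_map = res$omap,
    shared_ref_ids = res$shared_refs,
    a_specific_ref_ids = res$a_specific,
    b_specific_ref_ids = res$b_specific,
    n_shared = length(res$shared_refs),
    planted_motifs = config$planted_motifs,
    annotation_subsets = res$subsets,
    de_gene_ids = res$expr$de_gene_ids,
    config = config[setdiff(names(config),
                            c("planted_motifs", "categories"))])
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  list(paths = paths, truth = truth)
}
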