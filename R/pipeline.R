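# Full comparison in fixed stage order: annotate -> map -> partition ->
# enrich -> expression filter -> motif enrichment -> anchored array diff.
# Every stage's table is persisted; a MANIFEST records completed stages so a
# failed run leaves an honest trail.

#' Build a run configuration
#'
#' @param species_a,species_b Named lists with paths `genome` (FASTA),
#'   `genes` (GFF3) and `peaks` (character vector of replicate BEDs), plus an
#'   optional `label`.
#' @param orthologs Path to the ortholog TSV.
#' @param annotation Path to the category-annotation TSV (reference ids).
#' @param expression Optional path to a two-condition expression TSV for
#'   species B.
#' @param motifs Path to a motif-library JSON; `NULL` uses the bundled
#'   default library.
#' @param max_distance_bp Nearest-gene assignment cutoff.
#' @param min_overlap_bp Replicate reconciliation overlap.
#' @param replicate_mode `"intersect"` or `"union"`.
#' @param universe Gene universe size for overlap significance; `NULL`
#'   defaults to the number of reference genes with an ortholog entry.
#' @param categories Category ids to profile; `NULL` uses every category in
#'   the annotation.
#' @param min_fold,pseudocount Expression-filter parameters.
#' @param window_bp Anchored-array half-window.
#' @param n_draws Background draws for motif fold-enrichment.
#' @param n_array_anchors Number of top-scoring peaks per species to compare
#'   as anchored binding-site arrays.
#' @param seed Master seed, recorded in the report; stage s uses seed + s.
#' @return List of class `run_config`.
#' @export
run_config <- function(species_a, species_b, orthologs, annotation,
                       expression = NULL, motifs = NULL,
                       max_distance_bp = 10000L, min_overlap_bp = 1L,
                       replicate_mode = "intersect", universe = NULL,
                       categories = NULL, min_fold = 2, pseudocount = 1,
                       window_bp = 500L, n_draws = 200L,
                       n_array_anchors = 3L, seed = 1L) {
  cfg <- list(species_a = species_a, species_b = species_b,
              orthologs = orthologs, annotation = annotation,
              expression = expression, motifs = motifs,
              max_distance_bp = max_distance_bp,
              min_overlap_bp = min_overlap_bp,
              replicate_mode = replicate_mode, universe = universe,
              categories = categories, min_fold = min_fold,
              pseudocount = pseudocount, window_bp = window_bp,
              n_draws = n_draws, n_array_anchors = n_array_anchors,
              seed = as.integer(seed))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks that every referenced path exists before any stage runs.
#'
#' @param config A `run_config`.
#' @return Invisibly `TRUE`; otherwise an error naming the missing file.
#' @export
validate_run_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- c(config$species_a$genome, config$species_a$genes,
             config$species_a$peaks,
             config$species_b$genome, config$species_b$genes,
             config$species_b$peaks,
             config$orthologs, config$annotation,
             config$expression, config$motifs)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    stop("validation error: missing input file(s): ",
         paste(missing, collapse = ", "))
  }
  if (!config$replicate_mode %in% c("intersect", "union")) {
    stop("validation error: replicate_mode must be 'intersect' or 'union'")
  }
  invisible(TRUE)
}

.annotate_species <- function(sp, config) {
  peaks <- lapply(seq_along(sp$peaks), function(i) {
    read_bed(sp$peaks[i], replicate_id = sprintf("rep%d", i))
  })
  reconciled <- reconcile_replicates(peaks, config$min_overlap_bp,
                                     mode = config$replicate_mode)
  genes <- read_gff3(sp$genes)
  assignments <- nearest_gene(reconciled, genes, config$max_distance_bp)
  list(peaks = reconciled, genes = genes, assignments = assignments,
       unassigned = attr(assignments, "unassigned"),
       targets = target_gene_set(assignments, species_tag = sp$label,
                                 label = sp$label))
}

#' Run the full cross-species comparison
#'
#' Stages run in fixed order (annotate, ortholog mapping, Venn partition
#' with overlap significance, category profiles and enrichment, expression
#' filter and overlap, motif fold-enrichment, anchored array comparison);
#' each stage's table is written under `out_dir` and the consolidated report
#' both as JSON and as the returned object. Identical configuration and seed
#' give byte-identical outputs.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory.
#' @return List of class `comparison_report`.
#' @export
run_pipeline <- function(config, out_dir) {
  validate_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(out_dir, "MANIFEST")
  writeLines(c(sprintf("seed\t%d", config$seed), "status\tincomplete"),
             manifest)
  done <- character(0)
  stage <- function(name, code) {
    res <- tryCatch(code, error = function(e) {
      writeLines(c(sprintf("seed\t%d", config$seed), "status\tfailed",
                   sprintf("failed_stage\t%s", name),
                   sprintf("completed\t%s", paste(done, collapse = ","))),
                 manifest)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    done <<- c(done, name)
    res
  }
  tsv <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  label_a <- config$species_a$label %||% "species_a"
  label_b <- config$species_b$label %||% "species_b"
  config$species_a$label <- label_a
  config$species_b$label <- label_b

  ann_a <- stage("annotate_a", {
    r <- .annotate_species(config$species_a, config)
    tsv(r$assignments, sprintf("targets_%s.tsv", label_a))
    r
  })
  ann_b <- stage("annotate_b", {
    r <- .annotate_species(config$species_b, config)
    tsv(r$assignments, sprintf("targets_%s.tsv", label_b))
    r
  })

  omap <- stage("orthologs", read_ortholog_map(config$orthologs))
  map_a <- stage("map_a", map_to_reference(ann_a$targets, omap))
  map_b <- stage("map_b", map_to_reference(ann_b$targets, omap))
  stage("mapped_sets", {
    tsv(data.frame(set = c(rep(label_a, length(map_a$set$ids)),
                           rep(label_b, length(map_b$set$ids))),
                   ref_id = c(map_a$set$ids, map_b$set$ids)),
        "mapped_targets.tsv")
  })

  venn <- stage("venn", {
    v <- venn_partition(list(map_a$set, map_b$set))
    tsv(data.frame(region = names(v$region_counts),
                   count = as.integer(v$region_counts)),
        "venn_regions.tsv")
    v
  })
  universe <- config$universe %||%
    length(unique(unlist(omap, use.names = FALSE)))
  ov_test <- stage("overlap_test",
                   overlap_significance(map_a$set, map_b$set, universe))

  annotation <- stage("annotation", read_annotation_table(config$annotation))
  categories <- config$categories %||% sort(names(annotation$labels))
  shared_ids <- intersect(map_a$set$ids, map_b$set$ids)
  enrich <- stage("enrichment", {
    shared <- gene_set(shared_ids, "reference", label = "shared")
    prof <- list()
    for (s in list(map_a$set, map_b$set)) {
      prof[[s$label]] <- category_proportions(s, annotation, categories)
    }
    fold_rows <- NULL
    if (length(shared_ids) > 0) {
      for (s in list(map_a$set, map_b$set)) {
        spec_ids <- setdiff(s$ids, shared_ids)
        if (length(spec_ids) == 0) next
        spec <- gene_set(spec_ids, "reference",
                         label = paste0(s$label, "_specific"))
        for (cat in categories) {
          row <- fold_overrepresentation(shared, spec, annotation, cat)
          row$comparison <- sprintf("shared_vs_%s_specific", s$label)
          fold_rows <- rbind(fold_rows, row)
        }
      }
    }
    uni_set <- gene_set(unique(unlist(omap, use.names = FALSE)), "reference",
                        label = "universe")
    hyper <- enrichment_vs_universe(
      gene_set(intersect(shared_ids, uni_set$ids), "reference", "shared"),
      annotation, uni_set, categories)
    profiles <- do.call(rbind, lapply(names(prof), function(nm) {
      cbind(set = nm, prof[[nm]])
    }))
    tsv(profiles, "category_proportions.tsv")
    if (!is.null(fold_rows)) tsv(fold_rows, "category_fold.tsv")
    tsv(hyper, "category_enrichment.tsv")
    list(profiles = prof, folds = fold_rows, hyper = hyper)
  })

  de <- if (!is.null(config$expression)) {
    stage("expression", {
      expr <- read_expression_table(config$expression)
      de_set <- fold_change_filter(expr, config$min_fold, config$pseudocount,
                                   species_tag = label_b)
      ov <- de_overlap(ann_b$targets, de_set)
      tsv(data.frame(gene_id = de_set$ids), "de_genes.tsv")
      list(de_set = de_set, overlap = ov)
    })
  } else NULL

  motifs <- stage("motif_library", {
    if (is.null(config$motifs)) default_motif_library()
    else read_motif_library(config$motifs)
  })
  motif_tab <- stage("motif_enrichment", {
    rows <- NULL
    for (sp in list(list(ann = ann_a, cfg = config$species_a, label = label_a),
                    list(ann = ann_b, cfg = config$species_b,
                         label = label_b))) {
      genome <- read_fasta(sp$cfg$genome)
      fg <- interval_sequences(genome, sp$ann$peaks)
      for (m in motifs) {
        fe <- fold_enrichment(fg, m, genome, sp$ann$genes,
                              n_draws = config$n_draws,
                              seed = config$seed + 101L)
        rows <- rbind(rows, data.frame(
          species = sp$label, motif_id = fe$motif_id,
          fg_density = fe$fg_density, bg_mean_density = fe$bg_mean_density,
          bg_sd = fe$bg_sd, fold = fe$fold, empirical_p = fe$empirical_p,
          n_draws = fe$n_background_draws, stringsAsFactors = FALSE))
      }
    }
    tsv(rows, "motif_enrichment.tsv")
    rows
  })

  arrays <- stage("array_diff", {
    n_anchor <- min(config$n_array_anchors, nrow(ann_a$peaks),
                    nrow(ann_b$peaks))
    if (n_anchor == 0) return(NULL)
    top_peaks <- function(ann) {
      ord <- order(-ann$peaks$score, ann$peaks$scaffold, ann$peaks$start)
      ann$peaks[ord[seq_len(n_anchor)], , drop = FALSE]
    }
    genome_a <- read_fasta(config$species_a$genome)
    genome_b <- read_fasta(config$species_b$genome)
    arr_a <- peak_anchor_arrays(genome_a, top_peaks(ann_a), motifs,
                                config$window_bp)
    arr_b <- peak_anchor_arrays(genome_b, top_peaks(ann_b), motifs,
                                config$window_bp)
    cmp <- lapply(seq_len(n_anchor), function(i) {
      compare_arrays(arr_a[[i]], arr_b[[i]])
    })
    out <- lapply(cmp, function(x) {
      list(shared_tfs = x$shared_tfs, a_only_tfs = x$a_only_tfs,
           b_only_tfs = x$b_only_tfs)
    })
    jsonlite::write_json(out, file.path(out_dir, "array_comparison.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    cmp
  })

  report <- structure(list(
    seed = config$seed,
    species = c(a = label_a, b = label_b),
    target_counts = c(a = length(ann_a$targets$ids),
                      b = length(ann_b$targets$ids)),
    unassigned_peaks = c(a = ann_a$unassigned, b = ann_b$unassigned),
    mapped_counts = c(a = length(map_a$set$ids), b = length(map_b$set$ids)),
    unmapped_counts = c(a = map_a$unmapped_count, b = map_b$unmapped_count),
    venn_region_counts = as.list(venn$region_counts),
    overlap_test = unclass(ov_test),
    category_folds = enrich$folds,
    category_enrichment = enrich$hyper,
    de_gene_count = if (!is.null(de)) length(de$de_set$ids) else NA_integer_,
    de_target_overlap = if (!is.null(de)) de$overlap$overlap_count else
      NA_integer_,
    de_target_proportion = if (!is.null(de)) {
      de$overlap$proportion_of_targets
    } else NA_real_,
    motif_enrichment = motif_tab,
    array_comparisons = arrays), class = "comparison_report")

  stage("report", {
    slim <- report
    slim$array_comparisons <- lapply(arrays %||% list(), function(x) {
      list(shared_tfs = x$shared_tfs, a_only_tfs = x$a_only_tfs,
           b_only_tfs = x$b_only_tfs)
    })
    jsonlite::write_json(unclass(slim), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 8,
                         force = TRUE)
  })
  writeLines(c(sprintf("seed\t%d", config$seed), "status\tcomplete",
               sprintf("completed\t%s", paste(done, collapse = ","))),
             manifest)
  report
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison_report (seed", x$seed, ")\n")
  cat(sprintf("  targets: %s = %d, %s = %d\n", x$species["a"],
              x$target_counts["a"], x$species["b"], x$target_counts["b"]))
  cat(sprintf("  ortholog-mapped: %d and %d; shared reference targets: %d\n",
              x$mapped_counts["a"], x$mapped_counts["b"],
              x$overlap_test$overlap))
  if (!is.na(x$de_gene_count)) {
    cat(sprintf("  DE genes (filter): %d, of which %d are targets\n",
                x$de_gene_count, x$de_target_overlap))
  }
  invisible(x)
}
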