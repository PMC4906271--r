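# Functional-category profiles, fold over-representation between target
# subsets, hypergeometric enrichment with BH correction, and the 2-fold
# expression filter used to intersect targets with differential expression.

.count_in_category <- function(ids, annotation, category) {
  ann <- annotation$assignments[ids]
  sum(vapply(ann, function(a) !is.null(a) && category %in% a, logical(1)))
}

#' Per-category counts and proportions within a gene set
#'
#' Genes lacking any annotation still count in the denominator, so the
#' proportions are comparable between sets annotated at different depths.
#'
#' @param gene_set A non-empty `gene_set`.
#' @param annotation An `annotation_table`.
#' @param categories Character vector of category ids to profile.
#' @return `data.frame` with columns `category_id`, `label`, `count`,
#'   `proportion`.
#' @export
category_proportions <- function(gene_set, annotation, categories) {
  stopifnot(inherits(gene_set, "gene_set"),
            inherits(annotation, "annotation_table"))
  if (length(gene_set$ids) == 0) stop("gene_set is empty")
  if (length(categories) == 0) stop("categories must be non-empty")
  counts <- vapply(categories, .count_in_category, integer(1),
                   ids = gene_set$ids, annotation = annotation)
  data.frame(category_id = categories,
             label = unname(ifelse(categories %in% names(annotation$labels),
                                   annotation$labels[categories], categories)),
             count = unname(counts),
             proportion = unname(counts) / length(gene_set$ids),
             stringsAsFactors = FALSE)
}

#' Fold over-representation of a category between two gene sets
#'
#' The statistic is the ratio of the category's proportion in `set_a` to its
#' proportion in `set_b`; significance is a two-sided Fisher exact test on
#' the 2x2 table (annotated/not x set A/set B). When the category is absent
#' from `set_b` but present in `set_a` the fold is flagged undefined
#' (`fold_defined = FALSE`, fold `Inf`); absent from both gives an undefined
#' fold with p = 1.
#'
#' @param set_a,set_b Non-empty `gene_set` objects.
#' @param annotation An `annotation_table`.
#' @param category Category id.
#' @return One-row `data.frame` with `category_id`, `count_a`, `size_a`,
#'   `count_b`, `size_b`, `proportion_a`, `proportion_b`, `fold`,
#'   `fold_defined`, `p_value`.
#' @export
fold_overrepresentation <- function(set_a, set_b, annotation, category) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  if (length(set_a$ids) == 0 || length(set_b$ids) == 0) {
    stop("both gene sets must be non-empty")
  }
  ka <- .count_in_category(set_a$ids, annotation, category)
  kb <- .count_in_category(set_b$ids, annotation, category)
  na <- length(set_a$ids); nb <- length(set_b$ids)
  pa <- ka / na; pb <- kb / nb
  defined <- pb > 0
  fold <- if (defined) pa / pb else if (pa > 0) Inf else NA_real_
  p <- stats::fisher.test(matrix(c(ka, na - ka, kb, nb - kb), nrow = 2))$p.value
  data.frame(category_id = category, count_a = ka, size_a = na,
             count_b = kb, size_b = nb,
             proportion_a = pa, proportion_b = pb,
             fold = fold, fold_defined = defined, p_value = p,
             stringsAsFactors = FALSE)
}

#' Category enrichment of a gene set against a universe
#'
#' Hypergeometric upper-tail test per category, Benjamini-Hochberg corrected
#' across the tested categories, sorted by q then p.
#'
#' @param gene_set A `gene_set`; must be a subset of `universe_set`.
#' @param annotation An `annotation_table`.
#' @param universe_set A `gene_set` covering the tested universe.
#' @param categories Character vector of category ids to test.
#' @return `data.frame` with `category_id`, `count_set`, `size_set`,
#'   `count_universe`, `size_universe`, `proportion_set`,
#'   `proportion_universe`, `p_value`, `q_value`.
#' @export
enrichment_vs_universe <- function(gene_set, annotation, universe_set,
                                   categories) {
  stopifnot(inherits(gene_set, "gene_set"),
            inherits(universe_set, "gene_set"))
  if (!all(gene_set$ids %in% universe_set$ids)) {
    stop("gene_set is not a subset of the universe")
  }
  if (length(categories) == 0) stop("categories must be non-empty")
  n <- length(gene_set$ids)
  U <- length(universe_set$ids)
  rows <- lapply(categories, function(cat) {
    K <- .count_in_category(universe_set$ids, annotation, cat)
    k <- .count_in_category(gene_set$ids, annotation, cat)
    p <- stats::phyper(k - 1, K, U - K, n, lower.tail = FALSE)
    data.frame(category_id = cat, count_set = k, size_set = n,
               count_universe = K, size_universe = U,
               proportion_set = if (n > 0) k / n else 0,
               proportion_universe = if (U > 0) K / U else 0,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$q_value, res$p_value, res$category_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Filter genes by unsigned expression fold change
#'
#' A gene is kept when the larger of the two pseudocounted condition ratios
#' reaches `min_fold` (inclusive). The fold is unsigned: a 2-fold change in
#' either direction passes a `min_fold` of 2. Genes with both values 0 under
#' a zero pseudocount are skipped and counted in the `n_skipped` attribute.
#'
#' @param expr Expression `data.frame` (see [read_expression_table()]).
#' @param min_fold Minimum fold difference, >= 1.
#' @param pseudocount Added to both values before forming ratios; default 1.
#' @param species_tag Namespace tag of the resulting set.
#' @return A `gene_set` of retained gene ids, with attribute `n_skipped`.
#' @export
fold_change_filter <- function(expr, min_fold = 2, pseudocount = 1,
                               species_tag = "expression") {
  stopifnot(min_fold >= 1, pseudocount >= 0)
  if (is.null(expr) || nrow(expr) == 0) {
    out <- gene_set(character(0), species_tag)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  v1 <- expr$value1 + pseudocount
  v2 <- expr$value2 + pseudocount
  degenerate <- v1 == 0 & v2 == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) with zero expression in both conditions skipped")
  }
  ratio <- pmax(v1 / v2, v2 / v1)
  keep <- !degenerate & ratio >= min_fold
  out <- gene_set(expr$gene_id[keep], species_tag)
  attr(out, "n_skipped") <- sum(degenerate)
  out
}

#' Overlap of a target set with a differential-expression set
#'
#' @param target_set Non-empty `gene_set` of putative targets.
#' @param de_set `gene_set` of differentially expressed genes in the same
#'   namespace.
#' @return List with `overlap_count` and `proportion_of_targets`.
#' @export
de_overlap <- function(target_set, de_set) {
  stopifnot(inherits(target_set, "gene_set"), inherits(de_set, "gene_set"))
  if (length(target_set$ids) == 0) stop("target_set is empty")
  ov <- length(intersect(target_set$ids, de_set$ids))
  list(overlap_count = ov,
       proportion_of_targets = ov / length(target_set$ids))
}
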