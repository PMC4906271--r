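# Projection of species target sets onto a reference gene space and
# exhaustive overlap partitions with hypergeometric significance.

#' Map a gene set onto the reference gene space
#'
#' Members with an ortholog entry are replaced by the union of their reference
#' ids (many-to-one and many-to-many relations collapse silently); members
#' without an entry are counted as unmapped.
#'
#' @param gene_set A `gene_set`.
#' @param ortholog_map Named list: species gene id -> character vector of
#'   reference ids (see [read_ortholog_map()]).
#' @param reference_tag Namespace tag of the resulting set.
#' @return List with `set` (the mapped `gene_set`), `n_input`, `n_mapped`
#'   (input members with at least one ortholog) and `unmapped_count`.
#' @export
map_to_reference <- function(gene_set, ortholog_map,
                             reference_tag = "reference") {
  stopifnot(inherits(gene_set, "gene_set"))
  hit <- gene_set$ids %in% names(ortholog_map)
  ref_ids <- unlist(ortholog_map[gene_set$ids[hit]], use.names = FALSE)
  list(set = gene_set(ref_ids, reference_tag,
                      label = gene_set$label),
       n_input = length(gene_set$ids),
       n_mapped = sum(hit),
       unmapped_count = sum(!hit))
}

#' Exhaustive Venn partition of 2-4 gene sets
#'
#' Every gene in the union is placed in exactly one of the 2^k - 1 regions,
#' keyed by the `&`-joined labels of the sets containing it. Regions are
#' ordered by subset bitmask over the input order, so the ordering is
#' deterministic.
#'
#' @param sets List of 2 to 4 `gene_set` objects sharing a namespace
#'   (`species_tag`); a mismatch is an error unless `force = TRUE`.
#' @param force Allow mismatched namespaces.
#' @return List of class `venn_partition` with `labels`, `region_counts`
#'   (named integer vector) and `region_members` (named list).
#' @export
venn_partition <- function(sets, force = FALSE) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("venn_partition needs between 2 and 4 sets")
  stopifnot(all(vapply(sets, inherits, logical(1), "gene_set")))
  tags <- vapply(sets, function(s) s$species_tag, character(1))
  if (!force && length(unique(tags)) > 1) {
    stop("gene sets live in different namespaces (",
         paste(unique(tags), collapse = ", "),
         "); map them to a common reference first or use force = TRUE")
  }
  labels <- vapply(sets, function(s) s$label, character(1))
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = "_")
  }
  universe <- sort(unique(unlist(lapply(sets, `[[`, "ids"))))
  member <- vapply(sets, function(s) universe %in% s$ids,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  counts <- integer(0); members <- list()
  for (mask in seq_len(2^k - 1)) {
    inset <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
    key <- paste(labels[inset], collapse = "&")
    sel <- if (length(universe) == 0) logical(0) else {
      apply(member, 1, function(row) all(row == inset))
    }
    counts[key] <- sum(sel)
    members[[key]] <- universe[sel]
  }
  structure(list(labels = labels, region_counts = counts,
                 region_members = members),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat("venn_partition over", paste(x$labels, collapse = ", "), "\n")
  for (k in names(x$region_counts)) {
    cat(sprintf("  %-30s %d\n", k, x$region_counts[[k]]))
  }
  invisible(x)
}

#' Hypergeometric significance of a two-set overlap
#'
#' Upper-tail probability of drawing at least the observed overlap when
#' `size_b` genes are drawn from a universe containing `size_a` marked genes,
#' together with the fold ratio observed/expected.
#'
#' @param set_a,set_b `gene_set` objects in a shared namespace.
#' @param universe Size of the gene universe; must be at least the size of
#'   the union of the two sets.
#' @return List of class `overlap_test` with `overlap`, `size_a`, `size_b`,
#'   `universe`, `p_value` and `fold` (= overlap * universe / (size_a *
#'   size_b); 0 when either set is empty).
#' @export
overlap_significance <- function(set_a, set_b, universe) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  n_union <- length(unique(c(set_a$ids, set_b$ids)))
  if (universe < n_union) {
    stop("universe (", universe, ") smaller than the union of the sets (",
         n_union, ")")
  }
  ov <- length(intersect(set_a$ids, set_b$ids))
  na <- length(set_a$ids); nb <- length(set_b$ids)
  p <- stats::phyper(ov - 1, na, universe - na, nb, lower.tail = FALSE)
  fold <- if (na > 0 && nb > 0) ov * universe / (na * nb) else 0
  structure(list(overlap = ov, size_a = na, size_b = nb,
                 universe = universe, p_value = p, fold = fold),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "overlap_test: %d / (%d x %d) in universe %d; fold %.3g, p = %.3g\n",
    x$overlap, x$size_a, x$size_b, x$universe, x$fold, x$p_value))
  invisible(x)
}
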