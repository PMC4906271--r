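# Peak -> putative target gene assignment. Distances are edge-to-edge gaps
# between the peak interval and the gene body, strand-agnostic; a gap of 0
# (overlap or direct adjacency) is classified "overlapping".

.peaks_gr <- function(peaks, levels = NULL) {
  sn <- if (is.null(levels)) peaks$scaffold else
    factor(peaks$scaffold, levels = levels)
  GenomicRanges::GRanges(sn, IRanges::IRanges(peaks$start + 1L, peaks$end))
}

.genes_gr <- function(genes, levels = NULL) {
  sn <- if (is.null(levels)) genes$scaffold else
    factor(genes$scaffold, levels = levels)
  GenomicRanges::GRanges(sn, IRanges::IRanges(genes$start + 1L, genes$end))
}

#' Construct a species-tagged gene set
#'
#' @param ids Character vector of gene ids (deduplicated and sorted).
#' @param species_tag Namespace tag: gene sets can only be compared when their
#'   ids live in the same namespace.
#' @param label Human-readable label for reports; defaults to the tag.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(ids, species_tag, label = species_tag) {
  stopifnot(is.character(species_tag), length(species_tag) == 1)
  ids <- sort(unique(as.character(ids[!is.na(ids)])))
  structure(list(ids = ids, species_tag = species_tag, label = label),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s' [%s]: %d ids\n", x$label, x$species_tag,
              length(x$ids)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$ids)

#' Reconcile replicate peak sets
#'
#' With `mode = "intersect"` (the default, conservative rule) a peak is kept
#' only if it is present in every replicate, where presence means an overlap
#' of at least `min_overlap_bp`; the merged peak is the running intersection
#' interval, its score the mean of the contributing replicate scores and its
#' replicate ids their union. With `mode = "union"` overlapping peaks from any
#' replicate are merged into their union interval.
#'
#' @param peak_lists List of peak `data.frame`s (see [read_bed()]), one per
#'   replicate.
#' @param min_overlap_bp Minimum overlap, in bp, for two replicate peaks to be
#'   treated as the same peak (>= 1).
#' @param mode `"intersect"` or `"union"`.
#' @return Peak `data.frame`, sorted by scaffold and start.
#' @export
reconcile_replicates <- function(peak_lists, min_overlap_bp = 1L,
                                 mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  if (!is.list(peak_lists) || length(peak_lists) == 0) {
    stop("peak_lists must be a non-empty list of replicate peak tables")
  }
  stopifnot(min_overlap_bp >= 1)
  if (length(peak_lists) == 1) {
    return(.sort_peaks(peak_lists[[1]]))
  }
  if (mode == "union") {
    all <- do.call(rbind, peak_lists)
    gr <- GenomicRanges::reduce(.peaks_gr(all))
    hits <- GenomicRanges::findOverlaps(gr, .peaks_gr(all))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    score <- as.numeric(tapply(all$score[s], q, mean))
    reps <- vapply(split(all$replicate_ids[s], q), function(r) {
      paste(sort(unique(stats::na.omit(r))), collapse = ",")
    }, character(1))
    out <- data.frame(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      name = NA_character_, score = score, strand = "*",
      summit_offset = NA_integer_,
      replicate_ids = ifelse(nzchar(reps), reps, NA_character_),
      stringsAsFactors = FALSE)
    return(.sort_peaks(out))
  }
  cur <- peak_lists[[1]]
  cur$.score_sum <- cur$score
  cur$.n <- 1L
  for (k in 2:length(peak_lists)) {
    rep_k <- peak_lists[[k]]
    if (nrow(cur) == 0 || is.null(rep_k) || nrow(rep_k) == 0) {
      cur <- cur[0, , drop = FALSE]
      break
    }
    lv <- sort(unique(c(cur$scaffold, rep_k$scaffold)))
    hits <- GenomicRanges::findOverlaps(.peaks_gr(cur, lv),
                                        .peaks_gr(rep_k, lv),
                                        minoverlap = min_overlap_bp)
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    if (length(q) == 0) {
      cur <- cur[0, , drop = FALSE]
      break
    }
    nxt <- cur[q, , drop = FALSE]
    nxt$start <- pmax(cur$start[q], rep_k$start[s])
    nxt$end <- pmin(cur$end[q], rep_k$end[s])
    nxt$.score_sum <- cur$.score_sum[q] + rep_k$score[s]
    nxt$.n <- cur$.n[q] + 1L
    rr <- mapply(function(a, b) {
      paste(sort(unique(stats::na.omit(c(
        strsplit(a %||% "", ",")[[1]], strsplit(b %||% "", ",")[[1]])))),
        collapse = ",")
    }, cur$replicate_ids[q], rep_k$replicate_ids[s])
    nxt$replicate_ids <- ifelse(nzchar(rr), rr, NA_character_)
    nxt$summit_offset <- NA_integer_
    cur <- nxt
  }
  if (nrow(cur) > 0) {
    cur$score <- cur$.score_sum / cur$.n
  }
  cur$.score_sum <- NULL
  cur$.n <- NULL
  .sort_peaks(cur)
}

`%||%` <- function(a, b) {
  if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
}

.sort_peaks <- function(peaks) {
  if (is.null(peaks) || nrow(peaks) == 0) return(peaks)
  peaks <- peaks[order(peaks$scaffold, peaks$start, peaks$end), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}

#' Assign each peak to its nearest gene(s)
#'
#' The distance is the edge-to-edge gap between the peak interval and the gene
#' body on the same scaffold (0 when they overlap or touch). Exact distance
#' ties yield one assignment per tied gene, each flagged `tie = TRUE`, ordered
#' lexicographically by gene id. Peaks farther than `max_distance_bp` from
#' every gene yield no assignment; their number is attached as the
#' `unassigned` attribute.
#'
#' The relation is reported for the peak relative to the gene in genome (+)
#' orientation: `"upstream"` when the peak lies before the gene start,
#' `"downstream"` when it lies after the gene end, `"overlapping"` at gap 0.
#'
#' @param peaks Peak `data.frame` (see [read_bed()]).
#' @param genes Gene `data.frame` (see [read_gff3()]); must be non-empty.
#' @param max_distance_bp Maximum assignment distance in bp (default 10000).
#' @return `data.frame` with columns `peak_index`, `scaffold`, `peak_start`,
#'   `peak_end`, `gene_id`, `distance_bp`, `relation`, `tie`, plus attribute
#'   `unassigned` (count of peaks with no gene within range).
#' @export
nearest_gene <- function(peaks, genes, max_distance_bp = 10000L) {
  if (is.null(genes) || nrow(genes) == 0) stop("genes must be non-empty")
  stopifnot(max_distance_bp >= 0)
  empty <- data.frame(peak_index = integer(0), scaffold = character(0),
                      peak_start = integer(0), peak_end = integer(0),
                      gene_id = character(0), distance_bp = integer(0),
                      relation = character(0), tie = logical(0))
  if (is.null(peaks) || nrow(peaks) == 0) {
    attr(empty, "unassigned") <- 0L
    return(empty)
  }
  lv <- sort(unique(c(peaks$scaffold, genes$scaffold)))
  gp <- .peaks_gr(peaks, levels = lv)
  gg <- .genes_gr(genes, levels = lv)
  # candidate gene per peak: overlap/adjacency hits plus the closest
  # neighbour(s) on each side (select = "all" keeps same-coordinate ties)
  cand_q <- integer(0); cand_s <- integer(0)
  ov <- GenomicRanges::findOverlaps(gp, gg, maxgap = 0L, ignore.strand = TRUE)
  cand_q <- c(cand_q, S4Vectors::queryHits(ov))
  cand_s <- c(cand_s, S4Vectors::subjectHits(ov))
  fol <- GenomicRanges::follow(gp, gg, select = "all", ignore.strand = TRUE)
  cand_q <- c(cand_q, S4Vectors::queryHits(fol))
  cand_s <- c(cand_s, S4Vectors::subjectHits(fol))
  pre <- GenomicRanges::precede(gp, gg, select = "all", ignore.strand = TRUE)
  cand_q <- c(cand_q, S4Vectors::queryHits(pre))
  cand_s <- c(cand_s, S4Vectors::subjectHits(pre))
  keep <- !duplicated(cbind(cand_q, cand_s))
  cand_q <- cand_q[keep]; cand_s <- cand_s[keep]
  if (length(cand_q) == 0) {
    attr(empty, "unassigned") <- nrow(peaks)
    return(empty)
  }
  d <- GenomicRanges::distance(gp[cand_q], gg[cand_s], ignore.strand = TRUE)
  ok <- !is.na(d) & d <= max_distance_bp
  cand_q <- cand_q[ok]; cand_s <- cand_s[ok]; d <- d[ok]
  if (length(cand_q) > 0) {
    dmin <- tapply(d, cand_q, min)
    is_min <- d == as.integer(dmin[as.character(cand_q)])
    cand_q <- cand_q[is_min]; cand_s <- cand_s[is_min]; d <- d[is_min]
  }
  n_tied <- table(cand_q)
  tie <- as.integer(n_tied[as.character(cand_q)]) > 1L
  relation <- ifelse(d == 0, "overlapping",
                     ifelse(peaks$end[cand_q] <= genes$start[cand_s],
                            "upstream", "downstream"))
  out <- data.frame(
    peak_index = cand_q,
    scaffold = peaks$scaffold[cand_q],
    peak_start = peaks$start[cand_q],
    peak_end = peaks$end[cand_q],
    gene_id = genes$gene_id[cand_s],
    distance_bp = as.integer(d),
    relation = relation,
    tie = tie,
    stringsAsFactors = FALSE)
  out <- out[order(out$peak_index, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- nrow(peaks) - length(unique(cand_q))
  out
}

#' Collapse assignments into a putative target gene set
#'
#' @param assignments Assignment `data.frame` from [nearest_gene()].
#' @param species_tag Namespace tag for the resulting set.
#' @param label Optional label; defaults to the tag.
#' @return A `gene_set` of deduplicated target gene ids.
#' @export
target_gene_set <- function(assignments, species_tag, label = species_tag) {
  ids <- if (is.null(assignments) || nrow(assignments) == 0) {
    character(0)
  } else {
    assignments$gene_id
  }
  gene_set(ids, species_tag, label)
}
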