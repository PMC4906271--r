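# Independent oracles, deliberately written with different algorithms and
# data representations than the package internals.

# --- brute-force IUPAC scanner -------------------------------------------
# Sequence N matches nothing; degenerate codes are expanded to base sets.
.oracle_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

.oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
            R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
            B = "V", D = "H", H = "D", V = "B")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

.oracle_match_fwd <- function(seq_chars, motif_chars) {
  L <- length(motif_chars)
  np <- length(seq_chars) - L + 1
  if (np < 1) return(integer(0))
  hits <- integer(0)
  for (i in seq_len(np)) {
    ok <- TRUE
    for (j in seq_len(L)) {
      if (!(seq_chars[i + j - 1] %in% .oracle_sets[[motif_chars[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L)  # 0-based
  }
  hits
}

# Reverse-strand hits found by scanning the reverse-complemented *sequence*
# and mapping coordinates back (a different route than the implementation,
# which reverse-complements the motif).
brute_scan <- function(consensus, sequence, both_strands = TRUE) {
  sc <- strsplit(sequence, "")[[1]]
  mc <- strsplit(consensus, "")[[1]]
  fwd <- .oracle_match_fwd(sc, mc)
  out <- data.frame(position = fwd,
                    strand = rep("+", length(fwd)))
  if (both_strands) {
    rc_chars <- strsplit(.oracle_revcomp(sequence), "")[[1]]
    rev_raw <- .oracle_match_fwd(rc_chars, mc)
    n <- length(sc); L <- length(mc)
    rev_pos <- n - rev_raw - L  # forward coordinate of the match start
    out <- rbind(out, data.frame(position = rev_pos,
                                 strand = rep("-", length(rev_pos))))
  }
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- brute-force nearest gene --------------------------------------------
.oracle_gap <- function(a_start, a_end, b_start, b_end) {
  max(0L, b_start - a_end, a_start - b_end)
}

brute_nearest <- function(peaks, genes, max_distance_bp) {
  rows <- list()
  for (i in seq_len(nrow(peaks))) {
    d <- rep(NA_integer_, nrow(genes))
    for (j in seq_len(nrow(genes))) {
      if (genes$scaffold[j] != peaks$scaffold[i]) next
      d[j] <- .oracle_gap(peaks$start[i], peaks$end[i],
                          genes$start[j], genes$end[j])
    }
    if (all(is.na(d))) next
    dmin <- min(d, na.rm = TRUE)
    if (dmin > max_distance_bp) next
    js <- which(!is.na(d) & d == dmin)
    for (j in js) {
      relation <- if (dmin == 0) "overlapping" else if
        (genes$start[j] >= peaks$end[i]) "upstream" else "downstream"
      rows[[length(rows) + 1]] <- data.frame(
        peak_index = i, scaffold = peaks$scaffold[i],
        peak_start = peaks$start[i], peak_end = peaks$end[i],
        gene_id = genes$gene_id[j], distance_bp = dmin,
        relation = relation, tie = length(js) > 1,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(out$peak_index, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- exhaustive hypergeometric tail --------------------------------------
# P(overlap >= k) by enumerating every size_b subset of the universe.
enum_hyper_tail <- function(k, size_a, size_b, universe) {
  if (size_b == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(universe, size_b)
  hits <- colSums(draws <= size_a)  # set A = 1..size_a
  mean(hits >= k)
}

# --- fixture builders ----------------------------------------------------
random_dna <- function(n, p_n = 0) {
  bases <- c("A", "C", "G", "T")
  s <- sample(bases, n, replace = TRUE)
  if (p_n > 0) {
    idx <- which(runif(n) < p_n)
    s[idx] <- "N"
  }
  paste(s, collapse = "")
}

empty_genes <- function() {
  data.frame(gene_id = character(0), scaffold = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             name = character(0), stringsAsFactors = FALSE)
}

make_peaks <- function(scaffold, start, end, score = 0,
                       summit_offset = NA_integer_, name = NA_character_,
                       replicate_ids = NA_character_) {
  data.frame(scaffold = scaffold, start = as.integer(start),
             end = as.integer(end), name = name, score = score,
             strand = "*", summit_offset = as.integer(summit_offset),
             replicate_ids = replicate_ids, stringsAsFactors = FALSE)
}

make_genes <- function(gene_id, scaffold, start, end) {
  data.frame(gene_id = gene_id, scaffold = scaffold,
             start = as.integer(start), end = as.integer(end),
             strand = "+", name = NA_character_, stringsAsFactors = FALSE)
}

small_sim_config <- function(seed, shared_target_fraction = 0.3,
                             de_fraction_2fold = 0.1, n_genes = 60L,
                             n_peaks = 40L) {
  synthetic_config(seed = seed, n_scaffolds = 2L,
                   scaffold_length_bp = 250000L, n_genes = n_genes,
                   n_peaks = n_peaks,
                   shared_target_fraction = shared_target_fraction,
                   de_fraction_2fold = de_fraction_2fold)
}
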