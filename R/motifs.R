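# Motif scanning and enrichment. Consensus motifs are matched by per-position
# IUPAC bitmasks; matrix motifs by log2-odds against a uniform background.
# A sequence 'N' never matches any non-N code, on either strand.

.iupac_match_positions <- function(enc, masks) {
  L <- length(masks)
  np <- length(enc) - L + 1L
  if (np < 1L) return(integer(0))
  ok <- rep(TRUE, np)
  for (j in seq_len(L)) {
    ok <- ok & bitwAnd(enc[j:(j + np - 1L)], masks[j]) > 0L
  }
  which(ok)
}

.pwm_scores <- function(enc, lo) {
  L <- nrow(lo)
  np <- length(enc) - L + 1L
  if (np < 1L) return(numeric(0))
  idx <- match(enc, c(1L, 2L, 4L, 8L))  # N -> NA -> score NA -> no hit
  s <- numeric(np)
  for (j in seq_len(L)) {
    s <- s + lo[j, ][idx[j:(j + np - 1L)]]
  }
  s
}

.revcomp_pwm <- function(lo) lo[rev(seq_len(nrow(lo))), rev(seq_len(ncol(lo))),
                                drop = FALSE]

#' Scan a sequence for motif hits
#'
#' Consensus mode reports every position where the IUPAC pattern matches
#' exactly; matrix mode reports positions whose log2-odds score against a
#' uniform background reaches the motif's threshold. Reverse-strand hits are
#' found by scanning with the reverse-complemented motif and are reported at
#' the forward coordinate of the match start.
#'
#' @param motif A `motif_model`.
#' @param sequence Character scalar over A,C,G,T,N.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return `data.frame` with columns `motif_id`, `tf_name`, `position`
#'   (0-based start within `sequence`), `strand`, `score` (1 in consensus
#'   mode). A motif longer than the sequence yields zero rows.
#' @export
scan_motif <- function(motif, sequence, both_strands = TRUE) {
  stopifnot(inherits(motif, "motif_model"))
  enc <- encode_dna(sequence)
  if (any(enc == 0L)) stop("sequence contains characters outside A,C,G,T,N")
  strands <- if (both_strands) c("+", "-") else "+"
  rows <- lapply(strands, function(st) {
    if (motif$type == "iupac") {
      masks <- if (st == "+") iupac_masks(motif$consensus) else
        iupac_masks(revcomp(motif$consensus))
      pos <- .iupac_match_positions(enc, masks)
      score <- rep(1, length(pos))
    } else {
      lo <- if (st == "+") motif$logodds else .revcomp_pwm(motif$logodds)
      s <- .pwm_scores(enc, lo)
      pos <- which(!is.na(s) & s >= motif$score_threshold)
      score <- s[pos]
    }
    if (length(pos) == 0) return(NULL)
    data.frame(motif_id = motif$motif_id, tf_name = motif$tf_name,
               position = pos - 1L, strand = st, score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(motif_id = character(0), tf_name = character(0),
                      position = integer(0), strand = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  } else {
    out <- out[order(out$position, out$strand), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# hit count over a set of sequences, both strands; sequences are joined with
# a single N so no window can span a boundary (N matches nothing)
.motif_hit_count <- function(motif, seqs) {
  if (length(seqs) == 0) return(0L)
  nrow(scan_motif(motif, paste(seqs, collapse = "N"), both_strands = TRUE))
}

#' Run code with a temporary RNG seed
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`; the caller's RNG state is restored.
#' @export
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Precompute the non-coding space of a genome: per-scaffold complement of
# gene bodies, as a table of 0-based half-open intervals with cumulative
# widths for uniform position draws.
.noncoding_space <- function(genome, genes) {
  rows <- lapply(names(genome), function(sc) {
    len <- nchar(genome[[sc]])
    g <- genes[genes$scaffold == sc, , drop = FALSE]
    if (nrow(g) == 0) {
      return(data.frame(scaffold = sc, start = 0L, end = len))
    }
    ir <- IRanges::reduce(IRanges::IRanges(g$start + 1L, g$end))
    gaps <- IRanges::gaps(ir, start = 1L, end = len)
    if (length(gaps) == 0) return(NULL)
    data.frame(scaffold = sc, start = IRanges::start(gaps) - 1L,
               end = IRanges::end(gaps), stringsAsFactors = FALSE)
  })
  sp <- do.call(rbind, rows)
  if (is.null(sp) || nrow(sp) == 0) {
    stop("genome has no non-coding space outside gene bodies")
  }
  sp$width <- sp$end - sp$start
  sp$cum <- cumsum(as.numeric(sp$width))
  sp
}

.draw_noncoding <- function(genome, space, lengths, max_attempts) {
  total <- space$cum[nrow(space)]
  out <- character(length(lengths))
  attempts <- 0L
  for (i in seq_along(lengths)) {
    len <- lengths[i]
    repeat {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("insufficient non-coding space: gave up after ", max_attempts,
             " rejection attempts")
      }
      u <- floor(stats::runif(1, min = 0, max = total))
      r <- findInterval(u, c(0, space$cum), rightmost.closed = FALSE)
      off <- u - c(0, space$cum)[r]
      if (off + len > space$width[r]) next
      s0 <- space$start[r] + off
      seq <- substr(genome[[space$scaffold[r]]], s0 + 1, s0 + len)
      if (grepl("N", seq, fixed = TRUE)) next
      out[i] <- seq
      break
    }
  }
  out
}

#' Sample random non-coding sequences from a genome
#'
#' Draws sequences uniformly from scaffold positions whose intervals do not
#' intersect any gene body and contain no N. Deterministic under `seed`.
#'
#' @param genome Named character vector of scaffold sequences.
#' @param genes Gene `data.frame` (see [read_gff3()]); may have zero rows.
#' @param n Number of sequences; must equal `length(lengths)`.
#' @param lengths Integer vector of sequence lengths to draw.
#' @param seed Integer seed.
#' @return Character vector of `n` sequences. Fails with an error when no
#'   accepting position is found within `10 * n` rejection attempts.
#' @export
sample_noncoding <- function(genome, genes, n, lengths, seed) {
  stopifnot(n == length(lengths), all(lengths >= 1))
  space <- .noncoding_space(genome, genes)
  with_seed(seed, .draw_noncoding(genome, space, lengths,
                                  max_attempts = 10L * n))
}

#' Motif fold-enrichment against sampled non-coding background
#'
#' The foreground density is the number of motif hits (both strands) per kb
#' over the concatenated foreground sequences. Each background draw is a
#' length-matched set (the same multiset of lengths as the foreground) of
#' random non-coding sequences; the fold is foreground density over mean
#' background density and the empirical p-value is
#' `(1 + #draws >= foreground) / (n_draws + 1)`, so it is never 0.
#'
#' @param fg_sequences Non-empty character vector of foreground sequences
#'   (e.g. ChIP peak sequences).
#' @param motif A `motif_model`.
#' @param genome Named character vector of scaffold sequences.
#' @param genes Gene `data.frame` whose bodies are excluded from background.
#' @param n_draws Number of background draws (>= 20; default 200).
#' @param seed Integer seed for the background sampling.
#' @return Object of class `fold_enrichment`: `motif_id`, `fg_density`,
#'   `bg_mean_density`, `bg_sd`, `fold`, `fold_defined` (`FALSE` when the
#'   background mean is 0 with foreground hits present), `empirical_p`,
#'   `n_background_draws`, `fg_hits`, `fg_kb`.
#' @export
fold_enrichment <- function(fg_sequences, motif, genome, genes,
                            n_draws = 200L, seed = 1L) {
  if (length(fg_sequences) == 0) stop("foreground is empty")
  stopifnot(n_draws >= 20)
  fg_kb <- sum(nchar(fg_sequences)) / 1000
  fg_hits <- .motif_hit_count(motif, fg_sequences)
  fg_density <- fg_hits / fg_kb
  lens <- nchar(fg_sequences)
  space <- .noncoding_space(genome, genes)
  bg_density <- with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      draws <- .draw_noncoding(genome, space, lens,
                               max_attempts = 10L * length(lens))
      .motif_hit_count(motif, draws) / fg_kb
    }, numeric(1))
  })
  bg_mean <- mean(bg_density)
  defined <- bg_mean > 0 || fg_hits == 0
  fold <- if (bg_mean > 0) fg_density / bg_mean else if (fg_hits > 0) Inf else 0
  p <- (1 + sum(bg_density >= fg_density)) / (n_draws + 1)
  structure(list(motif_id = motif$motif_id, fg_density = fg_density,
                 bg_mean_density = bg_mean, bg_sd = stats::sd(bg_density),
                 fold = fold, fold_defined = defined, empirical_p = p,
                 n_background_draws = n_draws, fg_hits = fg_hits,
                 fg_kb = fg_kb),
            class = "fold_enrichment")
}

#' @export
print.fold_enrichment <- function(x, ...) {
  cat(sprintf(
    "fold_enrichment %s: fg %.3g/kb vs bg %.3g/kb (sd %.3g); fold %.3g, p = %.3g (%d draws)\n",
    x$motif_id, x$fg_density, x$bg_mean_density, x$bg_sd, x$fold,
    x$empirical_p, x$n_background_draws))
  invisible(x)
}

.canonical_kmers <- function(seqs, k) {
  kmers <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    starts <- seq_len(n - k + 1L)
    substring(s, starts, starts + k - 1L)
  }), use.names = FALSE)
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Simple k-mer over-representation between two sequence sets
#'
#' Counts canonical k-mers (the lexicographic minimum of a k-mer and its
#' reverse complement) per kb in foreground and background; the background
#' frequency gets a pseudo-frequency of 0.5 occurrences to keep folds finite.
#' Ranked by fold descending, ties broken lexicographically.
#'
#' @param fg_sequences,bg_sequences Character vectors of sequences.
#' @param k k-mer size, between 4 and 12, no longer than the shortest
#'   sequence.
#' @param top_n Number of top rows to return (`Inf` for all).
#' @return `data.frame` with `kmer`, `fg_count`, `bg_count`,
#'   `fg_freq_per_kb`, `bg_freq_per_kb`, `fold`.
#' @export
kmer_enrichment <- function(fg_sequences, bg_sequences, k, top_n = 20L) {
  if (k < 4 || k > 12) stop("k must be between 4 and 12")
  if (length(fg_sequences) == 0 || length(bg_sequences) == 0) {
    stop("both sequence sets must be non-empty")
  }
  if (k > min(nchar(c(fg_sequences, bg_sequences)))) {
    stop("k (", k, ") exceeds the shortest sequence")
  }
  fg_tab <- table(.canonical_kmers(fg_sequences, k))
  bg_tab <- table(.canonical_kmers(bg_sequences, k))
  fg_kb <- sum(nchar(fg_sequences)) / 1000
  bg_kb <- sum(nchar(bg_sequences)) / 1000
  kmers <- sort(unique(c(names(fg_tab), names(bg_tab))))
  fg_n <- ifelse(kmers %in% names(fg_tab), as.integer(fg_tab[kmers]), 0L)
  bg_n <- ifelse(kmers %in% names(bg_tab), as.integer(bg_tab[kmers]), 0L)
  fg_f <- fg_n / fg_kb
  bg_f <- (bg_n + 0.5) / bg_kb
  out <- data.frame(kmer = kmers, fg_count = fg_n, bg_count = bg_n,
                    fg_freq_per_kb = fg_f, bg_freq_per_kb = bg_f,
                    fold = fg_f / bg_f, stringsAsFactors = FALSE)
  out <- out[order(-out$fold, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Binding-site array around an anchor position
#'
#' Scans every motif of a library (both strands) and keeps the hits whose
#' start lies within `[anchor - window, anchor + window]`, reported as signed
#' offsets of the hit start from the anchor, sorted by offset then TF name.
#'
#' @param sequence Character scalar over A,C,G,T,N.
#' @param anchor_midpoint 0-based anchor position within the sequence
#'   (e.g. a peak summit).
#' @param library List of `motif_model` objects.
#' @param window_bp Half-window size in bp (>= 0; default 500).
#' @return Object of class `binding_site_array`: `anchor_midpoint`,
#'   `window_bp` and `hits` (`data.frame` with `tf_name`, `motif_id`,
#'   `offset`, `strand`).
#' @export
anchor_array <- function(sequence, anchor_midpoint, library,
                         window_bp = 500L) {
  stopifnot(anchor_midpoint >= 0, anchor_midpoint < nchar(sequence),
            window_bp >= 0)
  rows <- lapply(library, function(m) {
    h <- scan_motif(m, sequence, both_strands = TRUE)
    h <- h[abs(h$position - anchor_midpoint) <= window_bp, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    data.frame(tf_name = h$tf_name, motif_id = h$motif_id,
               offset = h$position - anchor_midpoint, strand = h$strand,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (is.null(hits)) {
    hits <- data.frame(tf_name = character(0), motif_id = character(0),
                       offset = integer(0), strand = character(0),
                       stringsAsFactors = FALSE)
  } else {
    hits <- hits[order(hits$offset, hits$tf_name), , drop = FALSE]
    rownames(hits) <- NULL
  }
  structure(list(anchor_midpoint = anchor_midpoint, window_bp = window_bp,
                 hits = hits),
            class = "binding_site_array")
}

#' @export
print.binding_site_array <- function(x, ...) {
  cat(sprintf("binding_site_array: anchor %d, window %d bp, %d hits\n",
              x$anchor_midpoint, x$window_bp, nrow(x$hits)))
  if (nrow(x$hits) > 0) {
    print(utils::head(x$hits, 20))
  }
  invisible(x)
}

#' Binding-site arrays around peak anchors in a genome
#'
#' The anchor is the peak summit when present, otherwise the interval
#' midpoint `floor((start + end) / 2)`.
#'
#' @param genome Named character vector of scaffold sequences.
#' @param peaks Peak `data.frame` (see [read_bed()]).
#' @param library List of `motif_model` objects.
#' @param window_bp Half-window size in bp.
#' @return List of `binding_site_array` objects, one per peak, each with
#'   extra fields `scaffold` and `anchor_genomic` (0-based genome position).
#' @export
peak_anchor_arrays <- function(genome, peaks, library, window_bp = 500L) {
  max_len <- max(vapply(library, `[[`, numeric(1), "length"))
  lapply(seq_len(nrow(peaks)), function(i) {
    sc <- peaks$scaffold[i]
    slen <- nchar(genome[[sc]])
    mid <- if (!is.na(peaks$summit_offset[i])) {
      peaks$start[i] + peaks$summit_offset[i]
    } else {
      floor((peaks$start[i] + peaks$end[i]) / 2)
    }
    lo <- max(0L, mid - window_bp)
    hi <- min(slen, mid + window_bp + max_len)
    arr <- anchor_array(substr(genome[[sc]], lo + 1, hi), mid - lo,
                        library, window_bp)
    arr$scaffold <- sc
    arr$anchor_genomic <- mid
    arr
  })
}

#' Compare two binding-site arrays at the TF level
#'
#' Partitions the TFs hit in either array into shared / A-only / B-only and,
#' for shared TFs, pairs every offset in A with the nearest offset in B.
#'
#' @param a,b `binding_site_array` objects.
#' @return Object of class `array_comparison`: `shared_tfs`, `a_only_tfs`,
#'   `b_only_tfs` (sorted character vectors) and `per_tf_offset_pairs`
#'   (named list of `data.frame(offset_a, offset_b)`).
#' @export
compare_arrays <- function(a, b) {
  stopifnot(inherits(a, "binding_site_array"),
            inherits(b, "binding_site_array"))
  tfs_a <- unique(a$hits$tf_name)
  tfs_b <- unique(b$hits$tf_name)
  shared <- sort(intersect(tfs_a, tfs_b))
  pairs <- lapply(shared, function(tf) {
    oa <- a$hits$offset[a$hits$tf_name == tf]
    ob <- b$hits$offset[b$hits$tf_name == tf]
    data.frame(offset_a = oa,
               offset_b = vapply(oa, function(o) ob[which.min(abs(ob - o))],
                                 numeric(1)))
  })
  names(pairs) <- shared
  structure(list(shared_tfs = shared,
                 a_only_tfs = sort(setdiff(tfs_a, tfs_b)),
                 b_only_tfs = sort(setdiff(tfs_b, tfs_a)),
                 per_tf_offset_pairs = pairs),
            class = "array_comparison")
}

#' @export
print.array_comparison <- function(x, ...) {
  cat("array_comparison:\n")
  cat("  shared:", paste(x$shared_tfs, collapse = ", "), "\n")
  cat("  A only:", paste(x$a_only_tfs, collapse = ", "), "\n")
  cat("  B only:", paste(x$b_only_tfs, collapse = ", "), "\n")
  invisible(x)
}

#' Extract interval sequences from a genome
#'
#' @param genome Named character vector of scaffold sequences.
#' @param intervals `data.frame` with `scaffold`, `start`, `end` (0-based
#'   half-open).
#' @return Character vector of sequences.
#' @export
interval_sequences <- function(genome, intervals) {
  vapply(seq_len(nrow(intervals)), function(i) {
    substr(genome[[intervals$scaffold[i]]], intervals$start[i] + 1,
           intervals$end[i])
  }, character(1))
}

#' Plant motif instances into sequences
#'
#' Replaces `n` non-overlapping random stretches with concrete instances of
#' the consensus (degenerate codes are instantiated uniformly at random;
#' instances are inserted on a random strand). Used by the synthetic-data
#' generator and in calibration experiments.
#'
#' @param seqs Character vector of sequences.
#' @param consensus IUPAC consensus string to plant.
#' @param n Number of instances to plant across all sequences.
#' @param seed Integer seed.
#' @return List with `seqs` (modified sequences) and `sites`
#'   (`data.frame(seq_index, position, strand)`, 0-based positions).
#' @export
plant_motif <- function(seqs, consensus, n, seed) {
  L <- nchar(consensus)
  codes <- iupac_codes()
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  with_seed(seed, {
    occupied <- lapply(seqs, function(s) integer(0))
    sites <- vector("list", n)
    weights <- pmax(nchar(seqs) - L + 1L, 0L)
    if (n > 0 && sum(weights) == 0) stop("sequences shorter than the motif")
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(100L)) {
        si <- sample.int(length(seqs), 1L, prob = weights)
        pos <- sample.int(weights[si], 1L) - 1L  # 0-based
        if (any(abs(occupied[[si]] - pos) < L)) next
        inst <- paste(vapply(chars, function(ch) {
          set <- codes[[ch]]
          set[sample.int(length(set), 1L)]
        }, character(1)), collapse = "")
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        if (strand == "-") inst <- revcomp(inst)
        substr(seqs[si], pos + 1L, pos + L) <- inst
        occupied[[si]] <- c(occupied[[si]], pos)
        sites[[i]] <- data.frame(seq_index = si, position = pos,
                                 strand = strand)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place motif instance ", i,
             " without overlap after 100 attempts")
      }
    }
    list(seqs = seqs,
         sites = do.call(rbind, c(sites, list(make.row.names = FALSE))))
  })
}
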