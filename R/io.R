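# File readers/writers. Internal coordinates are uniformly 0-based half-open:
# BED is taken verbatim, GFF3 (1-based closed) is shifted on read and write.

#' IUPAC nucleotide codes
#'
#' The 15 standard degenerate DNA codes, each mapped to the set of
#' unambiguous bases it stands for.
#' @return Named list of character vectors.
#' @keywords internal
iupac_codes <- function() {
  list(A = "A", C = "C", G = "G", T = "T",
       R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
       K = c("G", "T"), M = c("A", "C"),
       B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
       V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
}

# base -> bit (A=1, C=2, G=4, T=8); sequence 'N' gets bit 16 so that it never
# matches any degenerate code (codes only carry A/C/G/T bits).
.base_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 16L)

# 128-slot lookup from ASCII code to base bit (0 for anything else)
.seq_bit_lut <- local({
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 4L; lut[utf8ToInt("T")] <- 8L
  lut[utf8ToInt("N")] <- 16L
  lut
})

#' Encode a DNA string as base bits
#'
#' @param seq Character scalar over A,C,G,T,N (upper case).
#' @return Integer vector, one bit code per base.
#' @keywords internal
encode_dna <- function(seq) {
  .seq_bit_lut[utf8ToInt(seq)]
}

#' Bitmasks for an IUPAC consensus string
#'
#' @param consensus Character scalar of IUPAC codes.
#' @return Integer vector of per-position masks over the A/C/G/T bits.
#' @keywords internal
iupac_masks <- function(consensus) {
  codes <- iupac_codes()
  chars <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(codes))
  if (length(bad) > 0) {
    stop("unknown IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  }
  vapply(chars, function(ch) sum(.base_bits[codes[[ch]]]), integer(1),
         USE.NAMES = FALSE)
}

.iupac_complement <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", D = "H", H = "D", V = "B", N = "N")

#' Reverse complement of a DNA or IUPAC string
#'
#' @param x Character vector of sequences (A,C,G,T,N or any IUPAC code).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(paste(names(.iupac_complement), collapse = ""),
                 paste(.iupac_complement, collapse = ""),
                 toupper(x))
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Read a FASTA file
#'
#' Residues are case-folded to upper case on read and restricted to the
#' alphabet A,C,G,T,N; violations are reported with the offending line number.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector: names are record ids (first whitespace
#'   token of the header), values are upper-case residue strings, in file
#'   order.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  ids <- character(0)
  chunks <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      id <- sub("\\s.*$", "", sub("^>", "", ln))
      if (nchar(id) == 0) {
        stop(sprintf("%s: malformed FASTA header at line %d", path, i))
      }
      ids <- c(ids, id)
      cur <- length(ids)
      chunks[[cur]] <- character(0)
    } else if (nzchar(trimws(ln))) {
      if (is.null(cur)) {
        stop(sprintf("%s: sequence before any header at line %d", path, i))
      }
      res <- toupper(trimws(ln))
      bad <- regmatches(res, regexpr("[^ACGTN]", res))
      if (length(bad) > 0) {
        stop(sprintf("%s: illegal character '%s' at line %d", path, bad, i))
      }
      chunks[[cur]] <- c(chunks[[cur]], res)
    }
  }
  seqs <- vapply(chunks, paste, character(1), collapse = "")
  if (any(!nzchar(seqs))) {
    stop(sprintf("%s: empty sequence for record '%s'",
                 path, ids[which(!nzchar(seqs))[1]]))
  }
  names(seqs) <- ids
  seqs
}

#' Write a FASTA file
#'
#' @param seqs Named character vector as returned by [read_fasta()].
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a BED file of ChIP peaks
#'
#' BED coordinates are 0-based half-open and are kept verbatim. Columns:
#' scaffold, start, end, then optionally name (4), score (5), strand (6) and a
#' documented seventh column holding the summit offset from the peak start.
#' Missing scores default to 0.
#'
#' @param path Path to a BED3+ file. Lines starting with `#`, `track` or
#'   `browser` are ignored.
#' @param replicate_id Optional replicate label attached to every peak.
#' @return A `data.frame` with columns `scaffold`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit_offset`, `replicate_ids`.
#' @export
read_bed <- function(path, replicate_id = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("%s: fewer than 3 BED columns at line %d", path, i))
    }
    if (!grepl("^-?[0-9]+$", f[2]) || !grepl("^-?[0-9]+$", f[3])) {
      stop(sprintf("%s: non-integer coordinate at line %d", path, i))
    }
    start <- as.integer(f[2]); end <- as.integer(f[3])
    if (start < 0 || start >= end) {
      stop(sprintf("%s: invalid interval [%d,%d) at line %d",
                   path, start, end, i))
    }
    score <- if (length(f) >= 5 && nzchar(f[5]) && f[5] != ".") {
      as.numeric(f[5])
    } else 0
    if (is.na(score) || score < 0) {
      stop(sprintf("%s: invalid score at line %d", path, i))
    }
    summit <- if (length(f) >= 7 && nzchar(f[7]) && f[7] != ".") {
      as.integer(f[7])
    } else NA_integer_
    if (!is.na(summit) && (summit < 0 || summit >= end - start)) {
      stop(sprintf("%s: summit offset outside peak at line %d", path, i))
    }
    j <- j + 1L
    out[[j]] <- data.frame(
      scaffold = f[1], start = start, end = end,
      name = if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_,
      score = score,
      strand = if (length(f) >= 6 && f[6] %in% c("+", "-")) f[6] else "*",
      summit_offset = summit,
      replicate_ids = replicate_id,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write peaks to a BED file
#'
#' Inverse of [read_bed()]: coordinates are written verbatim (0-based
#' half-open), with name, score, strand and the summit-offset column 7.
#'
#' @param peaks Peak `data.frame` (see [read_bed()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(peaks, path) {
  fmt_na <- function(x) ifelse(is.na(x), ".", as.character(x))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%s",
                   peaks$scaffold, peaks$start, peaks$end,
                   fmt_na(peaks$name), fmt_na(peaks$score),
                   fmt_na(peaks$strand), fmt_na(peaks$summit_offset))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only features of type `gene` are kept. GFF3 1-based closed coordinates are
#' converted to the internal 0-based half-open convention (`start-1`, `end`).
#' The gene id is taken from the `ID` attribute; a missing or duplicated ID is
#' an error.
#'
#' @param path Path to a GFF3 file.
#' @return A `data.frame` with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `name`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  j <- 0L
  for (i in which(keep)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop(sprintf("%s: fewer than 9 GFF3 columns at line %d", path, i))
    }
    if (tolower(f[3]) != "gene") next
    if (!grepl("^[0-9]+$", f[4]) || !grepl("^[0-9]+$", f[5])) {
      stop(sprintf("%s: non-integer coordinate at line %d", path, i))
    }
    start1 <- as.integer(f[4]); end1 <- as.integer(f[5])
    if (start1 < 1 || end1 < start1) {
      stop(sprintf("%s: invalid gene coordinates at line %d", path, i))
    }
    attrs <- strsplit(f[9], ";", fixed = TRUE)[[1]]
    kv <- strsplit(attrs, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, character(1), 1)
    vals <- vapply(kv, function(x) if (length(x) >= 2) x[2] else "", character(1))
    id <- vals[match("ID", keys)]
    if (is.na(id) || !nzchar(id)) {
      stop(sprintf("%s: gene without ID attribute at line %d", path, i))
    }
    nm <- vals[match("Name", keys)]
    j <- j + 1L
    out[[j]] <- data.frame(
      gene_id = id, scaffold = f[1],
      start = start1 - 1L, end = end1,
      strand = if (f[7] %in% c("+", "-")) f[7] else "*",
      name = if (is.na(nm)) NA_character_ else nm,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, c(out[seq_len(j)], list(make.row.names = FALSE)))
  if (is.null(genes)) {
    stop(sprintf("%s: no gene features found", path))
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    stop(sprintf("%s: duplicate gene ID '%s'", path, dup[1]))
  }
  genes
}

#' Write gene models to a GFF3 file
#'
#' Internal 0-based half-open coordinates are converted back to GFF3 1-based
#' closed (`start+1`, `end`), so a read/write round trip preserves the printed
#' coordinates bit-exactly.
#'
#' @param genes Gene `data.frame` (see [read_gff3()]).
#' @param path Output path.
#' @param source Value for the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(genes, path, source = "crossbind") {
  attrs <- ifelse(is.na(genes$name),
                  sprintf("ID=%s", genes$gene_id),
                  sprintf("ID=%s;Name=%s", genes$gene_id, genes$name))
  lines <- sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\t%s",
                   genes$scaffold, source, genes$start + 1L, genes$end,
                   ifelse(genes$strand %in% c("+", "-"), genes$strand, "."),
                   attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Construct a motif model
#'
#' A motif is either an IUPAC consensus string or a position probability
#' matrix. Matrices are regularized with a pseudocount of 0.01 per cell and
#' row-normalized; scanning scores positions by log2-odds against a uniform
#' background, with the threshold defaulting to 80% of the motif's maximum
#' achievable score.
#'
#' @param motif_id Unique motif identifier.
#' @param tf_name Name of the transcription factor the motif belongs to.
#' @param iupac IUPAC consensus string (consensus mode).
#' @param matrix Numeric matrix, length x 4 (columns A,C,G,T), of counts or
#'   probabilities (matrix mode).
#' @param score_threshold Log2-odds score threshold (matrix mode only);
#'   `NULL` selects the 80%-of-maximum default.
#' @return An object of class `motif_model`.
#' @export
motif_model <- function(motif_id, tf_name, iupac = NULL, matrix = NULL,
                        score_threshold = NULL) {
  stopifnot(is.character(motif_id), nzchar(motif_id),
            is.character(tf_name), nzchar(tf_name))
  if (is.null(iupac) == is.null(matrix)) {
    stop("motif '", motif_id, "': supply exactly one of iupac or matrix")
  }
  if (!is.null(iupac)) {
    iupac <- toupper(iupac)
    iupac_masks(iupac)  # validates codes
    m <- list(motif_id = motif_id, tf_name = tf_name, type = "iupac",
              consensus = iupac, length = nchar(iupac))
  } else {
    matrix <- as.matrix(matrix)
    if (ncol(matrix) != 4) {
      stop("motif '", motif_id, "': matrix must have 4 columns (A,C,G,T)")
    }
    if (any(rowSums(matrix) <= 0)) {
      stop("motif '", motif_id, "': matrix row sums to zero")
    }
    prob <- matrix + 0.01
    prob <- prob / rowSums(prob)
    colnames(prob) <- c("A", "C", "G", "T")
    lo <- log2(prob / 0.25)
    max_score <- sum(apply(lo, 1, max))
    thr <- if (is.null(score_threshold)) 0.8 * max_score else score_threshold
    m <- list(motif_id = motif_id, tf_name = tf_name, type = "pwm",
              prob = prob, logodds = lo, max_score = max_score,
              score_threshold = thr, length = nrow(prob))
  }
  class(m) <- "motif_model"
  m
}

#' @export
print.motif_model <- function(x, ...) {
  if (x$type == "iupac") {
    cat(sprintf("motif_model %s (%s): consensus %s\n",
                x$motif_id, x$tf_name, x$consensus))
  } else {
    cat(sprintf("motif_model %s (%s): %d bp matrix, threshold %.2f (max %.2f)\n",
                x$motif_id, x$tf_name, x$length, x$score_threshold, x$max_score))
  }
  invisible(x)
}

#' Read a motif library from JSON
#'
#' The library is a JSON array of motif objects. Each object has fields `id`
#' and `tf` plus either `iupac` (a consensus string) or `matrix` (an array of
#' length-4 rows in A,C,G,T order) with optional `threshold`. Matrices are
#' normalized as described in [motif_model()].
#'
#' @param path Path to a motif JSON file.
#' @return List of `motif_model` objects.
#' @export
read_motif_library <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) stop(sprintf("%s: empty motif library", path))
  lapply(raw, function(m) {
    if (is.null(m$id) || is.null(m$tf)) {
      stop(sprintf("%s: motif entry without id or tf", path))
    }
    if (!is.null(m$iupac)) {
      motif_model(m$id, m$tf, iupac = m$iupac)
    } else if (!is.null(m$matrix)) {
      mat <- do.call(rbind, lapply(m$matrix, unlist))
      motif_model(m$id, m$tf, matrix = mat,
                  score_threshold = m$threshold)
    } else {
      stop(sprintf("%s: motif '%s' has neither iupac nor matrix", path, m$id))
    }
  })
}

#' Bundled default motif library
#'
#' IUPAC approximations of the binding preferences used throughout the
#' package: the Hox/Ubx core `TAAT`, the extended Ubx site `ATAATS`
#' (S = G or C), Adf-1 `TGGCTGCCGTCGCGAT`, the two MAD1 sites `GCCGTCGC`
#' (fly form, contained in the Adf-1 site) and `GCTGCCCGCCGC` (bee form),
#' and the GAGA-factor repeat `GAGAG`.
#'
#' @return List of `motif_model` objects.
#' @export
default_motif_library <- function() {
  read_motif_library(system.file("extdata", "tf_motifs.json",
                                 package = "crossbind", mustWork = TRUE))
}

#' Read an ortholog table
#'
#' Tab-separated, two columns: species gene id, reference gene id; `#` lines
#' are comments. A species gene may map to several reference genes.
#'
#' @param path Path to the TSV file.
#' @return Named list: species gene id -> character vector of reference ids.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("species_id", "ref_id"),
                          colClasses = "character")
  if (any(!nzchar(df$species_id)) || any(!nzchar(df$ref_id))) {
    stop(sprintf("%s: empty gene id in ortholog table", path))
  }
  m <- split(df$ref_id, df$species_id)
  lapply(m, unique)
}

#' Write an ortholog table
#' @param map Named list as returned by [read_ortholog_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ortholog_map <- function(map, path) {
  sp <- rep(names(map), lengths(map))
  writeLines(c("# species_gene_id\treference_gene_id",
               sprintf("%s\t%s", sp, unlist(map, use.names = FALSE))), path)
  invisible(path)
}

#' Read a functional-category annotation table
#'
#' Tab-separated: gene id, category id, optional category label.
#'
#' @param path Path to the TSV file.
#' @return An `annotation_table`: list with `assignments` (named list gene id
#'   -> character vector of category ids) and `labels` (named character
#'   vector; categories never seen with a label are labelled by their id).
#' @export
read_annotation_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  gene <- vapply(parts, `[`, character(1), 1)
  cat_id <- vapply(parts, `[`, character(1), 2)
  label <- vapply(parts, function(x) if (length(x) >= 3) x[3] else NA_character_,
                  character(1))
  if (any(is.na(cat_id))) stop(sprintf("%s: row without category id", path))
  labs <- tapply(label, cat_id, function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 0) x[1] else NA_character_
  })
  labs <- vapply(names(labs), function(k) {
    if (is.na(labs[[k]])) k else labs[[k]]
  }, character(1))
  annotation_table(split(cat_id, gene), labs)
}

#' Construct an annotation table
#' @param assignments Named list: gene id -> character vector of category ids.
#' @param labels Optional named character vector of category labels; any
#'   referenced category without a label entry gets its id as label.
#' @return An object of class `annotation_table`.
#' @export
annotation_table <- function(assignments, labels = NULL) {
  assignments <- lapply(assignments, unique)
  cats <- unique(unlist(assignments, use.names = FALSE))
  if (is.null(labels)) labels <- character(0)
  missing <- setdiff(cats, names(labels))
  add <- structure(missing, names = missing)
  labels <- c(labels, add)
  structure(list(assignments = assignments, labels = labels),
            class = "annotation_table")
}

#' Write an annotation table
#' @param annotation An `annotation_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(annotation, path) {
  gene <- rep(names(annotation$assignments),
              lengths(annotation$assignments))
  cat_id <- unlist(annotation$assignments, use.names = FALSE)
  writeLines(c("# gene_id\tcategory_id\tlabel",
               sprintf("%s\t%s\t%s", gene, cat_id, annotation$labels[cat_id])),
             path)
  invisible(path)
}

#' Read a two-condition expression table
#'
#' Tab-separated: gene id, value in condition 1, value in condition 2.
#'
#' @param path Path to the TSV file.
#' @return `data.frame` with columns `gene_id`, `value1`, `value2`.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          col.names = c("gene_id", "value1", "value2"),
                          colClasses = c("character", "numeric", "numeric"))
  if (any(!is.finite(df$value1)) || any(!is.finite(df$value2)) ||
      any(df$value1 < 0) || any(df$value2 < 0)) {
    stop(sprintf("%s: expression values must be finite and non-negative", path))
  }
  df
}

#' Write a two-condition expression table
#' @param expr `data.frame` with columns `gene_id`, `value1`, `value2`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(expr, path) {
  writeLines(c("# gene_id\tcondition1\tcondition2",
               sprintf("%s\t%.6g\t%.6g", expr$gene_id, expr$value1,
                       expr$value2)), path)
  invisible(path)
}
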