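# Motif and promoter input: JASPAR PFM parsing, PWM construction and
# validation, promoter extraction from a genome FASTA plus a TSS BED.

#' Construct a position weight matrix (PWM) object
#'
#' Converts a count (position frequency) matrix into a probability matrix by
#' adding a pseudocount to every cell and normalizing each position (row) to
#' sum to one. Probabilities are strictly positive whenever `pseudocount > 0`.
#'
#' @param counts numeric matrix, either 4 x width (JASPAR layout, rows
#'   A/C/G/T) or width x 4. Negative entries are an error.
#' @param tf_id identifier of the motif/TF.
#' @param pseudocount nonnegative value added to every cell before
#'   normalization (default 1).
#' @param background length-4 base composition used for log-odds scoring;
#'   defaults to uniform.
#' @param name optional secondary name (JASPAR header second token).
#' @return An object of class `pwm` with fields `tf_id`, `name`, `width`,
#'   `probs` (width x 4, rows sum to 1), `counts`, `pseudocount`,
#'   `background`.
#' @examples
#' m <- rbind(A = c(10, 0), C = c(0, 10), G = c(0, 0), T = c(0, 0))
#' p <- pwm(m, "toy")
#' p$probs[1, "A"]  # 11/14
#' @export
pwm <- function(counts, tf_id, pseudocount = 1, background = rep(0.25, 4),
                name = tf_id) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("PWM '%s': counts must be a numeric matrix", tf_id)
  if (nrow(counts) == 4L && ncol(counts) != 4L) counts <- t(counts)
  if (ncol(counts) != 4L)
    stopf("PWM '%s': count matrix must have 4 nucleotide rows or columns",
          tf_id)
  if (any(counts < 0)) stopf("PWM '%s': negative counts", tf_id)
  if (any(!is.finite(counts))) stopf("PWM '%s': non-finite counts", tf_id)
  if (pseudocount < 0) stopf("PWM '%s': pseudocount must be >= 0", tf_id)
  colnames(counts) <- DNA_BASES
  adj <- counts + pseudocount
  rs <- rowSums(adj)
  if (any(rs <= 0))
    stopf("PWM '%s': zero column sum with zero pseudocount", tf_id)
  probs <- adj / rs
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-9)
    stopf("PWM '%s': background must be 4 positive values summing to 1",
          tf_id)
  obj <- structure(
    list(tf_id = as.character(tf_id), name = as.character(name),
         width = nrow(probs), probs = probs, counts = counts,
         pseudocount = pseudocount,
         background = setNames(background, DNA_BASES)),
    class = "pwm")
  validate_pwm(obj)
  obj
}

#' Validate PWM invariants
#' @param x a `pwm` object.
#' @return `x`, invisibly; errors when an invariant is violated.
#' @export
validate_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  if (x$width < 1L) stopf("PWM '%s': empty matrix", x$tf_id)
  if (any(abs(rowSums(x$probs) - 1) > 1e-9))
    stopf("PWM '%s': probability rows must sum to 1", x$tf_id)
  if (x$pseudocount > 0 && any(x$probs <= 0))
    stopf("PWM '%s': nonpositive probability after pseudocount", x$tf_id)
  if (abs(sum(x$background) - 1) > 1e-9)
    stopf("PWM '%s': background must sum to 1", x$tf_id)
  invisible(x)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s (%s), width %d, pseudocount %g\n",
              x$tf_id, x$name, x$width, x$pseudocount))
  invisible(x)
}

#' Reverse complement of a PWM
#' @param x a `pwm` object.
#' @return the reverse-complemented `pwm`.
#' @export
revcomp_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  x$probs <- x$probs[rev(seq_len(x$width)), rev(seq_len(4L)), drop = FALSE]
  colnames(x$probs) <- DNA_BASES
  x$counts <- x$counts[rev(seq_len(nrow(x$counts))), rev(seq_len(4L)),
                       drop = FALSE]
  colnames(x$counts) <- DNA_BASES
  x$background <- setNames(rev(x$background), DNA_BASES)
  x
}

#' Per-position consensus base of a PWM
#' @param x a `pwm` object.
#' @return character string of length `x$width`.
#' @export
pwm_consensus <- function(x) {
  stopifnot(inherits(x, "pwm"))
  paste(DNA_BASES[apply(x$probs, 1L, which.max)], collapse = "")
}

# Tokenize one JASPAR count row; accepts "A [ 1 2 3 ]", "1 2 3" or "A 1 2 3".
.parse_jaspar_row <- function(line, record) {
  line <- gsub("[][]", " ", line)
  toks <- strsplit(trimws(line), "[ \t]+")[[1L]]
  base <- NA_character_
  if (length(toks) && toupper(toks[1L]) %in% DNA_BASES &&
      is.na(suppressWarnings(as.numeric(toks[1L])))) {
    base <- toupper(toks[1L])
    toks <- toks[-1L]
  }
  vals <- suppressWarnings(as.numeric(toks))
  if (length(vals) == 0L || any(is.na(vals)))
    stopf("malformed JASPAR record '%s': unparseable count row", record)
  list(base = base, counts = vals)
}

#' Read TF motifs from a JASPAR PFM file
#'
#' Parses one or more JASPAR-format records (a `>ID NAME` header followed by
#' four count rows for A, C, G, T, optionally bracketed) into `pwm` objects.
#' Record order is preserved. Gzip-compressed files are read transparently.
#'
#' @param path path to the PFM file.
#' @param pseudocount per-cell pseudocount added before normalization.
#' @param background length-4 background distribution for downstream scoring.
#' @return list of `pwm` objects, named by `tf_id`.
#' @export
read_jaspar <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  if (!file.exists(path)) stopf("JASPAR file not found: %s", path)
  lines <- readLines(con <- gzfile(path)); close(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stopf("empty JASPAR file: %s", path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stopf("no '>' record headers in %s", path)
  bounds <- c(hdr, length(lines) + 1L)
  out <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    head_line <- sub("^>\\s*", "", lines[hdr[i]])
    toks <- strsplit(trimws(head_line), "[ \t]+")[[1L]]
    id <- toks[1L]
    nm <- if (length(toks) >= 2L) toks[2L] else id
    body <- lines[seq(hdr[i] + 1L, bounds[i + 1L] - 1L)]
    if (length(body) != 4L)
      stopf("malformed JASPAR record '%s': expected 4 count rows, got %d",
            id, length(body))
    rows <- lapply(body, .parse_jaspar_row, record = id)
    widths <- vapply(rows, function(r) length(r$counts), integer(1L))
    if (length(unique(widths)) != 1L)
      stopf("malformed JASPAR record '%s': ragged row widths", id)
    counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
    bases <- vapply(rows, `[[`, character(1L), "base")
    if (!anyNA(bases)) {
      if (!setequal(bases, DNA_BASES))
        stopf("malformed JASPAR record '%s': rows are not A/C/G/T", id)
      counts <- counts[match(DNA_BASES, bases), , drop = FALSE]
    }
    rownames(counts) <- DNA_BASES
    # pass in width x 4 orientation so square matrices are unambiguous
    out[[i]] <- pwm(t(counts), tf_id = id, pseudocount = pseudocount,
                    background = background, name = nm)
  }
  names(out) <- vapply(out, `[[`, character(1L), "tf_id")
  out
}

#' Write PWMs back to a JASPAR PFM file
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    stopifnot(inherits(p, "pwm"))
    cat(sprintf(">%s %s\n", p$tf_id, p$name), file = con)
    cnt <- t(p$counts)
    for (b in seq_len(4L))
      cat(sprintf("%s [ %s ]\n", DNA_BASES[b],
                  paste(format(cnt[b, ], trim = TRUE), collapse = " ")),
          file = con)
  }
  invisible(path)
}

#' Construct a promoter set
#'
#' @param sequences named character vector of uppercase DNA sequences
#'   (names are gene ids).
#' @param coords optional data.frame with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (BED convention, 0-based half-open).
#' @return object of class `promoter_set` with fields `sequences` and
#'   `coords`.
#' @export
promoter_set <- function(sequences, coords = NULL) {
  if (is.null(names(sequences)) || anyNA(names(sequences)))
    stopf("promoter sequences must be named by gene_id")
  if (anyDuplicated(names(sequences)))
    stopf("duplicate gene ids in promoter set: %s",
          paste(unique(names(sequences)[duplicated(names(sequences))]),
                collapse = ", "))
  sequences <- toupper(sequences)
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stopf("non-ACGTN characters in promoter sequences of: %s",
          paste(head(names(sequences)[bad], 5L), collapse = ", "))
  if (!is.null(coords)) {
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(coords)))
      stopf("coords must have columns %s", paste(need, collapse = ", "))
    coords <- coords[match(names(sequences), coords$gene_id), , drop = FALSE]
    if (any(coords$end - coords$start != nchar(sequences)))
      stopf("coordinate span must equal sequence length")
  }
  structure(list(sequences = sequences, coords = coords),
            class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("<promoter_set> %d promoters, lengths %d-%d bp\n",
              length(x$sequences), min(nchar(x$sequences)),
              max(nchar(x$sequences))))
  invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$sequences)

#' Gene universe of a promoter set
#' @param promoters a `promoter_set`.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(promoters) names(promoters$sequences)

#' Read promoters directly from a FASTA file keyed by gene id
#' @param path FASTA path (gzip-transparent). Record ids (first whitespace
#'   token) are taken as gene ids.
#' @return a `promoter_set`.
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  promoter_set(setNames(as.character(ss), ids))
}

#' Write a promoter set to FASTA
#' @param promoters a `promoter_set`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(promoters, path) {
  stopifnot(inherits(promoters, "promoter_set"))
  ss <- Biostrings::DNAStringSet(promoters$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Extract promoter windows from a genome and a TSS BED file
#'
#' For a `+`-strand TSS the window is `[TSS - upstream, TSS + downstream)`
#' in 0-based half-open genomic coordinates; for `-` strand the mirrored
#' window `[TSS - downstream, TSS + upstream)` is taken and
#' reverse-complemented so that position 0 of the returned sequence is
#' farthest upstream of the TSS. Windows extending past a contig boundary
#' are truncated with a warning; genes on contigs absent from the genome
#' are skipped with a warning; for duplicated gene ids the first BED line
#' wins and the duplicate is reported.
#'
#' @param genome path to a genome FASTA, or a named `DNAStringSet`.
#' @param tss_bed path to a BED6 file; column 4 carries the gene id, the
#'   TSS is the `start` coordinate for `+` strand and `end - 1` for `-`.
#' @param upstream,downstream nonnegative window extents in bp
#'   (defaults 500 and 0: the 500 bp immediately upstream of the TSS).
#' @return a `promoter_set` with genomic coordinates attached.
#' @export
extract_promoters <- function(genome, tss_bed, upstream = 500,
                              downstream = 0) {
  if (upstream < 0 || downstream < 0)
    stopf("upstream/downstream must be nonnegative")
  if (upstream + downstream <= 0) stopf("empty promoter window")
  gen <- if (inherits(genome, "DNAStringSet")) genome else
    Biostrings::readDNAStringSet(genome)
  names(gen) <- sub("\\s.*$", "", names(gen))
  bed <- read.table(tss_bed, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(bed) < 6L) stopf("TSS BED must have 6 columns (BED6)")
  names(bed)[1:6] <- c("chrom", "start", "end", "gene_id", "score", "strand")
  dup <- duplicated(bed$gene_id)
  if (any(dup))
    warnf("duplicate gene ids in BED (first occurrence kept): %s",
          paste(unique(bed$gene_id[dup]), collapse = ", "))
  bed <- bed[!dup, , drop = FALSE]
  keep <- bed$chrom %in% names(gen)
  if (!all(keep))
    warnf("skipping %d gene(s) on contigs absent from the genome",
          sum(!keep))
  bed <- bed[keep, , drop = FALSE]
  if (nrow(bed) == 0L) stopf("no usable TSS records")

  seqs <- character(nrow(bed))
  starts <- integer(nrow(bed)); ends <- integer(nrow(bed))
  truncated <- 0L
  for (i in seq_len(nrow(bed))) {
    chrom_len <- Biostrings::width(gen[bed$chrom[i]])
    if (bed$strand[i] == "-") {
      tss <- bed$end[i] - 1L
      w0 <- tss - downstream
      w1 <- tss + upstream
    } else {
      tss <- bed$start[i]
      w0 <- tss - upstream
      w1 <- tss + downstream
    }
    c0 <- max(w0, 0L); c1 <- min(w1, chrom_len)
    if (c0 > w0 || c1 < w1) truncated <- truncated + 1L
    if (c1 <= c0) { seqs[i] <- ""; starts[i] <- c0; ends[i] <- c0; next }
    s <- Biostrings::subseq(gen[[bed$chrom[i]]], start = c0 + 1L, end = c1)
    if (bed$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
    starts[i] <- c0; ends[i] <- c1
  }
  if (truncated > 0L)
    warnf("%d promoter window(s) truncated at contig boundaries", truncated)
  ok <- nchar(seqs) > 0L
  promoter_set(setNames(seqs[ok], bed$gene_id[ok]),
               coords = data.frame(gene_id = bed$gene_id[ok],
                                   chrom = bed$chrom[ok],
                                   start = starts[ok], end = ends[ok],
                                   strand = bed$strand[ok],
                                   stringsAsFactors = FALSE))
}
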