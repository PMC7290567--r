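#' Alignment scoring parameters
#'
#' @param match Match bonus (positive integer).
#' @param mismatch Mismatch penalty (negative integer).
#' @param gap_open Penalty of the first base of a gap (negative).
#' @param gap_extend Penalty of each further gap base (negative).
#' @param band Half-width of the reference window around a seed diagonal.
#' @param seed_step Spacing of sampled seed k-mers along the read.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1L, mismatch = -1L, gap_open = -2L,
                          gap_extend = -1L, band = 15L, seed_step = 10L) {
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), band = as.integer(band),
                 seed_step = as.integer(seed_step)), class = "align_scoring")
}

#' Build a k-mer index over the circular mtDNA plus decoy contigs
#'
#' The mitochondrial sequence is stored doubled so k-mers spanning the
#' origin are indexed; hits on the second copy are canonicalised modulo the
#' genome length. Decoy contigs are indexed linearly and tagged as nuclear.
#'
#' @param ref A `mito_reference`.
#' @param decoys Optional named character vector of nuclear decoy contigs.
#' @param k K-mer size in `[8, 31]` (default 15).
#' @return An object of class `kmer_index`.
#' @export
build_index <- function(ref, decoys = NULL, k = 15L) {
  k <- as.integer(k)
  if (k < 4L || k > 31L) stop("k must be in [4, 31]")
  if (ref$length < k) stop("reference shorter than k")
  seqs <- paste0(ref$sequence, ref$sequence)
  names_ <- ref$name
  klass <- 0L
  if (!is.null(decoys) && length(decoys) > 0) {
    if (any(nchar(decoys) < k)) stop("decoy contig shorter than k")
    seqs <- c(seqs, unname(decoys))
    names_ <- c(names_, names(decoys))
    klass <- c(klass, rep(1L, length(decoys)))
  }
  ptr <- cpp_build_index(seqs, names_, klass, k, ref$length)
  structure(list(ptr = ptr, k = k, mt_len = ref$length, names = names_,
                 klass = klass, n_skipped = attr(ptr, "n_skipped")),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("k-mer index (k=", x$k, "): mt ", x$mt_len, " bp (circular), ",
      sum(x$klass == 1L), " decoy contig(s)\n", sep = "")
  invisible(x)
}

#' Look up all occurrences of a k-mer
#'
#' @param index A `kmer_index`.
#' @param kmer K-mer string of the index's k.
#' @return Data frame `ref` (sequence name), `pos` (1-based canonical).
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(ref = index$names[hits$ref], pos = hits$pos,
             stringsAsFactors = FALSE)
}

#' Align reads to the indexed references
#'
#' Seed-and-extend: exact k-mer seeds are sampled along the read (both
#' strands), each seed diagonal is extended by local alignment with affine
#' gaps over a banded reference window, and the best-scoring alignment per
#' reference class (mitochondrial, nuclear) is kept. Mitochondrial
#' coordinates are reported modulo the genome length in `[1, L]`; reads
#' with multiple equal-best mitochondrial placements are assigned the lowest
#' start and flagged ambiguous.
#'
#' @param reads A `read_set`.
#' @param index A `kmer_index`.
#' @param scoring An `align_scoring`.
#' @return An `alignment_set`: data frame with per-read columns `id`, `seq`,
#'   `qual`, `mt_score`, `mt_start`, `mt_span`, `mt_strand`, `mt_cigar`,
#'   `ambiguous`, `nuc_score`, `nuc_ref` (NA where unmapped in a class).
#' @export
align_reads <- function(reads, index, scoring = align_scoring()) {
  res <- cpp_align_reads(index$ptr, reads$seq, scoring$seed_step,
                         scoring$band, scoring$match, scoring$mismatch,
                         -scoring$gap_open, -scoring$gap_extend)
  out <- data.frame(id = reads$id, seq = reads$seq, qual = reads$qual,
                    mt_score = res$mt_score, mt_start = res$mt_start,
                    mt_span = res$mt_span, mt_strand = res$mt_strand,
                    mt_cigar = res$mt_cigar, ambiguous = res$ambiguous,
                    nuc_score = res$nuc_score,
                    nuc_ref = index$names[res$nuc_ref],
                    stringsAsFactors = FALSE)
  if ("origin" %in% names(reads)) out$origin <- reads$origin
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "mt_len") <- index$mt_len
  attr(out, "mt_name") <- index$names[1]
  out
}

#' Align a single read
#'
#' @param read Read sequence (character scalar).
#' @param index A `kmer_index`.
#' @param scoring An `align_scoring`.
#' @return One-row `alignment_set` (empty columns NA when unmapped).
#' @export
align_read <- function(read, index, scoring = align_scoring()) {
  if (nchar(read) < index$k) stop("read shorter than the seed k-mer")
  rs <- data.frame(id = "read1", seq = toupper(read),
                   qual = strrep("I", nchar(read)), stringsAsFactors = FALSE)
  align_reads(rs, index, scoring)
}

#' Remove PCR duplicates among mitochondrial alignments
#'
#' Among reads sharing identical (start, mapped end, strand) on the
#' mitochondrial reference, exactly one is retained: the one with the
#' highest base-quality sum, ties broken by lexicographically smallest read
#' id. Unmapped rows are dropped. The operation is idempotent.
#'
#' @param aln An `alignment_set`.
#' @return The deduplicated `alignment_set`.
#' @export
remove_duplicates <- function(aln) {
  x <- aln[!is.na(aln$mt_start), , drop = FALSE]
  if (nrow(x) == 0) return(x)
  key <- paste(x$mt_start, x$mt_start + x$mt_span - 1L, x$mt_strand)
  qsum <- unname(vapply(x$qual, function(q) sum(utf8ToInt(q) - 33L), numeric(1)))
  ord <- order(key, -qsum, x$id)
  x <- x[ord, , drop = FALSE]
  keep <- !duplicated(key[ord])
  out <- x[keep, , drop = FALSE]
  out <- out[order(out$mt_start, out$id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "mt_len") <- attr(aln, "mt_len")
  attr(out, "mt_name") <- attr(aln, "mt_name")
  out
}

#' Filter putative NumtS reads by score comparison
#'
#' A read is retained iff its best mitochondrial alignment score is strictly
#' greater than its best nuclear alignment score (a missing nuclear hit
#' counts as minus infinity); score ties and nuclear-only reads are
#' discarded.
#'
#' @param aln An `alignment_set` aligned against an index that includes the
#'   nuclear decoys.
#' @return The retained `alignment_set`, with a `report` attribute (data
#'   frame `id`, `mt_score`, `nuc_score`, `decision`).
#' @export
filter_numts <- function(aln) {
  mt <- ifelse(is.na(aln$mt_score), -Inf, aln$mt_score)
  nuc <- ifelse(is.na(aln$nuc_score), -Inf, aln$nuc_score)
  keep <- is.finite(mt) & (mt > nuc)
  report <- data.frame(id = aln$id, mt_score = aln$mt_score,
                       nuc_score = aln$nuc_score,
                       decision = ifelse(keep, "retained", "discarded"),
                       stringsAsFactors = FALSE)
  out <- aln[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "mt_len") <- attr(aln, "mt_len")
  attr(out, "mt_name") <- attr(aln, "mt_name")
  attr(out, "report") <- report
  out
}

## Orient sequence/quality into reference orientation for SAM/pileup.
oriented_seq <- function(aln) {
  s <- aln$seq
  q <- aln$qual
  minus <- !is.na(aln$mt_strand) & aln$mt_strand == "-"
  if (any(minus)) {
    s[minus] <- revcomp(s[minus])
    q[minus] <- vapply(strsplit(q[minus], ""),
                       function(x) paste(rev(x), collapse = ""), "")
  }
  # CIGAR computed on the oriented read already matches this orientation
  list(seq = s, qual = q)
}

#' Write mitochondrial alignments as SAM
#'
#' Emits a minimal, valid SAM text file: `@HD`/`@SQ` header, one record per
#' mapped read with soft-clipped ends, flag 0/16 by strand, MAPQ 60 (0 when
#' the placement is ambiguous) and the alignment score in `AS:i`.
#'
#' @param aln An `alignment_set`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path) {
  L <- attr(aln, "mt_len")
  nm <- attr(aln, "mt_name") %||% "chrM"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:", nm, "\tLN:", L),
               paste0("@PG\tID:scmito\tPN:scmito")), con)
  x <- aln[!is.na(aln$mt_start), , drop = FALSE]
  if (nrow(x) == 0) return(invisible(path))
  o <- oriented_seq(x)
  flag <- ifelse(x$mt_strand == "-", 16L, 0L)
  mapq <- ifelse(isTRUE_vec(x$ambiguous), 0L, 60L)
  writeLines(paste(x$id, flag, nm, x$mt_start, mapq, x$mt_cigar, "*", 0L, 0L,
                   o$seq, o$qual, paste0("AS:i:", x$mt_score), sep = "\t"),
             con)
  invisible(path)
}

isTRUE_vec <- function(x) !is.na(x) & x
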