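# Shared fixtures, all built in code or loaded from packaged plain-text data.

toy_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- read_reference(system.file("extdata", "toy_mt_ref.fa",
                                           package = "scmito"))
    cache
  }
})

toy_tree <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- read_phylotree(system.file("extdata", "toy_phylotree.tsv",
                                           package = "scmito"))
    cache
  }
})

# Phred integer vector -> Phred+33 string
q2s <- function(q) intToUtf8(q + 33L)

# Hand-built alignment set for pileup/dedup tests
mk_aln <- function(start, cigar, seq, qual = NULL, strand = "+",
                   id = NULL, L = 2000L, score = NULL) {
  n <- length(start)
  seq <- rep_len2(seq, n)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))  # Q40
  qual <- rep_len2(qual, n)
  strand <- rep_len2(strand, n)
  cigar <- rep_len2(cigar, n)
  if (is.null(id)) id <- sprintf("r%03d", seq_len(n))
  span <- vapply(cigar, cigar_ref_span, 0L)
  out <- data.frame(id = id, seq = seq, qual = qual,
                    mt_score = if (is.null(score)) nchar(seq) else score,
                    mt_start = start, mt_span = unname(span),
                    mt_strand = strand, mt_cigar = cigar,
                    ambiguous = rep(FALSE, n),
                    nuc_score = rep(NA_integer_, n),
                    nuc_ref = rep(NA_character_, n),
                    stringsAsFactors = FALSE)
  class(out) <- c("alignment_set", "data.frame")
  attr(out, "mt_len") <- L
  attr(out, "mt_name") <- "chrM"
  out
}

cigar_ref_span <- function(cg) {
  if (is.na(cg)) return(NA_integer_)
  n <- as.integer(regmatches(cg, gregexpr("[0-9]+", cg))[[1]])
  op <- regmatches(cg, gregexpr("[A-Z]", cg))[[1]]
  sum(n[op %in% c("M", "D")])
}

# Simple callset from positions (AF/depth constant unless given)
mk_callset <- function(pos, id, af = 1, total = 100L, assay = "WGS",
                       ref = "A", alt = "G") {
  callset(data.frame(pos = pos, ref = ref, alt = alt,
                     af = rep_len(af, length(pos)),
                     total = rep_len(total, length(pos)),
                     stringsAsFactors = FALSE), id, assay)
}

# Full Smith-Waterman oracle score (independent of the package aligner):
# best local-alignment score of the read against the doubled circular
# reference, both strands, affine gaps matching align_scoring() defaults.
sw_oracle_score <- function(read, ref_seq) {
  doubled <- paste0(ref_seq, ref_seq)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  s1 <- Biostrings::pairwiseAlignment(read, doubled, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 1, gapExtension = 1,
                                      scoreOnly = TRUE)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  s2 <- Biostrings::pairwiseAlignment(rc, doubled, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = 1, gapExtension = 1,
                                      scoreOnly = TRUE)
  max(s1, s2)
}

# Mutate n_mm random positions of a sequence
mutate_seq <- function(s, n_mm) {
  if (n_mm == 0) return(s)
  x <- strsplit(s, "")[[1]]
  at <- sample.int(length(x), n_mm)
  x[at] <- vapply(x[at], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(x, collapse = "")
}

rep_len2 <- function(x, n) if (length(x) == n) x else rep_len(x, n)
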