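#' Build a synthetic circular mitochondrial reference
#'
#' Generates a random A/C/G/T sequence standing in for the circular
#' mitochondrial genome (16,569 bp in humans). Positions on the reference are
#' 1-based and wrap modulo its length, mirroring the circular molecule.
#'
#' @param length Genome length in bases (>= 1000). Default 16569, the length
#'   of the human mitochondrial reference.
#' @param seed Integer seed; the sequence is a pure function of
#'   `(length, seed)`.
#' @param name Sequence name used in FASTA/SAM/VCF output.
#' @return An object of class `mito_reference`: a list with `name`,
#'   `sequence` (uppercase character scalar), `length` and `circular = TRUE`.
#' @examples
#' ref <- build_reference(2000, seed = 1)
#' nchar(ref$sequence)
#' @export
build_reference <- function(length = 16569L, seed, name = "chrM") {
  length <- as.integer(length)
  if (is.na(length) || length < 1000L)
    stop("reference length must be at least 1000 bases, got ", length)
  seq <- with_seed(seed, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = ""))
  mito_reference(name, seq)
}

#' Construct a mito_reference from an existing sequence
#'
#' @param name Sequence name.
#' @param sequence A/C/G/T string.
#' @return A `mito_reference` object.
#' @export
mito_reference <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence))
    stop("reference sequence must contain only A/C/G/T")
  structure(list(name = name, sequence = sequence,
                 length = nchar(sequence), circular = TRUE),
            class = "mito_reference")
}

#' @export
print.mito_reference <- function(x, ...) {
  cat("Circular mtDNA reference '", x$name, "': ", x$length, " bp\n", sep = "")
  invisible(x)
}

## Reduce a 1-based position onto the circle.
wrap_pos <- function(pos, L) ((pos - 1L) %% L) + 1L

## Extract a (possibly origin-spanning) substring of a circular sequence.
circular_substr <- function(seq, start, len) {
  L <- nchar(seq)
  start <- wrap_pos(start, L)
  if (start + len - 1L <= L) return(substr(seq, start, start + len - 1L))
  paste0(substr(seq, start, L), substr(seq, 1L, start + len - 1L - L))
}

#' Write sequences to a FASTA file
#'
#' @param x A `mito_reference`, or a named character vector of sequences.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "mito_reference")) x <- setNames(x$sequence, x$name)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(s))
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Read a FASTA file as a circular mitochondrial reference
#'
#' @param path FASTA path; the first record is used.
#' @return A `mito_reference`.
#' @export
read_reference <- function(path) {
  s <- read_fasta(path)
  mito_reference(names(s)[1], s[[1]])
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Reverse-complement (vectorised over a character vector).
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
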