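#' Simulate a sequencing read set from a cell haplotype
#'
#' Fragment start positions are drawn from the protocol's positional weight
#' function over the circular genome (fragments may span the origin). At
#' each heteroplasmic site, a fragment covering it carries the alternate
#' allele with independent probability equal to the site's fraction. PCR
#' duplicates are exact copies of already-drawn fragments making up the
#' protocol's duplicate rate of the emitted reads; every emitted copy then
#' receives independent per-base sequencing errors. Erroneous bases are
#' assigned low Phred qualities (2-20) and correct bases high ones (25-40),
#' so downstream base-quality filtering is informative.
#'
#' @param haplotype A `haplotype` from [apply_genotype()].
#' @param protocol A `protocol_model`.
#' @param depth Target mean depth (reads emitted =
#'   `round(depth * L / read_length)`).
#' @param seed Integer seed; the read set is a pure function of inputs and
#'   seed.
#' @param prefix Read-id prefix.
#' @return A `read_set`: data frame with `id`, `seq`, `qual` (Phred+33),
#'   `origin` (`"mt"`), `start`, `end` (1-based circular source interval,
#'   `end` may exceed `L` to denote origin wrap), `strand`, `is_dup`.
#' @export
generate_reads <- function(haplotype, protocol, depth, seed,
                           prefix = haplotype$id %||% "cell") {
  stopifnot(inherits(protocol, "protocol_model"))
  if (depth <= 0) stop("target depth must be positive")
  L <- haplotype$length
  len <- protocol$read_length
  n <- max(1L, as.integer(round(depth * L / len)))
  w <- positional_weights(protocol, L, seed = seed_child(seed, 1L))
  with_seed(seed_child(seed, 2L), {
    n_dup <- as.integer(round(protocol$dup_rate * n))
    n_frag <- n - n_dup
    starts <- sample.int(L, n_frag, replace = TRUE, prob = w)
    strands <- sample(c("+", "-"), n_frag, replace = TRUE)
    ext <- paste0(haplotype$sequence, substr(haplotype$sequence, 1L, len))
    frags <- substring(ext, starts, starts + len - 1L)
    het <- haplotype$het
    for (i in seq_len(nrow(het))) {
      off <- (het$pos[i] - starts) %% L  # 0-based offset of site in fragment
      idx <- which(off < len)
      if (length(idx) == 0) next
      carry <- idx[runif(length(idx)) < het$fraction[i]]
      for (j in carry) {
        o <- off[j] + 1L
        substr(frags[j], o, o) <- het$alt[i]
      }
    }
    if (n_dup > 0) {
      src <- sample.int(n_frag, n_dup, replace = TRUE)
      starts <- c(starts, starts[src])
      strands <- c(strands, strands[src])
      frags <- c(frags, frags[src])
    }
    is_dup <- c(rep(FALSE, n_frag), rep(TRUE, n_dup))
    fin <- finalize_reads(frags, strands, protocol$error_rate)
    data.frame(id = sprintf("%s_r%06d", prefix, seq_len(n)),
               seq = fin$seq, qual = fin$qual, origin = "mt",
               start = starts, end = starts + len - 1L, strand = strands,
               is_dup = is_dup, stringsAsFactors = FALSE) -> out
    class(out) <- c("read_set", "data.frame")
    attr(out, "n_requested") <- n
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Independent sub-seed derivation (kept below 2^31; double arithmetic is
## exact here and avoids 32-bit overflow for large parent seeds).
seed_child <- function(seed, i)
  as.integer((as.numeric(seed) * 1009 + i * 7919) %% 2147483647)

## Apply sequencing errors and draw qualities, then orient minus-strand
## reads (reverse complement sequence, reverse qualities).
finalize_reads <- function(frags, strands, error_rate) {
  n <- length(frags)
  lens <- nchar(frags)
  n_err <- rbinom(n, lens, error_rate)
  quals <- character(n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    q <- sample(25:40, lens[i], replace = TRUE)
    if (n_err[i] > 0) {
      at <- sample.int(lens[i], n_err[i])
      s <- strsplit(frags[i], "")[[1]]
      s[at] <- vapply(s[at], function(b) sample(setdiff(bases, b), 1L), "")
      frags[i] <- paste(s, collapse = "")
      q[at] <- sample(2:20, n_err[i], replace = TRUE)
    }
    quals[i] <- intToUtf8(q + 33L)
  }
  minus <- strands == "-"
  if (any(minus)) {
    frags[minus] <- revcomp(frags[minus])
    quals[minus] <- vapply(strsplit(quals[minus], ""),
                           function(x) paste(rev(x), collapse = ""), "")
  }
  list(seq = frags, qual = quals)
}

#' NumtS insertion model
#'
#' @param count Number of mtDNA-derived insertions in the decoy contig.
#' @param len_min,len_max Bounds (bases) of insertion lengths.
#' @param divergence Per-base substitution rate of insertions relative to
#'   their mtDNA source, in `[0, 0.2]`.
#' @param contig_length Length of the nuclear decoy contig.
#' @return An object of class `numts_model`.
#' @export
numts_model <- function(count = 3L, len_min = 300L, len_max = 800L,
                        divergence = 0.05, contig_length = 8000L) {
  if (divergence < 0 || divergence > 0.2) stop("divergence must be in [0, 0.2]")
  structure(list(count = as.integer(count), len_min = as.integer(len_min),
                 len_max = as.integer(len_max), divergence = divergence,
                 contig_length = as.integer(contig_length)),
            class = "numts_model")
}

#' Embed diverged mtDNA segments (NumtS) in a nuclear decoy contig
#'
#' Each NumtS is a contiguous substring of the cell's mtDNA haplotype with
#' i.i.d. substitutions at the model's divergence rate, embedded at recorded
#' coordinates in random nuclear background sequence.
#'
#' @param haplotype A `haplotype` (or `mito_reference`) supplying the mtDNA
#'   sequence the insertions derive from.
#' @param model A `numts_model`.
#' @param seed Integer seed.
#' @return List with `contigs` (named character vector, one decoy contig)
#'   and `truth` (data frame: `contig`, `start`, `end`, `mt_start`,
#'   `mt_len`, `n_sub`).
#' @export
insert_numts <- function(haplotype, model, seed) {
  mt <- if (inherits(haplotype, "mito_reference")) haplotype$sequence
        else haplotype$sequence
  L <- nchar(mt)
  slot_len <- model$contig_length %/% model$count
  if (model$len_max + 2L > slot_len)
    stop("decoy contig too short to host ", model$count,
         " insertions of up to ", model$len_max, " bases")
  # derived sub-seed: keeps the decoy background decorrelated from a
  # reference built with the same user seed (both start by sampling bases)
  with_seed(seed_child(seed, 9001L), {
    bases <- c("A", "C", "G", "T")
    bg <- sample(bases, model$contig_length, replace = TRUE)
    truth <- vector("list", model$count)
    for (i in seq_len(model$count)) {
      ilen <- if (model$len_min == model$len_max) model$len_min
              else sample(model$len_min:model$len_max, 1L)
      mt_start <- sample.int(L, 1L)
      seg <- strsplit(circular_substr(mt, mt_start, ilen), "")[[1]]
      sub_at <- which(runif(ilen) < model$divergence)
      seg[sub_at] <- vapply(seg[sub_at],
                            function(b) sample(setdiff(bases, b), 1L), "")
      off <- sample.int(slot_len - ilen, 1L)
      start <- (i - 1L) * slot_len + off
      bg[start:(start + ilen - 1L)] <- seg
      truth[[i]] <- data.frame(contig = "decoy1", start = start,
                               end = start + ilen - 1L, mt_start = mt_start,
                               mt_len = ilen, n_sub = length(sub_at))
    }
    list(contigs = c(decoy1 = paste(bg, collapse = "")),
         truth = do.call(rbind, truth))
  })
}

#' Simulate reads from nuclear decoy contigs
#'
#' Read starts are uniform over the (linear) decoy contig. A read falling
#' entirely inside a recorded NumtS interval is truth-labelled `"numts"`;
#' all other decoy reads are labelled `"nuclear"`.
#'
#' @param decoys Named character vector of decoy contigs (from
#'   [insert_numts()]).
#' @param truth NumtS truth intervals (from [insert_numts()]).
#' @param protocol A `protocol_model` (read length and error rate are used).
#' @param n_reads Number of reads to emit.
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return A `read_set` with origins in `{"numts", "nuclear"}`.
#' @export
generate_decoy_reads <- function(decoys, truth, protocol, n_reads, seed,
                                 prefix = "decoy") {
  contig <- decoys[[1]]
  clen <- nchar(contig)
  len <- protocol$read_length
  with_seed(seed, {
    starts <- sample.int(clen - len + 1L, n_reads, replace = TRUE)
    strands <- sample(c("+", "-"), n_reads, replace = TRUE)
    frags <- substring(contig, starts, starts + len - 1L)
    ends <- starts + len - 1L
    inside <- rep(FALSE, n_reads)
    for (i in seq_len(nrow(truth)))
      inside <- inside | (starts >= truth$start[i] & ends <= truth$end[i])
    fin <- finalize_reads(frags, strands, protocol$error_rate)
    out <- data.frame(id = sprintf("%s_r%06d", prefix, seq_len(n_reads)),
                      seq = fin$seq, qual = fin$qual,
                      origin = ifelse(inside, "numts", "nuclear"),
                      start = starts, end = ends, strand = strands,
                      is_dup = FALSE, stringsAsFactors = FALSE)
    class(out) <- c("read_set", "data.frame")
    out
  })
}

#' Simulate one cell end to end
#'
#' Convenience wrapper: realises the genotype, draws mtDNA reads under the
#' protocol, and optionally mixes in decoy-contig reads (NumtS
#' contamination).
#'
#' @param ref A `mito_reference`.
#' @param tree A `phylotree` (or `NULL`).
#' @param genotype A `cell_genotype`.
#' @param protocol A `protocol_model`.
#' @param depth Target mean mtDNA depth.
#' @param decoys Optional list from [insert_numts()].
#' @param contam_frac Decoy reads emitted as a fraction of mtDNA reads.
#' @param seed Integer seed.
#' @return List with `reads` (combined `read_set`), `haplotype`, and
#'   `truth` (the genotype's variant list).
#' @export
simulate_cell <- function(ref, tree, genotype, protocol, depth,
                          decoys = NULL, contam_frac = 0.1, seed = 1L) {
  hap <- apply_genotype(ref, tree, genotype)
  reads <- generate_reads(hap, protocol, depth, seed = seed_child(seed, 11L),
                          prefix = genotype$id)
  if (!is.null(decoys)) {
    n_dec <- max(1L, as.integer(round(contam_frac * nrow(reads))))
    dr <- generate_decoy_reads(decoys$contigs, decoys$truth, protocol, n_dec,
                               seed = seed_child(seed, 12L),
                               prefix = paste0(genotype$id, "_nuc"))
    reads <- rbind(reads, dr)
    class(reads) <- c("read_set", "data.frame")
  }
  list(reads = reads, haplotype = hap, truth = hap$truth)
}

#' Write a read set to FASTQ (Phred+33)
#'
#' @param reads A `read_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)),
    Biostrings::PhredQuality(reads$qual))
  # Biostrings warns that the (empty) metadata columns are dropped on write
  suppressWarnings(Biostrings::writeQualityScaledXStringSet(x, path))
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ path.
#' @return A `read_set` (truth columns absent).
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropped (empty) metadata columns on conversion
  x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  out <- data.frame(id = sub("\\s.*$", "", names(x)),
                    seq = as.character(x),
                    qual = as.character(Biostrings::quality(x)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write the simulation truth table
#'
#' @param truth Variant truth data frame (`pos`, `ref`, `alt`, `fraction`).
#' @param cell_id Cell identifier recorded per row.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, cell_id, path) {
  df <- cbind(cell = cell_id, truth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
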