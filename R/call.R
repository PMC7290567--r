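#' Build a base-quality-filtered pileup
#'
#' Every aligned, non-clipped base with quality at or above the threshold
#' contributes one count to its position's allele tally; insertions are
#' recorded at their left-anchor position and deletions as length-tagged
#' events anchored at the base before the deleted run. Raw depth counts all
#' aligned bases regardless of quality.
#'
#' @param aln An `alignment_set` (deduplicated and NumtS-filtered).
#' @param ref A `mito_reference`.
#' @param min_base_quality Phred threshold (default 30).
#' @return An object of class `mito_pileup`: list with `counts` (4 x L
#'   matrix, rows A/C/G/T), `filtered_depth`, `raw_depth`, `ins`, `del`,
#'   `min_base_quality`, `L`.
#' @export
build_pileup <- function(aln, ref, min_base_quality = 30L) {
  x <- aln[!is.na(aln$mt_start), , drop = FALSE]
  if (any(x$mt_start < 1L | x$mt_start > ref$length))
    stop("alignment start outside [1, L]")
  o <- oriented_seq(x)
  res <- cpp_pileup(x$mt_start, x$mt_cigar, o$seq, o$qual, ref$length,
                    as.integer(min_base_quality))
  counts <- res$counts
  rownames(counts) <- c("A", "C", "G", "T")
  structure(list(counts = counts,
                 filtered_depth = as.integer(colSums(counts)),
                 raw_depth = as.integer(res$raw),
                 ins = res$ins, del = res$del,
                 min_base_quality = as.integer(min_base_quality),
                 L = ref$length),
            class = "mito_pileup")
}

#' @export
print.mito_pileup <- function(x, ...) {
  cat("mtDNA pileup: L=", x$L, ", mean filtered depth ",
      round(mean(x$filtered_depth), 2), " (Q>=", x$min_base_quality, ")\n",
      sep = "")
  invisible(x)
}

#' Call variants from a pileup
#'
#' Every non-reference allele supported by at least `min_support`
#' quality-filtered reads becomes a call with allele frequency
#' supporting/total at its position; an insertion or deletion is dropped if
#' on every supporting read the event lies closer than `indel_end_distance`
#' bases to a read end. Multiple alternates at one site yield multiple
#' calls. Indel supporting totals use the filtered depth at the left-anchor
#' position.
#'
#' @param pileup A `mito_pileup`.
#' @param ref The `mito_reference` the pileup was built against.
#' @param min_support Minimum supporting depth (default 5).
#' @param indel_end_distance Minimum distance from a read end for an indel
#'   to count as well-anchored (default 5).
#' @return A `variant_calls` data frame: `pos`, `ref`, `alt`, `type`
#'   (`snp`/`ins`/`del`), `support`, `total`, `af`, sorted by position.
#' @export
call_variants <- function(pileup, ref, min_support = 5L,
                          indel_end_distance = 5L) {
  L <- pileup$L
  refbase <- strsplit(ref$sequence, "")[[1]]
  counts <- pileup$counts
  total <- pileup$filtered_depth
  bases <- rownames(counts)
  calls <- list()
  for (b in bases) {
    cnt <- counts[b, ]
    hit <- which(cnt >= min_support & refbase != b)
    if (length(hit))
      calls[[b]] <- data.frame(pos = hit, ref = refbase[hit], alt = b,
                               type = "snp", support = cnt[hit],
                               total = total[hit],
                               stringsAsFactors = FALSE)
  }
  ins <- pileup$ins
  if (nrow(ins) > 0) {
    key <- paste(ins$pos, ins$seq)
    for (k in unique(key)) {
      grp <- ins[key == k, , drop = FALSE]
      if (nrow(grp) < min_support) next
      if (all(grp$end_dist < indel_end_distance)) next
      p <- grp$pos[1]
      calls[[paste0("ins", k)]] <-
        data.frame(pos = p, ref = refbase[p],
                   alt = paste0(refbase[p], grp$seq[1]), type = "ins",
                   support = nrow(grp), total = max(total[p], nrow(grp)),
                   stringsAsFactors = FALSE)
    }
  }
  del <- pileup$del
  if (nrow(del) > 0) {
    key <- paste(del$pos, del$len)
    for (k in unique(key)) {
      grp <- del[key == k, , drop = FALSE]
      if (nrow(grp) < min_support) next
      if (all(grp$end_dist < indel_end_distance)) next
      p <- grp$pos[1]
      dl <- grp$len[1]
      delled <- paste(refbase[wrap_pos((p + 1L):(p + dl), L)], collapse = "")
      calls[[paste0("del", k)]] <-
        data.frame(pos = p, ref = paste0(refbase[p], delled), alt = refbase[p],
                   type = "del", support = nrow(grp),
                   total = max(total[p], nrow(grp)),
                   stringsAsFactors = FALSE)
    }
  }
  out <- if (length(calls)) do.call(rbind, unname(calls)) else
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               type = character(0), support = integer(0), total = integer(0),
               stringsAsFactors = FALSE)
  out$af <- ifelse(out$total > 0, out$support / out$total, 0)
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Assemble the consensus genome over callable intervals
#'
#' Positions with filtered depth below `min_depth` are non-callable and
#' split the assembly into contigs. At callable positions the most frequent
#' alternate substitution is written iff its allele frequency reaches
#' `hf_threshold`; otherwise the reference base is kept. Indels are reported
#' in the VCF but not applied to the consensus sequence, which therefore
#' stays reference-registered.
#'
#' @param pileup A `mito_pileup`.
#' @param calls A `variant_calls` from the same pileup.
#' @param ref The `mito_reference`.
#' @param hf_threshold Consensus heteroplasmy threshold (default 0.8).
#' @param min_depth Minimum callable filtered depth (default 5).
#' @return A `consensus_assembly`: list with `contigs` (data frame `start`,
#'   `end`, `sequence`), `callable` (data frame `start`, `end`),
#'   `breadth_pct`, `mean_depth`, `n_contigs`.
#' @export
build_consensus <- function(pileup, calls, ref, hf_threshold = 0.8,
                            min_depth = 5L) {
  L <- pileup$L
  callable <- pileup$filtered_depth >= min_depth
  cons <- strsplit(ref$sequence, "")[[1]]
  snps <- calls[calls$type == "snp" & calls$af >= hf_threshold, , drop = FALSE]
  if (nrow(snps) > 0) {
    # one alternate per site: the most frequent passing one
    snps <- snps[order(snps$pos, -snps$support), , drop = FALSE]
    snps <- snps[!duplicated(snps$pos), , drop = FALSE]
    cons[snps$pos] <- snps$alt
  }
  r <- rle(callable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- data.frame(start = starts[r$values], end = ends[r$values])
  contigs <- iv
  contigs$sequence <- vapply(seq_len(nrow(iv)), function(i)
    paste(cons[iv$start[i]:iv$end[i]], collapse = ""), "")
  structure(list(contigs = contigs, callable = iv,
                 breadth_pct = 100 * sum(callable) / L,
                 mean_depth = mean(pileup$filtered_depth),
                 n_contigs = nrow(contigs)),
            class = "consensus_assembly")
}

#' @export
print.consensus_assembly <- function(x, ...) {
  cat("Consensus assembly: ", x$n_contigs, " contig(s), breadth ",
      sprintf("%.2f%%", x$breadth_pct), ", mean depth ",
      sprintf("%.2f", x$mean_depth), "\n", sep = "")
  invisible(x)
}

#' Write consensus contigs to FASTA
#'
#' Record headers follow `cell|contig_i|start-end`.
#'
#' @param assembly A `consensus_assembly`.
#' @param cell_id Cell identifier used in headers.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(assembly, cell_id, path) {
  ct <- assembly$contigs
  if (nrow(ct) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  nm <- sprintf("%s|contig_%d|%d-%d", cell_id, seq_len(nrow(ct)),
                ct$start, ct$end)
  write_fasta(setNames(ct$sequence, nm), path)
}

#' Write callable intervals as BED
#'
#' @param callable Data frame `start`, `end` (1-based inclusive).
#' @param path Output BED path (0-based half-open).
#' @param chrom Chromosome name.
#' @return `path`, invisibly.
#' @export
write_bed <- function(callable, path, chrom = "chrM") {
  df <- data.frame(chrom = chrom, start = callable$start - 1L,
                   end = callable$end)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file of callable intervals
#'
#' @param path BED path.
#' @return Data frame `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE)
  data.frame(start = df[[2]] + 1L, end = df[[3]])
}

#' Write calls as a VCF v4.2 document
#'
#' One record per call with `DP` (total depth) and `AF` (allele frequency)
#' INFO fields; indels are left-anchored as produced by [call_variants()].
#'
#' @param calls A `variant_calls`, sorted by position.
#' @param ref The `mito_reference`.
#' @param sample_id Sample name recorded in the header.
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, ref, sample_id, path) {
  if (is.unsorted(calls$pos)) stop("calls must be sorted by position")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", ref$name, ",length=", ref$length, ">"),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered total depth\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency (heteroplasmic fraction)\">",
           paste0("##sample=<ID=", sample_id, ">"),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (nrow(calls) > 0)
    rows <- paste(ref$name, calls$pos, ".", calls$ref, calls$alt, ".", "PASS",
                  sprintf("DP=%d;AF=%g", calls$total, calls$af),
                  sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a VCF file into a variant_calls data frame
#'
#' Uses the `vcfR` parser; `DP` and `AF` are taken from INFO.
#'
#' @param path VCF path.
#' @return A `variant_calls` data frame (`type` inferred from allele
#'   lengths).
#' @export
read_vcf <- function(path) {
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), type = character(0),
                      support = integer(0), total = integer(0),
                      af = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("variant_calls", "data.frame")
    return(out)
  }
  info <- vcfR::INFO2df(v)
  dp <- as.integer(info$DP)
  af <- as.numeric(info$AF)
  type <- ifelse(nchar(fix$REF) == 1 & nchar(fix$ALT) == 1, "snp",
                 ifelse(nchar(fix$REF) < nchar(fix$ALT), "ins", "del"))
  out <- data.frame(pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    type = type, support = as.integer(round(af * dp)),
                    total = dp, af = af, stringsAsFactors = FALSE)
  class(out) <- c("variant_calls", "data.frame")
  out
}

#' Assembly summary statistics as JSON
#'
#' @param assembly A `consensus_assembly`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_assembly_stats <- function(assembly, path) {
  jsonlite::write_json(list(breadth_pct = assembly$breadth_pct,
                            mean_depth = assembly$mean_depth,
                            n_contigs = assembly$n_contigs),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
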