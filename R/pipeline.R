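#' Run the full per-cell analysis pipeline
#'
#' Trim, align against the circular mitochondrial reference plus decoys,
#' remove PCR duplicates, filter NumtS-like reads by score comparison,
#' pile up, call variants, assemble the consensus and (optionally)
#' classify the haplogroup.
#'
#' @param reads A `read_set` (e.g. from [simulate_cell()] or
#'   [read_fastq()]).
#' @param ref A `mito_reference`.
#' @param decoys Optional named character vector of nuclear decoy contigs.
#' @param tree Optional `phylotree` for haplogroup classification.
#' @param trim Optional `trim_config` (NULL skips trimming).
#' @param scoring An `align_scoring`.
#' @param min_base_quality Pileup base-quality threshold (default 30).
#' @param min_support Variant-call supporting depth (default 5).
#' @param hf_threshold Consensus heteroplasmy threshold (default 0.8).
#' @param min_depth Minimum callable depth (default 5).
#' @return List of class `cell_result` with `alignments`, `pileup`,
#'   `calls`, `assembly`, `haplogroup` (or NULL), `lorenz`.
#' @export
run_cell_pipeline <- function(reads, ref, decoys = NULL, tree = NULL,
                              trim = NULL, scoring = align_scoring(),
                              min_base_quality = 30L, min_support = 5L,
                              hf_threshold = 0.8, min_depth = 5L) {
  if (!is.null(trim)) reads <- trim_reads(reads, trim)
  idx <- build_index(ref, decoys)
  aln <- align_reads(reads, idx, scoring)
  aln <- filter_numts(aln)
  aln <- remove_duplicates(aln)
  pp <- build_pileup(aln, ref, min_base_quality)
  calls <- call_variants(pp, ref, min_support)
  asm <- build_consensus(pp, calls, ref, hf_threshold, min_depth)
  hg <- if (!is.null(tree))
    classify_haplogroup(calls, asm$callable, tree, ref$length,
                        min_depth = min_depth, hf = hf_threshold)
  structure(list(alignments = aln, pileup = pp, calls = calls,
                 assembly = asm, haplogroup = hg,
                 lorenz = lorenz(depth_profile(pp))),
            class = "cell_result")
}

#' @export
print.cell_result <- function(x, ...) {
  cat("Cell pipeline result:\n  ")
  print(x$assembly)
  cat("  ", nrow(x$calls), " variant call(s); Gini ",
      sprintf("%.3f", x$lorenz$gini), "\n", sep = "")
  if (!is.null(x$haplogroup))
    cat("  top haplogroup: ", attr(x$haplogroup, "best"),
        " (p_hg ", sprintf("%.3f", x$haplogroup$p_hg[1]), ")\n", sep = "")
  invisible(x)
}
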