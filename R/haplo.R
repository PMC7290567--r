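#' Classify the haplogroup of a reconstructed genome
#'
#' The observed variant set is the SNP calls passing the depth and
#' heteroplasmy filters. For each haplogroup in the tree, `nph_exp` counts
#' its cumulative defining variants whose positions fall inside the
#' callable intervals (uncovered sites are not held against the
#' prediction), and `nph` counts how many of those are present in the
#' observed set. The reliability score `p_hg = nph / nph_exp` ranks the
#' predictions; ties are broken by larger `nph_exp`, then name. When the
#' callable breadth is below `min_breadth_pct` the prediction is flagged
#' unresolved.
#'
#' @param calls A `variant_calls` (or any data frame with `pos`, `ref`,
#'   `alt`, `type`, `total`, `af`).
#' @param callable Data frame of callable intervals (`start`, `end`,
#'   1-based inclusive), e.g. from [build_consensus()].
#' @param tree A `phylotree`.
#' @param L Genome length used for the breadth computation.
#' @param min_depth Minimum total depth of an observed variant (default 5).
#' @param hf Minimum allele frequency of an observed variant (default 0.8).
#' @param min_breadth_pct Callable breadth (percent) below which the
#'   prediction is unresolved (default 10).
#' @return A `haplogroup_prediction` data frame ranked best-first:
#'   `haplogroup`, `nph`, `nph_exp`, `p_hg`, `resolved`, with attributes
#'   `breadth_pct` and `best`.
#' @export
classify_haplogroup <- function(calls, callable, tree, L,
                                min_depth = 5L, hf = 0.8,
                                min_breadth_pct = 10) {
  if (nrow(tree$table) == 0) stop("empty haplogroup tree")
  obs <- calls[calls$type == "snp" & calls$total >= min_depth &
                 calls$af >= hf, , drop = FALSE]
  obs_key <- paste0(obs$pos, obs$ref, ">", obs$alt)
  in_callable <- function(pos) {
    if (nrow(callable) == 0) return(rep(FALSE, length(pos)))
    ok <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(callable)))
      ok <- ok | (pos >= callable$start[i] & pos <= callable$end[i])
    ok
  }
  breadth <- if (nrow(callable) == 0) 0 else
    100 * sum(callable$end - callable$start + 1) / L
  hgs <- tree$table$haplogroup
  nph <- nph_exp <- integer(length(hgs))
  for (i in seq_along(hgs)) {
    cv <- cumulative_variants(tree, hgs[i])
    cv <- cv[in_callable(cv$pos), , drop = FALSE]
    nph_exp[i] <- nrow(cv)
    nph[i] <- sum(paste0(cv$pos, cv$ref, ">", cv$alt) %in% obs_key)
  }
  p_hg <- ifelse(nph_exp > 0, nph / nph_exp, 0)
  out <- data.frame(haplogroup = hgs, nph = nph, nph_exp = nph_exp,
                    p_hg = p_hg, resolved = breadth >= min_breadth_pct,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$p_hg, -out$nph_exp, out$haplogroup), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("haplogroup_prediction", "data.frame")
  attr(out, "breadth_pct") <- breadth
  attr(out, "best") <- out$haplogroup[1]
  out
}

#' @export
print.haplogroup_prediction <- function(x, n = 5L, ...) {
  cat("Haplogroup prediction (breadth ",
      sprintf("%.2f%%", attr(x, "breadth_pct")), "):\n", sep = "")
  y <- as.data.frame(head(x, n))
  y$p_hg <- sprintf("%.3f", y$p_hg)
  print(y, row.names = FALSE)
  if (!x$resolved[1]) cat("  [unresolved: callable breadth below threshold]\n")
  invisible(x)
}

#' Write ranked haplogroup predictions to TSV
#'
#' @param pred A `haplogroup_prediction`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_haplogroup_tsv <- function(pred, path) {
  write.table(as.data.frame(pred), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
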