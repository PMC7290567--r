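#' Define a single cell's mitochondrial genotype
#'
#' A genotype is a haplogroup (whose cumulative defining variants are
#' homoplasmic), optional extra homoplasmic substitutions, and heteroplasmic
#' substitutions each carried by a fraction `h` of the cell's mtDNA
#' molecules (0 < h < 1).
#'
#' @param id Cell identifier.
#' @param haplogroup Haplogroup name from the tree (or `NULL` for none).
#' @param extra_hom Data frame `pos`, `ref`, `alt` of extra homoplasmic
#'   substitutions (may be empty/NULL).
#' @param het Data frame `pos`, `ref`, `alt`, `fraction` of heteroplasmic
#'   substitutions (may be empty/NULL).
#' @return An object of class `cell_genotype`.
#' @export
cell_genotype <- function(id, haplogroup = NULL, extra_hom = NULL, het = NULL) {
  empty <- data.frame(pos = integer(0), ref = character(0), alt = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(extra_hom)) extra_hom <- empty
  if (is.null(het)) het <- cbind(empty, fraction = numeric(0))
  if (nrow(het) > 0 && (any(het$fraction <= 0) || any(het$fraction >= 1)))
    stop("heteroplasmic fractions must lie strictly between 0 and 1")
  both <- intersect(extra_hom$pos, het$pos)
  if (length(both) > 0)
    stop("position(s) ", paste(both, collapse = ", "),
         " appear in both homoplasmic and heteroplasmic sets")
  structure(list(id = id, haplogroup = haplogroup, extra_hom = extra_hom,
                 het = het), class = "cell_genotype")
}

#' Draw a random genotype from a haplogroup tree
#'
#' @param ref A `mito_reference`.
#' @param tree A `phylotree`; the haplogroup is sampled from its leaves.
#' @param n_extra_hom,n_het Numbers of extra homoplasmic and heteroplasmic
#'   substitutions at positions not used by the tree.
#' @param het_range Range the heteroplasmic fractions are drawn from.
#' @param seed Integer seed.
#' @param id Cell identifier.
#' @return A `cell_genotype`.
#' @export
random_genotype <- function(ref, tree, n_extra_hom = 2L, n_het = 3L,
                            het_range = c(0.05, 0.95), seed = 1L,
                            id = "cell1") {
  used <- unlist(lapply(tree$table$variants,
                        function(v) parse_variant_tokens(v)$pos))
  with_seed(seed, {
    hg <- sample(tree_leaves(tree), 1L)
    free <- setdiff(seq_len(ref$length), used)
    pos <- sample(free, n_extra_hom + n_het)
    mk <- function(p) {
      if (length(p) == 0)
        return(data.frame(pos = integer(0), ref = character(0),
                          alt = character(0), stringsAsFactors = FALSE))
      rb <- substring(ref$sequence, p, p)
      ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      data.frame(pos = p, ref = rb, alt = ab, stringsAsFactors = FALSE)
    }
    hom <- mk(head(pos, n_extra_hom))
    het <- mk(pos[seq_len(n_het) + n_extra_hom])
    het$fraction <- runif(n_het, het_range[1], het_range[2])
    cell_genotype(id, hg, hom, het)
  })
}

#' Realise a genotype on the reference
#'
#' Applies the genotype's homoplasmic variants (cumulative haplogroup path
#' plus extras) to the reference sequence, keeping heteroplasmic variants as
#' mixture instructions for read generation.
#'
#' @param ref A `mito_reference`.
#' @param tree A `phylotree` (may be `NULL` when the genotype has no
#'   haplogroup).
#' @param genotype A `cell_genotype`.
#' @return A list of class `haplotype` with `sequence` (homoplasmic-applied),
#'   `het` (heteroplasmic instructions) and `truth`, the full variant list
#'   (`pos`, `ref`, `alt`, `fraction`; fraction 1 for homoplasmic).
#' @export
apply_genotype <- function(ref, tree, genotype) {
  hom <- genotype$extra_hom
  if (!is.null(genotype$haplogroup)) {
    if (is.null(tree)) stop("genotype names a haplogroup but no tree given")
    hom <- rbind(cumulative_variants(tree, genotype$haplogroup), hom)
  }
  all_pos <- c(hom$pos, genotype$het$pos)
  if (any(all_pos < 1L | all_pos > ref$length))
    stop("variant position outside reference")
  check <- rbind(hom[c("pos", "ref")], genotype$het[c("pos", "ref")])
  if (nrow(check) > 0) {
    have <- substring(ref$sequence, check$pos, check$pos)
    bad <- have != check$ref
    if (any(bad))
      stop("reference allele mismatch at position(s) ",
           paste(check$pos[bad], collapse = ", "))
  }
  seq <- ref$sequence
  if (nrow(hom) > 0) {
    s <- strsplit(seq, "")[[1]]
    s[hom$pos] <- hom$alt
    seq <- paste(s, collapse = "")
  }
  truth <- rbind(
    if (nrow(hom) > 0) cbind(hom, fraction = 1) else NULL,
    genotype$het)
  if (is.null(truth))
    truth <- data.frame(pos = integer(0), ref = character(0),
                        alt = character(0), fraction = numeric(0),
                        stringsAsFactors = FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(sequence = seq, het = genotype$het, truth = truth,
                 id = genotype$id, length = ref$length),
            class = "haplotype")
}
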