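#' Phylotree-like haplogroup trees
#'
#' A haplogroup tree assigns each named haplogroup a parent and a set of
#' defining variants; the variants carried by a haplogroup are the union of
#' the defining variants along its root-to-node path, applied left to right
#' so that a later entry at a position overrides an ancestral allele
#' (a back-mutation is notated as a reversion entry `posALT>REF` deeper in
#' the path). The on-disk format is a TSV with columns `haplogroup`,
#' `parent` (`-` for the root) and `variants` (comma-separated `posREF>ALT`,
#' empty allowed).
#'
#' @param table Data frame with columns `haplogroup`, `parent`, `variants`.
#' @return An object of class `phylotree`.
#' @export
phylotree <- function(table) {
  stopifnot(all(c("haplogroup", "parent", "variants") %in% names(table)))
  table$haplogroup <- as.character(table$haplogroup)
  table$parent <- as.character(table$parent)
  table$parent[is.na(table$parent) | table$parent == ""] <- "-"
  table$variants <- as.character(table$variants)
  table$variants[is.na(table$variants)] <- ""
  roots <- table$haplogroup[table$parent == "-"]
  if (length(roots) != 1L)
    stop("tree must have exactly one root, found ", length(roots))
  non_root <- table$parent != "-"
  if (!all(table$parent[non_root] %in% table$haplogroup))
    stop("unknown parent haplogroup(s): ",
         paste(setdiff(table$parent[non_root], table$haplogroup), collapse = ", "))
  if (anyDuplicated(table$haplogroup))
    stop("duplicated haplogroup names")
  tr <- structure(list(table = table, root = roots), class = "phylotree")
  for (hg in table$haplogroup) cumulative_variants(tr, hg)  # validates paths
  tr
}

#' @export
print.phylotree <- function(x, ...) {
  cat("Haplogroup tree: ", nrow(x$table), " nodes, root '", x$root, "'\n",
      sep = "")
  invisible(x)
}

parse_variant_tokens <- function(s) {
  if (is.na(s) || s == "") {
    return(data.frame(pos = integer(0), ref = character(0),
                      alt = character(0), stringsAsFactors = FALSE))
  }
  toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  toks <- toks[toks != ""]
  m <- regmatches(toks, regexec("^([0-9]+)([ACGT])>([ACGT])$", toks))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) stop("malformed variant token(s): ",
                     paste(toks[bad], collapse = ", "))
  data.frame(pos = as.integer(vapply(m, `[`, "", 2L)),
             ref = vapply(m, `[`, "", 3L),
             alt = vapply(m, `[`, "", 4L), stringsAsFactors = FALSE)
}

format_variant_tokens <- function(df) {
  if (nrow(df) == 0L) return("")
  paste0(df$pos, df$ref, ">", df$alt, collapse = ",")
}

#' Read a haplogroup tree from TSV
#'
#' @param path TSV path with columns `haplogroup`, `parent`, `variants`.
#' @return A `phylotree`.
#' @export
read_phylotree <- function(path) {
  phylotree(read.delim(path, colClasses = "character"))
}

#' Write a haplogroup tree to TSV
#'
#' @param tree A `phylotree`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylotree <- function(tree, path) {
  write.table(tree$table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

path_to_root <- function(tree, haplogroup) {
  tab <- tree$table
  chain <- character(0)
  hg <- haplogroup
  repeat {
    i <- match(hg, tab$haplogroup)
    if (is.na(i)) stop("unknown haplogroup: ", hg)
    chain <- c(hg, chain)
    if (tab$parent[i] == "-") break
    hg <- tab$parent[i]
    if (length(chain) > nrow(tab)) stop("cycle detected in tree")
  }
  chain
}

#' Cumulative defining variants of a haplogroup
#'
#' Walks the root-to-node path and accumulates defining variants; a later
#' entry at an already-seen position replaces the earlier allele, and a
#' reversion back to the reference allele removes the position entirely.
#'
#' @param tree A `phylotree`.
#' @param haplogroup Haplogroup name present in the tree.
#' @param ref Optional `mito_reference`; when given, a variant whose `alt`
#'   equals the reference base at its position (a reversion to reference)
#'   drops out of the cumulative set.
#' @return Data frame with columns `pos`, `ref`, `alt`.
#' @export
cumulative_variants <- function(tree, haplogroup, ref = NULL) {
  chain <- path_to_root(tree, haplogroup)
  tab <- tree$table
  acc <- list()
  for (hg in chain) {
    df <- parse_variant_tokens(tab$variants[match(hg, tab$haplogroup)])
    for (i in seq_len(nrow(df))) {
      key <- as.character(df$pos[i])
      prev <- acc[[key]]
      if (!is.null(prev)) {
        if (prev$alt != df$ref[i])
          stop("inconsistent path at position ", df$pos[i], " for ", haplogroup,
               ": have allele ", prev$alt, ", entry expects ", df$ref[i])
        if (df$alt[i] == prev$ref) { acc[[key]] <- NULL; next }  # reversion
        acc[[key]] <- data.frame(pos = df$pos[i], ref = prev$ref,
                                 alt = df$alt[i], stringsAsFactors = FALSE)
      } else {
        acc[[key]] <- df[i, , drop = FALSE]
      }
    }
  }
  out <- if (length(acc) == 0L)
    data.frame(pos = integer(0), ref = character(0), alt = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, unname(acc))
  if (!is.null(ref)) {
    base <- substring(ref$sequence, out$pos, out$pos)
    out <- out[out$alt != base, , drop = FALSE]
  }
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leaf haplogroups of a tree
#'
#' @param tree A `phylotree`.
#' @return Character vector of haplogroups that are no node's parent.
#' @export
tree_leaves <- function(tree) {
  setdiff(tree$table$haplogroup, tree$table$parent)
}

#' Generate a random haplogroup tree consistent with a reference
#'
#' Builds a balanced toy tree whose defining variants are substitutions drawn
#' at distinct positions of `ref`, so that any haplogroup's cumulative
#' variants can be applied to the reference without allele mismatches.
#'
#' @param ref A `mito_reference`.
#' @param levels Number of levels below the root.
#' @param children Children per internal node.
#' @param vars_per_node Defining variants per node (root included).
#' @param seed Integer seed.
#' @return A `phylotree`.
#' @export
random_phylotree <- function(ref, levels = 2L, children = 2L,
                             vars_per_node = 3L, seed = 1L) {
  n_nodes <- sum(children ^ (0:levels))
  need <- n_nodes * vars_per_node
  if (need > ref$length) stop("reference too short for requested tree")
  with_seed(seed, {
    pos_pool <- sample.int(ref$length, need)
    rows <- list()
    take <- local({
      i <- 0L
      function(n) {
        out <- pos_pool[(i + 1L):(i + n)]
        i <<- i + n
        out
      }
    })
    mk_vars <- function() {
      p <- sort(take(vars_per_node))
      rb <- substring(ref$sequence, p, p)
      ab <- vapply(rb, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
      format_variant_tokens(data.frame(pos = p, ref = rb, alt = ab,
                                       stringsAsFactors = FALSE))
    }
    rows[["H"]] <- data.frame(haplogroup = "H", parent = "-",
                              variants = mk_vars(), stringsAsFactors = FALSE)
    frontier <- "H"
    for (lv in seq_len(levels)) {
      nxt <- character(0)
      for (par in frontier) {
        for (ch in seq_len(children)) {
          nm <- paste0(par, ch)
          rows[[nm]] <- data.frame(haplogroup = nm, parent = par,
                                   variants = mk_vars(),
                                   stringsAsFactors = FALSE)
          nxt <- c(nxt, nm)
        }
      }
      frontier <- nxt
    }
    phylotree(do.call(rbind, rows))
  })
}
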