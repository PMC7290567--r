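#' Construct a call set for concordance analysis
#'
#' @param variants Data frame with `pos`, `ref`, `alt`, `af`, `total`
#'   (a `variant_calls` works directly; its `total` column is used as
#'   depth).
#' @param id Cell/sample identifier.
#' @param assay Assay label, one of `"WGS"`, `"WES"`, `"ATAC"`, `"BULK"`.
#' @return An object of class `callset`.
#' @export
callset <- function(variants, id, assay = c("WGS", "WES", "ATAC", "BULK")) {
  assay <- match.arg(assay)
  df <- as.data.frame(variants)
  if (!"af" %in% names(df) && "AF" %in% names(df)) df$af <- df$AF
  stopifnot(all(c("pos", "ref", "alt", "af", "total") %in% names(df)))
  if (any(df$af < 0 | df$af > 1)) stop("allele frequencies must be in [0, 1]")
  if (any(df$total < 0)) stop("depths must be non-negative")
  df$key <- variant_key(df)
  if (anyDuplicated(df$key)) stop("duplicate (pos, ref, alt) keys")
  df <- df[order(df$pos, df$alt), c("pos", "ref", "alt", "af", "total", "key")]
  rownames(df) <- NULL
  structure(list(id = id, assay = assay, variants = df), class = "callset")
}

variant_key <- function(df) paste0("m.", df$pos, df$ref, ">", df$alt)

#' @export
print.callset <- function(x, ...) {
  cat("Call set '", x$id, "' (", x$assay, "): ", nrow(x$variants),
      " variants\n", sep = "")
  invisible(x)
}

#' Read a VCF file as a call set
#'
#' @param path VCF path.
#' @param id Sample identifier.
#' @param assay Assay label.
#' @return A `callset`.
#' @export
vcf_callset <- function(path, id, assay = "WGS") {
  callset(read_vcf(path), id, assay)
}

#' Filter a call set on allele frequency and depth
#'
#' Retains variants with `af >= af_min` and `total >= depth_min`.
#'
#' @param cs A `callset`.
#' @param af_min Minimum allele frequency (fraction).
#' @param depth_min Minimum total depth.
#' @return The filtered `callset`.
#' @export
filter_callset <- function(cs, af_min, depth_min) {
  if (af_min <= 0 && depth_min <= 0) return(cs)
  v <- cs$variants
  v <- v[v$af >= af_min & v$total >= depth_min, , drop = FALSE]
  rownames(v) <- NULL
  out <- cs
  out$variants <- v
  out
}

#' Pairwise variant concordance between two cells
#'
#' Variant identity is the exact (pos, ref, alt) key. `all` is the union,
#' `common` the intersection; common variants with both allele frequencies
#' above `hom_af` are homoplasmic, the rest heteroplasmic. When a filtered
#' bulk call set is supplied, `confirmed` counts common variants also
#' present in it. Percentages are reported to two decimals; with no common
#' variants `pct_confirmed` is reported as 0 and flagged degenerate.
#'
#' @param a,b `callset`s of the two cells.
#' @param bulk Optional bulk `callset`.
#' @param af_min,depth_min Thresholds applied to `a`, `b` and `bulk` alike
#'   (default 3% and 50).
#' @param hom_af Homoplasmy threshold on AF (strict, default 0.95).
#' @return An object of class `pairwise_concordance`: list with `all`,
#'   `common`, `hom`, `het`, `pct_common`, `unique`, `confirmed`,
#'   `pct_confirmed`, per-cell totals `n_a`, `n_b`, and `degenerate`.
#' @export
pairwise_concordance <- function(a, b, bulk = NULL, af_min = 0.03,
                                 depth_min = 50L, hom_af = 0.95) {
  fa <- filter_callset(a, af_min, depth_min)$variants
  fb <- filter_callset(b, af_min, depth_min)$variants
  common_keys <- intersect(fa$key, fb$key)
  all_n <- length(union(fa$key, fb$key))
  common <- length(common_keys)
  af_a <- fa$af[match(common_keys, fa$key)]
  af_b <- fb$af[match(common_keys, fb$key)]
  hom <- sum(af_a > hom_af & af_b > hom_af)
  confirmed <- NA_integer_
  if (!is.null(bulk)) {
    fk <- filter_callset(bulk, af_min, depth_min)$variants$key
    confirmed <- sum(common_keys %in% fk)
  }
  degenerate <- common == 0L
  structure(list(
    all = all_n, common = common, hom = hom, het = common - hom,
    pct_common = if (all_n > 0) round(100 * common / all_n, 2) else 0,
    unique = all_n - common,
    confirmed = confirmed,
    pct_confirmed = if (is.na(confirmed)) NA_real_
                    else if (degenerate) 0
                    else round(100 * confirmed / common, 2),
    n_a = nrow(fa), n_b = nrow(fb),
    af_min = af_min, depth_min = depth_min,
    degenerate = degenerate), class = "pairwise_concordance")
}

#' @export
print.pairwise_concordance <- function(x, ...) {
  cat("Pairwise concordance (AF>=", x$af_min, ", DP>=", x$depth_min, "): ",
      "all=", x$all, " common=", x$common, " (", x$pct_common, "%), hom=",
      x$hom, " het=", x$het, " unique=", x$unique, sep = "")
  if (!is.na(x$confirmed))
    cat(", confirmed=", x$confirmed, " (", x$pct_confirmed, "%)", sep = "")
  cat("\n")
  invisible(x)
}

#' Variant-calling precision from replicate concordance
#'
#' Treats variants shared between the replicates as true positives: each
#' cell's positive predictive value is the number of common variants over
#' that cell's total calls, as a percentage.
#'
#' @param pc A `pairwise_concordance`.
#' @return List with `ppv_a`, `ppv_b` and `mean` (percentages).
#' @export
ppv <- function(pc) {
  stopifnot(inherits(pc, "pairwise_concordance"))
  pa <- if (pc$n_a > 0) 100 * pc$common / pc$n_a else 0
  pb <- if (pc$n_b > 0) 100 * pc$common / pc$n_b else 0
  list(ppv_a = pa, ppv_b = pb, mean = (pa + pb) / 2)
}

#' Threshold grid for concordance sweeps
#'
#' @param af Allele-frequency thresholds (ascending fractions; default 1%
#'   to 10% by 1%).
#' @param depth Depth thresholds (ascending; default 10, 30, 50, 100, 500,
#'   1000).
#' @return A list of class `threshold_grid`.
#' @export
threshold_grid <- function(af = seq(0.01, 0.10, by = 0.01),
                           depth = c(10L, 30L, 50L, 100L, 500L, 1000L)) {
  if (any(af <= 0) || any(depth <= 0)) stop("thresholds must be positive")
  if (is.unsorted(af) || is.unsorted(depth))
    stop("thresholds must be ascending")
  structure(list(af = af, depth = as.integer(depth)),
            class = "threshold_grid")
}

#' Concordance across a grid of thresholds
#'
#' @param a,b,bulk `callset`s (bulk optional).
#' @param grid A `threshold_grid`.
#' @return Data frame with one row per (af, depth) grid point and the
#'   pairwise-concordance fields as columns.
#' @export
threshold_sweep <- function(a, b, bulk = NULL, grid = threshold_grid()) {
  if (length(grid$af) == 0 || length(grid$depth) == 0) stop("empty grid")
  pts <- expand.grid(af_min = grid$af, depth_min = grid$depth)
  rows <- lapply(seq_len(nrow(pts)), function(i) {
    pc <- pairwise_concordance(a, b, bulk, pts$af_min[i], pts$depth_min[i])
    data.frame(af_min = pts$af_min[i], depth_min = pts$depth_min[i],
               all = pc$all, common = pc$common, hom = pc$hom, het = pc$het,
               pct_common = pc$pct_common, unique = pc$unique,
               confirmed = if (is.na(pc$confirmed)) NA_integer_ else pc$confirmed,
               pct_confirmed = pc$pct_confirmed)
  })
  do.call(rbind, rows)
}

#' Allele-frequency correlation over shared variants
#'
#' Pearson correlation of the allele frequencies of variants present in
#' both call sets, with the two-sided p-value from the t transform.
#'
#' @param a,b `callset`s.
#' @return List with `r`, `p_value`, `n` (shared variants).
#' @export
af_correlation <- function(a, b) {
  va <- a$variants
  vb <- b$variants
  keys <- intersect(va$key, vb$key)
  n <- length(keys)
  if (n < 3) stop("need at least 3 shared variants, have ", n)
  x <- va$af[match(keys, va$key)]
  y <- vb$af[match(keys, vb$key)]
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * pt(abs(tstat), n - 2, lower.tail = FALSE), n = n)
}

#' Tabulate variants across many cells
#'
#' Builds the variant-by-cell table: one row per variant passing the AF and
#' depth filters in at least `min_cells` cells of some assay, with
#' per-assay cell counts and mean allele frequencies, a flag for presence
#' in the (identically filtered) bulk call set, and the raw bulk allele
#' frequency reported regardless of bulk depth (0 when the site is absent).
#'
#' @param callsets List of `callset`s (possibly spanning several assays).
#' @param bulk Optional bulk `callset`.
#' @param af_min,depth_min Filter thresholds (default 3% and 30).
#' @param min_cells Minimum number of cells carrying the variant (default
#'   2).
#' @return A `multicell_table` data frame: `variant`, `pos`, `ref`, `alt`,
#'   `n_cells_<assay>` and `mean_af_<assay>` per assay, `in_bulk`,
#'   `bulk_af`.
#' @export
tabulate_multicell <- function(callsets, bulk = NULL, af_min = 0.03,
                               depth_min = 30L, min_cells = 2L) {
  if (length(callsets) < 2) stop("need at least 2 cells")
  assays <- unique(vapply(callsets, function(cs) cs$assay, ""))
  filt <- lapply(callsets, filter_callset, af_min = af_min,
                 depth_min = depth_min)
  allv <- do.call(rbind, lapply(filt, function(cs)
    cbind(cs$variants, assay = cs$assay)))
  if (is.null(allv) || nrow(allv) == 0) stop("no variants pass the filters")
  keys <- unique(allv$key)
  per_assay <- lapply(assays, function(as_) {
    sub <- allv[allv$assay == as_, , drop = FALSE]
    n <- vapply(keys, function(k) sum(sub$key == k), 0L)
    maf <- vapply(keys, function(k) {
      af <- sub$af[sub$key == k]
      if (length(af)) mean(af) else NA_real_
    }, 0)
    list(n = n, maf = maf)
  })
  names(per_assay) <- assays
  counts <- do.call(cbind, lapply(per_assay, `[[`, "n"))
  keep <- apply(counts >= min_cells, 1, any)
  keys <- keys[keep]
  first <- allv[match(keys, allv$key), c("pos", "ref", "alt")]
  out <- data.frame(variant = keys, first, stringsAsFactors = FALSE)
  for (as_ in assays) {
    out[[paste0("n_cells_", as_)]] <- per_assay[[as_]]$n[keep]
    out[[paste0("mean_af_", as_)]] <- per_assay[[as_]]$maf[keep]
  }
  if (!is.null(bulk)) {
    fb <- filter_callset(bulk, af_min, depth_min)$variants$key
    out$in_bulk <- as.integer(keys %in% fb)
    raw <- bulk$variants
    out$bulk_af <- ifelse(keys %in% raw$key, raw$af[match(keys, raw$key)], 0)
  } else {
    out$in_bulk <- NA_integer_
    out$bulk_af <- NA_real_
  }
  out <- out[order(out$pos, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("multicell_table", "data.frame")
  out
}

#' Summary statistics of a multi-cell variant table
#'
#' @param tab Data frame with one row per variant carrying a cell count, a
#'   mean allele frequency and a bulk flag (see `cells_col`, `af_col`,
#'   `bulk_col`).
#' @param n_cells Number of cells the counts refer to.
#' @param hom_af Homoplasmy threshold: rows with mean AF strictly above it
#'   are homoplasmic/quasi-homoplasmic (default 0.95).
#' @param cells_col,af_col,bulk_col Column names holding the per-variant
#'   cell count, mean allele frequency and bulk 0/1 flag.
#' @return List with `n_variants`, `n_hom`, `n_het`, `het_af_min`,
#'   `het_af_max`, `pct_bulk_confirmed` and `pct_shared_by_majority`
#'   (percentages rounded to the nearest integer; majority is a strict
#'   `> n_cells / 2`), and `n_majority`, the corresponding count.
#' @export
table_stats <- function(tab, n_cells, hom_af = 0.95, cells_col = "n_cells",
                        af_col = "mean_af", bulk_col = "in_bulk") {
  if (nrow(tab) == 0) stop("empty variant table")
  cells <- tab[[cells_col]]
  maf <- tab[[af_col]]
  bulkf <- tab[[bulk_col]]
  if (is.null(cells) || is.null(maf) || is.null(bulkf))
    stop("missing required column(s)")
  n <- nrow(tab)
  hom <- maf > hom_af
  n_major <- sum(cells > n_cells / 2)
  list(n_variants = n,
       n_hom = sum(hom),
       n_het = sum(!hom),
       het_af_min = if (any(!hom)) min(maf[!hom]) else NA_real_,
       het_af_max = if (any(!hom)) max(maf[!hom]) else NA_real_,
       pct_bulk_confirmed = round(100 * sum(bulkf == 1) / n),
       n_majority = n_major,
       pct_shared_by_majority = round(100 * n_major / n))
}

#' Load a packaged published variant table
#'
#' Packaged transcriptions of published single-cell mtDNA variant tables:
#' `"ht29_pairwise"` (pairwise concordance of HT-29 cell pairs per
#' amplification protocol), `"ht29_ewga_cells"` (variants across nine
#' eWGA-amplified HT-29 cells sequenced by WGS and WES) and
#' `"tf1_atac_cells"` (variants across 48 TF-1 cells from scATAC-seq
#' libraries).
#'
#' @param name Table name.
#' @return Data frame.
#' @export
packaged_table <- function(name = c("ht29_pairwise", "ht29_ewga_cells",
                                    "tf1_atac_cells")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "scmito",
                      mustWork = TRUE)
  read.delim(path, na.strings = "-")
}

#' Normalise a packaged multi-cell table to one assay
#'
#' Selects one assay's columns of a packaged multi-cell table and renames
#' them to the standard `n_cells` / `mean_af` / `in_bulk` schema expected
#' by [table_stats()], dropping variants absent from that assay.
#'
#' @param tab A packaged multi-cell table data frame.
#' @param assay `"WGS"`, `"WES"` (for the HT-29 table) or `"ATAC"` (for the
#'   TF-1 table).
#' @return Data frame `variant`, `n_cells`, `mean_af`, `in_bulk`,
#'   `bulk_af`.
#' @export
assay_view <- function(tab, assay = c("WGS", "WES", "ATAC")) {
  assay <- match.arg(assay)
  if (assay == "ATAC") {
    out <- data.frame(variant = tab$variant, n_cells = tab$n_cells,
                      mean_af = tab$maf, in_bulk = tab$in_bulk,
                      bulk_af = tab$maf_bulk, stringsAsFactors = FALSE)
  } else {
    cc <- if (assay == "WGS") tab$in_wgs else tab$in_wes
    af <- if (assay == "WGS") tab$maf_wgs else tab$maf_wes
    out <- data.frame(variant = tab$variant, n_cells = cc, mean_af = af,
                      in_bulk = tab$in_bulk, bulk_af = tab$maf_bulk,
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$n_cells), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
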