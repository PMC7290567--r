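#' Adapter/quality trimming configuration
#'
#' @param adapter Adapter sequence expected at read 3' ends.
#' @param stringency Minimum adapter-prefix overlap with the read suffix
#'   required to trim (default 3).
#' @param quality_cutoff 3'-end Phred cutoff (default 20); trailing bases
#'   below it are removed after adapter trimming.
#' @param min_length Reads shorter than this after trimming are dropped.
#' @return An object of class `trim_config`.
#' @export
trim_config <- function(adapter = "AGATCGGAAGAGC", stringency = 3L,
                        quality_cutoff = 20L, min_length = 30L) {
  if (nchar(adapter) < 1) stop("adapter must be non-empty")
  if (stringency < 1) stop("stringency (minimum overlap) must be >= 1")
  if (quality_cutoff < 0 || quality_cutoff > 41)
    stop("quality cutoff must be in [0, 41]")
  structure(list(adapter = toupper(adapter), stringency = as.integer(stringency),
                 quality_cutoff = as.integer(quality_cutoff),
                 min_length = as.integer(min_length)),
            class = "trim_config")
}

#' Trim adapters and low-quality 3' ends
#'
#' For each read, the longest adapter prefix of length at least the
#' stringency that matches the read suffix is removed; then trailing bases
#' with quality below the cutoff are removed; reads shorter than the minimum
#' length are dropped. Qualities stay in register with bases throughout.
#'
#' @param reads A `read_set`.
#' @param cfg A `trim_config`.
#' @return The trimmed `read_set` (possibly fewer rows).
#' @export
trim_reads <- function(reads, cfg = trim_config()) {
  stopifnot(inherits(cfg, "trim_config"))
  adapter <- cfg$adapter
  alen <- nchar(adapter)
  seqs <- reads$seq
  quals <- reads$qual
  lens <- nchar(seqs)
  keep_len <- lens
  for (i in seq_along(seqs)) {
    l <- lens[i]
    for (o in rev(seq_len(min(alen, l)))) {
      if (o < cfg$stringency) break
      if (substr(seqs[i], l - o + 1L, l) == substr(adapter, 1L, o)) {
        keep_len[i] <- l - o
        break
      }
    }
    # 3' quality trim
    q <- utf8ToInt(quals[i]) - 33L
    kl <- keep_len[i]
    while (kl > 0L && q[kl] < cfg$quality_cutoff) kl <- kl - 1L
    keep_len[i] <- kl
  }
  seqs <- substr(seqs, 1L, keep_len)
  quals <- substr(quals, 1L, keep_len)
  out <- reads
  out$seq <- seqs
  out$qual <- quals
  out <- out[keep_len >= cfg$min_length, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}
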