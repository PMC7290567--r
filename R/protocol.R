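#' Amplification-protocol read models
#'
#' Each protocol is a minimal positional-bias model chosen to reproduce the
#' qualitative coverage-uniformity ordering observed across single-cell
#' whole-genome-amplification chemistries: an unamplified bulk is uniform;
#' MDA and eWGA produce smooth multiplicative bias (block-lognormal
#' positional weights, eWGA less dispersed than MDA); DOP-PCR concentrates
#' coverage in amplicon-like windows; MALBAC adds genome-fraction dropout on
#' top of windowed bias; ATAC-like libraries are uniform but heavily
#' duplicated.
#'
#' @param name One of `"BULK"`, `"MDA"`, `"eWGA"`, `"DOP"`, `"MALBAC"`,
#'   `"ATAC"`.
#' @param sigma Lognormal sigma of the block bias field (smooth-bias
#'   protocols).
#' @param block Length in bases of one bias block / amplicon window.
#' @param window_frac Fraction of the genome inside high-weight windows
#'   (windowed protocols).
#' @param window_ratio Weight ratio inside vs outside windows.
#' @param dropout Fraction of the genome receiving zero weight.
#' @param dup_rate Fraction of emitted reads that are PCR duplicates, in
#'   `[0, 1)`.
#' @param error_rate Per-base sequencing error rate, in `[0, 0.1]`.
#' @param read_length Read length in bases.
#' @param paired Logical; paired ends are simulated as two independent
#'   single-end reads, so this is informational only.
#' @return An object of class `protocol_model`.
#' @examples
#' protocol_model("MDA")
#' @export
protocol_model <- function(name = c("BULK", "MDA", "eWGA", "DOP", "MALBAC", "ATAC"),
                           sigma = NULL, block = NULL, window_frac = NULL,
                           window_ratio = NULL, dropout = NULL,
                           dup_rate = NULL, error_rate = NULL,
                           read_length = 100L, paired = FALSE) {
  name <- match.arg(name)
  def <- switch(name,
    BULK   = list(sigma = 0,    block = 500L, window_frac = 0,    window_ratio = 1,  dropout = 0,    dup_rate = 0.01, error_rate = 0.001),
    MDA    = list(sigma = 0.55, block = 500L, window_frac = 0,    window_ratio = 1,  dropout = 0,    dup_rate = 0.05, error_rate = 0.001),
    eWGA   = list(sigma = 0.35, block = 500L, window_frac = 0,    window_ratio = 1,  dropout = 0,    dup_rate = 0.05, error_rate = 0.001),
    DOP    = list(sigma = 0,    block = 600L, window_frac = 0.35, window_ratio = 20, dropout = 0,    dup_rate = 0.10, error_rate = 0.001),
    MALBAC = list(sigma = 0,    block = 600L, window_frac = 0.30, window_ratio = 20, dropout = 0.90, dup_rate = 0.10, error_rate = 0.002),
    ATAC   = list(sigma = 0,    block = 500L, window_frac = 0,    window_ratio = 1,  dropout = 0,    dup_rate = 0.30, error_rate = 0.001))
  take <- function(given, dflt) if (is.null(given)) dflt else given
  m <- list(name = name,
            sigma = take(sigma, def$sigma),
            block = as.integer(take(block, def$block)),
            window_frac = take(window_frac, def$window_frac),
            window_ratio = take(window_ratio, def$window_ratio),
            dropout = take(dropout, def$dropout),
            dup_rate = take(dup_rate, def$dup_rate),
            error_rate = take(error_rate, def$error_rate),
            read_length = as.integer(read_length),
            paired = paired)
  if (m$dropout < 0 || m$dropout >= 1) stop("dropout fraction must be in [0, 1)")
  if (m$dup_rate < 0 || m$dup_rate >= 1) stop("duplicate rate must be in [0, 1)")
  if (m$error_rate < 0 || m$error_rate > 0.1)
    stop("error rate must be in [0, 0.1]")
  if (m$read_length < 30L) stop("read length must cover at least two seed k-mers")
  structure(m, class = "protocol_model")
}

#' @export
print.protocol_model <- function(x, ...) {
  cat("Protocol model ", x$name,
      ": sigma=", x$sigma, ", window_frac=", x$window_frac,
      ", dropout=", x$dropout, ", dup=", x$dup_rate,
      ", err=", x$error_rate, ", len=", x$read_length, "\n", sep = "")
  invisible(x)
}

#' Positional fragment-start weights of a protocol
#'
#' Returns the (unnormalised) probability weight of a fragment starting at
#' each of the `L` positions of the circular genome, drawn from the
#' protocol's bias model under the given seed.
#'
#' @param model A `protocol_model`.
#' @param L Genome length.
#' @param seed Integer seed.
#' @return Numeric vector of length `L`, non-negative, not all zero.
#' @export
positional_weights <- function(model, L, seed) {
  with_seed(seed, {
    n_block <- max(1L, ceiling(L / model$block))
    block_id <- rep(seq_len(n_block), each = model$block)[seq_len(L)]
    w <- rep(1, L)
    if (model$sigma > 0) {
      bw <- rlnorm(n_block, meanlog = 0, sdlog = model$sigma)
      w <- bw[block_id]
    }
    if (model$window_frac > 0) {
      n_win <- max(1L, round(model$window_frac * n_block))
      win <- sample.int(n_block, n_win)
      bw <- rep(1, n_block)
      bw[win] <- model$window_ratio
      w <- w * bw[block_id]
    }
    if (model$dropout > 0) {
      keep <- runif(n_block) >= model$dropout
      if (!any(keep)) keep[sample.int(n_block, 1L)] <- TRUE
      w <- w * as.numeric(keep[block_id])
    }
    w
  })
}
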