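#' Per-base depth profile
#'
#' @param x A `mito_pileup` (filtered depth is used), an `alignment_set`
#'   (aligned spans), or a `read_set` (true source intervals).
#' @param L Genome length (required for alignment/read-set inputs lacking
#'   the attribute).
#' @param ... Unused.
#' @return Integer vector of length `L` of class `depth_profile`.
#' @export
depth_profile <- function(x, L = NULL, ...) UseMethod("depth_profile")

#' @export
depth_profile.mito_pileup <- function(x, L = NULL, ...) {
  structure(x$filtered_depth, class = "depth_profile")
}

#' @export
depth_profile.alignment_set <- function(x, L = attr(x, "mt_len"), ...) {
  a <- x[!is.na(x$mt_start), , drop = FALSE]
  structure(cpp_interval_depth(a$mt_start, a$mt_span, L),
            class = "depth_profile")
}

#' @export
depth_profile.read_set <- function(x, L, ...) {
  structure(cpp_interval_depth(wrap_pos(x$start, L), x$end - x$start + 1L, L),
            class = "depth_profile")
}

#' @export
depth_profile.numeric <- function(x, L = NULL, ...) {
  if (any(x < 0)) stop("depths must be non-negative")
  structure(as.integer(round(x)), class = "depth_profile")
}

#' @export
depth_profile.integer <- depth_profile.numeric

#' Lorenz curve and Gini coefficient of a depth profile
#'
#' Positions are sorted by ascending depth; the curve plots the cumulative
#' fraction of genome positions against the cumulative fraction of
#' sequenced bases. A perfectly uniform profile lies on the diagonal
#' (Gini 0); concentration of coverage bows the curve below it. The Gini
#' coefficient is one minus twice the trapezoidal area under the polyline.
#'
#' @param profile A `depth_profile` (or plain non-negative vector).
#' @param include_zeros Keep zero-depth positions (default TRUE, the full
#'   genome); set FALSE to restrict to covered positions only.
#' @return An object of class `lorenz_curve`: list with `x`, `y` (polyline
#'   including (0,0)), `gini`, `include_zeros`.
#' @export
lorenz <- function(profile, include_zeros = TRUE) {
  d <- as.numeric(unclass(profile))
  if (any(d < 0)) stop("depths must be non-negative")
  if (!include_zeros) d <- d[d > 0]
  if (length(d) == 0 || sum(d) <= 0)
    stop("total depth is zero; Lorenz curve undefined")
  d <- sort(d)
  n <- length(d)
  x <- c(0, seq_len(n) / n)
  y <- c(0, cumsum(d) / sum(d))
  auc <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  structure(list(x = x, y = y, gini = 1 - 2 * auc,
                 include_zeros = include_zeros),
            class = "lorenz_curve")
}

#' Gini coefficient of coverage inequality
#'
#' @param x A `depth_profile`, numeric vector, or `lorenz_curve`.
#' @param ... Passed to [lorenz()].
#' @return Gini coefficient in `[0, 1)`.
#' @export
gini <- function(x, ...) {
  if (inherits(x, "lorenz_curve")) return(x$gini)
  lorenz(x, ...)$gini
}

#' @export
print.lorenz_curve <- function(x, ...) {
  cat("Lorenz curve over ", length(x$x) - 1L, " positions: Gini = ",
      sprintf("%.4f", x$gini), "\n", sep = "")
  invisible(x)
}

#' Plot a Lorenz coverage-uniformity curve
#'
#' @param x A `lorenz_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lorenz_curve <- function(x, ...) {
  graphics::plot(x$x, x$y, type = "l",
                 xlab = "Cumulative fraction of genome positions",
                 ylab = "Cumulative fraction of sequenced bases", ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
}

#' Coverage summary statistics
#'
#' @param profile A `depth_profile`.
#' @param min_depth Depth a position needs to count as covered.
#' @return List with `breadth_pct` (percent of positions at or above
#'   `min_depth`) and `mean_depth`.
#' @export
coverage_stats <- function(profile, min_depth = 1L) {
  d <- as.numeric(unclass(profile))
  if (length(d) == 0) stop("empty depth profile")
  list(breadth_pct = 100 * sum(d >= min_depth) / length(d),
       mean_depth = mean(d))
}

#' Write Lorenz polyline points to TSV
#'
#' @param curve A `lorenz_curve`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lorenz_tsv <- function(curve, path) {
  write.table(data.frame(x = curve$x, y = curve$y), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
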