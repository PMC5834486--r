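# Multiple-testing control and diagnostic plot tables: Storey-Tibshirani
# q-values, QQ points with pointwise confidence bands, Manhattan tables.

#' Storey-Tibshirani q-values
#'
#' The null proportion pi0 is estimated from the tail of the p-value
#' distribution on the lambda grid, pi0(lambda) = #\{p > lambda\} /
#' (m (1 - lambda)), smoothed with a cubic smoothing spline (3 df) and
#' evaluated at the largest lambda, then clamped to (0, 1]. Sorted q-values
#' are the step-down minima of `pi0 * m * p_(j) / j`, so a q-value of 0.1
#' corresponds to an estimated false discovery rate of 10% among calls at
#' that threshold. With fewer than 100 p-values the smoother is unreliable;
#' pi0 is forced to 1 with a warning, which reduces the procedure to
#' Benjamini-Hochberg.
#'
#' @param p vector of p-values in (0, 1].
#' @param lambda tuning grid for the pi0 estimate.
#' @param pi0 optionally force the null proportion (e.g. `pi0 = 1`).
#' @return List of class `qvalue_result`: `q` (input order), `pi0`,
#'   `lambda`, `pi0_lambda` (the raw grid estimates).
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05),
                           pi0 = NULL) {
  m <- length(p)
  if (m < 1L) stop("need at least one p-value")
  if (any(p <= 0 | p > 1 | is.na(p))) stop("p-values must lie in (0, 1]")
  pi0_lambda <- vapply(lambda, function(l) mean(p > l) / (1 - l), 0)
  if (is.null(pi0)) {
    if (m < 100L) {
      warning("fewer than 100 p-values: pi0 smoother unreliable, ",
              "forcing pi0 = 1 (Benjamini-Hochberg)")
      pi0 <- 1
    } else {
      sp <- stats::smooth.spline(lambda, pi0_lambda, df = 3)
      pi0 <- stats::predict(sp, x = max(lambda))$y
      pi0 <- min(max(pi0, 1e-8), 1)
    }
  }
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))   # step-down minimum
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(q = q, pi0 = pi0, lambda = lambda,
                 pi0_lambda = pi0_lambda), class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat("qvalue_result: ", length(x$q), " tests, pi0 = ",
      format(x$pi0, digits = 4), ", min q = ",
      format(min(x$q), digits = 4), "\n", sep = "")
  invisible(x)
}

#' QQ-plot table with a pointwise confidence band
#'
#' For rank i of m (ascending p), the expected quantile is
#' `-log10(i / (m + 1))`; the band endpoints are the alpha/2 and 1 - alpha/2
#' quantiles of the Beta(i, m - i + 1) distribution of the i-th uniform
#' order statistic, on the -log10 scale. The band is pointwise, not
#' simultaneous.
#'
#' @param p p-values in (0, 1].
#' @param band band coverage (default 0.95).
#' @return data.frame with `expected`, `observed`, `band_lo`, `band_hi`
#'   (-log10 scale, ordered by rank; `band_lo < band_hi`).
#' @export
qq_points <- function(p, band = 0.95) {
  m <- length(p)
  stopifnot(m >= 1L, band > 0, band < 1)
  i <- seq_len(m)
  a <- (1 - band) / 2
  data.frame(expected = -log10(i / (m + 1)),
             observed = -log10(sort(p)),
             band_lo = -log10(stats::qbeta(1 - a, i, m - i + 1)),
             band_hi = -log10(stats::qbeta(a, i, m - i + 1)))
}

#' Manhattan-plot table from a scan
#'
#' One row per scan row (windows keep only their `top` haplotype), with a
#' cumulative x-coordinate across chromosomes and a highlight flag for
#' p-values below the threshold.
#'
#' @param scan a `gxe_scan` (needs `chrom`, `pos`, `p`).
#' @param highlight_p highlight threshold (default 1e-6).
#' @param top_only keep one row (lowest p) per window (default TRUE).
#' @return data.frame with `chrom`, `pos`, `x` (cumulative), `neglog10p`,
#'   `highlight`.
#' @export
manhattan_table <- function(scan, highlight_p = 1e-6, top_only = TRUE) {
  df <- as.data.frame(scan)
  if (!nrow(df))
    return(data.frame(chrom = integer(), pos = integer(), x = numeric(),
                      neglog10p = numeric(), highlight = logical()))
  if (top_only && "top" %in% names(df)) df <- df[df$top, , drop = FALSE]
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  offsets <- c(0, cumsum(tapply(df$pos, factor(df$chrom), max)))
  chri <- as.integer(factor(df$chrom))
  # strictly increasing x within and across chromosomes
  data.frame(chrom = df$chrom, pos = df$pos,
             x = df$pos + offsets[chri] + (chri - 1),
             neglog10p = -log10(df$p),
             highlight = df$p < highlight_p, row.names = NULL)
}

#' Fill the q column of a scan from its p-values
#'
#' @param scan a `gxe_scan`.
#' @param ... passed to [storey_qvalues()].
#' @return The scan with `q` filled; pi0 attached as attribute `"pi0"`.
#' @export
add_qvalues <- function(scan, ...) {
  qv <- storey_qvalues(scan$p, ...)
  scan$q <- qv$q
  attr(scan, "pi0") <- qv$pi0
  scan
}

#' Render a QQ plot (base graphics)
#' @param qq a [qq_points()] table.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `qq`.
#' @export
plot_qq <- function(qq, ...) {
  graphics::plot(qq$expected, qq$observed, pch = 20,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)), ...)
  graphics::polygon(c(qq$expected, rev(qq$expected)),
                    c(qq$band_lo, rev(qq$band_hi)),
                    col = grDevices::adjustcolor("grey", 0.5), border = NA)
  graphics::points(qq$expected, qq$observed, pch = 20)
  graphics::abline(0, 1, col = "red")
  invisible(qq)
}

#' Render a Manhattan plot (base graphics)
#' @param mh a [manhattan_table()] table.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `mh`.
#' @export
plot_manhattan <- function(mh, ...) {
  col <- ifelse(mh$highlight, "blue",
                c("grey30", "grey60")[1 + mh$chrom %% 2])
  graphics::plot(mh$x, mh$neglog10p, col = col, pch = 20,
                 xlab = "Position", ylab = expression(-log[10](p)), ...)
  invisible(mh)
}
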