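#' Empirical frequency spectrum
#'
#' The spectrum \eqn{f(n)} gives, for every observed frequency value `n`, the
#' fraction of types having that frequency. It carries the first and second
#' moments of the count distribution (over types), which drive the finite-size
#' rescaling of [rescale_spectrum()].
#'
#' @param table A `freq_tbl` or bare vector of counts.
#' @return A `freq_spectrum`: tibble with columns `n` (strictly increasing)
#'   and `f` (summing to one), with moments stored as attributes `mean_n` and
#'   `mean_n2`.
#' @export
frequency_spectrum <- function(table) {
  counts <- as_counts(table)
  tab <- table(counts)
  n <- as.numeric(names(tab))
  out <- tibble::tibble(n = n, f = as.numeric(tab) / length(counts))
  structure(out,
            mean_n = mean(counts), mean_n2 = mean(counts^2),
            unit = attr(table, "unit", exact = TRUE),
            class = c("freq_spectrum", class(out)))
}

#' Finite-size rescaling of a frequency spectrum
#'
#' Applies the moment rescaling
#' \deqn{x = n \langle n \rangle / \langle n^2 \rangle, \qquad
#'       y = f(n) \langle n^2 \rangle^2 / \langle n \rangle^3,}
#' which in a log-log plot is a pure shift: it preserves the shape of the
#' distribution (and hence any power-law exponent) while removing the leading
#' dependence on sample size. Spectra of distributions sharing a tail
#' exponent collapse onto a common curve after rescaling.
#'
#' @param spec A `freq_spectrum`.
#' @return The spectrum with extra columns `x` and `y`.
#' @export
rescale_spectrum <- function(spec) {
  m1 <- attr(spec, "mean_n", exact = TRUE)
  m2 <- attr(spec, "mean_n2", exact = TRUE)
  if (is.null(m1) || is.null(m2) || !is.finite(m1) || !is.finite(m2) ||
      m1 <= 0 || m2 <= 0) {
    stop("spectrum moments are absent or not positive")
  }
  spec$x <- spec$n * m1 / m2
  spec$y <- spec$f * m2^2 / m1^3
  spec
}

#' Collapse distance between two rescaled spectra
#'
#' Quantifies how well two rescaled spectra collapse onto each other: the mean
#' absolute difference of \eqn{\log_{10} y} over geometrically binned
#' overlapping `x` in the top `decades` decades of the common range. Within
#' each bin the y-values of each spectrum are averaged before taking logs.
#'
#' @param s1,s2 Rescaled spectra (see [rescale_spectrum()]).
#' @param decades Number of upper decades of overlap to compare.
#' @param bins_per_decade Geometric binning resolution.
#' @return A single non-negative number; 0 for identical spectra.
#' @export
collapse_distance <- function(s1, s2, decades = 1.5, bins_per_decade = 5) {
  for (s in list(s1, s2)) {
    if (!all(c("x", "y") %in% names(s))) stop("spectra must be rescaled first")
  }
  hi <- min(max(s1$x), max(s2$x))
  lo <- max(min(s1$x), min(s2$x), hi / 10^decades)
  if (hi <= lo || log10(hi / lo) < decades - 1e-9) {
    stop("insufficient overlap: need at least ", decades,
         " shared decades in x")
  }
  lo <- hi / 10^decades
  edges <- 10^seq(log10(lo), log10(hi), length.out =
                    ceiling(decades * bins_per_decade) + 1)
  # average density over the bin: sum the point masses (y * point spacing)
  # and divide by bin width, so sparsely occupied tail bins are unbiased
  binned <- function(s) {
    keep <- s$x >= lo & s$x <= hi & s$y > 0
    b <- findInterval(s$x[keep], edges, rightmost.closed = TRUE)
    dx <- s$x[1] / s$n[1]  # x spacing per unit count
    mass <- tapply(s$y[keep] * dx, factor(b, levels = seq_len(length(edges) - 1)),
                   sum)
    mass / diff(edges)
  }
  y1 <- binned(s1)
  y2 <- binned(s2)
  ok <- !is.na(y1) & !is.na(y2)
  if (!any(ok)) stop("no shared occupied bins in the comparison range")
  mean(abs(log10(y1[ok]) - log10(y2[ok])))
}

#' Write a spectrum to TSV
#'
#' Columns `n`, `f` and, if present, the rescaled `x`, `y`.
#'
#' @param spec A `freq_spectrum`.
#' @param path Output file path.
#' @export
write_spectrum <- function(spec, path) {
  readr::write_tsv(tibble::as_tibble(spec), path)
  invisible(spec)
}

#' Plot a frequency spectrum
#'
#' Log-log plot of \eqn{f(n)} (or the rescaled coordinates when present).
#'
#' @param object A `freq_spectrum`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.freq_spectrum <- function(object, ...) {
  rescaled <- !is.null(object$x)
  df <- tibble::as_tibble(object)
  base <- if (rescaled) {
    ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$n, .data$f))
  }
  base +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = if (rescaled) expression(n * group("<", n, ">") / group("<", n^2, ">"))
          else "frequency n",
      y = if (rescaled) "rescaled f(n)" else "fraction of types f(n)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted power-law tail over its spectrum
#'
#' @param object A `tail_fit`.
#' @param table The frequency table the fit was obtained from.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tail_fit <- function(object, table, ...) {
  spec <- frequency_spectrum(table)
  p <- autoplot.freq_spectrum(spec)
  if (isTRUE(object$accepted)) {
    b <- object$b %||% Inf
    hi <- if (is.finite(b)) b else max(spec$n)
    grid <- unique(round(10^seq(log10(object$a), log10(hi), length.out = 200)))
    # model pmf scaled by the fraction of types in the fitted range
    counts <- as_counts(table)
    frac <- mean(counts >= object$a & counts <= hi)
    line <- tibble::tibble(
      n = grid,
      f = dpowerlaw(grid, object$gamma_hat, object$a, b) * frac
    )
    p <- p + ggplot2::geom_line(data = line, color = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
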