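#' Maximum-likelihood exponent of a discrete power-law tail
#'
#' Fits \eqn{\gamma} by maximizing the log-likelihood
#' \eqn{\sum_i [-\gamma \ln n_i - \ln Z(\gamma, a, b)]} over the counts with
#' \eqn{n \ge a} (and \eqn{\le b} when truncated), with the normalization from
#' the Hurwitz zeta function (or the finite sum when `b` is finite). The
#' one-dimensional search runs over \eqn{\gamma \in (1 + 10^{-6}, 10]} to a
#' tolerance of `1e-6`.
#'
#' @param counts Integer vector of type frequencies (a multiset of counts).
#' @param a Lower cutoff; only counts `>= a` enter the fit.
#' @param b Upper truncation, or `Inf`.
#' @return The fitted exponent `gamma_hat` (a single number).
#' @examples
#' x <- rpowerlaw(2000, gamma = 2, a = 5, seed = 1)
#' fit_exponent(x, a = 5)
#' @export
fit_exponent <- function(counts, a, b = Inf) {
  x <- tail_counts(counts, a, b)
  if (length(x) < 2) {
    stop("insufficient data: need at least 2 counts with n >= ", a,
         if (is.finite(b)) paste0(" and n <= ", b) else "")
  }
  if (all(x == x[1])) {
    stop("all in-range counts are equal (n = ", x[1],
         "); the exponent is unidentifiable")
  }
  s <- mean(log(x))
  nll <- function(g) g * s + log(powerlaw_norm(g, a, b))
  opt <- stats::optimize(nll, interval = c(1 + 1e-6, 10), tol = 1e-6)
  opt$minimum
}

tail_counts <- function(counts, a, b = Inf) {
  if (anyNA(counts)) stop("counts must not contain NA")
  counts[counts >= a & counts <= b]
}

powerlaw_loglik <- function(counts, gamma, a, b = Inf) {
  x <- tail_counts(counts, a, b)
  -gamma * sum(log(x)) - length(x) * log(powerlaw_norm(gamma, a, b))
}

#' Kolmogorov-Smirnov distance between counts and a discrete power law
#'
#' Maximum absolute difference between the empirical CDF of the in-range
#' counts and the model CDF, evaluated over the integer support from `a` to
#' the largest relevant value.
#'
#' @inheritParams fit_exponent
#' @param gamma Model exponent.
#' @return The KS distance, in `[0, 1]`.
#' @export
ks_distance <- function(counts, gamma, a, b = Inf) {
  x <- tail_counts(counts, a, b)
  if (length(x) == 0) stop("no counts in the fitted range")
  hi <- if (is.finite(b)) b else max(x)
  n_x <- length(x)
  if (hi - a <= 1e5) {
    grid <- seq(a, hi)
    model <- cumsum(grid^(-gamma)) / powerlaw_norm(gamma, a, b)
    if (is.finite(b)) model[length(model)] <- 1
    emp <- cumsum(tabulate(x - a + 1L, nbins = hi - a + 1L)) / n_x
    max(abs(emp - model))
  } else {
    # sparse support: the discrepancy is extremal at observed values or just
    # before the next observed value (the empirical CDF is flat in between)
    ux <- sort(unique(x))
    emp <- cumsum(tabulate(match(x, ux), nbins = length(ux))) / n_x
    model_at <- ppowerlaw(ux, gamma, a, b)
    before <- ppowerlaw(c(ux[-1] - 1, hi), gamma, a, b)
    max(abs(emp - model_at), abs(emp - before))
  }
}

#' Monte-Carlo goodness-of-fit for a power-law tail at a fixed cutoff
#'
#' Fits the exponent on the in-range counts, then simulates `n_sims` datasets
#' of the same size from the fitted model. Each simulated dataset is re-fitted
#' by maximum likelihood (same `a`, `b`) and its KS distance computed against
#' its own re-fit, so the simulated data undergo the same estimation step as
#' the empirical data (naively comparing against the original fit inflates
#' p-values). The p-value is the fraction of simulated KS distances at least
#' as large as the empirical one, and `sigma` is the standard deviation of
#' the re-fitted exponents.
#'
#' @inheritParams fit_exponent
#' @param n_sims Number of Monte-Carlo replicas.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with elements `gamma_hat`, `sigma`, `ks`, `p_value`,
#'   `n_tail` (number of in-range counts) and `n_sims`.
#' @export
gof_tail <- function(counts, a, n_sims = 1000, seed = NULL, b = Inf) {
  if (n_sims < 1) stop("n_sims must be >= 1")
  x <- tail_counts(counts, a, b)
  gamma_hat <- fit_exponent(x, a, b)
  ks_emp <- ks_distance(x, gamma_hat, a, b)
  n_tail <- length(x)
  draw <- powerlaw_sampler(gamma_hat, a, b)
  run <- function() {
    sims <- purrr::map(seq_len(n_sims), function(i) {
      y <- draw(n_tail)
      g <- tryCatch(fit_exponent(y, a, b), error = function(e) NA_real_)
      if (is.na(g)) {
        # degenerate replica (all draws equal): KS against the original fit
        c(gamma_hat, ks_distance(y, gamma_hat, a, b))
      } else {
        c(g, ks_distance(y, g, a, b))
      }
    })
    m <- do.call(rbind, sims)
    list(gammas = m[, 1], ks = m[, 2])
  }
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  list(
    gamma_hat = gamma_hat,
    sigma = stats::sd(sim$gammas),
    ks = ks_emp,
    p_value = mean(sim$ks >= ks_emp),
    n_tail = n_tail,
    n_sims = n_sims
  )
}

#' Geometric grid of candidate cutoffs
#'
#' Candidate cutoffs in geometric progression, `per_decade` points per order
#' of magnitude: successive values multiply by \eqn{10^{1/\mathrm{per\_decade}}}
#' (about 1.26 for the default 10/decade), non-integer values are rounded up,
#' and duplicates are dropped.
#'
#' @param a_min,a_max Integer range limits, `1 <= a_min <= a_max`.
#' @param per_decade Number of grid points per order of magnitude.
#' @return Strictly increasing integer vector from `a_min` up to at most
#'   `a_max`.
#' @examples
#' cutoff_grid(1, 100)
#' @export
cutoff_grid <- function(a_min, a_max, per_decade = 10) {
  stopifnot(a_min >= 1, a_min <= a_max)
  if (per_decade < 1) stop("per_decade must be >= 1")
  k_max <- ceiling(per_decade * (log10(a_max) - log10(a_min))) + 1
  raw <- a_min * 10^(seq(0, k_max) / per_decade)
  grid <- unique(ceiling(raw - 1e-9))
  grid[grid <= a_max]
}

#' Fit a power-law tail with automatic lower-cutoff selection
#'
#' Scans candidate lower cutoffs over a geometric grid (smallest first). At
#' each cutoff the exponent is fitted by maximum likelihood and the fit is
#' judged by the Monte-Carlo KS goodness-of-fit of [gof_tail()]; the selected
#' cutoff is the smallest one whose p-value exceeds `p_threshold`, which gives
#' the widest accepted power-law range. The fit is flagged `zipf_valid` when
#' the accepted tail spans at least two decades (`n_m / a >= 100`).
#'
#' @param table A frequency table (`freq_tbl` from [count_types()] or
#'   [freq_table()]), or a bare integer vector of counts.
#' @param per_decade Cutoff grid resolution (points per order of magnitude).
#' @param p_threshold Acceptance threshold for the goodness-of-fit p-value.
#' @param n_sims Monte-Carlo replicas per candidate cutoff.
#' @param seed Optional integer seed; each candidate cutoff uses a seed
#'   derived deterministically from it.
#' @param a_min Smallest cutoff to try.
#' @return A `tail_fit` object: list with `a`, `gamma_hat`, `sigma`, `ks`,
#'   `p_value`, `n_tail`, `n_m`, `zipf_valid`, `accepted`, `n_sims`, `seed`
#'   and a `grid` tibble of per-cutoff diagnostics. When no cutoff is accepted
#'   the object has `accepted = FALSE` (an explicit "no power-law tail found"
#'   result, not an error). Use [generics::tidy()] / [generics::glance()] to
#'   extract results as tibbles.
#' @examples
#' tab <- sample_lemma_table(synthetic_spec(gamma = 2, a = 1, V_lemmas = 800, seed = 7))
#' fit_powerlaw_tail(tab, n_sims = 30, seed = 1)
#' @export
fit_powerlaw_tail <- function(table, per_decade = 10, p_threshold = 0.20,
                              n_sims = 1000, seed = NULL, a_min = 1) {
  counts <- as_counts(table)
  n_m <- max(counts)
  grid <- cutoff_grid(max(a_min, min(counts)), n_m, per_decade)
  diag_rows <- list()
  chosen <- NULL
  for (i in seq_along(grid)) {
    a <- grid[i]
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    res <- tryCatch(
      gof_tail(counts, a, n_sims = n_sims, seed = sub_seed),
      error = function(e) NULL
    )
    if (is.null(res)) next
    diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
      a = a, gamma_hat = res$gamma_hat, sigma = res$sigma,
      ks = res$ks, p_value = res$p_value, n_tail = res$n_tail
    )
    if (res$p_value > p_threshold) {
      chosen <- c(res, list(a = a, seed = sub_seed))
      break
    }
  }
  grid_tbl <- if (length(diag_rows)) dplyr::bind_rows(diag_rows) else
    tibble::tibble(a = integer(), gamma_hat = numeric(), sigma = numeric(),
                   ks = numeric(), p_value = numeric(), n_tail = integer())
  if (is.null(chosen)) {
    return(new_tail_fit(list(
      accepted = FALSE, a = NA_integer_, gamma_hat = NA_real_,
      sigma = NA_real_, ks = NA_real_, p_value = NA_real_,
      n_tail = NA_integer_, n_m = n_m, zipf_valid = FALSE,
      n_sims = n_sims, seed = seed, grid = grid_tbl,
      unit = attr(table, "unit", exact = TRUE)
    )))
  }
  new_tail_fit(list(
    accepted = TRUE, a = chosen$a, gamma_hat = chosen$gamma_hat,
    sigma = chosen$sigma, ks = chosen$ks, p_value = chosen$p_value,
    n_tail = chosen$n_tail, n_m = n_m, zipf_valid = n_m / chosen$a >= 100,
    n_sims = n_sims, seed = seed, grid = grid_tbl,
    unit = attr(table, "unit", exact = TRUE)
  ))
}

#' Fit a truncated power law to the low-frequency regime
#'
#' Some lemma distributions show a second, shallower power-law regime between
#' `n = 1` and some maximum frequency. This fixes the lower end at `a` and
#' scans truncation points `b` downward from the maximum observed frequency
#' over the same geometric grid, returning the largest accepted truncated fit
#' or an explicit all-rejected result.
#'
#' @inheritParams fit_powerlaw_tail
#' @param a Fixed lower end of the fitted range.
#' @return A `tail_fit` object with an extra element `b` (the accepted
#'   truncation), or `accepted = FALSE` when every truncation is rejected.
#' @export
fit_truncated_head <- function(table, a = 1, per_decade = 10,
                               p_threshold = 0.20, n_sims = 1000,
                               seed = NULL) {
  counts <- as_counts(table)
  n_m <- max(counts)
  grid <- rev(cutoff_grid(a + 1, n_m, per_decade))
  diag_rows <- list()
  chosen <- NULL
  for (i in seq_along(grid)) {
    b <- grid[i]
    sub_seed <- if (is.null(seed)) NULL else derive_seed(seed, i)
    res <- tryCatch(
      gof_tail(counts, a, n_sims = n_sims, seed = sub_seed, b = b),
      error = function(e) NULL
    )
    if (is.null(res)) next
    diag_rows[[length(diag_rows) + 1]] <- tibble::tibble(
      b = b, gamma_hat = res$gamma_hat, sigma = res$sigma,
      ks = res$ks, p_value = res$p_value, n_tail = res$n_tail
    )
    if (res$p_value > p_threshold) {
      chosen <- c(res, list(b = b))
      break
    }
  }
  grid_tbl <- if (length(diag_rows)) dplyr::bind_rows(diag_rows) else
    tibble::tibble(b = integer(), gamma_hat = numeric(), sigma = numeric(),
                   ks = numeric(), p_value = numeric(), n_tail = integer())
  if (is.null(chosen)) {
    return(new_tail_fit(list(
      accepted = FALSE, a = a, b = NA_integer_, gamma_hat = NA_real_,
      sigma = NA_real_, ks = NA_real_, p_value = NA_real_,
      n_tail = NA_integer_, n_m = n_m, zipf_valid = FALSE,
      n_sims = n_sims, seed = seed, grid = grid_tbl,
      unit = attr(table, "unit", exact = TRUE)
    )))
  }
  new_tail_fit(list(
    accepted = TRUE, a = a, b = chosen$b, gamma_hat = chosen$gamma_hat,
    sigma = chosen$sigma, ks = chosen$ks, p_value = chosen$p_value,
    n_tail = chosen$n_tail, n_m = n_m, zipf_valid = FALSE,
    n_sims = n_sims, seed = seed, grid = grid_tbl,
    unit = attr(table, "unit", exact = TRUE)
  ))
}

new_tail_fit <- function(x) structure(x, class = "tail_fit")

derive_seed <- function(seed, i) (seed * 1009L + i * 9973L) %% 2147483647L

as_counts <- function(table) {
  counts <- if (is.data.frame(table)) table$n else table
  if (is.null(counts) || length(counts) == 0) stop("empty frequency table")
  if (any(counts < 1) || any(counts != floor(counts))) {
    stop("counts must be positive integers")
  }
  as.numeric(counts)
}

#' @export
print.tail_fit <- function(x, ...) {
  if (!x$accepted) {
    cat("<tail_fit> no power-law tail found (all cutoffs rejected)\n")
    cat("  n_m =", x$n_m, "; cutoffs tried:", nrow(x$grid), "\n")
    return(invisible(x))
  }
  rng <- if (!is.null(x$b) && is.finite(x$b %||% Inf))
    paste0("[", x$a, ", ", x$b, "]") else paste0("n >= ", x$a)
  cat("<tail_fit> discrete power law on ", rng, "\n", sep = "")
  cat(sprintf("  gamma = %.4f +- %.4f  (KS = %.4f, p = %.3f, N_a = %d, n_m = %d)\n",
              x$gamma_hat, x$sigma, x$ks, x$p_value, x$n_tail, x$n_m))
  cat("  Zipf validity (two decades):", x$zipf_valid, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy tail_fit
#' @export
tidy.tail_fit <- function(x, ...) {
  tibble::tibble(
    term = c("gamma", "a"),
    estimate = c(x$gamma_hat, x$a),
    std.error = c(x$sigma, NA_real_)
  )
}

#' @method glance tail_fit
#' @export
glance.tail_fit <- function(x, ...) {
  tibble::tibble(
    accepted = x$accepted, a = x$a,
    b = if (is.null(x$b)) Inf else x$b,
    gamma_hat = x$gamma_hat, sigma = x$sigma, ks = x$ks,
    p_value = x$p_value, n_tail = x$n_tail, n_m = x$n_m,
    zipf_valid = x$zipf_valid, n_sims = x$n_sims
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
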