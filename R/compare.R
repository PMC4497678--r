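#' Standard deviation of a difference under independence
#'
#' For two estimates with standard deviations `sigma1` and `sigma2`, the
#' standard deviation of their difference, assuming independence, is
#' \eqn{\sigma_d = \sqrt{\sigma_1^2 + \sigma_2^2}}. `2 sigma_d` bounds the
#' 95\% interval of the difference.
#'
#' @param sigma1,sigma2 Non-negative standard deviations (vectorized).
#' @return Tibble with columns `sigma_d` and `two_sigma_d`.
#' @export
sigma_diff <- function(sigma1, sigma2) {
  if (any(sigma1 < 0) || any(sigma2 < 0)) stop("sigmas must be non-negative")
  sd_ <- sqrt(sigma1^2 + sigma2^2)
  tibble::tibble(sigma_d = sd_, two_sigma_d = 2 * sd_)
}

#' Paired parameter vectors across texts
#'
#' @param labels Text identifiers.
#' @param x,y Per-text values of the two conditions (e.g. word vs lemma
#'   exponents, or word vs lemma cutoffs).
#' @return A `paired_params` tibble with columns `label`, `x`, `y`.
#' @export
paired_params <- function(labels, x, y) {
  stopifnot(length(labels) == length(x), length(x) == length(y),
            length(x) >= 2)
  structure(tibble::tibble(label = as.character(labels), x = x, y = y),
            class = c("paired_params", "tbl_df", "tbl", "data.frame"))
}

#' Paired t statistic with optional outlier removal
#'
#' Computes the paired-sample t statistic on the differences `d = x - y`:
#' \eqn{t = \bar d \sqrt{M} / s_d} with `s_d` the unbiased standard deviation
#' and `M` the number of retained pairs. Before computing, the `n_remove`
#' pairs with the largest absolute difference are dropped (ties broken by
#' input order), which is how a single outlier text is treated.
#'
#' @param pairs A `paired_params` (or tibble with columns `label`, `x`, `y`).
#' @param n_remove Number of largest-|d| pairs to drop.
#' @return Tibble with `t`, `m` (retained pairs) and a list-column
#'   `removed` of the dropped labels.
#' @export
paired_t <- function(pairs, n_remove = 0) {
  d <- pairs$x - pairs$y
  removed <- character()
  if (n_remove > 0) {
    drop <- order(-abs(d))[seq_len(n_remove)]
    removed <- pairs$label[drop]
    d <- d[-drop]
  }
  if (length(d) < 2) stop("fewer than 2 pairs remain")
  if (stats::sd(d) == 0) stop("zero variance in the paired differences")
  tibble::tibble(
    t = mean(d) * sqrt(length(d)) / stats::sd(d),
    m = length(d),
    removed = list(removed)
  )
}

#' Simulated-null p-value for the outlier-removed paired t
#'
#' Under the null hypothesis the paired differences are independent normals
#' with zero mean and a common standard deviation. Each replica draws `N`
#' standard normals, removes the `n_remove` largest in absolute value --
#' exactly as done for the empirical data -- and computes the t statistic on
#' the remainder. The two-sided p-value is the fraction of replicas with
#' \eqn{|t_{sim}| \ge |t_{obs}|}. With `n_remove = 0` this converges to the
#' classical two-sided Student-t(N-1) tail.
#'
#' @param t_obs Observed t statistic.
#' @param n Number of pairs before removal.
#' @param n_remove Outliers removed (as in [paired_t()]).
#' @param n_sims Number of null replicas (at least 100).
#' @param seed Optional integer seed.
#' @return The two-sided p-value.
#' @export
simulated_t_pvalue <- function(t_obs, n, n_remove = 0, n_sims = 10000,
                               seed = NULL) {
  if (n - n_remove < 2) stop("n - n_remove must be >= 2")
  if (n_sims < 100) stop("n_sims < 100 gives an unstable p-value")
  run <- function() {
    z <- matrix(stats::rnorm(n_sims * n), nrow = n_sims)
    t_sim <- apply(z, 1, function(row) {
      if (n_remove > 0) row <- row[-order(-abs(row))[seq_len(n_remove)]]
      mean(row) * sqrt(length(row)) / stats::sd(row)
    })
    mean(abs(t_sim) >= abs(t_obs))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Exact sign-flip (coin-flipping) test for paired parameters
#'
#' Tests whether `x` and `y` are identically distributed within each text.
#' Under the null, swapping `x` and `y` inside any text leaves the statistic
#' \eqn{|\bar x - \bar y|} distributionally unchanged, so all \eqn{2^N} swap
#' configurations are enumerated and the exact p-value is the proportion with
#' a statistic at least as large as the observed one (the identity
#' configuration always counts, so \eqn{p \ge 2^{-N}}).
#'
#' @param pairs A `paired_params`.
#' @return Tibble with `statistic` (\eqn{|\bar x - \bar y|}), `p_value` and
#'   `n_configs` (\eqn{2^N}).
#' @export
coin_flip_test <- function(pairs) {
  d <- pairs$x - pairs$y
  n <- length(d)
  if (n > 25) {
    stop("exact enumeration limited to N <= 25; subsample or use a sampled ",
         "sign-flip test")
  }
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  stats_all <- abs(signs %*% d) / n
  tibble::tibble(
    statistic = obs,
    p_value = mean(stats_all >= obs - 1e-12),
    n_configs = 2L^n
  )
}

#' Correlation with a permutation p-value
#'
#' Pearson or Spearman correlation between `x` and `y`, with a two-sided
#' p-value for the null `rho = 0` obtained by reshuffling `y`: the p-value is
#' the fraction of reshuffled correlations whose absolute value is at least
#' the observed one. When `N! <= 1e6` (i.e. `N <= 9`) all permutations are
#' enumerated and the p-value is exact; otherwise `n_perm` seeded random
#' permutations are drawn.
#'
#' @param x,y Numeric vectors (length at least 3, non-degenerate).
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm Number of sampled permutations when enumeration is not
#'   feasible.
#' @param seed Optional integer seed (sampled mode only).
#' @return Tibble with `method`, `rho`, `p_value` and `n_resamples`
#'   (`"exact"` marks full enumeration in the `exact` column).
#' @export
cor_perm_test <- function(x, y, method = c("pearson", "spearman"),
                          n_perm = 1e5, seed = NULL) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) {
    stop("x and y must have equal length >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  rho <- stats::cor(x, y)
  n <- length(x)
  exact <- factorial(n) <= 1e6
  run <- function() {
    if (exact) {
      perms <- permutations_all(n)
      rhos <- apply(perms, 1, function(p) stats::cor(x, y[p]))
      c(mean(abs(rhos) >= abs(rho) - 1e-12), nrow(perms))
    } else {
      rhos <- vapply(seq_len(n_perm),
                     function(i) stats::cor(x, sample(y)), numeric(1))
      c(mean(abs(rhos) >= abs(rho) - 1e-12), n_perm)
    }
  }
  res <- if (is.null(seed) || exact) run() else withr::with_seed(seed, run())
  tibble::tibble(method = method, rho = rho, p_value = res[1],
                 n_resamples = res[2], exact = exact)
}

permutations_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_all(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    # i leads; the recursive block fills in the remaining values
    cbind(i, sub + (sub >= i))
  }))
}

#' Mean-independence regression with reference tests
#'
#' Ordinary least squares of `y` on `x` with the two reference t-tests used
#' to probe mean independence of a ratio: is the slope significantly
#' different from one, and the intercept from zero? A slope of one with zero
#' intercept is what \eqn{E[y | x] = x} predicts. Classical standard errors
#' with `N - 2` degrees of freedom; two-sided p-values from Student's t.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @return Tibble with `slope`, `se_slope`, `t_slope_vs_1`, `p_slope`,
#'   `intercept`, `se_intercept`, `t_intercept_vs_0`, `p_intercept`, `df`.
#' @export
mean_independence_regression <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need at least 3 (x, y) pairs")
  }
  if (stats::sd(x) == 0) stop("zero predictor variance")
  fit <- stats::lm(y ~ x)
  co <- summary(fit)$coefficients
  df <- length(x) - 2
  t_slope <- (co[2, 1] - 1) / co[2, 2]
  t_int <- co[1, 1] / co[1, 2]
  tibble::tibble(
    slope = co[2, 1], se_slope = co[2, 2],
    t_slope_vs_1 = t_slope, p_slope = 2 * stats::pt(-abs(t_slope), df),
    intercept = co[1, 1], se_intercept = co[1, 2],
    t_intercept_vs_0 = t_int, p_intercept = 2 * stats::pt(-abs(t_int), df),
    df = df
  )
}

#' Cross-text comparison battery for word vs lemma tail parameters
#'
#' Runs the full comparison battery on per-text paired parameters (exponents
#' and lower cutoffs for word forms and lemmas): per-text
#' \eqn{\sigma_d}/\eqn{2\sigma_d} of the exponent difference, paired t with 0
#' and 1 outliers removed and simulated-null p-values, the exact coin-flip
#' test (with and without one outlier), Pearson/Spearman correlations of the
#' pair and of the ratio-vs-value forms (the mean-independence probes) with
#' permutation p-values, and both mean-independence regressions. Raw p-values
#' are accompanied by Bonferroni and Sidak adjustments across the correlation
#' family.
#'
#' @param params Tibble with one row per text and columns `label`, `gamma_w`,
#'   `sigma_w`, `a_w`, `gamma_l`, `sigma_l`, `a_l` (see [ten_novels()] for an
#'   example). Alternatively pass two aligned lists of `tail_fit` objects via
#'   `fits_w`/`fits_l`.
#' @param fits_w,fits_l Optional aligned lists of `tail_fit` objects (used
#'   when `params` is missing); labels default to the list names or indices.
#' @param n_sims Replicas for the simulated-null paired-t p-values.
#' @param n_perm Sampled permutations for the correlation tests when exact
#'   enumeration is infeasible.
#' @param seed Optional integer seed governing all resampling.
#' @return A `zipf_comparison`: list of tibbles `per_text`, `tests` (paired t
#'   and coin-flip rows for both parameter kinds), `correlations` and
#'   `regressions`.
#' @export
compare_texts <- function(params = NULL, fits_w = NULL, fits_l = NULL,
                          n_sims = 10000, n_perm = 1e5, seed = NULL) {
  if (is.null(params)) {
    if (is.null(fits_w) || is.null(fits_l) ||
        length(fits_w) != length(fits_l)) {
      stop("provide `params`, or two aligned lists `fits_w` and `fits_l`")
    }
    labels <- names(fits_w) %||% as.character(seq_along(fits_w))
    params <- tibble::tibble(
      label = labels,
      gamma_w = vapply(fits_w, function(f) f$gamma_hat, numeric(1)),
      sigma_w = vapply(fits_w, function(f) f$sigma, numeric(1)),
      a_w = vapply(fits_w, function(f) f$a, numeric(1)),
      gamma_l = vapply(fits_l, function(f) f$gamma_hat, numeric(1)),
      sigma_l = vapply(fits_l, function(f) f$sigma, numeric(1)),
      a_l = vapply(fits_l, function(f) f$a, numeric(1))
    )
  }
  need <- c("label", "gamma_w", "sigma_w", "a_w", "gamma_l", "sigma_l", "a_l")
  missing_cols <- setdiff(need, names(params))
  if (length(missing_cols)) {
    stop("params is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(params) < 2) stop("N >= 2 texts required")

  per_text <- dplyr::bind_cols(
    params[c("label", "gamma_w", "sigma_w", "gamma_l", "sigma_l",
             "a_w", "a_l")],
    sigma_diff(params$sigma_w, params$sigma_l)
  ) |>
    dplyr::mutate(
      delta_gamma = .data$gamma_l - .data$gamma_w,
      outside_2sigma_d = abs(.data$delta_gamma) > .data$two_sigma_d
    )

  battery <- function(x, y, kind, seed_off) {
    pp <- paired_params(params$label, x, y)
    rows <- list()
    for (nr in 0:1) {
      # degenerate differences (x == y) leave the t undefined: report NA
      t_row <- tryCatch(paired_t(pp, n_remove = nr), error = function(e) NULL)
      p <- if (is.null(t_row)) NA_real_ else
        simulated_t_pvalue(t_row$t, nrow(pp), n_remove = nr,
                           n_sims = n_sims,
                           seed = seed_shift(seed, seed_off + nr))
      rows[[length(rows) + 1]] <- tibble::tibble(
        parameter = kind, test = "paired_t", n_removed = nr,
        statistic = if (is.null(t_row)) NA_real_ else t_row$t, p_value = p,
        removed = if (is.null(t_row)) list(character()) else t_row$removed
      )
    }
    cf <- coin_flip_test(pp)
    rows[[length(rows) + 1]] <- tibble::tibble(
      parameter = kind, test = "coin_flip", n_removed = 0L,
      statistic = cf$statistic, p_value = cf$p_value, removed = list(character())
    )
    drop <- order(-abs(pp$x - pp$y))[1]
    cf1 <- coin_flip_test(pp[-drop, ])
    rows[[length(rows) + 1]] <- tibble::tibble(
      parameter = kind, test = "coin_flip", n_removed = 1L,
      statistic = cf1$statistic, p_value = cf1$p_value,
      removed = list(pp$label[drop])
    )
    dplyr::bind_rows(rows)
  }

  cors <- function(x, y, assoc, seed_off) {
    purrr::imap(c("pearson", "spearman"), function(m, j) {
      res <- tryCatch(
        cor_perm_test(x, y, method = m, n_perm = n_perm,
                      seed = seed_shift(seed, seed_off + j)),
        error = function(e) tibble::tibble(
          method = m, rho = NA_real_, p_value = NA_real_,
          n_resamples = NA_real_, exact = NA)
      )
      dplyr::bind_cols(tibble::tibble(association = assoc), res)
    }) |> dplyr::bind_rows()
  }

  with(params, {
    tests <- dplyr::bind_rows(
      battery(gamma_w, gamma_l, "gamma", 10),
      battery(a_w, a_l, "a", 20)
    )
    correlations <- dplyr::bind_rows(
      cors(gamma_w, gamma_l, "gamma_w ~ gamma_l", 30),
      cors(a_w, a_l, "a_w ~ a_l", 40),
      cors(gamma_l, gamma_w / gamma_l, "gamma_w/gamma_l ~ gamma_l", 50),
      cors(gamma_w, gamma_l / gamma_w, "gamma_l/gamma_w ~ gamma_w", 60),
      cors(a_l, a_w / a_l, "a_w/a_l ~ a_l", 70),
      cors(a_w, a_l / a_w, "a_l/a_w ~ a_w", 80)
    )
    k <- nrow(correlations)
    correlations <- dplyr::mutate(
      correlations,
      p_bonferroni = pmin(1, .data$p_value * k),
      p_sidak = 1 - (1 - .data$p_value)^k
    )
    regressions <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(model = "E[gamma_w|gamma_l]"),
                       mean_independence_regression(gamma_l, gamma_w)),
      dplyr::bind_cols(tibble::tibble(model = "E[gamma_l|gamma_w]"),
                       mean_independence_regression(gamma_w, gamma_l)),
      dplyr::bind_cols(tibble::tibble(model = "E[a_w|a_l]"),
                       mean_independence_regression(a_l, a_w)),
      dplyr::bind_cols(tibble::tibble(model = "E[a_l|a_w]"),
                       mean_independence_regression(a_w, a_l))
    )
    structure(
      list(per_text = per_text, tests = tests, correlations = correlations,
           regressions = regressions, n_texts = nrow(params), seed = seed),
      class = "zipf_comparison"
    )
  })
}

seed_shift <- function(seed, off) if (is.null(seed)) NULL else
  (seed * 1013L + off * 7919L) %% 2147483647L

#' @export
print.zipf_comparison <- function(x, ...) {
  cat("<zipf_comparison> across", x$n_texts, "texts\n\n")
  cat("Paired and sign-flip tests:\n")
  print(dplyr::select(x$tests, -"removed"))
  cat("\nCorrelations (permutation p-values):\n")
  print(dplyr::select(x$correlations, "association", "method", "rho",
                      "p_value"))
  cat("\nMean-independence regressions:\n")
  print(dplyr::select(x$regressions, "model", "slope", "se_slope", "p_slope",
                      "intercept", "se_intercept", "p_intercept"))
  invisible(x)
}

#' @method tidy zipf_comparison
#' @export
tidy.zipf_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$tests,
                     family = "test",
                     name = paste0(.data$parameter, ":", .data$test,
                                   "-", .data$n_removed),
                     statistic = .data$statistic, p_value = .data$p_value),
    dplyr::transmute(x$correlations,
                     family = "correlation",
                     name = paste0(.data$association, " [", .data$method, "]"),
                     statistic = .data$rho, p_value = .data$p_value),
    dplyr::transmute(x$regressions,
                     family = "regression-slope",
                     name = .data$model,
                     statistic = .data$slope, p_value = .data$p_slope),
    dplyr::transmute(x$regressions,
                     family = "regression-intercept",
                     name = .data$model,
                     statistic = .data$intercept, p_value = .data$p_intercept)
  )
}
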