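#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' Pools the within-group variance (`MSE`, with `N - k` error df) and, for
#' every pair of groups, computes the studentized-range statistic
#' `q = |m_i - m_j| / sqrt(MSE/2 * (1/n_i + 1/n_j))` and the adjusted
#' p-value from the studentized-range distribution with `(k, N - k)`
#' parameters (Tukey-Kramer for unequal group sizes).
#'
#' @param groups a named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values).  Homoscedasticity is assumed.
#' @return a tibble of class `tukey_result` with one row per pair and
#'   columns `pair, group_i, group_j, diff, se, q, p_adj`; attributes
#'   `dferror`, `k_groups`, `mse`.
#' @export
#' @examples
#' anova_tukey(list(control = rnorm(5, 1), gradual = rnorm(5),
#'                  abrupt = rnorm(5)))
anova_tukey <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(seq_along(groups),
         function(i) .check_group(groups[[i]], names(groups)[i]))
  k <- length(groups)
  n_i <- lengths(groups)
  N <- sum(n_i)
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (N - k)
  df <- N - k
  pairs <- utils::combn(k, 2)
  zero_var <- mse <= 0
  rows <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    diff <- means[j] - means[i]
    se <- sqrt(mse / 2 * (1 / n_i[i] + 1 / n_i[j]))
    if (zero_var) {
      q <- if (abs(diff) > 0) Inf else 0
      p <- if (abs(diff) > 0) .Machine$double.xmin else 1
    } else {
      q <- abs(diff) / se
      p <- stats::ptukey(q, nmeans = k, df = df, lower.tail = FALSE)
    }
    tibble::tibble(
      pair = paste0(names(groups)[j], "-", names(groups)[i]),
      group_i = names(groups)[i], group_j = names(groups)[j],
      diff = unname(diff), se = unname(se), q = unname(q), p_adj = unname(p)
    )
  })
  out <- do.call(rbind, rows)
  if (zero_var && any(out$q > 0)) {
    warning("zero pooled variance with unequal means: ",
            "adjusted p reported below machine floor", call. = FALSE)
  }
  structure(out, dferror = df, k_groups = k, mse = mse,
            class = c("tukey_result", class(out)))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation, two-sided p from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df, and a
#' `1 - alpha` interval from the Fisher transformation
#' `atanh(r) +/- z_{1 - alpha/2} / sqrt(n - 3)`, back-transformed with
#' `tanh`.
#'
#' @param x,y numeric vectors of equal length `n >= 4`, each with non-zero
#'   variance.
#' @param alpha interval level (default 0.05).
#' @return an object of class `correlation_result`: list with `r`, `p`,
#'   `ci_low`, `ci_high`, `n`, `alpha`.
#' @export
#' @examples
#' pearson_ci(1:10, jitter(1:10))
pearson_ci <- function(x, y, alpha = 0.05) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length",
                                   call. = FALSE)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need n >= 4 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in 'x' or 'y'", call. = FALSE)
  }
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) {
    0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tval), df = n - 2, lower.tail = FALSE)
  }
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  half <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  structure(
    list(r = r, p = p, ci_low = tanh(z - half), ci_high = tanh(z + half),
         n = n, alpha = alpha),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p = %.3g, %d%% CI [%.3f, %.3f], n = %d\n",
              x$r, x$p, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Per-isolate Tukey table for a replicate table
#'
#' Runs [anova_tukey()] on the three treatment arms of every isolate for one
#' response column, mirroring the per-isolate pairwise tests reported with
#' reaction patterns.
#'
#' @inheritParams effect_size_table
#' @return a tibble with one row per isolate x pair, plus `dferror` and
#'   `mse` columns.
#' @export
tukey_table <- function(table, response = c("biomass_g", "cu_mg_per_g")) {
  response <- match.arg(response)
  isolates <- unique(table$isolate)
  rows <- lapply(isolates, function(iso) {
    sub <- table[table$isolate == iso, ]
    tk <- anova_tukey(split(sub[[response]], sub$treatment))
    tibble::tibble(isolate = iso, response = response,
                   pair = tk$pair, diff = tk$diff, se = tk$se, q = tk$q,
                   p_adj = tk$p_adj, dferror = attr(tk, "dferror"),
                   mse = attr(tk, "mse"))
  })
  do.call(rbind, rows)
}
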