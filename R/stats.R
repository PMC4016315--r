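# The non-phylogenetic tests used throughout the analysis. Every test
# returns one uniform tibble row (method, statistic, df, p_value,
# effect_size, n, note) so results stack with bind_rows().

test_row <- function(method, statistic = NA_real_, df = NA_real_,
                     p_value = NA_real_, effect_size = NA_real_,
                     n = NA_integer_, note = NA_character_) {
  tibble(method = method, statistic = as.numeric(statistic),
         df = as.numeric(df), p_value = as.numeric(p_value),
         effect_size = as.numeric(effect_size), n = as.integer(n),
         note = note)
}

#' Paired-sample Student t-test
#'
#' Classic paired t on the within-pair differences, df = n - 1,
#' two-tailed. Pairs with a missing value in either member are dropped.
#' Zero-variance differences are handled explicitly: all-zero
#' differences give t = 0, p = 1; constant non-zero differences are a
#' degenerate infinite-t case reported with p = 0 and a note.
#'
#' @param x,y Numeric vectors of equal length (pairing by position).
#' @return One-row result tibble.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- stats::complete.cases(x, y)
  d <- x[keep] - y[keep]
  n <- length(d)
  if (n < 2) abort("need at least 2 complete pairs.")
  if (sd(d) == 0) {
    if (all(d == 0)) return(test_row("paired_t", 0, n - 1, 1, n = n))
    return(test_row("paired_t", sign(mean(d)) * Inf, n - 1, 0, n = n,
                    note = "zero-variance differences"))
  }
  ht <- stats::t.test(x[keep], y[keep], paired = TRUE)
  test_row("paired_t", ht$statistic, ht$parameter, ht$p.value, n = n)
}

#' One-sample Student t-test
#'
#' Tests mean(x) against `mu`, t = (mean - mu) / (sd / sqrt(n)),
#' df = n - 1, two-tailed. A zero-variance sample equal to `mu` gives
#' t = 0; unequal, a degenerate infinite-t result.
#'
#' @param x Numeric vector (NA dropped).
#' @param mu Null mean (default 0).
#' @return One-row result tibble.
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) abort("need at least 2 observations.")
  if (sd(x) == 0) {
    if (isTRUE(all.equal(mean(x), mu))) {
      return(test_row("one_sample_t", 0, n - 1, 1, n = n))
    }
    return(test_row("one_sample_t", sign(mean(x) - mu) * Inf, n - 1, 0,
                    n = n, note = "zero variance"))
  }
  ht <- stats::t.test(x, mu = mu)
  test_row("one_sample_t", ht$statistic, ht$parameter, ht$p.value, n = n)
}

#' Two-sample t-test (pooled-variance Student by default)
#'
#' @param x,y Numeric vectors (NA dropped).
#' @param welch Use the Welch unequal-variance form instead of the
#'   pooled-variance Student form (default FALSE).
#' @return One-row result tibble; df = nx + ny - 2 under pooling.
#' @export
two_sample_t <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) abort("need at least 2 per group.")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(test_row("two_sample_t", 0, length(x) + length(y) - 2, 1,
                      n = length(x) + length(y)))
    }
    return(test_row("two_sample_t", sign(mean(x) - mean(y)) * Inf,
                    length(x) + length(y) - 2, 0,
                    n = length(x) + length(y), note = "zero variance"))
  }
  ht <- stats::t.test(x, y, var.equal = !welch)
  test_row("two_sample_t", ht$statistic, ht$parameter, ht$p.value,
           n = length(x) + length(y))
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties averaged); the
#' p-value uses t = rho * sqrt((n-2)/(1-rho^2)) on n - 2 df, two-tailed
#' (exact permutation is impractical at the sample sizes this analysis
#' meets). A constant vector yields an undefined-rho result rather than
#' an error.
#'
#' @param x,y Numeric vectors (pairs with NA dropped).
#' @return One-row result tibble; `statistic` is rho, `effect_size` the
#'   t value behind the p.
#' @export
spearman_test <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs.")
  if (sd(x) == 0 || sd(y) == 0) {
    return(test_row("spearman", NA_real_, n - 2, NA_real_, n = n,
                    note = "constant vector: rho undefined"))
  }
  rho <- cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    return(test_row("spearman", sign(rho), n - 2, 0, n = n,
                    note = "perfect monotone relation"))
  }
  tval <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  test_row("spearman", rho, n - 2, p, effect_size = tval, n = n)
}

#' Exact two-tailed binomial sign test
#'
#' Direction test under a fair-coin null: with `n_pos` of `n_tot`
#' outcomes in one direction, p is twice the upper binomial tail at the
#' more extreme count, capped at 1:
#' `p = min(1, 2 * P(X >= max(n_pos, n_tot - n_pos)))`, X ~ Bin(n_tot, 1/2).
#'
#' @param n_pos Count in the focal direction.
#' @param n_tot Total count (>= 1).
#' @return One-row result tibble; `statistic` is `n_pos`.
#' @export
#' @examples
#' sign_test(8, 10)$p_value  # 0.109375 = 2 * (45 + 10 + 1) / 1024
sign_test <- function(n_pos, n_tot) {
  if (n_tot < 1) abort("`n_tot` must be >= 1.")
  if (n_pos < 0 || n_pos > n_tot) abort("`n_pos` must be in [0, n_tot].")
  m <- max(n_pos, n_tot - n_pos)
  p <- min(1, 2 * pbinom(m - 1, n_tot, 0.5, lower.tail = FALSE))
  test_row("sign_test", n_pos, p_value = p, n = n_tot)
}

#' Fisher's exact test with a chi-square effect size
#'
#' Exact two-tailed p for a 2x2 table (sum of table probabilities not
#' exceeding the observed one, at fixed margins), with
#' `effect_size = sqrt(chi2 / N)` computed from the Pearson chi-square
#' of the same table without continuity correction (the phi-style
#' association measure). A table with a zero margin is degenerate:
#' p = 1 and the effect size is undefined.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return One-row result tibble; `statistic` is the chi-square.
#' @export
fisher_phi <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("`table` must be 2x2.")
  if (any(table < 0) || any(table != round(table))) {
    abort("cells must be non-negative integers.")
  }
  N <- sum(table)
  if (N < 1) abort("empty table.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(test_row("fisher_phi", NA_real_, p_value = 1, n = N,
                    note = "zero margin"))
  }
  p <- stats::fisher.test(table)$p.value
  chi2 <- suppressWarnings(
    stats::chisq.test(table, correct = FALSE)$statistic
  )
  test_row("fisher_phi", chi2, p_value = p,
           effect_size = sqrt(as.numeric(chi2) / N), n = N)
}
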