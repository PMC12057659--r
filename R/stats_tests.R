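#' Exact two-sided test result
#'
#' Lightweight container for the count-based tests: statistic (when one is
#' defined), two-sided p-value, method label and sample sizes.
#'
#' @keywords internal
test_result <- function(statistic, p_value, method, sample_sizes,
                        extra = list()) {
  stopifnot(p_value >= 0, p_value <= 1 + 1e-12)
  structure(c(list(statistic = statistic, p_value = min(p_value, 1),
                   method = method, sample_sizes = sample_sizes), extra),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %s, p = %.6g (two-sided)\n", x$method,
              if (is.na(x$statistic)) "NA" else format(x$statistic, digits = 6),
              x$p_value))
  invisible(x)
}

# two-sided exact convention shared by the count tests: sum the null
# probabilities of every outcome no more probable than the observed one,
# with a 1e-12 relative tie tolerance (conventions differ between tools,
# so the tolerance is pinned explicitly)
sum_two_sided <- function(probs, p_obs, tie_tol = 1e-12) {
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact conditional test of independence: with all margins fixed, the first
#' cell follows a hypergeometric distribution, and the two-sided p-value sums
#' the probabilities of every table whose probability does not exceed the
#' observed one (relative tie tolerance 1e-12). Symmetric under row and
#' column swaps.
#'
#' @param table A 2x2 matrix (or object coercible to one) of non-negative
#'   integer counts with at least one positive margin.
#'
#' @return An `exact_test_result`; the statistic is the sample odds ratio
#'   (possibly `Inf`).
#' @examples
#' fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2))
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("`table` must be a 2x2 matrix of counts")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0)
    stop("empty table: no observations to test")

  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  p <- sum_two_sided(probs, p_obs)

  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  test_result(or, p, "two-sided Fisher's exact test",
              c(row1 = r1, row2 = n - r1),
              extra = list(table = tab))
}

#' Exact two-sided binomial test of a single proportion
#'
#' Tests `k` successes in `n` trials against success probability `p0`
#' (default the 50:50 null used for X-versus-Y spermatid counts). The
#' two-sided p-value sums `Binomial(n, p0)` probabilities of all outcomes no
#' more probable than the observed one (relative tie tolerance 1e-12).
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param p0 Null success probability in (0, 1) (default 0.5).
#'
#' @return An `exact_test_result`; the statistic is the sample fraction
#'   `k/n`.
#' @examples
#' binomial_two_sided(8, 10)$p_value # 0.109375
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n || k != round(k) || n != round(n))
    stop("k must be an integer in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie in (0, 1)")
  probs <- stats::dbinom(0:n, n, p0)
  p <- sum_two_sided(probs, probs[k + 1L])
  test_result(k / n, p, "exact two-sided binomial test", c(n = n),
              extra = list(k = k, p0 = p0))
}

#' Two-sided unpaired t test on per-male sex ratios
#'
#' Classic equal-variance two-sample Student t test (the common
#' graphing-software default), with the Welch unequal-variance form behind a
#' flag. Thin wrapper over [stats::t.test()].
#'
#' @param group_a,group_b Numeric vectors of per-male sex ratios (>= 2 values
#'   each, with nonzero pooled variance).
#' @param welch Use the Welch (unequal variance) form (default `FALSE`).
#'
#' @return An `exact_test_result` with the t statistic; degrees of freedom in
#'   `df`.
#' @examples
#' unpaired_t_two_sided(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_two_sided <- function(group_a, group_b, welch = FALSE) {
  stopifnot(is.numeric(group_a), is.numeric(group_b))
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(group_a) + stats::var(group_b) == 0)
    stop("degenerate data: pooled variance is zero")
  tt <- stats::t.test(group_a, group_b, var.equal = !welch,
                      alternative = "two.sided")
  test_result(unname(tt$statistic), tt$p.value,
              if (welch) "two-sided Welch t test"
              else "two-sided unpaired t test (equal variance)",
              c(n_a = length(group_a), n_b = length(group_b)),
              extra = list(df = unname(tt$parameter),
                           mean_a = mean(group_a), mean_b = mean(group_b)))
}

#' Estimate drive strength from progeny sex counts
#'
#' Pools female and male offspring over all males and mating periods:
#' `t_hat = females / (females + males)` (female offspring mark X-bearing
#' sperm), with an exact Clopper-Pearson confidence interval. Also reports
#' the per-male female:male ratio, the unit of analysis for between-genotype
#' t tests.
#'
#' @param progeny A `progeny_records` data frame (see
#'   [gen_progeny_counts()]), or any data frame with columns `male`,
#'   `females`, `males`.
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list with `t_hat`, `lower`, `upper`, `n_offspring`,
#'   `per_male_ratio` (named vector, `Inf` where a male sired no sons).
#' @export
estimate_drive_strength <- function(progeny, conf_level = 0.95) {
  stopifnot(is.data.frame(progeny),
            all(c("male", "females", "males") %in% names(progeny)))
  fem <- sum(progeny$females)
  mal <- sum(progeny$males)
  if (fem + mal == 0) stop("no offspring recorded")
  bt <- stats::binom.test(fem, fem + mal, conf.level = conf_level)
  per_f <- tapply(progeny$females, progeny$male, sum)
  per_m <- tapply(progeny$males, progeny$male, sum)
  ratio <- ifelse(per_m > 0, per_f / per_m, Inf)
  list(t_hat = fem / (fem + mal),
       lower = bt$conf.int[1], upper = bt$conf.int[2],
       n_offspring = fem + mal,
       per_male_ratio = ratio)
}
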