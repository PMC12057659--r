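# Independent oracles used across the suite. Each recomputes a quantity by a
# route different from the production code: exhaustive enumeration, expanded
# algebraic forms, or first-principles probability bookkeeping.

# Offspring genotype counts by enumerating egg x sperm products directly.
# Egg pool: X' at frequency K, X at 1 - K. Sperm pool: driver males (fraction
# R) sire X' sperm at frequency t_drive and Y at 1 - t_drive; normal males
# sire X and Y sperm at 1/2 each.
oracle_offspring_counts <- function(N, R, K, t_drive) {
  sperm_Xp <- t_drive * R
  sperm_X <- 0.5 * (1 - R)
  sperm_Y <- (1 - t_drive) * R + 0.5 * (1 - R)
  list(A = N * K * sperm_Y,          # X'Y males
       B = N * (1 - K) * sperm_Y,    # XY males
       C = N * K * sperm_Xp,         # X'X' females
       D = N * K * sperm_X + N * (1 - K) * sperm_Xp, # X'X females
       E = N * (1 - K) * sperm_X)    # XX females
}

# Expanded allele-counting form of the female-frequency recursion
# (numerator: X' copies among daughters; denominator: 2 * daughters / N).
oracle_next_K <- function(R, K, t_drive) {
  (K / 2 + t_drive * R + (t_drive - 0.5) * K * R) / (1 + (2 * t_drive - 1) * R)
}

# Expected spermatid class counts (and exact per-meiosis variances) by
# exhaustive enumeration of the 2 x 2 x 2 x 2 branching tree of one meiosis:
# MI asymmetric or not, cosegregation side, and each secondary spermatocyte's
# MII division asymmetric or not.
oracle_spermatid_tree <- function(p1, q, p2) {
  classes <- c("X_Ste_pos", "X_Ste_neg", "Y_Ste_pos", "Y_Ste_neg")
  ex <- stats::setNames(numeric(4), classes)
  ex2 <- stats::setNames(numeric(4), classes)
  for (mi_asym in 0:1) for (to_y in 0:1) for (a2x in 0:1) for (a2y in 0:1) {
    pr <- (if (mi_asym) p1 else 1 - p1) *
      (if (mi_asym) (if (to_y) q else 1 - q) else (if (to_y) 1 else 0)) *
      (if (a2x) p2 else 1 - p2) * (if (a2y) p2 else 1 - p2)
    # symmetric MI puts protein on both sides; fold the cosegregation branch
    # away by letting to_y = 1 carry the whole symmetric mass (factor above)
    if (pr == 0) next
    x_has <- if (mi_asym) 1 - to_y else 1
    y_has <- if (mi_asym) to_y else 1
    n_xp <- if (x_has) (if (a2x) 1 else 2) else 0
    n_yp <- if (y_has) (if (a2y) 1 else 2) else 0
    cnt <- c(n_xp, 2 - n_xp, n_yp, 2 - n_yp)
    ex <- ex + pr * cnt
    ex2 <- ex2 + pr * cnt^2
  }
  list(mean = ex, var = ex2 - ex^2)
}

# Hypergeometric two-sided p-value by brute-force summation over the full
# support, probabilities from log binomial coefficients (no dhyper).
oracle_fisher_p <- function(tab, tie_tol = 1e-12) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  logp <- lchoose(c1, support) + lchoose(n - c1, r1 - support) - lchoose(n, r1)
  probs <- exp(logp)
  p_obs <- probs[match(tab[1, 1], support)]
  sum(probs[probs <= p_obs * (1 + tie_tol)])
}

# Exact binomial two-sided p-value from log binomial coefficients.
oracle_binom_p <- function(k, n, p0 = 0.5, tie_tol = 1e-12) {
  ks <- 0:n
  probs <- exp(lchoose(n, ks) + ks * log(p0) + (n - ks) * log1p(-p0))
  sum(probs[probs <= probs[k + 1] * (1 + tie_tol)])
}

standard_init <- function() population_state(1000, 1000, 1 / 1000, 1 / 1000)
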