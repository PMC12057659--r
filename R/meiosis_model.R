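#' Cytological parameters of the sequential asymmetric segregation model
#'
#' Four probabilities describe how a sperm-killing protein distributes over
#' the four spermatids of one male meiosis:
#'
#' * `p1` -- probability that meiosis I segregates the protein asymmetrically
#'   (all of it into one secondary spermatocyte);
#' * `q`  -- probability that, given asymmetric MI, the protein cosegregates
#'   with the Y chromosome rather than the X;
#' * `p2` -- probability that a meiosis II division segregates the protein
#'   asymmetrically (one of the two spermatids inherits it). `p2` is
#'   chromosome-independent: the same value applies to X-X and Y-Y divisions;
#' * `k`  -- killing penetrance: probability that a protein-containing
#'   spermatid fails to mature into functional sperm (default 1).
#'
#' A "symmetric" division leaves both daughters protein-positive; there is no
#' protein-loss branch, since every spermatocyte scores positive before
#' meiosis. The two MII divisions are assumed independent.
#'
#' @param p1,q,p2 Probabilities in `[0, 1]`.
#' @param k Killing penetrance in `[0, 1]` (default 1).
#'
#' @return An object of class `meiosis_params`.
#' @examples
#' meiosis_params(p1 = 0.82, q = 0.73, p2 = 0.8)
#' @export
meiosis_params <- function(p1, q, p2, k = 1) {
  vals <- c(p1 = p1, q = q, p2 = p2, k = k)
  if (!is.numeric(vals) || length(vals) != 4L || any(!is.finite(vals)))
    stop("p1, q, p2, k must be single finite numbers")
  if (any(vals < 0 | vals > 1))
    stop("p1, q, p2 and k are probabilities and must lie in [0, 1]")
  structure(as.list(vals), class = "meiosis_params")
}

#' @export
print.meiosis_params <- function(x, ...) {
  cat(sprintf("meiosis segregation parameters: p1 = %g, q = %g, p2 = %g, k = %g\n",
              x$p1, x$q, x$p2, x$k))
  invisible(x)
}

as_meiosis_params <- function(x) {
  if (inherits(x, "meiosis_params")) return(x)
  if (is.list(x) && all(c("p1", "q", "p2") %in% names(x)))
    return(meiosis_params(x$p1, x$q, x$p2, if (is.null(x$k)) 1 else x$k))
  stop("cannot interpret `params` as meiosis parameters")
}

#' Expected spermatid composition of one meiosis
#'
#' Closed-form expectations of the four spermatid classes
#' (X or Y chromosome, protein-positive or -negative) per meiosis under the
#' sequential asymmetric segregation model. MI sends the protein to the
#' Y-bearing secondary spermatocyte with probability `p1 * q`, to the X side
#' with `p1 * (1 - q)`, or to both sides with `1 - p1`; each protein-positive
#' secondary spermatocyte then yields `2 - p2` expected protein-positive
#' spermatids (one if its MII division is asymmetric, two if symmetric).
#'
#' The four expectations always sum to 4, with exactly 2 on each chromosome.
#'
#' @param params A [meiosis_params()] (`k` does not enter the composition;
#'   killing acts downstream).
#'
#' @return Object of class `spermatid_composition`: named numeric vector with
#'   elements `X_Ste_pos`, `X_Ste_neg`, `Y_Ste_pos`, `Y_Ste_neg`.
#' @examples
#' expected_spermatid_composition(meiosis_params(1, 1, 1))
#' @export
expected_spermatid_composition <- function(params) {
  p <- as_meiosis_params(params)
  y_pos <- (2 - p$p2) * (p$p1 * p$q + (1 - p$p1))
  x_pos <- (2 - p$p2) * (p$p1 * (1 - p$q) + (1 - p$p1))
  comp <- c(X_Ste_pos = x_pos, X_Ste_neg = 2 - x_pos,
            Y_Ste_pos = y_pos, Y_Ste_neg = 2 - y_pos)
  class(comp) <- "spermatid_composition"
  comp
}

#' @export
print.spermatid_composition <- function(x, ...) {
  v <- unclass(x)
  cat("expected spermatids per meiosis:\n")
  print(round(v, 6))
  invisible(x)
}

#' Fraction of protein-positive spermatids that carry the Y chromosome
#'
#' `(1 - p1 + p1 * q) / (2 - p1)`: the MII asymmetry cancels out of the
#' ratio, so this quantity is independent of `p2`. This is what a
#' chromosome-FISH scoring of protein-positive spermatids measures.
#'
#' @param params A [meiosis_params()].
#' @return Fraction in `[0, 1]`.
#' @examples
#' fraction_Y_among_Ste(meiosis_params(0.8, 0.8, 0.8)) # 0.7
#' @export
fraction_Y_among_Ste <- function(params) {
  p <- as_meiosis_params(params)
  comp <- expected_spermatid_composition(p)
  total_pos <- comp[["X_Ste_pos"]] + comp[["Y_Ste_pos"]]
  if (total_pos <= 0)
    stop("no protein-positive spermatids expected; fraction undefined")
  comp[["Y_Ste_pos"]] / total_pos
}

#' Drive strength implied by the cytological parameters
#'
#' Surviving X-bearing sperm per meiosis are `2 - k * E[X, protein+]` and
#' surviving Y-bearing sperm `2 - k * E[Y, protein+]`; the realised drive
#' strength is the X share among survivors,
#' `t = survX / (survX + survY)`. With full penetrance and fully asymmetric,
#' fully Y-biased segregation the model leaves 2 X : 1 Y sperm, i.e.
#' `t = 2/3` -- a built-in ceiling well below complete drive. Without killing
#' (`k = 0`) or without chromosome preference (`q = 0.5`) the ratio is
#' Mendelian (`t = 0.5`).
#'
#' @param params A [meiosis_params()].
#' @return Drive strength `t` in `[0, 1]`.
#' @examples
#' drive_strength_from_cytology(meiosis_params(1, 1, 1, 1)) # 2/3
#' @export
drive_strength_from_cytology <- function(params) {
  p <- as_meiosis_params(params)
  comp <- expected_spermatid_composition(p)
  surv_x <- 2 - p$k * comp[["X_Ste_pos"]]
  surv_y <- 2 - p$k * comp[["Y_Ste_pos"]]
  if (surv_x + surv_y <= 0)
    stop("no surviving sperm under these parameters")
  surv_x / (surv_x + surv_y)
}

#' Monte Carlo simulation of individual meioses
#'
#' Samples the branching model one meiosis at a time: a Bernoulli draw for MI
#' asymmetry, a draw for the cosegregation side, one independent draw per
#' secondary spermatocyte for MII asymmetry (with a uniformly chosen spared
#' spermatid), and one killing draw per protein-positive spermatid.
#' Aggregated class counts converge to
#' `n_meioses * expected_spermatid_composition(params)`.
#'
#' @param params A [meiosis_params()].
#' @param n_meioses Number of meioses to simulate (>= 1).
#' @param seed Integer seed; runs are bitwise reproducible and the caller's
#'   RNG state is left untouched.
#'
#' @return A list with `counts` (named spermatid class counts summing to
#'   `4 * n_meioses`), `surviving` (named counts of X- and Y-bearing sperm
#'   that escaped killing), `n_meioses`, `params`, `seed`.
#' @examples
#' simulate_meioses(meiosis_params(1, 1, 1), n_meioses = 1, seed = 1)$counts
#' @export
simulate_meioses <- function(params, n_meioses, seed) {
  p <- as_meiosis_params(params)
  stopifnot(is.numeric(n_meioses), n_meioses >= 1)
  n <- as.integer(n_meioses)
  withr::local_seed(seed)

  asym1 <- stats::rbinom(n, 1L, p$p1) == 1L
  coseg_y <- stats::rbinom(n, 1L, p$q) == 1L
  # protein status of the X- and Y-bearing secondary spermatocytes
  x_pos <- !asym1 | (asym1 & !coseg_y)
  y_pos <- !asym1 | (asym1 & coseg_y)
  # protein-positive spermatids contributed by each secondary spermatocyte
  asym2_x <- stats::rbinom(n, 1L, p$p2) == 1L
  asym2_y <- stats::rbinom(n, 1L, p$p2) == 1L
  x_ste <- ifelse(x_pos, ifelse(asym2_x, 1L, 2L), 0L)
  y_ste <- ifelse(y_pos, ifelse(asym2_y, 1L, 2L), 0L)

  killed_x <- stats::rbinom(n, x_ste, p$k)
  killed_y <- stats::rbinom(n, y_ste, p$k)

  counts <- c(X_Ste_pos = sum(x_ste), X_Ste_neg = 2L * n - sum(x_ste),
              Y_Ste_pos = sum(y_ste), Y_Ste_neg = 2L * n - sum(y_ste))
  surviving <- c(X = 2L * n - sum(killed_x), Y = 2L * n - sum(killed_y))
  list(counts = counts, surviving = surviving,
       n_meioses = n, params = p, seed = seed)
}

#' Estimate segregation probabilities from telophase scoring tables
#'
#' Binomial maximum-likelihood estimates (observed fractions) with exact
#' Clopper-Pearson 95% confidence intervals for the three scorable
#' parameters: `p1` from the asymmetric fraction of telophase I cells, `q`
#' from Y-cosegregation among the asymmetric telophase I cells only, and
#' `p2` from the asymmetric fraction of telophase II cells. Killing
#' penetrance is not cytologically scorable here and is not estimated.
#'
#' @param telophaseI_counts Named counts with elements `asymmetric`,
#'   `symmetric`, `coseg_Y`, `coseg_X` (a `scoring_table` from
#'   [gen_telophase_counts()] is accepted directly).
#' @param telophaseII_counts Named counts with elements `asymmetric`,
#'   `symmetric` (or a `scoring_table`).
#' @param conf_level Confidence level (default 0.95).
#'
#' @return A list with elements `p1`, `q`, `p2`, each a list
#'   `list(estimate, lower, upper, n)`. With zero asymmetric MI cells `q` is
#'   returned as `NA` estimates with `n = 0` (undefined, flagged).
#' @export
estimate_cytology_params <- function(telophaseI_counts, telophaseII_counts,
                                     conf_level = 0.95) {
  c1 <- scoring_counts(telophaseI_counts)
  c2 <- scoring_counts(telophaseII_counts)
  need1 <- c("asymmetric", "symmetric", "coseg_Y", "coseg_X")
  if (!all(need1 %in% names(c1)))
    stop("telophase I counts need categories: ", paste(need1, collapse = ", "))
  if (!all(c("asymmetric", "symmetric") %in% names(c2)))
    stop("telophase II counts need categories: asymmetric, symmetric")

  binom_est <- function(x, n) {
    if (n == 0) return(list(estimate = NA_real_, lower = NA_real_,
                            upper = NA_real_, n = 0L))
    bt <- stats::binom.test(x, n, conf.level = conf_level)
    list(estimate = x / n, lower = bt$conf.int[1], upper = bt$conf.int[2],
         n = as.integer(n))
  }

  n1 <- c1[["asymmetric"]] + c1[["symmetric"]]
  n_asym <- c1[["coseg_Y"]] + c1[["coseg_X"]]
  n2 <- c2[["asymmetric"]] + c2[["symmetric"]]
  if (n1 == 0 || n2 == 0) stop("scoring tables must contain at least one cell")

  list(p1 = binom_est(c1[["asymmetric"]], n1),
       q = binom_est(c1[["coseg_Y"]], n_asym),
       p2 = binom_est(c2[["asymmetric"]], n2))
}

# accept either a scoring_table or a bare named count vector/list
scoring_counts <- function(x) {
  if (inherits(x, "scoring_table")) return(x$counts)
  if (is.list(x)) return(unlist(x))
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a scoring_table or named counts")
}
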