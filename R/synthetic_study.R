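#' Synthetic scoring table
#'
#' Container for a synthetic cytological scoring table: named category counts
#' plus the seed and generating parameters, so every fixture documents how it
#' was made.
#'
#' @param genotype Genotype label.
#' @param counts Named non-negative integer counts.
#' @param n_total Total scored units; must equal the sum of the primary
#'   categories.
#' @param params Named list of generating parameters.
#' @param seed Integer seed used.
#' @param stage Optional stage label (`"MI"`, `"MII"`, `"spermatid"`).
#'
#' @return Object of class `scoring_table`.
#' @export
scoring_table <- function(genotype, counts, n_total, params, seed,
                          stage = NA_character_) {
  stopifnot(is.numeric(counts), all(counts >= 0), !is.null(names(counts)))
  structure(list(genotype = genotype, counts = counts,
                 n_total = as.integer(n_total), params = params,
                 seed = seed, stage = stage),
            class = "scoring_table")
}

#' @export
print.scoring_table <- function(x, ...) {
  cat(sprintf("scoring table [%s%s], n = %d (seed %s):\n", x$genotype,
              if (!is.na(x$stage)) paste0(", ", x$stage) else "",
              x$n_total, format(x$seed)))
  print(x$counts)
  invisible(x)
}

#' Generate a synthetic telophase scoring table
#'
#' Emulates per-cell scoring of protein segregation at telophase of meiosis I
#' or II: each scored cell is asymmetric with probability `p_asym`
#' (binomial), and -- for MI only -- each asymmetric cell cosegregates the
#' protein with the Y chromosome with probability `p_coseg_Y`. MII
#' segregation is chromosome-independent, so `p_coseg_Y` is ignored there.
#'
#' @param n_cells Number of scored cells (>= 1).
#' @param p_asym Probability a cell shows asymmetric segregation.
#' @param p_coseg_Y Probability an asymmetric MI cell sends the protein to
#'   the Y side.
#' @param stage `"MI"` or `"MII"`.
#' @param seed Integer seed (required; tables are reproducible).
#' @param genotype Genotype label for the table (default "synthetic").
#'
#' @return A [scoring_table()] with categories `asymmetric`, `symmetric` and,
#'   for MI, `coseg_Y`, `coseg_X` (subdividing the asymmetric cells).
#' @examples
#' gen_telophase_counts(100, 0.8, 0.7, stage = "MI", seed = 1)
#' @export
gen_telophase_counts <- function(n_cells, p_asym, p_coseg_Y = NULL,
                                 stage = c("MI", "MII"), seed,
                                 genotype = "synthetic") {
  stage <- match.arg(stage)
  stopifnot(n_cells >= 1, p_asym >= 0, p_asym <= 1)
  withr::local_seed(seed)
  n_asym <- stats::rbinom(1L, as.integer(n_cells), p_asym)
  counts <- c(asymmetric = n_asym, symmetric = as.integer(n_cells) - n_asym)
  params <- list(n_cells = n_cells, p_asym = p_asym, stage = stage)
  if (stage == "MI") {
    if (is.null(p_coseg_Y))
      stop("p_coseg_Y is required for telophase I tables")
    n_y <- stats::rbinom(1L, n_asym, p_coseg_Y)
    counts <- c(counts, coseg_Y = n_y, coseg_X = n_asym - n_y)
    params$p_coseg_Y <- p_coseg_Y
  }
  scoring_table(genotype, counts, n_cells, params, seed, stage)
}

#' Generate synthetic X/Y FISH counts among protein-positive spermatids
#'
#' Emulates chromosome-FISH scoring of protein-containing spermatids. Each
#' scored spermatid is a nondisjunction product (XY or nullo) with
#' probability `nondisjunction_rate`; otherwise it carries the Y chromosome
#' with probability [fraction_Y_among_Ste()] of the supplied meiosis
#' parameters. The nondisjunction category is kept in the table so the
#' downstream exclusion rule is exercised rather than bypassed.
#'
#' @param n_spermatids Number of scored spermatids (>= 1).
#' @param meiosis_params A [meiosis_params()].
#' @param nondisjunction_rate Nondisjunction probability, realistically in
#'   `[0, 0.04]` (default 0.02).
#' @param seed Integer seed.
#' @param genotype Genotype label.
#'
#' @return A [scoring_table()] with categories `Y`, `X`, `nondisjunction`.
#' @export
gen_spermatid_fish_counts <- function(n_spermatids, meiosis_params,
                                      nondisjunction_rate = 0.02, seed,
                                      genotype = "synthetic") {
  mp <- as_meiosis_params(meiosis_params)
  stopifnot(n_spermatids >= 1,
            nondisjunction_rate >= 0, nondisjunction_rate <= 1)
  f_y <- fraction_Y_among_Ste(mp)
  withr::local_seed(seed)
  n <- as.integer(n_spermatids)
  n_nd <- stats::rbinom(1L, n, nondisjunction_rate)
  n_y <- stats::rbinom(1L, n - n_nd, f_y)
  counts <- c(Y = n_y, X = n - n_nd - n_y, nondisjunction = n_nd)
  scoring_table(genotype, counts, n,
                list(n_spermatids = n, nondisjunction_rate = nondisjunction_rate,
                     fraction_Y = f_y, meiosis_params = unclass(mp)),
                seed, "spermatid")
}

#' Generate synthetic progeny sex counts from repeated matings
#'
#' Emulates the standard sex-ratio assay: each male is mated over
#' `n_periods` consecutive periods; per period the offspring number is
#' Poisson with the given mean and each offspring is female with probability
#' `t` (female offspring come from X-bearing sperm). An optional `age_trend`
#' adds a per-period increment to the female probability (clipped to
#' `[0, 1]`), emulating the drift of the sex ratio as males age.
#'
#' @param n_males Number of assayed males (default 10).
#' @param t Probability an offspring is female, i.e. the drive strength of
#'   the sires.
#' @param offspring_per_period_mean Poisson mean offspring per mating period
#'   (default 60).
#' @param n_periods Number of mating periods per male (default 5).
#' @param age_trend Additive per-period increment to the female probability
#'   (default 0).
#' @param seed Integer seed.
#' @param genotype Genotype label.
#'
#' @return A data frame of class `progeny_records` with columns `male`,
#'   `period`, `females`, `males`; generating parameters and seed stored as
#'   attributes `params` and `seed`, genotype as attribute `genotype`.
#' @examples
#' head(gen_progeny_counts(t = 2 / 3, seed = 1))
#' @export
gen_progeny_counts <- function(n_males = 10, t, offspring_per_period_mean = 60,
                               n_periods = 5, age_trend = 0, seed,
                               genotype = "synthetic") {
  stopifnot(n_males >= 1, t >= 0, t <= 1, offspring_per_period_mean >= 0,
            n_periods >= 1)
  withr::local_seed(seed)
  grid <- expand.grid(period = seq_len(n_periods), male = seq_len(n_males))
  p_female <- pmin(pmax(t + age_trend * (grid$period - 1), 0), 1)
  total <- stats::rpois(nrow(grid), offspring_per_period_mean)
  females <- stats::rbinom(nrow(grid), total, p_female)
  out <- data.frame(male = grid$male, period = grid$period,
                    females = females, males = total - females)
  attr(out, "params") <- list(n_males = n_males, t = t,
                              offspring_per_period_mean = offspring_per_period_mean,
                              n_periods = n_periods, age_trend = age_trend)
  attr(out, "seed") <- seed
  attr(out, "genotype") <- genotype
  class(out) <- c("progeny_records", class(out))
  out
}

#' Named parameter presets for synthetic studies
#'
#' Convenience presets for the synthetic-study generators, drawn from the
#' reported ranges for moderate driver expression (over 80% MI asymmetry,
#' 64-82% Y cosegregation, about 80% MII asymmetry, full killing
#' penetrance) plus Mendelian controls. These are labelled presets for
#' simulation, not measurements.
#'
#' @return Named list of presets; each preset is a list with `p1`, `q`, `p2`,
#'   `k` and `nondisjunction_rate`.
#' @examples
#' names(drive_presets())
#' @export
drive_presets <- function() {
  list(
    # moderate-expression driver genotypes (parameter bands, not measurements)
    XSte200_Y = list(p1 = 0.82, q = 0.73, p2 = 0.80, k = 1,
                     nondisjunction_rate = 0.02),
    XSte40_Ycry = list(p1 = 0.80, q = 0.64, p2 = 0.80, k = 1,
                       nondisjunction_rate = 0.02),
    # fully penetrant, fully asymmetric, fully Y-biased: the 2X:1Y ideal
    idealized = list(p1 = 1, q = 1, p2 = 1, k = 1,
                     nondisjunction_rate = 0),
    # no killing: Mendelian null with the same scoring structure
    control = list(p1 = 0.82, q = 0.5, p2 = 0.80, k = 0,
                   nondisjunction_rate = 0.02)
  )
}

resolve_preset <- function(preset) {
  if (is.character(preset)) {
    presets <- drive_presets()
    if (!preset %in% names(presets))
      stop("unknown preset: ", preset, "; available: ",
           paste(names(presets), collapse = ", "))
    c(presets[[preset]], list(name = preset))
  } else if (is.list(preset)) {
    if (is.null(preset$nondisjunction_rate)) preset$nondisjunction_rate <- 0.02
    c(preset, list(name = "custom"))
  } else stop("`preset` must be a preset name or a parameter list")
}
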