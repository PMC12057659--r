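#' One generation of the drive-model population
#'
#' Represents a single generation as sex totals, genotype counts and
#' driving-X frequencies. Counts are real-valued expected numbers: the model
#' is deterministic, with no demographic stochasticity.
#'
#' Genotypes follow the usual notation for an X-linked driver X': males are
#' X'Y (`A`) or XY (`B`); females are X'X' (`C`), X'X (`D`) or XX (`E`).
#' `R` is the frequency of X' among male X chromosomes (`A/M`) and `K` the
#' frequency of X' among female X chromosomes (`(2C + D)/(2F)`).
#'
#' When genotype counts are not supplied they are filled in from `R` and `K`
#' (males: `A = R * M`; females: Hardy-Weinberg proportions at allele
#' frequency `K`), which reproduces the requested frequencies exactly. The
#' recursion itself depends on the female genotype split only through `K`.
#'
#' @param M,F Male and female counts (real, >= 0).
#' @param R,K Frequencies of the driving X among male and female X
#'   chromosomes, in `[0, 1]`.
#' @param n Generation index (integer >= 0).
#' @param A,B,C,D,E Optional genotype counts; defaults derived from `R`, `K`.
#'
#' @return An object of class `population_state`.
#' @examples
#' population_state(M = 1000, F = 1000, R = 1 / 1000, K = 1 / 1000)
#' @export
population_state <- function(M, F, R = 0, K = 0, n = 0L,
                             A = NULL, B = NULL, C = NULL, D = NULL, E = NULL) {
  stopifnot(M >= 0, F >= 0, n >= 0)
  if (M > 0 && (R < 0 || R > 1)) stop("R must lie in [0, 1]")
  if (F > 0 && (K < 0 || K > 1)) stop("K must lie in [0, 1]")
  if (is.null(A)) A <- R * M
  if (is.null(B)) B <- (1 - R) * M
  if (is.null(C)) C <- K^2 * F
  if (is.null(D)) D <- 2 * K * (1 - K) * F
  if (is.null(E)) E <- (1 - K)^2 * F
  st <- structure(list(n = as.integer(n), M = M, F = F,
                       A = A, B = B, C = C, D = D, E = E,
                       R = R, K = K),
                  class = "population_state")
  validate_population_state(st)
  st
}

validate_population_state <- function(st, tol = 1e-9) {
  scale_m <- max(st$M, 1)
  scale_f <- max(st$F, 1)
  if (abs(st$A + st$B - st$M) > tol * scale_m)
    stop("genotype counts A + B do not sum to M")
  if (abs(st$C + st$D + st$E - st$F) > tol * scale_f)
    stop("genotype counts C + D + E do not sum to F")
  if (st$M > 0 && abs(st$A / st$M - st$R) > 1e-9)
    stop("R inconsistent with A/M")
  if (st$F > 0 && abs((2 * st$C + st$D) / (2 * st$F) - st$K) > 1e-9)
    stop("K inconsistent with (2C + D)/(2F)")
  invisible(st)
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("generation %d: M = %.6g, F = %.6g (R = %.6g, K = %.6g)\n",
              x$n, x$M, x$F, x$R, x$K))
  invisible(x)
}

#' Fertilized-egg pool and mating regime
#'
#' Number of fertilized eggs produced by a generation with `M` males and `F`
#' females. When `w * M >= F` there are enough males to fertilize every
#' female ("female-limited" reproduction) and the egg pool is `z * F`;
#' otherwise only `w * M` females reproduce ("male-limited") and the pool is
#' `z * w * M`.
#'
#' @param M,F Male and female counts (>= 0).
#' @param params A [drive_params()] object (only `z` and `w` are used).
#'
#' @return A list with `N` (fertilized egg count) and `regime`
#'   (`"female-limited"` or `"male-limited"`).
#' @examples
#' egg_number(1000, 1000, drive_params(0.75))
#' @export
egg_number <- function(M, F, params) {
  params <- as_drive_params(params)
  if (!is.finite(M) || !is.finite(F) || M < 0 || F < 0)
    stop("M and F must be finite and non-negative")
  female_limited <- params$w * M >= F
  N <- if (female_limited) params$z * F else params$z * params$w * M
  list(N = N, regime = if (female_limited) "female-limited" else "male-limited")
}

#' Advance the population one generation (genotype-count recursion)
#'
#' Applies the deterministic recursion for an X-linked driver: driver (X'Y)
#' males sire X'-bearing offspring at frequency `t` while normal (XY) males
#' segregate 1:1, eggs carry X' at the maternal frequency `K`, and the egg
#' pool comes from [egg_number()]. Sex totals, the five genotype counts and
#' the updated frequencies `R`, `K` are all recomputed; the genotype counts
#' conserve the sex totals exactly up to floating point.
#'
#' An all-zero state is an absorbing extinction state and is returned
#' unchanged (with its generation index advanced).
#'
#' @param state A [population_state()].
#' @param params A [drive_params()].
#'
#' @return The next generation's `population_state`, with an attribute
#'   `regime` recording the mating regime that produced it.
#' @export
advance_counts <- function(state, params) {
  params <- as_drive_params(params)
  stopifnot(inherits(state, "population_state"))
  t <- params$t
  R <- state$R
  K <- state$K

  eggs <- egg_number(state$M, state$F, params)
  N <- eggs$N
  if (N == 0) {
    nxt <- structure(list(n = state$n + 1L, M = 0, F = 0,
                          A = 0, B = 0, C = 0, D = 0, E = 0,
                          R = R, K = K),
                     class = "population_state")
    attr(nxt, "regime") <- eggs$regime
    return(nxt)
  }

  M1 <- (0.5 - t) * N * R + N / 2
  F1 <- (t - 0.5) * N * R + N / 2
  A1 <- (0.5 - t) * N * K * R + N * K / 2
  B1 <- (0.5 - t) * N * R + (t - 0.5) * N * K * R - N * K / 2 + N / 2
  C1 <- t * N * K * R
  D1 <- N * K / 2 + t * N * R - (0.5 + t) * N * K * R
  E1 <- N * (1 - K) * (1 - R) / 2

  R1 <- if (M1 > 0) A1 / M1 else K
  K1 <- if (F1 > 0) (2 * C1 + D1) / (2 * F1) else K
  # guard against last-ulp excursions outside [0, 1]
  R1 <- min(max(R1, 0), 1)
  K1 <- min(max(K1, 0), 1)

  nxt <- structure(list(n = state$n + 1L, M = M1, F = F1,
                        A = A1, B = B1, C = C1, D = D1, E = E1,
                        R = R1, K = K1),
                   class = "population_state")
  attr(nxt, "regime") <- eggs$regime
  nxt
}

#' Advance the driving-X frequencies one generation
#'
#' The frequency recursion decouples from population size: `R' = K` (sons
#' draw their X from eggs) and `K' = K/2 + t R / ((2t - 1) R + 1)` (daughters
#' average the maternal egg frequency with the paternal sperm frequency,
#' weighted by the sex-ratio shift among offspring). Equivalent to the
#' frequencies implied by [advance_counts()].
#'
#' @param R,K Current frequencies in `[0, 1]`.
#' @param t Drive strength in `[0.5, 1]`.
#'
#' @return Named numeric vector `c(R = R', K = K')`.
#' @examples
#' advance_frequencies(R = 0.001, K = 0.001, t = 0.75)
#' @export
advance_frequencies <- function(R, K, t) {
  if (!is.numeric(R) || !is.numeric(K) || any(R < 0 | R > 1) || any(K < 0 | K > 1))
    stop("R and K must lie in [0, 1]")
  if (!is.numeric(t) || any(t < 0.5 | t > 1))
    stop("t must lie in [0.5, 1]")
  K1 <- K / 2 + t * R / ((2 * t - 1) * R + 1)
  c(R = K, K = min(max(K1, 0), 1))
}

#' Simulate a population trajectory under X-linked drive
#'
#' Iterates [advance_counts()] from an initial state, recording per-step
#' population change rate (`Total[n+1]/Total[n]`), male/female sex ratio and
#' mating regime, and classifies the terminal outcome:
#'
#' * `"extinction"` -- either sex drops below `extinction_floor` (fewer than
#'   one expected individual, by default);
#' * `"steady"` -- after the driving X has effectively fixed
#'   (`R > 1 - fixation_tol`), the change rate stays within `steady_tol` of 1
#'   for `steady_window` consecutive generations;
#' * `"expansion"` -- after fixation, the change rate stays above
#'   `1 + steady_tol` for `steady_window` consecutive generations;
#' * `"undetermined"` -- `max_generations` reached without classification.
#'
#' For the Mendelian control `t = 0.5` the frequencies never move, so the
#' stationary dynamics are classified directly from the sustained change
#' rate without waiting for fixation.
#'
#' The steady state exists only at fixation of the driving X, so
#' steady/expansion calls are made after frequency convergence to avoid
#' mistaking the transient growth phase for the long-run behaviour. A
#' trajectory classified as expanding or steady stops at the call; a
#' declining one is followed until the extinction floor is hit (or the
#' horizon runs out).
#'
#' @param params A [drive_params()].
#' @param init Initial [population_state()]; default is the standard
#'   initialisation `M0 = F0 = 1000`, `R0 = K0 = 1/1000`.
#' @param max_generations Horizon (>= 1); default 500.
#' @param extinction_floor Count below which a sex is considered extinct
#'   (default 1).
#' @param steady_tol Tolerance on `|change rate - 1|` for the steady call
#'   (default 1e-6).
#' @param steady_window Consecutive generations the rate condition must hold
#'   (default 50).
#' @param fixation_tol Frequency convergence tolerance: fixation is declared
#'   when `R > 1 - fixation_tol` (default 1e-6).
#'
#' @return An object of class `drive_trajectory`: a list with `states`
#'   (data frame of n, M, F, Total, A--E, R, K), `change_rate`, `sex_ratio`,
#'   `regime`, `outcome`, `outcome_generation`, `extinction_generation` and
#'   the parameters. `as.data.frame()` flattens it to the tidy per-generation
#'   table.
#' @examples
#' traj <- simulate_trajectory(drive_params(t = 1))
#' traj$outcome
#' @export
simulate_trajectory <- function(params,
                                init = population_state(1000, 1000, 1 / 1000, 1 / 1000),
                                max_generations = 500L,
                                extinction_floor = 1,
                                steady_tol = 1e-6,
                                steady_window = 50L,
                                fixation_tol = 1e-6) {
  params <- as_drive_params(params)
  stopifnot(max_generations >= 1, extinction_floor >= 0, steady_tol > 0,
            steady_window >= 1)
  validate_population_state(init)

  n_max <- as.integer(max_generations)
  cols <- c("n", "M", "F", "Total", "A", "B", "C", "D", "E", "R", "K")
  states <- matrix(NA_real_, nrow = n_max + 1L, ncol = length(cols),
                   dimnames = list(NULL, cols))
  change_rate <- numeric(n_max)
  regime <- character(n_max)

  fill_row <- function(i, st) {
    states[i, ] <<- c(st$n, st$M, st$F, st$M + st$F,
                      st$A, st$B, st$C, st$D, st$E, st$R, st$K)
  }

  st <- init
  fill_row(1L, st)

  outcome <- "undetermined"
  outcome_generation <- NA_integer_
  extinction_generation <- NA_integer_
  steady_run <- 0L
  growth_run <- 0L
  decline_run <- 0L
  doomed <- FALSE
  last <- 1L

  for (i in seq_len(n_max)) {
    total_prev <- st$M + st$F
    nxt <- advance_counts(st, params)
    fill_row(i + 1L, nxt)
    change_rate[i] <- if (total_prev > 0) (nxt$M + nxt$F) / total_prev else 0
    regime[i] <- attr(nxt, "regime")
    st <- nxt
    last <- i + 1L

    if (st$M < extinction_floor || st$F < extinction_floor) {
      outcome <- "extinction"
      extinction_generation <- st$n
      outcome_generation <- st$n
      break
    }

    converged <- st$R > 1 - fixation_tol || params$t <= 0.5
    if (converged) {
      dev <- change_rate[i] - 1
      steady_run <- if (abs(dev) < steady_tol) steady_run + 1L else 0L
      growth_run <- if (dev >= steady_tol) growth_run + 1L else 0L
      decline_run <- if (dev <= -steady_tol) decline_run + 1L else 0L
      if (steady_run >= steady_window) {
        outcome <- "steady"
        outcome_generation <- st$n
        break
      }
      if (growth_run >= steady_window) {
        outcome <- "expansion"
        outcome_generation <- st$n
        break
      }
      if (decline_run >= steady_window) doomed <- TRUE  # keep going to the floor
    } else {
      steady_run <- growth_run <- decline_run <- 0L
    }
  }

  states <- as.data.frame(states[seq_len(last), , drop = FALSE])
  n_steps <- last - 1L
  sex_ratio <- ifelse(states$F > 0, states$M / states$F, Inf)

  structure(list(states = states,
                 change_rate = change_rate[seq_len(n_steps)],
                 sex_ratio = sex_ratio,
                 regime = regime[seq_len(n_steps)],
                 outcome = outcome,
                 outcome_generation = outcome_generation,
                 extinction_generation = extinction_generation,
                 doomed = doomed,
                 params = params),
            class = "drive_trajectory")
}

#' @export
print.drive_trajectory <- function(x, ...) {
  n <- nrow(x$states) - 1L
  cat(sprintf("drive trajectory: t = %g, z = %g, w = %g; %d generations\n",
              x$params$t, x$params$z, x$params$w, n))
  cat(sprintf("outcome: %s%s\n", x$outcome,
              if (!is.na(x$outcome_generation))
                sprintf(" (generation %d)", x$outcome_generation) else ""))
  invisible(x)
}

#' @describeIn simulate_trajectory Tidy per-generation table with columns
#'   `n, M, F, Total, A, B, C, D, E, R, K, change_rate, sex_ratio_MF, regime`
#'   (step quantities are `NA` on the final row).
#' @param x A `drive_trajectory`.
#' @param ... Unused.
#' @export
as.data.frame.drive_trajectory <- function(x, ...) {
  df <- x$states
  df$change_rate <- c(x$change_rate, NA_real_)
  df$sex_ratio_MF <- x$sex_ratio
  df$regime <- c(x$regime, NA_character_)
  df
}

#' Long-run log population change rate of a trajectory
#'
#' Mean of `log(Total[n+1]/Total[n])` over the final `window` recorded steps
#' after allele-frequency convergence; used as the sign oracle for the
#' numeric threshold search. If the trajectory never converged (frequencies
#' still travelling at the horizon) the transient tail rate is returned with
#' a `converged = FALSE` attribute.
#'
#' @param traj A `drive_trajectory`.
#' @param window Number of trailing steps to average over (default 20).
#' @return Mean log change rate (negative for a declining population).
#' @keywords internal
long_run_log_rate <- function(traj, window = 20L) {
  cr <- traj$change_rate
  cr <- cr[cr > 0]
  if (length(cr) == 0L) return(structure(-Inf, converged = TRUE))
  idx <- seq.int(max(1L, length(cr) - window + 1L), length(cr))
  converged <- traj$outcome != "undetermined" ||
    utils::tail(traj$states$R, 1) > 1 - 1e-6
  structure(mean(log(cr[idx])), converged = converged)
}
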