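#' Analytic extinction threshold for an X-linked driver
#'
#' At the steady state the driving X is fixed (`R = K = 1`) and the
#' population neither grows nor shrinks. That state is only reachable in the
#' male-limited regime (`w * M < F`), where the per-generation change rate at
#' fixation is `z * w * (1 - t)`; setting it to 1 gives the critical drive
#' strength `t = 1 - 1/(z * w)`. The female-limited candidate from the same
#' balance argument is `t = 1/z`, which is `<= 0.5` for every admissible `z`
#' and therefore contradicts the drive domain `0.5 < t <= 1`; it is exposed
#' in the result as `rejected_female_limited`.
#'
#' @param z Reproduction index (>= 2).
#' @param w Mating index (>= 2).
#'
#' @return An object of class `threshold_result`: list with `z`, `w`,
#'   `t_threshold`, `method = "analytic"` and `rejected_female_limited`.
#' @examples
#' analytic_threshold(2, 2)$t_threshold # 0.75
#' @export
analytic_threshold <- function(z, w) {
  if (!is.numeric(z) || !is.numeric(w) || z < 2 || w < 2)
    stop("model premises require z >= 2 and w >= 2")
  rejected <- 1 / z
  stopifnot(rejected <= 0.5) # female-limited steady state is self-contradictory
  structure(list(z = z, w = w,
                 t_threshold = 1 - 1 / (z * w),
                 method = "analytic",
                 rejected_female_limited = rejected),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("extinction threshold (%s): t = %.6g at z = %g, w = %g\n",
              x$method, x$t_threshold, x$z, x$w))
  invisible(x)
}

#' Numeric extinction threshold by bisection on simulated dynamics
#'
#' Finds the critical drive strength by bisection on `t` in (0.5, 1), using
#' the sign of the long-run log population change rate of a simulated
#' trajectory (measured after allele-frequency convergence, so the transient
#' growth phase cannot contaminate the sign test). Provides an end-to-end
#' check of the recursion against [analytic_threshold()].
#'
#' @param z,w Model parameters (>= 2).
#' @param search_tol Bisection half-interval at which to stop (default 1e-5).
#' @param max_generations Horizon per trajectory evaluation (default 3000).
#' @param max_iter Iteration cap (default 60).
#'
#' @return A `threshold_result` with `method = "numeric"`.
#' @examples
#' numeric_threshold(2, 2, search_tol = 1e-4)$t_threshold
#' @export
numeric_threshold <- function(z, w, search_tol = 1e-5,
                              max_generations = 3000L, max_iter = 60L) {
  if (z < 2 || w < 2) stop("model premises require z >= 2 and w >= 2")
  stopifnot(search_tol > 0)
  lo <- 0.5 + 1e-6   # any drive this weak expands: rate z*t or z*w*(1-t) > 1
  hi <- 1            # complete drive goes extinct
  iter <- 0L
  while (hi - lo > search_tol) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("bisection failed to converge within the iteration cap")
    mid <- (lo + hi) / 2
    traj <- simulate_trajectory(drive_params(mid, z, w),
                                max_generations = max_generations)
    g <- long_run_log_rate(traj)
    if (g > 0) lo <- mid else hi <- mid
  }
  structure(list(z = z, w = w,
                 t_threshold = (lo + hi) / 2,
                 method = "numeric",
                 rejected_female_limited = 1 / z),
            class = "threshold_result")
}

#' Classify the long-run population outcome at one parameter set
#'
#' Runs [simulate_trajectory()] and summarises it as a phase-diagram point:
#' the outcome class, the generation at which the change rate first crosses 1
#' downward (the transition out of the growth phase), the extinction
#' generation if any, and the final male/female sex ratio.
#'
#' @param params A [drive_params()] (or list with `t`, `z`, `w`).
#' @param horizon Simulation horizon in generations (default 2000, generous
#'   enough to resolve slow declines just above threshold).
#' @param init Initial state, as in [simulate_trajectory()].
#' @param ... Passed to [simulate_trajectory()] (tolerances, floors).
#'
#' @return An object of class `phase_result`: one-row data frame with columns
#'   `t, z, w, outcome, transition_generation, extinction_generation,
#'   final_sex_ratio`.
#' @examples
#' classify_dynamics(drive_params(t = 0.8))
#' @export
classify_dynamics <- function(params, horizon = 2000L,
                              init = population_state(1000, 1000, 1 / 1000, 1 / 1000),
                              ...) {
  params <- as_drive_params(params)
  traj <- simulate_trajectory(params, init = init,
                              max_generations = horizon, ...)
  outcome <- traj$outcome
  # a sustained post-fixation decline that has not yet hit the floor is a
  # tie-broken steady call only exactly at threshold; elsewhere it is doomed
  if (outcome == "undetermined" && isTRUE(traj$doomed)) outcome <- "extinction"

  cr <- traj$change_rate
  transition <- NA_integer_
  down <- which(cr[-length(cr)] >= 1 & cr[-1] < 1)
  if (length(down) > 0) transition <- as.integer(down[1] + 1L)

  ext_gen <- traj$extinction_generation
  if (outcome == "extinction" && is.na(ext_gen))
    ext_gen <- as.integer(nrow(traj$states) - 1L) # floor not yet reached at horizon

  res <- data.frame(t = params$t, z = params$z, w = params$w,
                    outcome = outcome,
                    transition_generation = transition,
                    extinction_generation = if (outcome == "extinction")
                      ext_gen else NA_integer_,
                    final_sex_ratio = utils::tail(traj$sex_ratio, 1),
                    stringsAsFactors = FALSE)
  class(res) <- c("phase_result", class(res))
  res
}

#' Generations until effective fixation of the driving X
#'
#' Iterates the frequency recursions alone (no population bookkeeping) from
#' `R0 = K0 = init_frequency` and returns the first generation at which the
#' male frequency `R` reaches `1 - epsilon`. Finite for every `t > 0.5`;
#' stronger drive fixes (weakly) faster.
#'
#' @param t Drive strength in (0.5, 1].
#' @param epsilon Convergence margin in (0, 0.5) (default 1e-3).
#' @param init_frequency Starting frequency in (0, 1) (default 1/1000).
#' @param max_generations Safety cap (default 1e6).
#'
#' @return Integer generation count (0 if already within `epsilon`).
#' @examples
#' fixation_generations(1.0) <= fixation_generations(0.6)
#' @export
fixation_generations <- function(t, epsilon = 1e-3, init_frequency = 1 / 1000,
                                 max_generations = 1e6) {
  if (!is.numeric(t) || t <= 0.5 || t > 1)
    stop("fixation requires drive: t must lie in (0.5, 1]")
  stopifnot(epsilon > 0, epsilon < 0.5,
            init_frequency > 0, init_frequency < 1)
  R <- init_frequency
  K <- init_frequency
  n <- 0L
  while (R < 1 - epsilon) {
    if (n >= max_generations)
      stop("fixation not reached within max_generations")
    rk <- advance_frequencies(R, K, t)
    R <- rk[["R"]]
    K <- rk[["K"]]
    n <- n + 1L
  }
  n
}

#' Phase-diagram sweep over drive strength and demographic parameters
#'
#' Classifies every combination of the supplied grids with
#' [classify_dynamics()] and returns the results as one tidy long-format
#' table. The empirical phase boundary between expansion and extinction
#' reproduces the analytic threshold `1 - 1/(z * w)`.
#'
#' @param t_grid,z_grid,w_grid Non-empty numeric grids.
#' @param horizon Simulation horizon per point (default 2000).
#' @param ... Passed to [classify_dynamics()].
#'
#' @return Data frame with one row per combination, columns as in
#'   [classify_dynamics()].
#' @examples
#' parameter_sweep(c(0.6, 0.75, 0.9), 2, 2)
#' @export
parameter_sweep <- function(t_grid, z_grid = 2, w_grid = 2,
                            horizon = 2000L, ...) {
  stopifnot(length(t_grid) > 0, length(z_grid) > 0, length(w_grid) > 0)
  grid <- expand.grid(t = t_grid, z = z_grid, w = w_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    classify_dynamics(drive_params(grid$t[i], grid$z[i], grid$w[i]),
                      horizon = horizon, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
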