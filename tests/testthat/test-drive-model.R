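test_that("egg pool size and mating regime follow male availability", {
  p <- drive_params(0.75, z = 2, w = 2)
  e <- egg_number(1000, 1000, p)
  expect_equal(e$N, 2000)
  expect_equal(e$regime, "female-limited")

  # no males, no fertilization
  e0 <- egg_number(0, 500, p)
  expect_equal(e0$N, 0)
  expect_equal(e0$regime, "male-limited")

  e1 <- egg_number(100, 500, drive_params(0.75, z = 3, w = 2))
  expect_equal(e1$N, 600) # z * w * M when males limit
  expect_equal(e1$regime, "male-limited")

  # regime switch is inclusive: w*M == F still counts as female-limited
  expect_equal(egg_number(500, 1000, p)$regime, "female-limited")
  expect_error(egg_number(-1, 10, p), "non-negative")
})

test_that("parameter domains are enforced", {
  expect_error(drive_params(0.4), "t")
  expect_error(drive_params(1.1), "t")
  expect_error(drive_params(0.75, z = 1.5), "z")
  expect_error(drive_params(0.75, w = 1), "w")
  expect_silent(drive_params(0.5)) # Mendelian control admitted
  expect_error(advance_frequencies(1.2, 0.5, 0.75), "R and K")
  expect_error(advance_frequencies(0.5, 0.5, 0.3), "t")
})

test_that("one-generation genotype counts match the egg x sperm enumeration oracle", {
  set.seed(11)
  for (i in 1:200) {
    t_drive <- runif(1, 0.5, 1)
    z <- runif(1, 2, 6); w <- runif(1, 2, 6)
    R <- runif(1); K <- runif(1)
    M <- runif(1, 1, 5000); F <- runif(1, 1, 5000)
    st <- population_state(M, F, R, K)
    p <- drive_params(t_drive, z, w)
    nxt <- advance_counts(st, p)
    N <- egg_number(M, F, p)$N
    orc <- oracle_offspring_counts(N, R, K, t_drive)
    expect_equal(nxt$A, orc$A, tolerance = 1e-12)
    expect_equal(nxt$B, orc$B, tolerance = 1e-12)
    expect_equal(nxt$C, orc$C, tolerance = 1e-12)
    expect_equal(nxt$D, orc$D, tolerance = 1e-12)
    expect_equal(nxt$E, orc$E, tolerance = 1e-12)
    # conservation of sex totals by genotype counts
    expect_lt(abs(nxt$A + nxt$B - nxt$M) / max(nxt$M, 1), 1e-9)
    expect_lt(abs(nxt$C + nxt$D + nxt$E - nxt$F) / max(nxt$F, 1), 1e-9)
  }
})

test_that("Mendelian t = 0.5 splits the egg pool equally", {
  st <- population_state(1000, 1000, 0.3, 0.6)
  nxt <- advance_counts(st, drive_params(0.5, 2, 2))
  expect_equal(nxt$M, 1000)
  expect_equal(nxt$F, 1000)
})

test_that("complete drive at fixation leaves no sons", {
  st <- population_state(100, 1000, R = 1, K = 1)
  nxt <- advance_counts(st, drive_params(1, 2, 2))
  expect_equal(nxt$M, 0)
})

test_that("an all-zero population is an absorbing extinction state", {
  st <- population_state(0, 0, 0, 0)
  nxt <- advance_counts(st, drive_params(0.8))
  expect_equal(nxt$M, 0)
  expect_equal(nxt$F, 0)
  expect_equal(nxt$n, 1L)
})

test_that("compact frequency recursion equals the genotype-count frequencies", {
  # mandatory internal consistency: Eq-level compact form vs counting route
  set.seed(7)
  for (i in 1:1000) {
    R <- runif(1); K <- runif(1); t_drive <- runif(1, 0.5, 1)
    rk <- advance_frequencies(R, K, t_drive)
    expect_equal(rk[["R"]], K, tolerance = 1e-12)
    # expanded allele-counting form
    expect_equal(rk[["K"]], oracle_next_K(R, K, t_drive), tolerance = 1e-12)
    # frequencies recomputed from genotype counts
    st <- population_state(1000, 1000, R, K)
    nxt <- advance_counts(st, drive_params(t_drive))
    if (nxt$F > 0) expect_equal(rk[["K"]], nxt$K, tolerance = 1e-12)
    if (nxt$M > 0) expect_equal(rk[["R"]], nxt$R, tolerance = 1e-12)
  }
})

test_that("frequency recursion fixed points and worked values", {
  # fixation is a fixed point for every t
  for (t_drive in c(0.5, 0.6, 0.75, 1)) {
    rk <- advance_frequencies(1, 1, t_drive)
    expect_equal(unname(rk), c(1, 1))
  }
  # fair Mendelian averaging at t = 0.5
  rk <- advance_frequencies(0.3, 0.8, 0.5)
  expect_equal(rk[["K"]], 0.8 / 2 + 0.3 / 2)
  # seeded low-frequency driver: K' = K/2 + tR/((2t-1)R + 1)
  rk <- advance_frequencies(0.001, 0.001, 0.75)
  expect_equal(rk[["R"]], 0.001)
  expect_equal(rk[["K"]], 0.0005 + 0.00075 / 1.0005, tolerance = 1e-15)
})

test_that("trajectories classify extinction, steady state and expansion", {
  ext <- simulate_trajectory(drive_params(1))
  expect_equal(ext$outcome, "extinction")
  # brief expansion precedes the collapse under complete drive
  expect_gt(max(ext$states$Total), ext$states$Total[1])

  steady <- simulate_trajectory(drive_params(0.75), max_generations = 2000)
  expect_equal(steady$outcome, "steady")
  expect_lt(abs(utils::tail(steady$change_rate, 1) - 1), 1e-6)

  grow <- simulate_trajectory(drive_params(0.6), max_generations = 2000)
  expect_equal(grow$outcome, "expansion")
  expect_gt(utils::tail(grow$change_rate, 1), 1)
})

test_that("Mendelian null keeps the population and frequencies constant", {
  tr <- simulate_trajectory(drive_params(0.5, 2, 2), max_generations = 200)
  expect_true(all(abs(tr$change_rate - 1) < 1e-12))
  expect_true(all(abs(tr$states$R - 1 / 1000) < 1e-12))
  expect_equal(tr$outcome, "steady")
})

test_that("driver frequencies rise monotonically to fixation for t > 0.5", {
  for (t_drive in c(0.6, 0.8, 1)) {
    R <- 0.001; K <- 0.001
    Rs <- numeric(400)
    for (n in 1:400) {
      rk <- advance_frequencies(R, K, t_drive)
      R <- rk[["R"]]; K <- rk[["K"]]
      Rs[n] <- R
    }
    burn <- Rs[5:400]
    expect_true(all(diff(burn) >= -1e-15))
    expect_gt(utils::tail(Rs, 1), 1 - 1e-6)
  }
})

test_that("extinction is preceded by the switch to the male-limited regime", {
  for (t_drive in c(0.8, 0.9, 1)) {
    tr <- simulate_trajectory(drive_params(t_drive), max_generations = 1000)
    expect_equal(tr$outcome, "extinction")
    expect_true("female-limited" %in% tr$regime)
    expect_equal(utils::tail(tr$regime, 1), "male-limited")
    switch_at <- which(tr$regime == "male-limited")[1]
    expect_true(all(tr$regime[seq_len(switch_at - 1)] == "female-limited"))
  }
})

test_that("trajectory table is tidy and internally consistent", {
  tr <- simulate_trajectory(drive_params(0.9))
  df <- as.data.frame(tr)
  expect_named(df, c("n", "M", "F", "Total", "A", "B", "C", "D", "E", "R", "K",
                     "change_rate", "sex_ratio_MF", "regime"))
  expect_equal(nrow(df), nrow(tr$states))
  expect_equal(length(tr$change_rate), nrow(df) - 1L)
  expect_equal(df$n, seq_len(nrow(df)) - 1)
  expect_equal(df$Total, df$M + df$F)
  expect_equal(df$change_rate[-nrow(df)],
               df$Total[-1] / df$Total[-nrow(df)], tolerance = 1e-12)
})
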