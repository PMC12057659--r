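test_that("Fisher exact p-values: worked cases, symmetry and cross-checks", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  # diagonal 3/3 table: 2 of the 20 equally likely arrangements are as extreme
  expect_equal(fisher_exact_two_sided(matrix(c(3, 0, 0, 3), 2))$p_value,
               2 / choose(6, 3), tolerance = 1e-12)
  tab <- matrix(c(70, 30, 50, 50), 2, byrow = TRUE)
  expect_equal(fisher_exact_two_sided(tab)$p_value, oracle_fisher_p(tab),
               tolerance = 1e-12)
  # symmetric under row swap, column swap and transpose
  p0 <- fisher_exact_two_sided(tab)$p_value
  expect_equal(fisher_exact_two_sided(tab[2:1, ])$p_value, p0)
  expect_equal(fisher_exact_two_sided(tab[, 2:1])$p_value, p0)
  expect_equal(fisher_exact_two_sided(t(tab))$p_value, p0)
  # agreement with the standard implementation on random tables
  set.seed(61)
  for (i in 1:50) {
    tb <- matrix(rpois(4, 20), 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_two_sided(tb)$p_value,
                 stats::fisher.test(tb)$p.value, tolerance = 1e-7)
  }
  expect_error(fisher_exact_two_sided(matrix(0, 2, 2)), "empty")
  expect_error(fisher_exact_two_sided(matrix(c(1, -1, 2, 3), 2)), "negative")
})

test_that("exact binomial p-values: worked cases and cross-checks", {
  expect_equal(binomial_two_sided(5, 10)$p_value, 1)
  expect_equal(binomial_two_sided(8, 10)$p_value, 0.109375, tolerance = 1e-12)
  # one-sided pair of extreme outcomes under the symmetric null
  for (n in c(1, 5, 12)) {
    expect_equal(binomial_two_sided(n, n)$p_value, 2 * 0.5^n,
                 tolerance = 1e-12)
  }
  set.seed(71)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    k <- sample(0:n, 1)
    p0 <- runif(1, 0.2, 0.8)
    expect_equal(binomial_two_sided(k, n, p0)$p_value,
                 stats::binom.test(k, n, p0)$p.value, tolerance = 1e-7)
  }
  expect_error(binomial_two_sided(3, 0), "positive")
  expect_error(binomial_two_sided(5, 4), "k must")
})

test_that("unpaired t test matches the closed form and is scale invariant", {
  same <- unpaired_t_two_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  res <- unpaired_t_two_sided(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$statistic, -1.224745, tolerance = 1e-6)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 0.2878641, tolerance = 1e-6)
  scaled <- unpaired_t_two_sided(10 * c(1, 2, 3), 10 * c(2, 3, 4))
  expect_equal(scaled$statistic, res$statistic, tolerance = 1e-12)
  expect_equal(scaled$p_value, res$p_value, tolerance = 1e-12)
  # Welch variant exposed behind a flag
  w <- unpaired_t_two_sided(c(1, 2, 3), c(2, 4, 9), welch = TRUE)
  expect_equal(w$p_value,
               stats::t.test(c(1, 2, 3), c(2, 4, 9))$p.value)
  expect_error(unpaired_t_two_sided(c(1, 1), c(1, 1)), "degenerate")
  expect_error(unpaired_t_two_sided(1, c(1, 2)), "at least 2")
})

test_that("drive strength estimator pools offspring and is consistent", {
  pr <- data.frame(male = c(1, 1, 2), females = c(10, 12, 30),
                   males = c(0, 0, 0))
  est <- estimate_drive_strength(pr)
  expect_equal(est$t_hat, 1)
  expect_true(all(is.infinite(est$per_male_ratio)))

  # |t_hat - t| shrinks as the offspring count grows
  errs <- vapply(c(20, 200, 2000), function(mu) {
    pr <- gen_progeny_counts(n_males = 10, t = 2 / 3,
                             offspring_per_period_mean = mu, seed = 83)
    abs(estimate_drive_strength(pr)$t_hat - 2 / 3)
  }, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)

  # per-male ratios separate a driver from a Mendelian control at large n
  drv <- gen_progeny_counts(n_males = 10, t = 2 / 3,
                            offspring_per_period_mean = 200, seed = 89)
  ctl <- gen_progeny_counts(n_males = 10, t = 0.5,
                            offspring_per_period_mean = 200, seed = 97)
  rd <- estimate_drive_strength(drv)$per_male_ratio
  rc <- estimate_drive_strength(ctl)$per_male_ratio
  expect_lt(abs(mean(rc) - 1), 0.1)
  expect_lt(unpaired_t_two_sided(rd, rc)$p_value, 1e-6)
  expect_error(estimate_drive_strength(data.frame(male = 1, females = 0,
                                                  males = 0)), "offspring")
})

test_that("the full pipeline is deterministic and internally consistent", {
  cfg <- list(preset = "XSte200_Y", seed = 404)
  rep1 <- run_full_pipeline(cfg)
  rep2 <- run_full_pipeline(cfg)
  expect_identical(as.character(write_pipeline_report(rep1)),
                   as.character(write_pipeline_report(rep2)))
  # forecast agrees with the phase classification at the estimated strength
  t_hat <- rep1$estimates$t_hat$estimate
  expect_equal(rep1$forecast$outcome,
               classify_dynamics(drive_params(min(max(t_hat, 0.5), 1),
                                              2, 2))$outcome)
  expect_equal(rep1$forecast$t_threshold, 0.75)
  # nondisjunction spermatids are excluded from the FISH test
  n_used <- rep1$tests$fish_vs_equal$sample_sizes[["n"]]
  expect_equal(n_used,
               sum(rep1$tables$fish$counts[c("Y", "X")]))
  expect_lt(n_used, sum(rep1$tables$fish$counts))
})

test_that("idealized and null presets give the expected pipeline endpoints", {
  ideal <- run_full_pipeline(list(preset = "idealized", seed = 11))
  expect_equal(ideal$t_cytology, 2 / 3)
  se <- sqrt((2 / 3) * (1 / 3) / ideal$estimates$t_hat$n_offspring)
  expect_lt(abs(ideal$estimates$t_hat$estimate - 2 / 3), 4 * se)
  expect_equal(ideal$forecast$outcome, "expansion") # 2/3 sits below 0.75
  expect_lt(ideal$tests$fish_vs_equal$p_value, 1e-6)

  null <- run_full_pipeline(list(preset = "control", seed = 12))
  expect_equal(null$t_cytology, 0.5)
  se0 <- sqrt(0.25 / null$estimates$t_hat$n_offspring)
  expect_lt(abs(null$estimates$t_hat$estimate - 0.5), 4 * se0)
})

test_that("pipeline errors carry the failing stage", {
  expect_error(run_full_pipeline(list(preset = "XSte200_Y")), "config")
  expect_error(run_full_pipeline(list(preset = "nonsense", seed = 1)),
               "unknown preset")
  expect_error(run_full_pipeline(list(preset = list(p1 = 2, q = 1, p2 = 1),
                                      seed = 1)),
               "stage")
})

test_that("pipeline writes CSV tables and a canonical JSON report", {
  out <- withr::local_tempdir()
  run_full_pipeline(list(preset = "XSte200_Y", seed = 7, out_dir = out))
  expect_setequal(list.files(out),
                  c("telophase_I.csv", "telophase_II.csv", "fish_counts.csv",
                    "progeny.csv", "control_progeny.csv", "report.json"))
  fish <- utils::read.csv(file.path(out, "fish_counts.csv"))
  expect_equal(sum(fish$count), 1000)
  parsed <- jsonlite::fromJSON(file.path(out, "report.json"))
  expect_equal(parsed$forecast$t_threshold, 0.75)
})
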