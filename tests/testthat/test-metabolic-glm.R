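# Multilevel model of log-metabolic parameters: exchangeability, sign
# recovery, degenerate nesting, the time-course variant, and posterior
# predictive checks.

sim_glm_data <- function(deflections = c(A = -0.5, B = 0.5), wells = 12,
                         replicates = 2, sd = 0.1, seed = 1) {
  set.seed(seed)
  d <- tidyr::expand_grid(cell_line = names(deflections),
                          replicate = seq_len(replicates),
                          well = seq_len(wells))
  d$log_value <- 5 + deflections[d$cell_line] + rnorm(nrow(d), 0, sd)
  d
}

test_that("identical values in both cell lines give p_minus near 0.5", {
  vals <- rnorm(24, 5, 0.2)
  d <- tidyr::expand_grid(cell_line = c("A", "B"), replicate = 1:2,
                          well = 1:12)
  d$log_value <- c(vals, vals)
  fit <- fit_metabolic_glm(d, chains = 2, iter = 2200, seed = 4)
  expect_equal(tidy(fit)$p_minus, c(0.5, 0.5), tolerance = 0.05 / 0.5)
  # sum-to-zero: posterior mean deflections cancel across cell lines
  expect_equal(sum(tidy(fit)$median), 0, tolerance = 1e-6)
})

test_that("simulated +-0.5 deflections are recovered with decisive p_minus", {
  d <- sim_glm_data(seed = 2)
  fit <- fit_metabolic_glm(d, chains = 2, iter = 2000, seed = 102)
  td <- tidy(fit)
  expect_lt(td$median[td$cell_line == "A"], 0)
  expect_gt(td$median[td$cell_line == "B"], 0)
  expect_gt(td$p_minus[td$cell_line == "A"], 0.95)
  expect_lt(td$p_minus[td$cell_line == "B"], 0.05)
  expect_true(all(td$hdi50_lo >= td$hdi95_lo & td$hdi50_hi <= td$hdi95_hi))
  expect_true(all(is.finite(td$rhat)))
})

test_that("single replicate per cell line degrades to cell-line-only model", {
  d <- sim_glm_data(replicates = 1, seed = 3)
  expect_message(
    fit <- fit_metabolic_glm(d, chains = 2, iter = 1000, seed = 5),
    "single replicate"
  )
  expect_false(glance(fit)$nested)
  expect_equal(nrow(tidy(fit)), 2)
})

test_that("time-course variant returns one row per cell line and time", {
  set.seed(6)
  d <- tidyr::expand_grid(cell_line = c("A", "B"), replicate = 1:2,
                          time_h = c(0, 1, 6), well = 1:6)
  d$log_value <- 5 + ifelse(d$time_h == 1, -0.8, 0) + rnorm(nrow(d), 0, 0.1)
  fit <- fit_time_course_glm(d, chains = 2, iter = 1500, seed = 7)
  td <- tidy(fit)
  expect_equal(nrow(td), 2 * 3)
  # the step drop at 1 h is recovered in sign for both cell lines
  expect_true(all(td$median[td$time_h == 1] < 0))
  expect_true(all(td$p_minus[td$time_h == 1] > 0.95))

  # identical distributions at all times: deflections centred at 0
  d$log_value <- 5 + rnorm(nrow(d), 0, 0.1)
  fit0 <- fit_time_course_glm(d, chains = 2, iter = 1500, seed = 8)
  expect_true(all(abs(tidy(fit0)$median) < 0.15))
})

test_that("posterior predictive checks are calibrated on well-fitting data
           and extreme on mis-scaled data", {
  d <- sim_glm_data(seed = 9)
  fit <- fit_metabolic_glm(d, chains = 2, iter = 1500, seed = 10)
  ppc <- posterior_predictive_check(fit, n_rep = 400, seed = 11)
  expect_equal(nrow(ppc), 4) # mean, sd, two cell-line means
  expect_true(all(ppc$p_tail > 0.01 & ppc$p_tail < 0.99))

  # grossly mis-scaled observations produce an extreme tail probability
  d_bad <- d; d_bad$log_value <- d_bad$log_value + 10
  fit_obs <- fit # replicate from the original fit, compare to shifted data
  ppc_bad <- posterior_predictive_check(
    structure(c(fit_obs[setdiff(names(fit_obs), "data")],
                list(data = dplyr::mutate(fit_obs$data,
                                          y = fit_obs$data$y + 10))),
              class = "metab_glm"),
    n_rep = 200, seed = 12)
  expect_lt(ppc_bad$p_tail[ppc_bad$statistic == "mean"], 0.01)
})

test_that("non-finite responses and missing columns are rejected", {
  d <- sim_glm_data(seed = 13)
  d$log_value[1] <- NA
  expect_error(fit_metabolic_glm(d), "finite")
  expect_error(fit_metabolic_glm(sim_glm_data(), response = "nope"),
               "not found")
})

test_that("95% HDIs cover true deflections across seeded studies", {
  truth <- c(A = -0.5, B = 0.2, C = 0.3) # sum-to-zero truth
  covered <- 0L; total <- 0L
  for (s in 1:10) {
    d <- sim_glm_data(deflections = truth, wells = 10, sd = 0.15,
                      seed = 40 + s)
    fit <- suppressWarnings(fit_metabolic_glm(d, chains = 2, iter = 1200,
                                              seed = 140 + s))
    td <- tidy(fit)
    hit <- truth[td$cell_line] >= td$hdi95_lo &
      truth[td$cell_line] <= td$hdi95_hi
    covered <- covered + sum(hit); total <- total + length(hit)
  }
  expect_gte(covered / total, 0.85)
})
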