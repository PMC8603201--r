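# Hierarchical focus-clearance model: marginal-likelihood identity,
# degenerate data, linearity of expected counts, PPC direction, LOO
# plumbing, and chain-order invariance.

test_that("beta-binomial pmf matches numerical integration of binomial x beta", {
  for (case in list(c(A = 10, k = 3, p = 0.05, conc = 50),
                    c(A = 40, k = 0, p = 0.01, conc = 500),
                    c(A = 25, k = 25, p = 0.9, conc = 20),
                    c(A = 50, k = 12, p = 0.3, conc = 5))) {
    a <- case[["p"]] * case[["conc"]]
    b <- (1 - case[["p"]]) * case[["conc"]]
    direct <- dbetabinom(case[["k"]], case[["A"]], a, b)
    quad <- stats::integrate(function(q)
      dbinom(case[["k"]], case[["A"]], q) * dbeta(q, a, b),
      0, 1, rel.tol = 1e-12, abs.tol = 0)$value
    expect_equal(direct, quad, tolerance = 1e-6)
  }
  # support boundaries
  expect_equal(dbetabinom(-1, 10, 2, 2), 0)
  expect_equal(dbetabinom(11, 10, 2, 2), 0)
  expect_equal(sum(dbetabinom(0:20, 20, 1.5, 30)), 1, tolerance = 1e-12)
})

test_that("beta shape conversion enforces the variance bound", {
  sh <- beta_shapes_mv(0.2, 0.01)
  expect_equal(sh$alpha / (sh$alpha + sh$beta), 0.2)
  v <- sh$alpha * sh$beta / ((sh$alpha + sh$beta)^2 * (sh$alpha + sh$beta + 1))
  expect_equal(v, 0.01)
  expect_error(beta_shapes_mv(0.2, 0.2), "outside")
})

test_that("all-zero counts at a time pull that p_t below 1e-3", {
  cfg <- foci_sim_config(cell_lines = "X",
                         p = matrix(c(0.02, 0.012, 0.006, 0.002, 0), 1),
                         seed = 2)
  rec <- simulate_foci_dataset(cfg)
  fit <- suppressWarnings(fit_foci_model(rec, chains = 2, iter = 1200,
                                         seed = 9, keep_loglik = FALSE))
  td <- tidy(fit)
  expect_lt(td$median[td$time_h == 24], 1e-3)
})

test_that("expected foci are linear in area and reduce to p_t at unit area", {
  q <- c(0.02, 0.012, 0.006, 0.002, 0.001)
  fit <- fake_foci_fit(q)
  e1 <- expected_foci(fit, area_units = 1)
  expect_equal(e1$median, q)
  e400 <- expected_foci(fit, area_units = 400)
  expect_equal(e400$median, 400 * e1$median)
  expect_equal(e400$cri95_hi, 400 * e1$cri95_hi)
})

test_that("posterior medians are monotone for cleanly decreasing data", {
  p_dec <- c(0.03, 0.02, 0.01, 0.005, 0.002)
  cfg <- foci_sim_config(cell_lines = "X", p = matrix(p_dec, 1), phi = 4000,
                         seed = 5)
  rec <- simulate_foci_dataset(cfg)
  fit <- suppressWarnings(fit_foci_model(rec, chains = 2, iter = 1500,
                                         seed = 6, keep_loglik = FALSE))
  expect_true(all(diff(tidy(fit)$median) < 0))
})

test_that("chain pooling is order-invariant", {
  cfg <- foci_sim_config(cell_lines = "X",
                         p = matrix(c(0.02, 0.012, 0.006, 0.002, 0.001), 1),
                         seed = 7)
  rec <- simulate_foci_dataset(cfg)
  fit <- suppressWarnings(fit_foci_model(rec, chains = 3, iter = 800,
                                         seed = 8, keep_loglik = FALSE))
  fit_perm <- fit
  fit_perm$draws <- fit$draws[c(3, 1, 2)]
  expect_equal(sort(tidy(fit)$median), sort(tidy(fit_perm)$median))
  expect_equal(tidy(fit)$median, tidy(fit_perm)$median)
})

test_that("single-replicate hierarchical fits are refused with guidance", {
  rec <- simulate_foci_dataset(
    foci_sim_config(cell_lines = "X",
                    p = matrix(c(0.02, 0.012, 0.006, 0.002, 0.001), 1),
                    n_replicates = 1, seed = 9))
  expect_error(fit_foci_model(rec), "pooled",
               class = "repairflux_model_error")
  expect_s3_class(fit_foci_model(rec, model = "pooled", chains = 2,
                                 iter = 600, seed = 1),
                  "foci_fit")
})

test_that("PPC flags doubled counts and reports all statistics", {
  cfg <- foci_sim_config(cell_lines = "X",
                         p = matrix(c(0.02, 0.012, 0.006, 0.003, 0.002), 1),
                         seed = 10)
  rec <- simulate_foci_dataset(cfg)
  fit <- suppressWarnings(fit_foci_model(rec, chains = 2, iter = 1200,
                                         seed = 11, keep_loglik = FALSE))
  ppc <- ppc_foci(fit, n_rep = 300, seed = 12)
  expect_equal(nrow(ppc), 2 * 5 + 1) # per-time means, vm ratios, max
  expect_true(all(ppc$p_tail[grep("mean", ppc$statistic)] > 0.01 &
                    ppc$p_tail[grep("mean", ppc$statistic)] < 0.99))

  doubled <- fit
  doubled$data$foci_count <- pmin(2L * doubled$data$foci_count,
                                  doubled$data$area_units)
  ppc2 <- ppc_foci(doubled, n_rep = 300, seed = 13)
  expect_lt(ppc2$p_tail[ppc2$statistic == "mean_t0.5"], 0.01)
})

test_that("PSIS weights on a tiny matrix equal hand-computed ratios", {
  ll <- c(-1, -2.5, -0.3)
  ps <- psis_weights(-ll)
  hand <- exp(-ll) / sum(exp(-ll)) # raw normalised importance ratios
  expect_equal(exp(ps$log_weights), hand, tolerance = 1e-12)
  expect_true(is.na(ps$pareto_k)) # too few draws to smooth
})

test_that("identical fits give exactly zero elpd difference", {
  cfg <- foci_sim_config(cell_lines = "X",
                         p = matrix(c(0.02, 0.012, 0.006, 0.002, 0.001), 1),
                         nuclei_per_replicate = 20, seed = 14)
  rec <- simulate_foci_dataset(cfg)
  fit <- suppressWarnings(fit_foci_model(rec, chains = 2, iter = 800,
                                         seed = 15))
  cmp <- loo_compare_foci(fit, fit)
  expect_equal(cmp$elpd_diff, 0)
  expect_equal(cmp$preferred, "indeterminate")

  other <- simulate_foci_dataset(
    foci_sim_config(cell_lines = "X",
                    p = matrix(c(0.02, 0.012, 0.006, 0.002, 0.001), 1),
                    nuclei_per_replicate = 20, seed = 99))
  fit2 <- suppressWarnings(fit_foci_model(other, chains = 2, iter = 800,
                                          seed = 16))
  expect_error(loo_compare_foci(fit, fit2), "different records")
})

test_that("replicate-pooled beta-binomial model fits and keeps logliks", {
  cfg <- foci_sim_config(cell_lines = "X",
                         p = matrix(c(0.02, 0.012, 0.006, 0.002, 0.001), 1),
                         nuclei_per_replicate = 25, seed = 17)
  rec <- simulate_foci_dataset(cfg)
  fit <- suppressWarnings(fit_foci_model(rec, model = "betabinom",
                                         chains = 2, iter = 700, seed = 18))
  expect_equal(dim(fit$loglik), c(nrow(rec), 2 * 350))
  expect_true(all(is.finite(fit$loglik)))
})

test_that("simulation-based calibration: rank statistics of p_t are uniform", {
  # truth drawn from the model's own prior; if sampler and model agree, the
  # rank of the truth among thinned posterior draws is uniform
  set.seed(2024)
  rf <- asNamespace("repairflux")
  n_sbc <- 200; L <- 19
  ranks <- integer(0)
  for (i in seq_len(n_sbc)) {
    TT <- 3; reps <- 3; nuc <- 12
    p0 <- runif(TT)
    k0 <- vapply(seq_len(TT), function(t) {
      k <- rchisq(1, 2); while (k < 1) k <- rchisq(1, 2); k
    }, 0)
    s20 <- rchisq(1, 2)
    bnd <- rf$v_bound(p0)
    v0 <- vapply(seq_len(TT), function(t)
      qchisq(runif(1, 0, pchisq(bnd[t] * k0[t] / s20, k0[t])), k0[t]) *
        s20 / k0[t], 0)
    sh <- beta_shapes_mv(p0, v0)
    recs <- list()
    for (t in seq_len(TT)) {
      for (r in seq_len(reps)) {
        prt <- rbeta(1, sh$alpha[t], sh$beta[t])
        A <- pmax(1L, as.integer(round(rlnorm(nuc, log(300), 0.3))))
        recs[[length(recs) + 1]] <- tibble::tibble(
          cell_line = "X", replicate = r, time_h = c(0, 2, 24)[t],
          nucleus_id = sprintf("t%dr%dn%d", t, r, seq_len(nuc)),
          area_units = A, foci_count = rbinom(nuc, A, prt))
      }
    }
    fit <- suppressWarnings(
      fit_foci_model(dplyr::bind_rows(recs), chains = 1, iter = 900,
                     warmup = 400, seed = 3000 + i, keep_loglik = FALSE))
    thin <- fit$draws[[1]]$p[seq(1, 500, length.out = L), ]
    ranks <- c(ranks, vapply(seq_len(TT),
                             function(t) sum(thin[, t] < p0[t]), 0L))
  }
  tab <- tabulate(ranks + 1L, L + 1L)
  expect_gt(stats::chisq.test(tab)$p.value, 0.01)
})
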