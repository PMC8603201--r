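# Generators: determinism, degenerate limits, dispersion structure, and the
# noiseless flux round trip.

test_that("foci generator is deterministic and respects its contracts", {
  cfg <- foci_sim_config(seed = 11)
  a <- simulate_foci_dataset(cfg)
  b <- simulate_foci_dataset(cfg)
  expect_identical(a, b)
  expect_true(all(a$foci_count <= a$area_units))
  expect_true(all(a$area_units >= 1))
  expect_equal(nrow(a), 2 * 3 * 5 * 80)
  # adding a cell line leaves the existing cell lines' draws untouched
  cfg3 <- foci_sim_config(cell_lines = c("CL1", "CL2", "CL3"), seed = 11)
  c3 <- simulate_foci_dataset(cfg3)
  expect_identical(a, dplyr::filter(c3, cell_line %in% c("CL1", "CL2")))
})

test_that("a forced zero probability yields all-zero counts at that time", {
  p <- matrix(c(0.02, 0.01, 0.005, 0.002, 0), 1)
  cfg <- foci_sim_config(cell_lines = "X", p = p, seed = 2)
  rec <- simulate_foci_dataset(cfg)
  expect_true(all(rec$foci_count[rec$time_h == 24] == 0))
  expect_true(any(rec$foci_count[rec$time_h == 0] > 0))
})

test_that("count variance approaches the binomial limit as phi grows", {
  # oracle: closed-form binomial variance A p (1 - p) at fixed area
  p0 <- 0.05; area <- 200L
  cfg <- foci_sim_config(cell_lines = "X", p = matrix(rep(p0, 5), 1),
                         phi = 1e9, n_replicates = 25,
                         nuclei_per_replicate = 80,
                         area_sdlog = 0, area_meanlog = log(area), seed = 3)
  rec <- simulate_foci_dataset(cfg) # 10^4 nuclei at the first time point
  k <- rec$foci_count[rec$time_h == 0]
  expect_length(k, 2000)
  k_all <- rec$foci_count # pool all times: same p, 10^4 nuclei
  expect_equal(var(k_all), area * p0 * (1 - p0), tolerance = 0.05)
})

test_that("finite phi produces between-replicate overdispersion", {
  cfg <- foci_sim_config(cell_lines = "X", p = matrix(rep(0.05, 5), 1),
                         phi = 100, n_replicates = 25,
                         nuclei_per_replicate = 80,
                         area_sdlog = 0, area_meanlog = log(200), seed = 4)
  rec <- simulate_foci_dataset(cfg)
  k <- rec$foci_count
  binom_var <- 200 * 0.05 * 0.95
  expect_gt(var(k) / binom_var, 1) # index of dispersion above binomial
})

test_that("invalid dispersion is rejected naming the offending values", {
  expect_error(foci_sim_config(phi = -1), "phi",
               class = "repairflux_config_error")
})

test_that("flux generator: noiseless plates are exact and deterministic", {
  cfg <- flux_sim_config(cv = 0, rfu_cv = 0, seed = 5)
  pl <- simulate_flux_plate(cfg, "mito", 0, irradiated = FALSE)
  basal <- pl[pl$phase == "basal" & pl$cell_line == "CL1", ]
  expect_true(all(basal$ocr == cfg$baseline_ocr[["CL1"]]))
  expect_identical(pl, simulate_flux_plate(cfg, "mito", 0, irradiated = FALSE))
  expect_error(simulate_flux_plate(cfg, "seahorse", 0, FALSE),
               "unknown assay")
})

test_that("noiseless shutdown propagates exactly into log2 fold change", {
  f <- 0.4
  cfg <- flux_sim_config(cv = 0, rfu_cv = 0,
                         mito_response = c(`1` = f, `6` = 0.6, `24` = 0.8),
                         seed = 6)
  ctrl <- simulate_flux_plate(cfg, "mito", 1, irradiated = FALSE)
  ir <- simulate_flux_plate(cfg, "mito", 1, irradiated = TRUE)
  params <- compute_mito_params(dplyr::bind_rows(ctrl, ir), normalize = FALSE)
  fc <- log2_fold_change(params, parameters = "basal")
  expect_equal(fc$log2_fc, rep(log2(f), nrow(fc)), tolerance = 1e-12)
})

test_that("coupled study echoes its slope and produces collinear truth", {
  st <- simulate_coupled_study(foci_sim_config(seed = 8),
                               flux_sim_config(seed = 8),
                               coupling_slope = -0.04, seed = 8)
  expect_true(all(st$truth$slope_true == -0.04))
  for (cl in unique(st$truth$cell_line)) {
    tr <- st$truth[st$truth$cell_line == cl, ]
    ls <- stats::lm(p_true ~ log_basal_true, data = tr)
    expect_equal(unname(coef(ls)[2]), -0.04, tolerance = 1e-12)
    expect_equal(unname(coef(ls)[1]), tr$intercept_true[1], tolerance = 1e-12)
  }
  expect_s3_class(st$foci, "tbl_df")
  expect_true(all(c("control", "IR") %in% st$flux$treatment))
})

test_that("null coupling gives uncorrelated repair and metabolism", {
  # with slope 0 the truth p is flat in time while metabolism still recovers
  st <- simulate_coupled_study(foci_sim_config(seed = 9),
                               flux_sim_config(seed = 9),
                               coupling_slope = 0, seed = 9)
  tr <- st$truth[st$truth$cell_line == "CL1", ]
  expect_equal(diff(range(tr$p_true)), 0)
  expect_gt(diff(range(tr$log_basal_true)), 0.1)
})
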