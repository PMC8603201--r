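# Stress-test parameter extraction: the kit formulas on forced cases, exact
# agreement with an independent brute-force oracle, normalisation linearity,
# and fold-change semantics.

test_that("mito parameters on constant phases match the stated formulas", {
  tr <- flux_well(values = c(basal = 100, oligo = 40, fccp = 150,
                             rot_aa = 20))
  p <- compute_mito_params(tr, normalize = FALSE)
  expect_equal(p$non_mito, 20)
  expect_equal(p$basal, 80)
  expect_equal(p$atp_production, 60)
  expect_equal(p$proton_leak, 20)
  expect_equal(p$maximal, 130)
  expect_equal(p$spare_capacity, 50)

  zero <- tr; zero$ocr <- 0
  pz <- suppressMessages(compute_mito_params(zero, normalize = FALSE))
  expect_true(all(unlist(pz[c("non_mito", "basal", "atp_production",
                              "proton_leak", "maximal",
                              "spare_capacity")]) == 0))
})

test_that("glyco parameters on constant phases match the stated formulas", {
  tr <- flux_well(assay = "glyco", values = c(baseline = 10, glucose = 40,
                                              oligo = 70, `2dg` = 12))
  p <- compute_glyco_params(tr, normalize = FALSE)
  expect_equal(p$non_glycolytic, 10)
  expect_equal(p$glycolysis, 30)
  expect_equal(p$glycolytic_capacity, 60)
  expect_equal(p$glycolytic_reserve, 30)

  flat <- flux_well(assay = "glyco", values = c(baseline = 10, glucose = 10,
                                                oligo = 70, `2dg` = 12))
  expect_equal(compute_glyco_params(flat, normalize = FALSE)$glycolysis, 0)
})

test_that("randomized traces agree exactly with the brute-force oracle", {
  for (s in 1:25) {
    tr <- random_trace("mito", s)
    got <- compute_mito_params(tr, normalize = FALSE)
    expect_equal(unlist(got[names(oracle_mito(tr))]), oracle_mito(tr),
                 ignore_attr = TRUE)
    tg <- random_trace("glyco", s + 1000)
    gotg <- compute_glyco_params(tg, normalize = FALSE)
    expect_equal(unlist(gotg[names(oracle_glyco(tg))]), oracle_glyco(tg),
                 ignore_attr = TRUE)
  }
})

test_that("missing phases are reported by name", {
  tr <- flux_well(values = c(basal = 100, oligo = 40, fccp = 150,
                             rot_aa = 20))
  tr <- tr[tr$phase != "fccp", ]
  expect_error(compute_mito_params(tr), "fccp")
})

test_that("scale equivariance: scaling a well scales every parameter", {
  tr <- random_trace("mito", 42)
  p1 <- compute_mito_params(tr, normalize = FALSE)
  tr2 <- tr; tr2$ocr <- tr2$ocr * 3.5
  p2 <- compute_mito_params(tr2, normalize = FALSE)
  cols <- c("non_mito", "basal", "atp_production", "proton_leak", "maximal",
            "spare_capacity")
  expect_equal(as.numeric(p2[cols]), 3.5 * as.numeric(p1[cols]))
})

test_that("RFU normalisation is linear and preserves additive invariants", {
  tr <- random_trace("mito", 7)
  p <- compute_mito_params(tr, normalize = FALSE)
  n1 <- normalize_params(p, rfu = 1)
  expect_equal(n1$basal, p$basal)
  n2 <- normalize_params(p, rfu = 2)
  expect_equal(n2$basal, p$basal / 2)
  expect_equal(n2$basal, n2$atp_production + n2$proton_leak)
  expect_equal(n2$spare_capacity, n2$maximal - n2$basal)
  expect_error(normalize_params(p, rfu = 0), "rfu")
})

test_that("fold change uses ratios of group means with recorded sizes", {
  ctrl <- dplyr::bind_rows(
    flux_well("c1", values = c(basal = 100, oligo = 40, fccp = 150,
                               rot_aa = 20)),
    flux_well("c2", values = c(basal = 120, oligo = 40, fccp = 150,
                               rot_aa = 20))
  )
  trt <- dplyr::bind_rows(
    flux_well("t1", treatment = "IR", timepoint_h = 1,
              values = c(basal = 50, oligo = 20, fccp = 75, rot_aa = 10)),
    flux_well("t2", treatment = "IR", timepoint_h = 1,
              values = c(basal = 60, oligo = 20, fccp = 75, rot_aa = 10))
  )
  params <- compute_mito_params(dplyr::bind_rows(ctrl, trt),
                                normalize = FALSE)
  fc <- log2_fold_change(params, parameters = "basal")
  # mean treated basal = (40 + 50)/2 = 45; mean control = (80 + 100)/2 = 90
  expect_equal(fc$log2_fc, log2(45 / 90))
  expect_equal(fc$n_treated, 2L)
  expect_equal(fc$n_control, 2L)

  same <- params
  same$treatment[3:4] <- "IR"
  same$basal[3:4] <- same$basal[1:2]
  expect_equal(log2_fold_change(same, parameters = "basal")$log2_fc, 0)

  neg <- params
  neg$basal[1:2] <- -5
  expect_error(log2_fold_change(neg, parameters = "basal"),
               "non-positive control mean",
               class = "repairflux_validation_error")
})
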