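# Repair vectors, Euclidean distances, clustering, residual damage.

test_that("repair vectors carry posterior medians in fixed time order", {
  q <- c(0.02, 0.01, 0.005, 0.002, 0.001)
  rv <- repair_vector(fake_foci_fit(q))
  expect_equal(rv$q, q)
  expect_equal(rv$time_h, foci_times())
  # permuting draws leaves the median untouched
  fit <- fake_foci_fit(q)
  fit$draws[[1]]$p <- fit$draws[[1]]$p[sample(nrow(fit$draws[[1]]$p)), ]
  expect_equal(repair_vector(fit)$q, q)
  # missing time errors with the available ones listed
  short <- fake_foci_fit(q[1:4], times = foci_times()[1:4])
  expect_error(repair_vector(short), "lacks time")
})

test_that("median matches a direct sort-based computation on 5 draws", {
  fit <- fake_foci_fit(0.5, times = 0, ndraw = 5)
  fit$draws[[1]]$p <- matrix(c(0.3, 0.1, 0.9, 0.2, 0.8), 5)
  expect_equal(repair_vector(fit, times = 0)$q, sort(c(0.3, 0.1, 0.9, 0.2,
                                                       0.8))[3])
})

test_that("distances: identity, the 3-4-5 case, and a brute-force oracle", {
  qa <- c(0.02, 0.01, 0.005, 0.002, 0.001)
  va <- tibble::tibble(cell_line = "a", time_h = foci_times(), q = qa)
  vb <- dplyr::mutate(va, cell_line = "b")
  expect_equal(unclass(distance_matrix(dplyr::bind_rows(va, vb)))["a", "b"],
               0)

  vc <- dplyr::mutate(va, cell_line = "c",
                      q = qa + c(0.003, 0, 0, 0, 0.004))
  D <- distance_matrix(dplyr::bind_rows(va, vc))
  expect_equal(unclass(D)["a", "c"], 0.005)

  set.seed(1)
  vecs <- purrr::map(1:9, ~tibble::tibble(cell_line = paste0("v", .x),
                                          time_h = foci_times(),
                                          q = runif(5, 0.001, 0.05)))
  vecs <- dplyr::bind_rows(vecs)
  D <- unclass(distance_matrix(vecs))
  wide <- tidyr::pivot_wider(vecs, names_from = time_h, values_from = q)
  m <- as.matrix(wide[-1])
  for (i in 1:9) for (j in 1:9) { # brute-force double loop
    expect_identical(D[i, j], sqrt(sum((m[i, ] - m[j, ])^2)))
  }
  # metric properties
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
  for (i in 1:9) for (j in 1:9) for (k in 1:9) {
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("distances are homogeneous of degree one in the vectors", {
  set.seed(2)
  vecs <- dplyr::bind_rows(purrr::map(1:4, ~tibble::tibble(
    cell_line = paste0("v", .x), time_h = foci_times(),
    q = runif(5, 0.001, 0.05))))
  D1 <- unclass(distance_matrix(vecs))
  D3 <- unclass(distance_matrix(dplyr::mutate(vecs, q = 3 * q)))
  expect_equal(D3, 3 * D1)
})

test_that("clustering: duplicates merge first at height zero", {
  qa <- c(0.02, 0.01, 0.005, 0.002, 0.001)
  vecs <- dplyr::bind_rows(
    tibble::tibble(cell_line = "dup1", time_h = foci_times(), q = qa),
    tibble::tibble(cell_line = "far", time_h = foci_times(), q = qa + 0.05),
    tibble::tibble(cell_line = "dup2", time_h = foci_times(), q = qa)
  )
  res <- cluster_order(distance_matrix(vecs))
  expect_equal(res$heights[1], 0)
  ord <- res$order
  expect_equal(abs(which(ord == "dup1") - which(ord == "dup2")), 1)
})

test_that("three points on a line merge the closest pair first", {
  vecs <- dplyr::bind_rows(purrr::imap(c(a = 0, b = 1, c = 10),
                                       ~tibble::tibble(cell_line = .y,
                                                       time_h = foci_times(),
                                                       q = rep(.x / 30, 5))))
  res <- cluster_order(distance_matrix(vecs), "single")
  m <- res$hclust$merge[1, ] # leaves merged at step 1 (negative indices)
  expect_setequal(res$hclust$labels[-m], c("a", "b"))
})

test_that("average-linkage heights match a hand agglomeration on 4 points", {
  # distances: d(a,b)=1, d(a,c)=4, d(a,d)=6, d(b,c)=4.2, d(b,d)=6.4, d(c,d)=1.5
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 1
  D["a", "c"] <- D["c", "a"] <- 4
  D["a", "d"] <- D["d", "a"] <- 6
  D["b", "c"] <- D["c", "b"] <- 4.2
  D["b", "d"] <- D["d", "b"] <- 6.4
  D["c", "d"] <- D["d", "c"] <- 1.5
  res <- cluster_order(structure(D, class = c("repair_dist", "matrix",
                                              "array")), "average")
  # hand: merge (a,b) at 1; merge (c,d) at 1.5;
  # then d({a,b},{c,d}) = mean(4, 6, 4.2, 6.4) = 5.15
  expect_equal(res$heights, c(1, 1.5, 5.15))
  expect_error(cluster_order(matrix(c(0, NA, NA, 0), 2)), "NA")
})

test_that("residual damage is the percent density ratio final/reference", {
  rec <- tibble::tibble(
    cell_line = "A", replicate = rep(1L, 6),
    time_h = rep(c(0.5, 24), each = 3),
    nucleus_id = paste0("n", 1:6),
    area_units = c(100L, 100L, 200L, 100L, 100L, 200L),
    foci_count = c(4L, 6L, 6L, 1L, 1L, 2L)
  )
  # density(0.5) = 16/400 = 0.04; density(24) = 4/400 = 0.01 -> 25%
  rd <- residual_damage(rec)
  expect_equal(rd$pct_residual, 25)

  equal <- rec
  equal$foci_count[4:6] <- equal$foci_count[1:3]
  expect_equal(residual_damage(equal)$pct_residual, 100)

  zero <- rec
  zero$foci_count[1:3] <- 0L
  expect_error(residual_damage(zero), "zero reference")
  expect_error(residual_damage(rec, t_ref = 2), "not present")
})
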