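test_that("thresholding removes exactly the regions with mean below cutoff", {
  vals <- cbind(c(0.001, 0.002, 0.003),      # mean 0.002  keep
                c(0.0005, 0.0005, 0.0005),   # mean 0.0005 drop
                c(0.01, 0.01, 0.01),         # mean 0.01   keep
                c(0.00099, 0.00099, 0.00099))# mean .00099 drop
  co <- toy_cohort(vals)
  res <- threshold_regions(co)
  expect_identical(res$removed, c("RG02", "RG04"))
  expect_identical(res$cohort$values, co$values[, c(1, 3)])
  expect_identical(res$cohort$stage, "thresholded")

  # boundary mean exactly at the threshold is retained
  co2 <- toy_cohort(matrix(0.001, 2, 1))
  expect_length(threshold_regions(co2)$removed, 0L)

  # all regions below threshold is an error
  co3 <- toy_cohort(matrix(1e-5, 2, 2))
  expect_error(threshold_regions(co3), "every region")

  # nothing removed when all means pass; values untouched
  co4 <- toy_cohort(matrix(runif(6, 0.01, 0.2), 2, 3))
  res4 <- threshold_regions(co4)
  expect_length(res4$removed, 0L)
  expect_identical(res4$cohort$values, co4$values)
})

test_that("power-law fit recovers a closed-form relation exactly", {
  # sum PF_i = 2 * V_i^0.3 for V in {1,2,4,8}, spread over 4 regions
  V <- c(1, 2, 4, 8)
  s <- 2 * V ^ 0.3 / 100          # scaled into [0,1] cell range
  vals <- matrix(rep(s / 4, 4), 4, 4)
  co <- toy_cohort(vals, animals = toy_animals(4, injection_volume = V))
  fit <- fit_volume_exponent(threshold_regions(co)$cohort)
  expect_lt(abs(fit$exponent - 0.3), 1e-10)
  expect_lt(abs(fit$prefactor - 2 / 100), 1e-12)
  expect_identical(fit$intercept, 0)

  # identical totals with differing volumes give slope zero
  co2 <- toy_cohort(matrix(0.05, 4, 3),
                    animals = toy_animals(4, injection_volume = V))
  expect_lt(abs(fit_volume_exponent(threshold_regions(co2)$cohort)$exponent),
            1e-12)

  # degenerate inputs
  co3 <- toy_cohort(matrix(0.05, 4, 2),
                    animals = toy_animals(4, injection_volume = rep(2, 4)))
  expect_error(fit_volume_exponent(threshold_regions(co3)$cohort),
               "all equal")
  expect_error(fit_volume_exponent(co))       # wrong stage
})

test_that("volume normalization divides rows by V^n and allows values above 1", {
  co <- toy_cohort(matrix(c(0.5, 0.9), 1, 2),
                   animals = toy_animals(1, injection_volume = 16))
  thr <- threshold_regions(co)$cohort
  out <- normalize_by_volume(thr, 0.25)
  expect_equal(unname(out$values[1, 1]), 0.25)     # 0.5 / 16^0.25

  co2 <- toy_cohort(matrix(0.9, 1, 1),
                    animals = toy_animals(1, injection_volume = 0.5))
  out2 <- normalize_by_volume(threshold_regions(co2)$cohort, 0.216)
  expect_equal(unname(out2$values[1, 1]), 0.9 / 0.5 ^ 0.216, tolerance = 1e-12)
  expect_gt(out2$values[1, 1], 1)                  # legal past this stage
  expect_identical(out2$stage, "volume_normalized")

  # n = 0 is the identity
  out3 <- normalize_by_volume(threshold_regions(co)$cohort, 0)
  expect_identical(out3$values, threshold_regions(co)$cohort$values)

  # zeros and within-row ordering are preserved
  set.seed(2)
  co4 <- toy_cohort(cbind(c(0, 0, 0.3, 0.5), matrix(runif(8, 0.01, 0.9), 4, 2)))
  thr4 <- threshold_regions(co4)$cohort
  out4 <- normalize_by_volume(thr4, 0.3)
  expect_true(all(out4$values[1:2, 1] == 0))
  for (i in 1:4)
    expect_identical(order(out4$values[i, ]), order(thr4$values[i, ]))
})

test_that("unit-mean scaling yields unit column means and is idempotent", {
  co <- toy_cohort(matrix(c(1, 2, 3, 5, 5, 5) / 10, 3, 2))
  vn <- normalize_by_volume(threshold_regions(co)$cohort, 0)
  um <- unit_mean_normalize(vn)
  expect_equal(unname(um$values[, 1]), c(0.5, 1, 1.5))
  expect_equal(unname(um$values[, 2]), c(1, 1, 1))
  expect_lt(max(abs(colMeans(um$values) - 1)), 1e-12)
  expect_identical(unit_mean_normalize(um)$values, um$values)  # idempotent
  expect_identical(um$stage, "unit_mean")
})

test_that("the stage tags enforce the canonical chain order", {
  co <- toy_cohort(matrix(0.05, 4, 2))
  expect_error(normalize_by_volume(co, 0.2), "thresholded")
  expect_error(unit_mean_normalize(co), "volume_normalized")
  expect_error(fit_region_glm(prep_chain(co)$values), "cohort_table|stage")
  thr <- threshold_regions(co)$cohort
  expect_error(threshold_regions(thr), "raw")
})

test_that("injection-distance correlations use the most distant animal as reference", {
  set.seed(9)
  vals <- matrix(runif(15, 0.01, 0.9), 3, 5)
  an <- toy_animals(3, ml_um = c(700, 950, 800))
  co <- toy_cohort(vals, animals = an)
  res <- injection_distance_correlations(co, axis = "ML", normalize = FALSE)
  expect_identical(attr(res, "reference"), "A02")
  expect_equal(res$pearson_r[2], 1)
  # hand-checked Pearson against the reference row
  for (i in c(1, 3))
    expect_equal(res$pearson_r[i], oracle_pearson(vals[i, ], vals[2, ]),
                 tolerance = 1e-12)

  # duplicated animal rows correlate exactly 1 with the reference
  vals2 <- rbind(vals[2, ], vals)
  an2 <- toy_animals(4, ml_um = c(100, 700, 950, 800))
  co2 <- toy_cohort(vals2, animals = an2)
  res2 <- injection_distance_correlations(co2, axis = "ML", normalize = FALSE)
  expect_equal(res2$pearson_r[1], 1)

  # unit-mean scaling changes correlations when region means differ
  res_norm <- injection_distance_correlations(co, axis = "ML", normalize = TRUE)
  expect_gt(max(abs(res_norm$pearson_r - res$pearson_r)), 1e-6)

  # zero-variance animal profile is an error
  co3 <- toy_cohort(rbind(vals, 0.5), animals = toy_animals(4))
  expect_error(injection_distance_correlations(co3, normalize = FALSE),
               "zero-variance")
})
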