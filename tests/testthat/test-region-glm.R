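# hand-built unit-mean cohort whose values follow the linear model exactly
exact_glm_cohort <- function(B, condition = c(1, 1, 1, -1, -1, -1),
                             ml = c(700, 830, 910, 760, 880, 795),
                             ap = c(1520, 1870, 1610, 1750, 1590, 1930),
                             dv = c(604, 663, 611, 645, 590, 652)) {
  # beta = 1 keeps every column mean at exactly 1 for balanced groups
  # because the centred covariates sum to zero
  n <- length(condition)
  X <- cbind(1, ml - mean(ml), ap - mean(ap), dv - mean(dv), condition)
  vals <- X %*% B
  an <- toy_animals(n, condition = condition, ml_um = ml, ap_um = ap,
                    dv_um = dv)
  toy_cohort(vals, stage = "unit_mean", animals = an)
}

test_that("the shared-design fit recovers exact coefficients and matches lm per region", {
  B <- rbind(beta = c(1, 1, 1),
             kx = c(2e-4, -1e-4, 0),
             ky = c(1e-4, 5e-5, -2e-4),
             kz = c(-3e-4, 0, 1e-3),
             kc = c(0.05, -0.02, 0))
  co <- exact_glm_cohort(B)
  fit <- fit_region_glm(co, include_condition = TRUE)
  expect_lt(max(abs(fit$beta - B["beta", ])), 1e-10)
  expect_lt(max(abs(fit$kx - B["kx", ])), 1e-10)
  expect_lt(max(abs(fit$ky - B["ky", ])), 1e-10)
  expect_lt(max(abs(fit$kz - B["kz", ])), 1e-10)
  expect_lt(max(abs(fit$kc - B["kc", ])), 1e-10)

  # independent oracle: stats::lm region by region on a noisy random cohort
  set.seed(12)
  g <- generate_cohort(synth_config(n_regions = 15), seed = 3)
  um <- prep_chain(g$cohort)
  f2 <- fit_region_glm(um, include_condition = TRUE)
  an <- um$animals
  for (j in seq_len(ncol(um$values))) {
    ref <- stats::lm(um$values[, j] ~ I(an$ml_um - mean(an$ml_um)) +
                       I(an$ap_um - mean(an$ap_um)) +
                       I(an$dv_um - mean(an$dv_um)) + an$condition)
    expect_equal(unname(c(f2$beta[j], f2$kx[j], f2$ky[j], f2$kz[j], f2$kc[j])),
                 unname(stats::coef(ref)), tolerance = 1e-12)
    expect_equal(f2$resid_var[j], summary(ref)$sigma ^ 2, tolerance = 1e-10)
  }
})

test_that("identical rows give zero covariate effects and unit intercepts", {
  co <- toy_cohort(matrix(1, 6, 3), stage = "unit_mean")
  fit <- fit_region_glm(co)
  expect_equal(fit$beta, rep(1, 3))
  expect_equal(fit$kx, rep(0, 3))
  expect_equal(fit$kc, rep(0, 3))
})

test_that("flipping condition labels negates kc and nothing else", {
  g <- generate_cohort(synth_config(n_regions = 12), seed = 44)
  um <- prep_chain(g$cohort)
  f1 <- fit_region_glm(um)
  um2 <- um
  um2$animals$condition <- -um2$animals$condition
  f2 <- fit_region_glm(um2)
  expect_equal(f2$kc, -f1$kc, tolerance = 1e-12)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f2$kx, f1$kx, tolerance = 1e-12)
})

test_that("kc is invariant to exchanging animals within a condition and to covariate shifts", {
  g <- generate_cohort(synth_config(n_regions = 10), seed = 15)
  um <- prep_chain(g$cohort)
  f1 <- fit_region_glm(um)

  ctrl <- which(um$animals$condition == 1)
  perm <- seq_len(nrow(um$values))
  perm[ctrl[1:2]] <- ctrl[2:1]
  um2 <- um
  um2$values <- um$values[perm, ]
  um2$animals <- um$animals[perm, ]
  rownames(um2$animals) <- NULL
  f2 <- fit_region_glm(um2)
  expect_equal(f2$kc, f1$kc, tolerance = 1e-12)

  # adding a constant to a raw covariate changes nothing after centering
  um3 <- um
  um3$animals$ml_um <- um3$animals$ml_um + 500
  f3 <- fit_region_glm(um3)
  expect_equal(f3$kx, f1$kx, tolerance = 1e-12)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-12)
  expect_equal(f3$kc, f1$kc, tolerance = 1e-12)
})

test_that("degenerate designs error and the mean condition effect is the plain mean", {
  g <- generate_cohort(synth_config(n_regions = 8), seed = 2)
  um <- prep_chain(g$cohort)
  um_one <- um
  um_one$animals$condition <- rep(1, nrow(um$values))
  expect_error(fit_region_glm(um_one), "rank")

  fit <- fit_region_glm(um)
  fit_mod <- fit
  fit_mod$kc <- c(0.1, -0.05, 0.07, rep(0, nrow(fit) - 3))
  expect_equal(mean_condition_effect(fit_mod), mean(fit_mod$kc))
  expect_equal(mean_condition_effect(within(fit, kc <- 0 * kc)), 0)
  nofit <- fit_region_glm(um, include_condition = FALSE)
  expect_error(mean_condition_effect(nofit), "condition")
  expect_null(nofit$kc)
})

test_that("residualization removes geometry without leaking held-out animals", {
  # slopes zero, null condition: residuals are the intercept column exactly
  co <- exact_glm_cohort(rbind(beta = c(1, 1), kx = 0, ky = 0, kz = 0,
                               kc = 0))
  res <- residualize_covariates(co)
  expect_equal(unname(res), matrix(1, 6, 2), tolerance = 1e-10)

  # nonzero slopes, condition orthogonal to geometry within the training
  # subset: a held-out animal's residual is its baseline-plus-condition
  # component exactly
  B <- rbind(beta = c(1, 1, 1), kx = c(2e-4, -1e-4, 1e-4),
             ky = c(1e-4, 0, -5e-5), kz = c(-2e-4, 4e-4, 0),
             kc = c(0.06, -0.03, 0.01))
  # both groups share the same five covariate positions; the held-out
  # position sits at the mean of the four training positions, so the
  # training subset keeps condition orthogonal to geometry and the
  # centring constants agree
  co2 <- exact_glm_cohort(
    B, condition = rep(c(1, -1), each = 5),
    ml = rep(c(700, 800, 900, 820, 805), 2),
    ap = rep(c(1500, 1900, 1600, 1760, 1690), 2),
    dv = rep(c(600, 660, 615, 637, 628), 2))
  res2 <- residualize_covariates(co2, fit_animals = c(1:4, 6:9))
  expected <- outer(co2$animals$condition, B["kc", ]) + 1
  expect_lt(max(abs(res2[c(5, 10), ] - expected[c(5, 10), ])), 1e-8)

  # fitting on everyone reproduces the whole-cohort variant
  expect_equal(residualize_covariates(co2),
               residualize_covariates(co2, fit_animals = 1:10))
})
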