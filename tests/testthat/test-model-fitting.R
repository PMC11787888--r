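# Canonical recovery-study layout: 9 timepoints spanning the fast
# absorption phase (tmax ~0.19 h for tobramycin) through the last dose tail.
recovery_design <- function(mice = 6) {
  sampling_design(c(0.05, 0.1, 0.2, 0.4, 0.75, 1.5, 3.25, 6, 9), mice)
}

tob_truth <- function() pk_params(0.37, 23.68, 0.31)
tob_regimen <- function() regimen(c(0, 3, 6, 9), c(9, 4, 2, 0.5))

test_that("IQR filter applies Tukey fences with interpolated quartiles", {
  res <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_equal(res$excluded, 100)
  expect_equal(res$kept, c(1, 2, 3, 4))
  expect_equal(res$upper, 7) # Q3 = 4, IQR = 2
  # constant groups are never filtered
  expect_length(iqr_filter(rep(5, 6))$excluded, 0)
  # groups below n = 4 pass through
  expect_equal(iqr_filter(c(5, 600))$kept, c(5, 600))
})

test_that("dataset-level filtering reports per-matrix exclusion tallies", {
  df <- tibble::tibble(
    time_h = rep(c(1, 2), each = 6),
    matrix = "plasma",
    analyte = "drug",
    conc_mg_L = c(10, 11, 9, 10, 12, 95, 5, 6, 5, 6, 5, 6)
  )
  res <- filter_outliers(df)
  expect_equal(nrow(res$excluded), 1)
  expect_equal(res$excluded$conc_mg_L, 95)
  expect_equal(res$tally$label, "1/12 (8.3%)")
})

test_that("least-squares AIC follows its defining identities", {
  expect_equal(pk_aic(54, 54, 3), 6) # 54 ln(1) + 6
  # equal rss: smaller k wins by twice the parameter difference
  expect_equal(pk_aic(30, 10, 5) - pk_aic(30, 10, 3), 4)
  # doubling rss raises the criterion by n ln 2
  expect_equal(pk_aic(30, 20, 3) - pk_aic(30, 10, 3), 30 * log(2))
  expect_warning(v <- pk_aic(10, 0, 3), "perfect fit")
  expect_identical(v, -Inf)
})

test_that("noiseless synthetic data are recovered essentially exactly", {
  st <- generate_pk_study(tob_truth(), tob_regimen(), recovery_design(),
                          noise_model(cv = 0), seed = 1)
  fit <- fit_pk(st$observations, tob_regimen())
  expect_true(fit$converged)
  al <- align_flipflop(fit$parameters, tob_truth())
  expect_equal(al$volume, 0.37, tolerance = 1e-4)
  expect_equal(al$ka, 23.68, tolerance = 1e-4)
  expect_equal(al$kel, 0.31, tolerance = 1e-4)
  # the generating parameters leave no residual on their own data
  expect_lt(fit$rss, 1e-8)
})

test_that("fitting is deterministic and unit-rescaling only moves the volume", {
  st <- generate_pk_study(tob_truth(), tob_regimen(), recovery_design(),
                          noise_model(cv = 0.2), seed = 11)
  f1 <- fit_pk(st$observations, tob_regimen())
  f2 <- fit_pk(st$observations, tob_regimen())
  expect_identical(f1$estimates, f2$estimates)
  # concentrations in ug/mL -> mg/L x10: V shrinks x10, rates unchanged
  obs10 <- dplyr::mutate(st$observations, conc_mg_L = conc_mg_L * 10)
  f10 <- fit_pk(obs10, tob_regimen())
  expect_equal(f10$estimates[["volume"]], f1$estimates[["volume"]] / 10,
               tolerance = 1e-6)
  expect_equal(f10$estimates[["ka"]], f1$estimates[["ka"]], tolerance = 1e-6)
  expect_equal(f10$estimates[["kel"]], f1$estimates[["kel"]],
               tolerance = 1e-6)
})

test_that("a flip-flop truth is recovered up to the ka/kel exchange", {
  mero <- pk_params(0.04, 1.34, 27.13)
  reg <- regimen(c(0, 1.25, 3.5, 6), c(65, 65, 45, 45))
  des <- sampling_design(c(0.05, 0.15, 0.35, 0.75, 1.5, 2.5, 4, 6, 7.5), 6)
  st <- generate_pk_study(mero, reg, des, noise_model(cv = 0), seed = 3)
  fit <- fit_pk(st$observations, reg)
  al <- align_flipflop(fit$parameters, mero)
  expect_equal(al$volume, 0.04, tolerance = 1e-3)
  expect_equal(al$ka, 1.34, tolerance = 1e-3)
  expect_equal(al$kel, 27.13, tolerance = 1e-3)
})

test_that("BLQ observations are dropped, never imputed", {
  st <- generate_pk_study(tob_truth(), tob_regimen(), recovery_design(),
                          noise_model(cv = 0), seed = 1)
  fit <- fit_pk(st$observations, tob_regimen(), lloq = 0.5)
  expect_equal(fit$n_obs + fit$n_blq_dropped, nrow(st$observations))
  expect_true(all(fit$residuals$observed >= 0.5))
})

test_that("model selection favours the generating one-compartment model", {
  picks <- vapply(1:20, function(s) {
    st <- generate_pk_study(tob_truth(), tob_regimen(), recovery_design(),
                            noise_model(cv = 0.2), seed = 100 + s)
    f1 <- fit_pk(st$observations, tob_regimen())
    f2 <- fit_pk(st$observations, tob_regimen(), model = "two_compartment")
    select_model(list(f1, f2))$model
  }, character(1))
  expect_gte(mean(picks == "one_compartment"), 0.9)
})

test_that("model selection breaks ties toward parsimony", {
  st <- generate_pk_study(tob_truth(), tob_regimen(), recovery_design(),
                          noise_model(cv = 0.1), seed = 5)
  fit <- fit_pk(st$observations, tob_regimen())
  expect_identical(select_model(list(fit)), fit)
  tied <- fit
  tied$k_params <- 5L
  # identical AIC, different k: the 3-parameter fit must win
  expect_identical(select_model(list(tied, fit))$k_params, 3L)
  broken <- fit
  broken$converged <- FALSE
  expect_error(select_model(list(broken)), "converged")
})

test_that("fitting refuses underdetermined designs", {
  st <- generate_pk_study(tob_truth(), tob_regimen(),
                          sampling_design(c(1, 2, 3), 6),
                          noise_model(cv = 0), seed = 1)
  expect_error(fit_pk(st$observations, tob_regimen()), "distinct timepoints")
})

test_that("broom views of a fit expose estimates, fit quality and residuals", {
  st <- generate_pk_study(tob_truth(), tob_regimen(), recovery_design(),
                          noise_model(cv = 0.1), seed = 2)
  fit <- fit_pk(st$observations, tob_regimen())
  expect_equal(tidy(fit)$term, c("volume", "ka", "kel"))
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n_obs, nrow(st$observations))
  expect_equal(nrow(augment(fit)), g$n_obs)
})
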