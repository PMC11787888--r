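test_that("free fraction is the ultrafiltrate/total ratio, pooled by dose", {
  rec <- tibble::tibble(dose_mg_kg = 5, replicate = 1,
                        total_mg_L = 10, uf_mg_L = 2)
  expect_equal(free_fraction(rec)$pooled, 0.2)
  same <- tibble::tibble(dose_mg_kg = 5, replicate = 1:3,
                         total_mg_L = 8, uf_mg_L = 8)
  expect_equal(free_fraction(same)$pooled, 1)
})

test_that("the escalating-dose binding study pools to ~22.5% bound", {
  # dose-group binding of 27.1%, 20.5%, 19.8% -> fractions 0.729/0.795/0.802
  rec <- tibble::tibble(
    dose_mg_kg = c(2.5, 5, 10), replicate = 1,
    total_mg_L = 1, uf_mg_L = c(0.729, 0.795, 0.802)
  )
  ff <- free_fraction(rec)
  expect_equal(ff$per_dose$fraction, c(0.729, 0.795, 0.802))
  # the mean of the rounded printed fractions; replicate-level pooling of
  # unrounded assay values gives 22.4% bound (fu 0.776)
  expect_equal(ff$percent_bound, 22.47, tolerance = 1e-3)
  expect_equal(ff$pooled, 0.776, tolerance = 0.01)
})

test_that("free fraction flags capped and rejects unusable records", {
  rec <- tibble::tibble(dose_mg_kg = c(1, 1, 2), replicate = c(1, 2, 1),
                        total_mg_L = c(10, 0, 10), uf_mg_L = c(12, 5, 5))
  expect_warning(expect_warning(ff <- free_fraction(rec), "dropped"),
                 "capped")
  expect_equal(nrow(ff$per_replicate), 2)
  expect_equal(max(ff$per_replicate$fraction), 1)
  expect_error(suppressWarnings(
    free_fraction(tibble::tibble(dose_mg_kg = 1, replicate = 1,
                                 total_mg_L = 0, uf_mg_L = 1))),
    "usable")
})

test_that("urea dilution correction inverts lavage dilution", {
  # identity dilution: BAL is already at ELF strength
  r1 <- elf_from_bal(tibble::tibble(bal_mg_L = 3, urea_plasma = 40,
                                    urea_bal = 40))
  expect_equal(r1$elf_mg_L, 3)
  r2 <- elf_from_bal(tibble::tibble(bal_mg_L = 0.5, urea_plasma = 40,
                                    urea_bal = 2))
  expect_equal(r2$elf_mg_L, 10)
  r3 <- elf_from_bal(tibble::tibble(bal_mg_L = 0, urea_plasma = 40,
                                    urea_bal = 2))
  expect_equal(r3$elf_mg_L, 0)
  expect_error(elf_from_bal(tibble::tibble(bal_mg_L = 1, urea_plasma = 40,
                                           urea_bal = 0)), "urea_bal")
  expect_warning(elf_from_bal(tibble::tibble(bal_mg_L = 1, urea_plasma = 10,
                                             urea_bal = 20)), "dilute")
})

test_that("urea correction is linear in BAL and urea_plasma, inverse in urea_bal", {
  base <- tibble::tibble(bal_mg_L = 2, urea_plasma = 40, urea_bal = 4)
  e0 <- elf_from_bal(base)$elf_mg_L
  expect_equal(elf_from_bal(dplyr::mutate(base, bal_mg_L = 3 * bal_mg_L))$elf_mg_L,
               3 * e0)
  expect_equal(elf_from_bal(dplyr::mutate(base, urea_plasma = 2 * urea_plasma))$elf_mg_L,
               2 * e0)
  expect_equal(elf_from_bal(dplyr::mutate(base, urea_bal = 2 * urea_bal))$elf_mg_L,
               e0 / 2)
})

test_that("penetration regression recovers lines exactly", {
  # two points define the line
  m <- fit_penetration_model(c(0, 1), c(1, 2))
  expect_equal(m$slope, 1, tolerance = 1e-12)
  expect_equal(m$intercept, 1, tolerance = 1e-12)
  # round trip through the fitter at the reference design times
  times <- c(0.5, 2, 4, 8)
  m2 <- fit_penetration_model(times, 0.1223 * times + 0.1567)
  expect_equal(m2$slope, 0.1223, tolerance = 1e-12)
  expect_equal(m2$intercept, 0.1567, tolerance = 1e-12)
  expect_equal(m2$r_squared, 1, tolerance = 1e-9)
  expect_error(fit_penetration_model(c(2, 2, 2), c(1, 2, 3)), "distinct")
})

test_that("penetration projection is exact for constant and decaying profiles", {
  # constant plasma level over [0, T]: ratio integrates to b + a T / 2
  const_prof <- hsrsim:::new_pk_profile(
    tibble::tibble(onset = 0, type = "const", coef = 5, rate = 0),
    window = c(0, 8), matrix = "plasma", binding = "unbound",
    unbound_fraction = 1
  )
  m <- penetration_model(0.1223, 0.1567, time_range = c(0, 8))
  res <- apply_penetration(const_prof, m)
  expect_equal(res$auc_ratio, 0.1567 + 0.1223 * 8 / 2, tolerance = 1e-9)
  # slope zero: the ratio is the intercept exactly
  res0 <- apply_penetration(const_prof, penetration_model(0, 0.69,
                                                          time_range = c(0, 8)))
  expect_equal(res0$auc_ratio, 0.69, tolerance = 1e-12)
  # monoexponential plasma: AUC of the projected profile matches quadrature
  p <- pk_params(0.37, 23.68, 0.31)
  prof <- simulate_regimen(p, regimen(0, 9), unbound_fraction = 0.776)
  res2 <- apply_penetration(prof, m, window = c(0.5, 8))
  quad <- stats::integrate(function(t) {
    profile_conc(prof, t) * (0.1223 * t + 0.1567)
  }, 0.5, 8, rel.tol = 1e-10)$value
  expect_equal(auc(res2$profile, c(0.5, 8)), quad, tolerance = 1e-3)
  expect_equal(res2$auc_ratio, quad / auc(prof, c(0.5, 8)), tolerance = 1e-3)
})

test_that("penetration projection guards its domain", {
  p <- pk_params(0.37, 23.68, 0.31)
  prof <- simulate_regimen(p, regimen(0, 9), unbound_fraction = 0.776)
  m <- penetration_model(0.1223, 0.1567, time_range = c(0.5, 8))
  expect_error(apply_penetration(prof, m, window = c(0, 24)), "extrapolate")
  ok <- apply_penetration(prof, m, window = c(0, 24), extrapolate = TRUE)
  expect_s3_class(ok$profile, "pk_profile")
  neg <- penetration_model(-0.1, 0.2, time_range = c(0, 24))
  expect_error(apply_penetration(prof, neg, window = c(0, 24),
                                 extrapolate = TRUE), "negative")
})

test_that("synthetic BAL records are inverted exactly at zero noise", {
  elf_truth <- simulate_regimen(pk_params(0.79, 1.74, 0.35),
                                regimen(c(0, 3), c(4.8, 2.4)))
  rec <- generate_bal_study(elf_truth, timepoints = c(1, 4, 8), cv = 0,
                            seed = 42)
  out <- elf_from_bal(rec)
  expect_equal(out$elf_mg_L, out$elf_true_mg_L, tolerance = 1e-12)
})
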