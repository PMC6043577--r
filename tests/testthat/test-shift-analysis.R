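test_that("temperature coefficients classify hydrogen bonding correctly", {
  mk <- function(slope) generate_temp_shift_series(slope,
                                                   seq(288, 308, 5))
  tc4 <- temperature_coefficient(mk(-4))
  expect_equal(tc4$slope_ppb_k, -4, tolerance = 1e-9)
  expect_true(tc4$h_bonded)
  tc7 <- temperature_coefficient(mk(-7))
  expect_false(tc7$h_bonded)
  # strict inequality at the -5 ppb/K boundary
  expect_false(temperature_coefficient(mk(-5))$h_bonded)
  expect_true(temperature_coefficient(mk(0))$h_bonded)
})

test_that("classification is invariant to a constant shift offset", {
  s <- generate_temp_shift_series(-6, seq(288, 308, 5), noise_sd = 0.5,
                                  seed = 3)
  s2 <- s; s2$h_ppm <- s2$h_ppm + 1.234
  expect_equal(temperature_coefficient(s)$slope_ppb_k,
               temperature_coefficient(s2)$slope_ppb_k, tolerance = 1e-9)
})

test_that("CSP index matches hand evaluation and flags significance", {
  free <- data.frame(residue_id = c("R01", "R02", "R03", "R04"),
                     h_ppm = c(8.0, 8.1, 7.9, 8.3),
                     n_ppm = c(120, 118, 122, 119))
  bound <- free
  expect_equal(csp_index(free, bound)$table$csp_ppm, rep(0, 4))
  expect_false(any(csp_index(free, bound)$table$significant))
  bound2 <- free
  bound2$h_ppm[2] <- free$h_ppm[2] + 0.1
  bound2$n_ppm[2] <- free$n_ppm[2] + 0.5
  out <- csp_index(free, bound2)
  expect_equal(out$table$csp_ppm[out$table$residue_id == "R02"],
               sqrt(0.1^2 + (0.14 * 0.5)^2), tolerance = 1e-12)
  expect_equal(out$table$residue_id[out$table$significant], "R02")
})

test_that("quadratic binding fit inverts a noiseless titration", {
  tit <- generate_titration_shifts(50e-6, 2)
  fit <- fit_binding_quadratic(tit)
  expect_equal(fit$kd, 50e-6, tolerance = 1e-6)
  expect_equal(fit$dw_max, 2, tolerance = 1e-6)
  expect_false(fit$poorly_determined)
})

test_that("KD recovery stays within 10 percent at 0.02 ppm shift noise", {
  errs <- vapply(1:20, function(s) {
    tit <- generate_titration_shifts(50e-6, 2, noise_sd = 0.02, seed = s)
    abs(fit_binding_quadratic(tit)$kd - 50e-6) / 50e-6
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("isotherm limits hold numerically", {
  kd <- 50e-6
  expect_equal(binding_isotherm(0, kd, 2, 80e-6), 0)
  expect_equal(binding_isotherm(1e6 * kd, kd, 2, 80e-6), 2,
               tolerance = 1e-4)
})

test_that("non-saturating and disappeared titrations are handled", {
  # max L0 far below KD: flagged poorly determined
  tit <- generate_titration_shifts(5e-3, 2,
                                   ligand_concs = c(5, 10, 20, 40) * 1e-6)
  fit <- fit_binding_quadratic(tit)
  expect_true(fit$poorly_determined)
  gone <- titration_series(data.frame(l0_m = c(5, 50, 500) * 1e-6,
                                      dw_obs_ppm = c(0.1, 0.3, 0.5)),
                           "R09", 80e-6, disappeared = TRUE)
  expect_error(fit_binding_quadratic(gone), "disappeared")
})

test_that("titration-dispersion shift comparison flags constructed outliers", {
  ids <- sprintf("R%02d", 1:8)
  disp <- setNames(seq(0.5, 4, 0.5), ids)
  tit <- disp
  expect_length(compare_dw(tit, disp)$outliers, 0)
  tit["R03"] <- tit["R03"] + 1
  tit["R07"] <- tit["R07"] - 0.8
  cmp <- compare_dw(tit, disp)
  expect_setequal(cmp$outliers, c("R03", "R07"))
  expect_equal(cmp$table$abs_diff[cmp$table$residue_id == "R03"], 1)
  expect_gt(cmp$correlation, 0.8)
})
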