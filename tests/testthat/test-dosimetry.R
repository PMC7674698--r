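lam_tc <- tc99m()$lambda_per_min

test_that("per-frame decay weights: closed forms and the 1/lambda total", {
  expect_equal(decay_weight(0:5, 0), rep(1, 6))
  expect_equal(decay_weight(0, lam_tc), 0.99904, tolerance = 1e-5)
  # geometric total: full residence equals the mean life in minutes
  s <- sum(decay_weight(0:50000, lam_tc))
  expect_equal(s, 1 / lam_tc, tolerance = 1e-9)
  expect_equal(1 / lam_tc, 520.26, tolerance = 1e-4)
  expect_error(decay_weight(0, -1), ">= 0")
})

test_that("constant activity without decay integrates to the closed form", {
  a <- 3.7e-5
  series <- pedidose:::.dose_rate_series(
    A = matrix(a, 1, 1), rel_err = matrix(0, 1, 1),
    frame_of = rep(1L, 200), frame_min = 1, organs = "organ")
  for (Tm in c(60, 100, 137.25)) {
    d <- integrate_organ_dose(series, integration_spec(Tm, B0 = 1,
                                                       lambda = 0))
    expect_equal(d$dose_mgy, a * 2.22e9 * 1.602e-7 * Tm, tolerance = 1e-12)
  }
})

test_that("integrator matches a fine-grid quadrature oracle", {
  set.seed(8)
  n_org <- 3; n_frames <- 120
  A <- matrix(stats::runif(n_org * n_frames, 1e-6, 1e-4), n_org, n_frames)
  series <- pedidose:::.dose_rate_series(
    A = A, rel_err = matrix(0, n_org, n_frames),
    frame_of = seq_len(n_frames), frame_min = 1,
    organs = paste0("o", 1:n_org))
  for (Tm in c(100, 87.3)) {       # whole and partial last frame
    got <- integrate_organ_dose(series, integration_spec(Tm,
                                                         lambda = lam_tc))
    ref <- quadrature_dose(A, 1, Tm, lam_tc)
    expect_equal(got$dose_mgy, ref, tolerance = 1e-6)
  }
})

test_that("dose is linear in B0, monotone in T, anti-monotone in lambda", {
  set.seed(9)
  A <- matrix(stats::runif(2 * 100, 1e-6, 1e-4), 2, 100)
  series <- pedidose:::.dose_rate_series(
    A = A, rel_err = matrix(0, 2, 100), frame_of = 1:100, frame_min = 1,
    organs = c("a", "b"))
  d1 <- integrate_organ_dose(series, integration_spec(100, B0 = 1,
                                                      lambda = lam_tc))
  d2 <- integrate_organ_dose(series, integration_spec(100, B0 = 2,
                                                      lambda = lam_tc))
  expect_equal(d2$dose_mgy, 2 * d1$dose_mgy)
  for (Ts in list(c(50, 100), c(99, 100))) {
    lo <- integrate_organ_dose(series, integration_spec(Ts[1],
                                                        lambda = lam_tc))
    hi <- integrate_organ_dose(series, integration_spec(Ts[2],
                                                        lambda = lam_tc))
    expect_true(all(hi$dose_mgy >= lo$dose_mgy))
  }
  for (lams in list(c(0, lam_tc), c(lam_tc, 10 * lam_tc))) {
    hi <- integrate_organ_dose(series, integration_spec(100,
                                                        lambda = lams[1]))
    lo <- integrate_organ_dose(series, integration_spec(100,
                                                        lambda = lams[2]))
    expect_true(all(hi$dose_mgy >= lo$dose_mgy))
  }
})

test_that("integration beyond the series duration is rejected", {
  series <- pedidose:::.dose_rate_series(
    A = matrix(1e-5, 1, 1), rel_err = matrix(0, 1, 1),
    frame_of = rep(1L, 60), frame_min = 1, organs = "a")
  expect_error(integrate_organ_dose(series, integration_spec(100)),
               "shorter than")
})

test_that("frame deduplication changes nothing", {
  ph <- ref_phantom("male")
  scn <- scenario(1, 1, sex = "male")
  r1 <- run_scenario(ph, scn, histories_per_frame = 2e3, seed = 14,
                     dedup = TRUE)
  r2 <- run_scenario(ph, scn, histories_per_frame = 2e3, seed = 14,
                     dedup = FALSE)
  expect_identical(r1$doses, r2$doses)
})

test_that("scenario runs are deterministic, positive, and validated", {
  ph <- ref_phantom("male")
  scn <- scenario(1, 1, sex = "male")
  r1 <- run_scenario(ph, scn, histories_per_frame = 5e3, seed = 15)
  r2 <- run_scenario(ph, scn, histories_per_frame = 5e3, seed = 15)
  expect_identical(r1$doses, r2$doses)
  expect_true(all(r1$doses$dose_mgy_per_mci >= 0))
  expect_true(all(r1$doses$dose_mgy_per_mci[
    r1$doses$organ %in% c("testis_L", "testis_R", "bladder_wall")] > 0))
  # horizon bookkeeping: one row set per requested horizon
  r3 <- run_scenario(ph, scn, histories_per_frame = 5e3, seed = 15,
                     T_eval = c(60, 100))
  expect_setequal(unique(r3$doses$T_min), c(60, 100))
  kl <- r3$doses[r3$doses$organ == "kidney_L", ]
  expect_gte(kl$dose_mgy_per_mci[kl$T_min == 100],
             kl$dose_mgy_per_mci[kl$T_min == 60])
  expect_error(run_scenario(ph, scenario(1, 1, sex = "female"),
                            histories_per_frame = 5e3, seed = 1),
               "does not match")
  expect_error(run_scenario(ph, scn, histories_per_frame = 5e3), "seed")
  # run log records reproducibility metadata
  lg <- attr(r1, "log")
  expect_equal(lg$seed, 15)
  expect_equal(lg$n_unique_frames, 2)
  expect_true(is.finite(lg$phantom_hash))
})
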