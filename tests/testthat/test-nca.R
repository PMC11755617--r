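test_that("terminal slope is exact on log-linear data and accurate on biexponentials", {
  lz <- estimate_lambda_z(mono_profile(100, 0.01))
  expect_equal(lz$lambda_z, 0.01, tolerance = 1e-6)

  biexp <- make_profile(rat_schedule,
                        80 * exp(-0.05 * rat_schedule) + 20 * exp(-0.004 * rat_schedule))
  lz2 <- estimate_lambda_z(biexp)
  expect_lt(abs(lz2$lambda_z - 0.004) / 0.004, 0.02)

  short <- make_profile(c(1, 6), c(100, 90))
  expect_error(estimate_lambda_z(short), "fewer than 3")
  rising <- make_profile(c(1, 6, 12, 24), c(1, 2, 3, 4))
  expect_error(estimate_lambda_z(rising), "negative slope|post-peak")
})

test_that("AUC matches closed forms and extrapolation behaves", {
  tt <- seq(0.5, 2000, by = 0.5)
  dense <- make_profile(tt, 100 * exp(-0.01 * tt))
  auc <- compute_auc(dense, 0.01)
  expect_lt(abs(auc$auc_inf - 10000) / 10000, 0.01)

  # single flat segment: linear rule gives the rectangle
  flat <- make_profile(c(0.5, 10.5), c(5, 5))
  expect_equal(compute_auc(flat, 0.01)$auc_last, 5 * 10)

  # log-down rule is exact for an exponential segment
  seg <- make_profile(c(0, 10), 100 * exp(-0.1 * c(0, 10)))
  expect_equal(compute_auc(seg, 0.1)$auc_last,
               (100 - 100 * exp(-1)) / 0.1)

  # truncated sampling leaves a large extrapolated fraction, failing the gate
  early <- make_profile(c(1, 6, 12, 24, 48), 100 * exp(-0.004 * c(1, 6, 12, 24, 48)))
  lz <- estimate_lambda_z(early)
  auc_e <- compute_auc(early, lz$lambda_z)
  expect_gt(auc_e$pct_extrapolated, 25)
  gated <- quality_gate(dplyr::bind_cols(lz[, "lambda_z"], auc_e))
  expect_false(gated$qc_pass)
})

test_that("excluding trailing points lowers auc_last while the tail compensates", {
  full <- mono_profile(100, 0.01)
  trunc <- full[1:12, ]
  a_full <- compute_auc(full, 0.01)
  a_trunc <- compute_auc(trunc, 0.01)
  expect_lt(a_trunc$auc_last, a_full$auc_last)
  # both extrapolate to the same closed-form total for exact data
  expect_equal(a_trunc$auc_inf, a_full$auc_inf, tolerance = 1e-6)
})

test_that("clearance from dose and AUC is unit-consistent", {
  expect_equal(compute_cl(3, 1.0, conc_unit = "mg/mL"), 3.0)
  expect_error(compute_cl(3, 0), "positive")
  # AUC scales with the concentration unit; CL is invariant when the unit
  # declaration follows
  p_ng <- mono_profile(60000, 0.004)
  p_mg <- p_ng
  p_mg$conc <- p_mg$conc / 1e6
  a_ng <- compute_auc(p_ng, 0.004)
  a_mg <- compute_auc(p_mg, 0.004)
  expect_equal(a_ng$auc_inf, a_mg$auc_inf * 1e6)
  expect_equal(compute_cl(3, a_ng$auc_inf, conc_unit = "ng/mL"),
               compute_cl(3, a_mg$auc_inf, conc_unit = "mg/mL"))
})

test_that("quality gate excludes the 25% boundary and missing slopes", {
  mk <- function(pe, lz = 0.01) tibble::tibble(lambda_z = lz, pct_extrapolated = pe)
  expect_true(quality_gate(mk(10))$qc_pass)
  expect_false(quality_gate(mk(25))$qc_pass)
  r <- quality_gate(mk(10, NA_real_))
  expect_false(r$qc_pass)
  expect_match(r$qc_reasons, "lambda_z")
})

test_that("noise-free simulated studies recover clearance and bioavailability", {
  st <- sim_pk_study(cl = 0.3, f = 0.62, cv_noise = 0, seed = 3)
  res <- run_nca_study(st$profiles)
  iv_cl <- res$nca$cl_or_cl_over_f[res$nca$route == "IV"]
  expect_lt(max(abs(iv_cl - 0.3) / 0.3), 0.05)
  expect_lt(abs(res$bioavailability$f_pct - 62), 2)
  expect_true(all(res$nca$qc_pass))
  expect_true(all(res$nca$pct_extrapolated < 25))
})

test_that("bioavailability of identical arms is exactly 100%", {
  expect_equal(compute_bioavailability(c(1000, 1100), c(1000, 1100))$f_pct, 100)
  expect_equal(compute_bioavailability(1000, 620)$f_pct, 62)
  expect_error(compute_bioavailability(numeric(0), 620), "empty")
  iv <- tibble::tibble(auc_inf = 1000, dose_mg_kg = 3)
  sc <- tibble::tibble(auc_inf = 500, dose_mg_kg = 1.5)
  expect_error(compute_bioavailability(iv, sc), "dose_normalize")
  expect_equal(compute_bioavailability(iv, sc, dose_normalize = TRUE)$f_pct, 100)
})

test_that("immunogenicity screen flags the collapsed tail and spares clean profiles", {
  clean <- make_profile(rat_schedule,
                        80 * exp(-0.05 * rat_schedule) + 20 * exp(-0.004 * rat_schedule))
  expect_equal(sum(flag_ada_points(clean)$excluded), 0)

  st <- sim_pk_study(cl = 0.3, cv_noise = 0,
                     ada = list(enabled = TRUE, onset_h = 336, fold = 10,
                                incidence = 1),
                     seed = 4)
  for (id in c("IV1", "SC1")) {
    pr <- st$profiles[st$profiles$animal_id == id, ]
    fl <- flag_ada_points(pr)
    usable_late <- !pr$bql & pr$conc > 0 & pr$time_h > 336
    expect_equal(fl$excluded, usable_late)
  }
  short <- make_profile(c(1, 6, 12), c(100, 90, 80))
  expect_error(flag_ada_points(short), "at least 4")
})
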