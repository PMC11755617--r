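test_that("noiseless power-law data reduces to log-log least squares", {
  sim <- sim_allometric_dataset(n_antibodies = 12, alpha = 0.007, beta = 0.9,
                                omega = 0, sigma = 0, seed = 2)
  # exact collinearity on the log scale
  ols <- lm(log(to_absolute_cl(cl_ml_h_kg, species_body_weights()[as.character(species)])) ~
              log(species_body_weights()[as.character(species)]), data = sim)
  expect_equal(unname(coef(ols)[2]), 0.9, tolerance = 1e-10)
  # degenerate limit (no random effect, vanishing residual variance): the
  # likelihood optimum in (alpha, beta) is the exact power law; the
  # variance is held at the limit because the noiseless likelihood is
  # unbounded in sigma itself
  obj <- function(p) {
    allometry_ofv(sim, exp(p[1]), p[2], omega2_alpha = 0, sigma2 = 1e-6,
                  species = c("rat", "monkey", "human"))
  }
  opt <- optim(c(log(0.005), 1.05), obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  opt <- optim(opt$par, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-15))
  expect_lt(abs(opt$par[2] - 0.9), 1e-6)
  expect_lt(abs(exp(opt$par[1]) - 0.007) / 0.007, 1e-6)
})

test_that("objective function collapses exactly when the random effect vanishes", {
  sim <- sim_allometric_dataset(n_antibodies = 8, seed = 9)
  alpha <- 0.007; beta <- 0.9; s2 <- 0.08
  ofv <- allometry_ofv(sim, alpha, beta, omega2_alpha = 0, sigma2 = s2,
                       species = c("rat", "monkey", "human"))
  # independent closed form: plain product of proportional-error normals
  bw <- species_body_weights()[as.character(sim$species)]
  y <- to_absolute_cl(sim$cl_ml_h_kg, bw)
  m <- alpha * bw^beta
  ofv_direct <- -2 * sum(dnorm(y, m, sqrt(s2) * m, log = TRUE))
  expect_equal(ofv, ofv_direct, tolerance = 1e-10)
})

test_that("the fitted optimum is a local minimum of the objective", {
  pk <- mab_pk()
  fit <- fit_allometry(pk, c("monkey", "human"), se = FALSE)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  at <- function(beta) {
    allometry_ofv(pk, est[["alpha_tv"]], beta, est[["omega2_alpha"]],
                  sigma2 = est[["sigma2"]], species = c("monkey", "human"))
  }
  expect_lt(at(est[["beta_tv"]]), at(est[["beta_tv"]] + 0.05))
  expect_lt(at(est[["beta_tv"]]), at(est[["beta_tv"]] - 0.05))
  expect_error(
    allometry_ofv(pk, 0.007, 0.9, 0.2, sigma2 = -1, species = c("monkey", "human")),
    "positive")
})

test_that("fixing the exponent at its estimate cannot beat the joint fit", {
  pk <- mab_pk()
  fit <- fit_allometry(pk, c("rat", "human"), se = FALSE)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  prof <- optim(
    log(c(est[["alpha_tv"]], est[["omega2_alpha"]], est[["sigma2"]])),
    function(p) allometry_ofv(pk, exp(p[1]), est[["beta_tv"]], exp(p[2]),
                              sigma2 = exp(p[3]), species = c("rat", "human")),
    method = "Nelder-Mead", control = list(maxit = 500)
  )
  expect_lt(prof$value - fit$ofv, 3.841)
  expect_gte(prof$value - fit$ofv, -0.01)
})

test_that("Laplace agrees with adaptive quadrature on a synthetic suite", {
  sim <- sim_allometric_dataset(n_antibodies = 20, seed = 11)
  fit <- fit_allometry(sim, c("rat", "monkey", "human"), se = FALSE)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  ofv_agq <- allometry_ofv(sim, est[["alpha_tv"]], est[["beta_tv"]],
                           est[["omega2_alpha"]], sigma2 = est[["sigma2"]],
                           species = c("rat", "monkey", "human"),
                           method = "agq", agq_nodes = 63)
  expect_lt(abs(fit$ofv - ofv_agq), 0.5)
})

test_that("simulated parameters are recovered at realistic dimensions", {
  sim <- sim_allometric_dataset(n_antibodies = 200, seed = 5)
  fit <- fit_allometry(sim, c("rat", "monkey", "human"), se = FALSE)
  est <- setNames(tidy(fit)$estimate, tidy(fit)$term)
  expect_lt(abs(est[["beta_tv"]] - 0.90), 0.02)
  truth_om2 <- 0.45^2
  expect_lt(abs(est[["omega2_alpha"]] - truth_om2) / truth_om2, 0.25)
})

test_that("empirical-Bayes effects center near zero and standard errors are sane", {
  pk <- mab_pk()
  fit <- fit_allometry(pk, c("monkey", "human"))
  expect_true(fit$converged)
  expect_true(all(is.finite(fit$coefficients$std_error)))
  # exp(eta) averages near 1 across antibodies
  expect_lt(abs(mean(exp(fit$eta$eta_alpha)) - 1), 0.15)
  # Wald interval on beta covers the estimate and is ordered
  b <- fit$coefficients[fit$coefficients$term == "beta_tv", ]
  expect_true(b$conf_low < b$estimate && b$estimate < b$conf_high)
})

test_that("single-species scaling follows the per-kg power law", {
  expect_equal(scale_human_cl(0.5, beta = 1, source_species = "rat"), 0.5)
  expect_equal(scale_human_cl(0.488, beta = 0.92, source_species = "rat"),
               0.488 * (70 / 0.3)^(-0.08))
  expect_equal(round(scale_human_cl(0.488, beta = 0.92, source_species = "rat"), 4),
               0.3155)
  expect_equal(round(scale_human_cl(1.85, beta = 0.84, source_species = "monkey"), 3),
               1.118)
  expect_error(scale_human_cl(-1, 0.9, "rat"), "positive")
  # per-kg form is the absolute power law divided by target body weight
  cl <- 0.35; beta <- 0.88
  expect_equal(to_absolute_cl(scale_human_cl(cl, beta, "monkey"), 70),
               to_absolute_cl(cl, 3) * (70 / 3)^beta)
})

test_that("fold-error summaries count inclusively and rescale-invariantly", {
  fe <- fold_error_summary(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(fe$pct_within, fe$mean_ratio), c(100, 1))
  fe2 <- fold_error_summary(c(1, 4), c(2, 2))
  expect_equal(fe2$n_within, 2) # ratios 0.5 and 2 are both within
  obs <- c(0.1, 0.4, 0.9); scl <- c(0.3, 0.2, 0.5)
  expect_equal(fold_error_summary(obs * 7, scl * 7),
               fold_error_summary(obs, scl))
  expect_error(fold_error_summary(numeric(0), numeric(0)), "empty")
})

test_that("model comparison applies the OFV drop threshold and admissibility", {
  mk_fit <- function(ofv, re, sigma2 = 0.08, converged = TRUE) {
    structure(list(
      ofv = ofv, species = c("rat", "human"), random_effect = re,
      converged = converged,
      coefficients = tibble::tibble(term = c("beta_tv", "sigma2"),
                                    estimate = c(0.9, sigma2))
    ), class = "allo_fit")
  }
  red <- mk_fit(100, "alpha")
  expect_true(compare_fits(red, mk_fit(95, c("alpha", "beta")))$select_full)
  expect_false(compare_fits(red, mk_fit(96.2, c("alpha", "beta")))$select_full)
  degen <- compare_fits(red, mk_fit(80, c("alpha", "beta"), sigma2 = 1e-5))
  expect_false(degen$select_full)
  expect_match(degen$note, "degenerate")
  expect_error(compare_fits(red, mk_fit(95, "alpha")), "nested")
})

test_that("cluster bootstrap is reproducible and conserves study size", {
  pk <- mab_pk()
  b1 <- bootstrap_allometry(pk, c("rat", "human"), n_replicates = 5, seed = 7)
  b2 <- bootstrap_allometry(pk, c("rat", "human"), n_replicates = 5, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$replicates$n_antibodies == b1$fit$n_antibodies))
  expect_equal(b1$n_failed + nrow(b1$replicates), 5)
  expect_error(bootstrap_allometry(pk, c("rat", "human"), n_replicates = 5),
               "seed")
})
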