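#' Simulate a single-dose IV/SC antibody PK study
#'
#' Generates per-animal concentration-time profiles from a two-compartment
#' disposition model with known ground truth, emulating a typical rat mAb
#' PK design: 3 mg/kg by IV bolus and by first-order subcutaneous
#' absorption with incomplete bioavailability, N = 3 animals per route,
#' sampling 1 h to 6 weeks. Observations carry multiplicative log-normal
#' assay noise and are flagged below the quantification limit; optionally a
#' random subset of animals develops late anti-drug antibodies, modeled as
#' a step increase in the elimination rate from the onset time.
#'
#' Kinetic parameters are per kg: clearance `cl` (mL/h/kg), central and
#' peripheral volumes `vc`, `vp` (mL/kg), inter-compartmental clearance `q`
#' (mL/h/kg), absorption rate `ka` (1/h). The defaults give a terminal
#' half-life of about two weeks, so the default 1008 h schedule leaves well
#' under 25% of the AUC extrapolated.
#'
#' @param cl True clearance, mL/h/kg.
#' @param vc,vp,q Two-compartment disposition parameters (see above).
#' @param ka First-order SC absorption rate, 1/h.
#' @param f True absolute bioavailability of the SC route, in (0, 1.1].
#' @param dose Dose in mg/kg for both routes.
#' @param schedule Sampling times in hours, strictly increasing.
#' @param n_per_route Animals per route.
#' @param cv_noise Proportional assay coefficient of variation (0 = noise
#'   free).
#' @param lloq Lower limit of quantification, ng/mL.
#' @param ada List: `enabled`, `onset_h`, `fold` (multiplier on the
#'   elimination rate from onset), `incidence` (per-animal probability).
#' @param seed Integer seed (required); identical seeds give identical
#'   studies.
#' @return List: `profiles` (long tibble as in [read_profiles()]) and
#'   `truth` (`cl`, `f`, `auc_iv` = dose/CL, `auc_sc` = f x dose/CL in
#'   ng.h/mL, `lambda_z` the true terminal rate, `ada_animals`).
#' @export
#' @examples
#' study <- sim_pk_study(cl = 0.3, cv_noise = 0, seed = 1)
#' head(study$profiles)
sim_pk_study <- function(cl = 0.3, vc = 50, vp = 30, q = 1.5, ka = 0.02,
                         f = 0.62, dose = 3,
                         schedule = c(1, 6, 12, 24, 48, 72, 96, 120, 144,
                                      168, 240, 336, 504, 672, 840, 1008),
                         n_per_route = 3, cv_noise = 0.15, lloq = 10,
                         ada = list(enabled = FALSE, onset_h = 336,
                                    fold = 10, incidence = 0.3),
                         seed) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot(cl > 0, vc > 0, vp > 0, q > 0, ka > 0, f > 0, f <= 1.1, dose > 0)
  if (length(schedule) < 4) abort("schedule too sparse (< 4 points)")
  if (is.unsorted(schedule, strictly = TRUE)) abort("schedule must be strictly increasing")
  ada <- modify_defaults(list(enabled = FALSE, onset_h = 336, fold = 10,
                              incidence = 0.3), ada)
  if (ada$enabled && (ada$incidence <= 0 || ada$incidence > 1)) {
    abort("ada incidence must be in (0, 1]")
  }
  set.seed(seed)
  sdlog <- if (cv_noise > 0) sqrt(log(1 + cv_noise^2)) else 0
  lambda_true <- disposition_rates(cl, vc, vp, q)$lambda_z

  one_animal <- function(route, idx) {
    has_ada <- ada$enabled && rbinom(1, 1, ada$incidence) == 1
    conc <- conc_profile(schedule, route, cl, vc, vp, q, ka, f, dose,
                         ada_onset = if (has_ada) ada$onset_h else Inf,
                         ada_fold = ada$fold)
    obs <- if (sdlog > 0) conc * exp(rnorm(length(conc), 0, sdlog)) else conc
    tibble::tibble(
      animal_id = paste0(route, idx),
      route = route,
      dose_mg_kg = dose,
      time_h = schedule,
      conc = obs,
      bql = obs < lloq,
      excluded = FALSE,
      ada_true = has_ada
    )
  }
  profiles <- purrr::map(c("IV", "SC"), function(rt) {
    purrr::map(seq_len(n_per_route), function(i) one_animal(rt, i)) |>
      purrr::list_rbind()
  }) |> purrr::list_rbind()

  auc_iv <- dose * 1e6 / cl
  list(
    profiles = profiles,
    truth = list(
      cl = cl, f = f, auc_iv = auc_iv, auc_sc = f * auc_iv,
      lambda_z = lambda_true,
      ada_animals = unique(profiles$animal_id[profiles$ada_true]),
      noise = list(type = "multiplicative log-normal", cv = cv_noise,
                   sdlog = sdlog),
      seed = seed
    )
  )
}

modify_defaults <- function(defaults, x) {
  defaults[names(x)] <- x
  defaults
}

# Macro rate constants of the two-compartment disposition.
disposition_rates <- function(cl, vc, vp, q) {
  k10 <- cl / vc
  k12 <- q / vc
  k21 <- q / vp
  s <- k10 + k12 + k21
  disc <- sqrt(s^2 - 4 * k10 * k21)
  list(k10 = k10, k12 = k12, k21 = k21,
       lambda_z = (s - disc) / 2, lambda_1 = (s + disc) / 2)
}

# Closed-form concentrations (ng/mL) via eigen-decomposition of the linear
# system; states are amounts per kg with an optional SC depot. Anti-drug
# antibodies switch the elimination rate to `ada_fold * k10` at
# `ada_onset`, propagating the compartment state across the breakpoint.
conc_profile <- function(times, route, cl, vc, vp, q, ka, f, dose,
                         ada_onset = Inf, ada_fold = 1) {
  amt <- dose * 1e6  # mg/kg -> ng/kg
  if (route == "IV") {
    x0 <- c(amt, 0)
    build <- function(k10) {
      k <- disposition_rates(k10 * vc, vc, vp, q)
      matrix(c(-(k$k10 + k$k12), k$k21, k$k12, -k$k21), 2, 2, byrow = TRUE)
    }
    central <- 1
  } else {
    x0 <- c(f * amt, 0, 0)
    build <- function(k10) {
      k <- disposition_rates(k10 * vc, vc, vp, q)
      matrix(c(-ka, 0, 0,
               ka, -(k$k10 + k$k12), k$k21,
               0, k$k12, -k$k21), 3, 3, byrow = TRUE)
    }
    central <- 2
  }
  k10 <- cl / vc
  states_at <- function(M, x0, t_vec) {
    e <- eigen(M)
    cvec <- solve(e$vectors, x0)
    # states x times
    Re(e$vectors %*% (cvec * exp(outer(e$values, t_vec))))
  }
  M1 <- build(k10)
  if (!is.finite(ada_onset) || ada_onset >= max(times)) {
    x <- states_at(M1, x0, times)
    return(x[central, ] / vc)
  }
  pre <- times < ada_onset
  out <- numeric(length(times))
  if (any(pre)) out[pre] <- states_at(M1, x0, times[pre])[central, ] / vc
  x_on <- states_at(M1, x0, ada_onset)[, 1]
  M2 <- build(ada_fold * k10)
  out[!pre] <- states_at(M2, x_on, times[!pre] - ada_onset)[central, ] / vc
  out
}

#' Simulate a cross-species clearance dataset from the allometric model
#'
#' Draws antibodies from the generative power law
#' `CL_ij = alpha * exp(eta_i) * BW_j^beta * (1 + eps_ij)` with
#' `eta_i ~ N(0, omega^2)` shared across an antibody's species and
#' `eps_ij ~ N(0, sigma^2)` truncated to keep clearance positive, then
#' stores the values in weight-normalized units in the same long dialect as
#' [mab_pk()].
#'
#' @param n_antibodies Number of antibodies (clusters).
#' @param alpha Allometric coefficient, L/day at 1 kg.
#' @param beta Allometric exponent.
#' @param omega Inter-antibody SD on the log scale.
#' @param sigma Proportional residual SD.
#' @param species_bw Named body weights (kg) of the simulated species.
#' @param missingness Named per-species probability that the clearance
#'   value is missing.
#' @param seed Integer seed (required).
#' @return Long tibble (`antibody`, `species`, `cl_ml_h_kg`,
#'   `scf_pct = NA`, `provenance = "simulated"`) with a `truth` attribute
#'   recording the generating parameters and per-antibody `eta`.
#' @export
#' @examples
#' sim <- sim_allometric_dataset(n_antibodies = 10, seed = 7)
#' attr(sim, "truth")$beta
sim_allometric_dataset <- function(n_antibodies = 23, alpha = 0.007,
                                   beta = 0.90, omega = 0.45, sigma = 0.28,
                                   species_bw = species_body_weights(),
                                   missingness = NULL, seed) {
  if (missing(seed)) abort("`seed` is required")
  stopifnot(n_antibodies >= 2, alpha > 0, omega >= 0, sigma >= 0)
  if (sigma > 0 && pnorm(-1 / sigma) > 0.01) {
    abort("sigma implies non-positive clearance in > 1% of draws")
  }
  miss <- setNames(rep(0, length(species_bw)), names(species_bw))
  if (!is.null(missingness)) miss[names(missingness)] <- missingness
  set.seed(seed)
  eta <- rnorm(n_antibodies, 0, omega)
  rows <- purrr::map(seq_len(n_antibodies), function(i) {
    purrr::map(names(species_bw), function(sp) {
      if (rbinom(1, 1, miss[[sp]]) == 1) return(NULL)
      repeat {
        eps <- rnorm(1, 0, sigma)
        if (1 + eps > 0) break
      }
      cl_abs <- alpha * exp(eta[i]) * species_bw[[sp]]^beta * (1 + eps)
      tibble::tibble(
        antibody = sprintf("sim-%03d", i),
        species = factor(sp, levels = names(species_bw)),
        cl_ml_h_kg = from_absolute_cl(cl_abs, species_bw[[sp]]),
        scf_pct = NA_real_,
        provenance = "simulated"
      )
    }) |> purrr::compact() |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  attr(rows, "truth") <- list(
    alpha = alpha, beta = beta, omega = omega, sigma = sigma,
    species_bw = species_bw,
    eta = tibble::tibble(antibody = sprintf("sim-%03d", seq_len(n_antibodies)),
                         eta = eta),
    seed = seed
  )
  rows
}

#' Write a simulated PK study to disk
#'
#' Emits the profile CSV dialect read by [read_profiles()] plus a JSON
#' sidecar with the simulation ground truth.
#'
#' @param study Result of [sim_pk_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pk_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  prof_path <- file.path(dir, "profiles.csv")
  truth_path <- file.path(dir, "truth.json")
  out <- study$profiles |>
    dplyr::transmute(
      .data$animal_id, .data$route, .data$dose_mg_kg, .data$time_h,
      conc_ng_ml = .data$conc, bql = as.integer(.data$bql)
    )
  readr::write_csv(out, prof_path)
  jsonlite::write_json(study$truth, truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(profiles = prof_path, truth = truth_path))
}
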