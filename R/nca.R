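#' Read single-dose concentration-time profiles
#'
#' Reads the long profile dialect
#' `animal_id,route,dose_mg_kg,time_h,conc_ng_ml,bql` (one row per sample;
#' `bql` 0/1 marks observations below the assay's lower limit of
#' quantification).
#'
#' @param path CSV file path.
#' @param lloq Lower limit of quantification in ng/mL; used to set `bql`
#'   when the column is absent. Default 10 ng/mL.
#' @return Tibble with columns `animal_id`, `route` ("IV"/"SC"),
#'   `dose_mg_kg`, `time_h`, `conc` (ng/mL), `bql`, `excluded` (logical).
#' @export
read_profiles <- function(path, lloq = 10) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      animal_id = readr::col_character(),
      route = readr::col_character(),
      dose_mg_kg = readr::col_double(),
      time_h = readr::col_double(),
      conc_ng_ml = readr::col_double(),
      bql = readr::col_double()
    )
  )
  needed <- c("animal_id", "route", "dose_mg_kg", "time_h", "conc_ng_ml")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("profile CSV is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- !raw$route %in% c("IV", "SC")
  if (any(bad)) {
    abort(paste0("unknown route in row(s) ", paste(which(bad), collapse = ", ")))
  }
  out <- tibble::tibble(
    animal_id = raw$animal_id,
    route = raw$route,
    dose_mg_kg = raw$dose_mg_kg,
    time_h = raw$time_h,
    conc = raw$conc_ng_ml,
    bql = if ("bql" %in% names(raw)) raw$bql > 0 else raw$conc_ng_ml < lloq,
    excluded = FALSE
  )
  out$bql[is.na(out$bql)] <- out$conc[is.na(out$bql)] < lloq
  out
}

# Points eligible for regression/AUC work: quantifiable, positive, not
# flagged out (anti-drug-antibody or manual exclusion).
usable_points <- function(profile) {
  bql <- if ("bql" %in% names(profile)) profile$bql else rep(FALSE, nrow(profile))
  exc <- if ("excluded" %in% names(profile)) profile$excluded else rep(FALSE, nrow(profile))
  ok <- !bql & !exc & !is.na(profile$conc) & profile$conc > 0
  p <- profile[ok, , drop = FALSE]
  if (is.unsorted(p$time_h, strictly = TRUE)) {
    abort("profile times must be strictly increasing")
  }
  p
}

#' Estimate the terminal elimination rate constant
#'
#' Log-linear regression on terminal points. Every candidate subset of the
#' last k points (k from 3 up to all post-peak points) is fit; the subset
#' with the highest adjusted R-squared wins, with ties (within 1e-4) broken
#' toward more points. Subsets with non-negative slope are rejected. For
#' extravascular (SC) profiles the peak itself is excluded.
#'
#' @param profile Profile tibble (see [read_profiles()]); below-limit and
#'   excluded points never enter the regression.
#' @param route `"IV"` or `"SC"`; governs whether the peak sample is
#'   eligible.
#' @return One-row tibble: `lambda_z` (1/h), `lambda_z_n_points`,
#'   `lambda_z_adj_r2`, `log_c0` (regression intercept).
#' @export
estimate_lambda_z <- function(profile, route = profile$route[1]) {
  p <- usable_points(profile)
  if (nrow(p) < 3) abort("fewer than 3 usable points for terminal slope")
  i_max <- which.max(p$conc)
  cand <- if (identical(route, "SC")) {
    p[seq_len(nrow(p)) > i_max, , drop = FALSE]
  } else {
    p[seq_len(nrow(p)) >= i_max, , drop = FALSE]
  }
  m <- nrow(cand)
  if (m < 3) abort("fewer than 3 usable post-peak points for terminal slope")
  best <- NULL
  for (k in 3:m) {
    sub <- tail(cand, k)
    fit <- lm(log(sub$conc) ~ sub$time_h)
    slope <- coef(fit)[[2]]
    if (!is.finite(slope) || slope >= 0) next
    lc <- log(sub$conc)
    r2 <- 1 - sum(fit$residuals^2) / sum((lc - mean(lc))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj + 1e-4 ||
        (adj > best$adj - 1e-4 && k > best$k)) {
      best <- list(adj = adj, k = k, slope = slope, icpt = coef(fit)[[1]])
    }
  }
  if (is.null(best)) abort("no terminal subset with a negative slope")
  tibble::tibble(
    lambda_z = -best$slope,
    lambda_z_n_points = best$k,
    lambda_z_adj_r2 = best$adj,
    log_c0 = best$icpt
  )
}

#' Area under the concentration-time curve
#'
#' Trapezoidal AUC to the last quantifiable point with the
#' linear-up/log-down rule (linear trapezoid on rising or flat segments,
#' log trapezoid on falling segments, which is exact for exponential
#' decline), extrapolated to infinity with `C_last / lambda_z`.
#'
#' @inheritParams estimate_lambda_z
#' @param lambda_z Terminal elimination rate constant (1/h).
#' @return One-row tibble: `auc_last`, `auc_inf` (conc x h),
#'   `pct_extrapolated` (percent of `auc_inf` beyond the last sample).
#' @export
compute_auc <- function(profile, lambda_z) {
  p <- usable_points(profile)
  if (nrow(p) < 2) abort("fewer than 2 usable points for AUC")
  if (!is.finite(lambda_z) || lambda_z <= 0) abort("invalid lambda_z")
  t <- p$time_h
  c1 <- head(p$conc, -1)
  c2 <- tail(p$conc, -1)
  dt <- diff(t)
  seg <- ifelse(
    c2 < c1 & c2 > 0,
    (c1 - c2) * dt / log(c1 / c2),
    (c1 + c2) / 2 * dt
  )
  auc_last <- sum(seg)
  auc_inf <- auc_last + tail(p$conc, 1) / lambda_z
  tibble::tibble(
    auc_last = auc_last,
    auc_inf = auc_inf,
    pct_extrapolated = 100 * (auc_inf - auc_last) / auc_inf
  )
}

#' Extrapolation quality gate for NCA results
#'
#' An individual-animal result is acceptable only when the terminal slope
#' was estimable and less than 25% of AUC to infinity is extrapolated
#' beyond the last quantifiable sample (the 25% boundary itself fails).
#'
#' @param result One-row (or multi-row) NCA result tibble containing
#'   `lambda_z` and `pct_extrapolated`.
#' @param max_pct_extrapolated Gate threshold, default 25.
#' @return `result` with logical `qc_pass` and character `qc_reasons`
#'   columns appended.
#' @export
quality_gate <- function(result, max_pct_extrapolated = 25) {
  reasons <- purrr::map2_chr(
    result$lambda_z, result$pct_extrapolated,
    function(lz, pe) {
      r <- character()
      if (is.na(lz)) r <- c(r, "lambda_z not estimable")
      if (!is.na(pe) && pe >= max_pct_extrapolated) {
        r <- c(r, sprintf("AUC extrapolation %.1f%% >= %g%%", pe, max_pct_extrapolated))
      }
      paste(r, collapse = "; ")
    }
  )
  result$qc_pass <- reasons == ""
  result$qc_reasons <- reasons
  result
}

#' Clearance from dose and AUC
#'
#' `CL = dose / AUC_inf`, returned in mL/h/kg for a dose in mg/kg. For the
#' SC route the value is apparent clearance, CL/F.
#'
#' @param dose_mg_kg Dose in mg/kg.
#' @param auc_inf AUC to infinity in `conc_unit` x h.
#' @param route `"IV"` or `"SC"` (informational; SC yields CL/F).
#' @param conc_unit Concentration unit of the AUC, `"ng/mL"` (default) or
#'   `"mg/mL"`.
#' @return Clearance (or CL/F) in mL/h/kg.
#' @export
compute_cl <- function(dose_mg_kg, auc_inf, route = "IV", conc_unit = "ng/mL") {
  if (any(!is.finite(auc_inf)) || any(auc_inf <= 0)) {
    abort("`auc_inf` must be positive")
  }
  scale <- switch(conc_unit, "ng/mL" = 1e6, "mg/mL" = 1,
                  abort("unsupported `conc_unit`"))
  dose_mg_kg * scale / auc_inf
}

#' Screen a profile for late anti-drug-antibody-mediated exposure loss
#'
#' Algorithmic surrogate for visual inspection of immunogenicity-affected
#' profiles. Candidate terminal runs (contiguous trailing points no
#' earlier than `onset_floor_h`) are tested largest-first against a
#' mono-exponential reference fit on the remaining post-peak points
#' (preferring points up to `anchor_h`, before anti-drug antibodies
#' plausibly act); a run is flagged when every run point falls below
#' `drop_threshold` x the reference prediction. Leaving the candidate run
#' out of the reference fit keeps the screen sensitive to a genuine late
#' exposure collapse while a clean noisy profile, whose trailing points
#' sit near the reference line, is left alone. Points before
#' `onset_floor_h` are never flagged (rodent anti-drug antibodies arise
#' late).
#'
#' @inheritParams estimate_lambda_z
#' @param anchor_h Preferred upper bound of the reference-fit window in
#'   hours (default 336).
#' @param onset_floor_h Earliest time a point may be flagged (default 168).
#' @param drop_threshold Fraction of the predicted concentration below
#'   which a point is considered consistent with accelerated elimination
#'   (default 0.5).
#' @return `profile` with its `excluded` column updated.
#' @export
flag_ada_points <- function(profile, anchor_h = 336, onset_floor_h = 168,
                            drop_threshold = 0.5) {
  if (!"excluded" %in% names(profile)) profile$excluded <- FALSE
  p <- usable_points(profile)
  i_max <- which.max(p$conc)
  from <- if (identical(profile$route[1], "SC")) i_max + 1 else i_max
  post <- p[seq_len(nrow(p)) >= from, , drop = FALSE]
  if (nrow(post) < 4) abort("need at least 4 usable post-peak points")
  n <- nrow(post)
  # largest candidate run leaving >= 3 reference points
  k_max <- min(sum(post$time_h >= onset_floor_h), n - 3)
  flagged_times <- numeric(0)
  for (k in seq(k_max, 1)) {
    run <- seq(n - k + 1, n)
    if (any(post$time_h[run] < onset_floor_h)) next
    ref <- setdiff(seq_len(n), run)
    # prefer pre-anchor points, but a thin window (sparse SC profiles)
    # extrapolates too noisily; runs are tested largest-first, so any
    # later non-run point has already been vetted and can serve as
    # reference
    ref_w <- ref[post$time_h[ref] <= anchor_h]
    if (length(ref_w) < 5) ref_w <- ref
    tr <- post$time_h[ref_w]
    fit <- lm(log(post$conc[ref_w]) ~ tr)
    if (coef(fit)[[2]] >= 0) next
    lpred <- coef(fit)[[1]] + coef(fit)[[2]] * post$time_h[run]
    # flag only drops that also clear the prediction-uncertainty band:
    # the reference slope is extrapolated, and on sparse SC profiles the
    # residual-absorption bias plus assay noise can shave a factor ~2 off
    # late predictions without any immunogenicity
    X <- cbind(1, post$time_h[run])
    se_fit <- sqrt(rowSums((X %*% vcov(fit)) * X))
    sig <- summary(fit)$sigma
    lower <- lpred - qnorm(0.995) * sqrt(se_fit^2 + sig^2)
    obs_log <- log(post$conc[run])
    if (all(obs_log < log(drop_threshold) + lpred & obs_log < lower)) {
      flagged_times <- post$time_h[run]
      break
    }
  }
  if (length(flagged_times) >= n) {
    abort("all post-peak points consistent with anti-drug antibodies; profile unusable")
  }
  profile$excluded <- profile$excluded | profile$time_h %in% flagged_times
  profile
}

#' Non-compartmental analysis of one profile
#'
#' Runs terminal-slope selection, linear-up/log-down AUC, extrapolation
#' gating and clearance for a single animal and route.
#'
#' @inheritParams estimate_lambda_z
#' @param dose_mg_kg Dose in mg/kg; defaults to the profile's `dose_mg_kg`
#'   column.
#' @return One-row tibble: identifiers, `lambda_z`, `lambda_z_n_points`,
#'   `lambda_z_adj_r2`, `half_life_h`, `auc_last`, `auc_inf`,
#'   `pct_extrapolated`, `cl_or_cl_over_f` (mL/h/kg), `qc_pass`,
#'   `qc_reasons`.
#' @export
#' @examples
#' prof <- tibble::tibble(
#'   animal_id = "r1", route = "IV", dose_mg_kg = 3,
#'   time_h = c(1, 6, 12, 24, 48, 96, 168, 336, 672, 1008),
#'   conc = 60000 * exp(-0.004 * c(1, 6, 12, 24, 48, 96, 168, 336, 672, 1008))
#' )
#' run_nca(prof)
run_nca <- function(profile, route = profile$route[1],
                    dose_mg_kg = profile$dose_mg_kg[1]) {
  lz <- estimate_lambda_z(profile, route = route)
  auc <- compute_auc(profile, lz$lambda_z)
  out <- dplyr::bind_cols(
    tibble::tibble(
      animal_id = as.character(profile$animal_id[1]),
      route = route,
      dose_mg_kg = dose_mg_kg
    ),
    lz[, c("lambda_z", "lambda_z_n_points", "lambda_z_adj_r2")],
    auc
  )
  out$half_life_h <- log(2) / out$lambda_z
  out$cl_or_cl_over_f <- compute_cl(dose_mg_kg, out$auc_inf, route = route)
  quality_gate(out)
}

#' Subcutaneous bioavailability from IV and SC study arms
#'
#' `F%% = 100 x mean(SC AUC_inf) / mean(IV AUC_inf)` with arithmetic means
#' across animals, the standard estimate for equal-dose parallel-arm
#' designs.
#'
#' @param iv_results,sc_results NCA result tibbles (from [run_nca()]) or
#'   bare numeric vectors of AUC-to-infinity values.
#' @param dose_normalize Divide each AUC by its dose before averaging
#'   (needed only when arm doses differ). Default `FALSE`; unequal doses
#'   without normalization is an error.
#' @return One-row tibble: `mean_auc_iv`, `mean_auc_sc`, `n_iv`, `n_sc`,
#'   `f_pct`.
#' @export
compute_bioavailability <- function(iv_results, sc_results, dose_normalize = FALSE) {
  pull_auc <- function(x, arm) {
    if (is.numeric(x)) return(list(auc = x, dose = NULL))
    if (!nrow(x)) abort(paste0("empty ", arm, " arm"))
    list(auc = x$auc_inf, dose = x$dose_mg_kg)
  }
  iv <- pull_auc(iv_results, "IV")
  sc <- pull_auc(sc_results, "SC")
  if (!length(iv$auc) || !length(sc$auc)) abort("empty study arm")
  if (!is.null(iv$dose) && !is.null(sc$dose)) {
    doses <- unique(c(iv$dose, sc$dose))
    if (length(doses) > 1 && !dose_normalize) {
      abort("arm doses differ; set `dose_normalize = TRUE`")
    }
    if (dose_normalize) {
      iv$auc <- iv$auc / iv$dose
      sc$auc <- sc$auc / sc$dose
    }
  }
  tibble::tibble(
    mean_auc_iv = mean(iv$auc),
    mean_auc_sc = mean(sc$auc),
    n_iv = length(iv$auc),
    n_sc = length(sc$auc),
    f_pct = 100 * mean(sc$auc) / mean(iv$auc)
  )
}

#' Run NCA over a whole IV/SC study
#'
#' Per-animal anti-drug-antibody screening, NCA, extrapolation gating,
#' route-level summary statistics and study bioavailability.
#'
#' @param profiles Long profile tibble covering one or more animals (see
#'   [read_profiles()]).
#' @param ada_screen Apply [flag_ada_points()] per profile before NCA
#'   (default `TRUE`).
#' @param ... Passed to [flag_ada_points()].
#' @return List of class `"nca_study"`: `nca` (one row per animal),
#'   `by_route` (mean/CV%% per route), `bioavailability` (one row, only when
#'   both routes have a gate-passing animal).
#' @export
run_nca_study <- function(profiles, ada_screen = TRUE, ...) {
  split_p <- split(profiles, profiles$animal_id)
  rows <- purrr::map(split_p, function(p) {
    p <- p[order(p$time_h), , drop = FALSE]
    if (ada_screen) p <- flag_ada_points(p, ...)
    res <- run_nca(p)
    res$n_ada_flagged <- sum(p$excluded)
    res
  })
  nca <- purrr::list_rbind(rows)
  nca <- nca[order(nca$route, nca$animal_id), , drop = FALSE]
  ok <- nca[nca$qc_pass, , drop = FALSE]
  by_route <- ok |>
    dplyr::group_by(.data$route) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_auc_inf = mean(.data$auc_inf),
      cv_pct_auc_inf = 100 * sd(.data$auc_inf) / mean(.data$auc_inf),
      mean_cl = mean(.data$cl_or_cl_over_f),
      .groups = "drop"
    )
  bio <- NULL
  if (all(c("IV", "SC") %in% ok$route)) {
    bio <- compute_bioavailability(
      ok[ok$route == "IV", , drop = FALSE],
      ok[ok$route == "SC", , drop = FALSE]
    )
  }
  structure(list(nca = nca, by_route = by_route, bioavailability = bio),
            class = "nca_study")
}

#' @export
print.nca_study <- function(x, ...) {
  cat("Non-compartmental analysis:", nrow(x$nca), "animal(s),",
      sum(x$nca$qc_pass), "passing the extrapolation gate\n")
  print(x$nca, ...)
  if (!is.null(x$bioavailability)) {
    cat(sprintf("Subcutaneous bioavailability: %.1f%%\n",
                x$bioavailability$f_pct))
  }
  invisible(x)
}
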