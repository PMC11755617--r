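#' Nonlinear mixed-effects allometric clearance model
#'
#' Fits the power-law relation between absolute clearance and body weight,
#' `CL_ij = alpha_TV * exp(eta_i) * BW_j^beta_TV * (1 + eps_ij)`, across
#' antibodies `i` and species `j`, by maximizing the marginal likelihood.
#' The inter-antibody random effect is log-normal on the allometric
#' coefficient (optionally on the exponent), residual error is proportional
#' on the untransformed clearance scale, and the random effect is
#' integrated out with a Laplace approximation (per-antibody Newton inner
#' optimization with interaction, i.e. the residual variance follows the
#' conditional prediction) or, for validation, adaptive Gauss-Hermite
#' quadrature.
#'
#' Clearance enters the model in absolute units (L/day), converted from the
#' weight-normalized table via [to_absolute_cl()] with the reference body
#' weights.
#'
#' @param data Long PK tibble from [mab_pk()] (or the simulator).
#' @param species Character vector of two or three species to model.
#' @param random_effect Parameters carrying an inter-antibody random
#'   effect: `"alpha"` (default, the final-model structure), `"beta"`, or
#'   both.
#' @param method `"laplace"` (default) or `"agq"` (adaptive Gauss-Hermite
#'   quadrature, polished from the Laplace optimum; product rule when both
#'   random effects are present). Quadrature is effectively exact for these
#'   low-dimensional integrals and is the reference when testing
#'   random-effect structures whose Laplace errors do not cancel.
#' @param agq_nodes Quadrature nodes for `method = "agq"` (default 31).
#' @param include `"any"` (default): every antibody with a clearance value
#'   in at least one modeled species contributes; `"complete"`: only
#'   antibodies measured in all modeled species.
#' @param body_weights Named body-weight vector in kg (default
#'   [species_body_weights()]).
#' @param start Optional named start values
#'   (`alpha`, `beta`, `omega2_alpha`, `omega2_beta`, `sigma2`); defaults
#'   are log-log least squares for `alpha`/`beta`, 0.2 and 0.1 for the
#'   variances.
#' @param se Compute standard errors from the observed information matrix
#'   (default `TRUE`; skipped during bootstrap refits).
#' @param restarts Jittered restarts attempted on non-convergence.
#' @return An object of class `"allo_fit"`; see [tidy.allo_fit()] and
#'   [glance.allo_fit()]. Key elements: `coefficients` (estimates, SE,
#'   %RSE, Wald 95% CI), `ofv` (-2 log marginal likelihood, 2*pi constants
#'   included), `eta` (empirical-Bayes antibody effects), `converged`.
#' @export
#' @examples
#' fit <- fit_allometry(mab_pk(), c("monkey", "human"))
#' tidy(fit)
fit_allometry <- function(data, species = c("monkey", "human"),
                          random_effect = "alpha",
                          method = c("laplace", "agq"), agq_nodes = 31,
                          include = c("any", "complete"),
                          body_weights = species_body_weights(),
                          start = NULL, se = TRUE, restarts = 3) {
  method <- match.arg(method)
  include <- match.arg(include)
  prep <- prep_allometry_data(data, species, include, body_weights)
  random_effect <- check_random_effect(random_effect)
  if (length(unique(prep$antibody)) < 5) {
    abort("need at least 5 antibodies to fit the mixed-effects model")
  }

  ols <- lm(log(cl_abs) ~ log(bw), data = prep)
  st <- list(alpha = exp(coef(ols)[[1]]), beta = coef(ols)[[2]],
             omega2_alpha = 0.2, omega2_beta = 0.2, sigma2 = 0.1)
  if (!is.null(start)) st[names(start)] <- start
  par0 <- pack_par(st, random_effect)

  obj <- function(par) {
    v <- ofv_engine(prep, unpack_par(par, random_effect), random_effect,
                    method, agq_nodes)$ofv
    if (!is.finite(v)) 1e10 else v
  }

  if (method == "agq") {
    # quadrature objectives are costly; polish from the Laplace optimum
    lap <- fit_allometry(data, species, random_effect = random_effect,
                         method = "laplace", include = include,
                         body_weights = body_weights, start = start,
                         se = FALSE, restarts = restarts)
    par0 <- lap$par
  }
  fit_once <- function(p0) {
    if (method == "agq") {
      return(optim(p0, obj, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10)))
    }
    o <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 3000, reltol = 1e-12))
    optim(o$par, obj, method = "Nelder-Mead",
          control = list(maxit = 3000, reltol = 1e-12))
  }
  opt <- fit_once(par0)
  converged <- opt$convergence == 0 && is.finite(opt$value) && opt$value < 1e9
  tries <- 0
  while (!converged && tries < restarts) {
    tries <- tries + 1
    opt2 <- fit_once(par0 + rnorm(length(par0), 0, 0.3))
    if (opt2$convergence == 0 && (!is.finite(opt$value) || opt2$value < opt$value)) {
      opt <- opt2
      converged <- is.finite(opt$value) && opt$value < 1e9
    }
  }

  pars <- unpack_par(opt$par, random_effect)
  inner <- ofv_engine(prep, pars, random_effect, method, agq_nodes)

  vc <- NULL
  coefs <- coef_table(opt$par, random_effect, vc)
  if (se) {
    H <- tryCatch(pracma::hessian(obj, opt$par), error = function(e) NULL)
    info <- if (!is.null(H)) H / 2 else NULL
    if (!is.null(info) && all(is.finite(info)) &&
        all(eigen(info, symmetric = TRUE, only.values = TRUE)$values > 0)) {
      vc <- solve(info)
      coefs <- coef_table(opt$par, random_effect, vc)
    } else {
      warn("information matrix is singular or indefinite; standard errors unavailable")
    }
  }

  structure(list(
    coefficients = coefs,
    ofv = opt$value,
    method = method,
    agq_nodes = if (method == "agq") agq_nodes else NA_integer_,
    species = species,
    random_effect = random_effect,
    include = include,
    body_weights = body_weights,
    data = prep,
    eta = inner$eta,
    fitted = inner$fitted,
    par = opt$par,
    vcov = vc,
    n_antibodies = length(unique(prep$antibody)),
    n_obs = nrow(prep),
    converged = converged
  ), class = "allo_fit")
}

# ---- parameter packing -----------------------------------------------------

check_random_effect <- function(random_effect) {
  random_effect <- match.arg(random_effect, c("alpha", "beta"), several.ok = TRUE)
  if (!length(random_effect)) abort("at least one random effect is required")
  random_effect
}

par_names <- function(random_effect) {
  c("log_alpha", "beta",
    if ("alpha" %in% random_effect) "log_omega2_alpha",
    if ("beta" %in% random_effect) "log_omega2_beta",
    "log_sigma2")
}

pack_par <- function(st, random_effect) {
  p <- c(log(st$alpha), st$beta,
         if ("alpha" %in% random_effect) log(st$omega2_alpha),
         if ("beta" %in% random_effect) log(st$omega2_beta),
         log(st$sigma2))
  setNames(p, par_names(random_effect))
}

unpack_par <- function(par, random_effect) {
  i <- 3
  om_a <- if ("alpha" %in% random_effect) { v <- exp(par[[i]]); i <- i + 1; v } else 0
  om_b <- if ("beta" %in% random_effect) { v <- exp(par[[i]]); i <- i + 1; v } else 0
  list(alpha = exp(par[[1]]), beta = par[[2]],
       omega2_alpha = om_a, omega2_beta = om_b, sigma2 = exp(par[[i]]))
}

prep_allometry_data <- function(data, species, include, body_weights) {
  bad <- setdiff(species, names(body_weights))
  if (length(bad)) abort(paste0("no body weight for species: ", paste(bad, collapse = ", ")))
  if (length(species) < 2) abort("`species` must contain at least two species")
  prep <- data |>
    dplyr::filter(.data$species %in% !!species, !is.na(.data$cl_ml_h_kg)) |>
    dplyr::mutate(
      bw = unname(body_weights[as.character(.data$species)]),
      cl_abs = to_absolute_cl(.data$cl_ml_h_kg, .data$bw)
    ) |>
    dplyr::select("antibody", "species", "bw", "cl_abs")
  if (include == "complete") {
    keep <- prep |>
      dplyr::count(.data$antibody) |>
      dplyr::filter(.data$n == length(!!species)) |>
      dplyr::pull(.data$antibody)
    prep <- dplyr::filter(prep, .data$antibody %in% keep)
  }
  if (!nrow(prep)) abort("no usable clearance observations for the requested species")
  prep
}

# ---- marginal likelihood engine -------------------------------------------
# Observation model: y_ij ~ N(m_ij, sigma2 * m_ij^2) with
# m_ij = alpha * exp(eta_a_i) * bw_j ^ (beta * exp(eta_b_i)).
# The inner Newton step uses analytic gradients and Hessians of the joint
# log-density with respect to (eta_a, eta_b), vectorized across antibodies.
ofv_engine <- function(prep, pars, random_effect, method = "laplace",
                       agq_nodes = 31) {
  if (pars$sigma2 <= 0) abort("sigma2 must be positive")
  if (pars$omega2_alpha < 0 || pars$omega2_beta < 0) abort("variances must be non-negative")
  ids <- factor(prep$antibody, levels = unique(prep$antibody))
  id <- as.integer(ids)
  n_ab <- nlevels(ids)
  y <- prep$cl_abs
  logbw <- log(prep$bw)
  has_a <- "alpha" %in% random_effect && pars$omega2_alpha > 0
  has_b <- "beta" %in% random_effect && pars$omega2_beta > 0
  s2 <- pars$sigma2
  om_a <- pars$omega2_alpha
  om_b <- pars$omega2_beta

  joint_ll <- function(ea, eb) {
    # per-antibody joint log density at (eta_a, eta_b)
    m <- pars$alpha * exp(ea[id]) * exp(pars$beta * exp(eb[id]) * logbw)
    r <- y / m
    obs <- -0.5 * log(2 * pi * s2) - log(m) - (r - 1)^2 / (2 * s2)
    ll <- rowsum_vec(obs, id, n_ab)
    if (has_a) ll <- ll - 0.5 * log(2 * pi * om_a) - ea^2 / (2 * om_a)
    if (has_b) ll <- ll - 0.5 * log(2 * pi * om_b) - eb^2 / (2 * om_b)
    ll
  }

  grad_hess <- function(ea, eb) {
    m <- pars$alpha * exp(ea[id]) * exp(pars$beta * exp(eb[id]) * logbw)
    r <- y / m
    s <- -1 + (r^2 - r) / s2            # d(obs ll)/d(log m) per observation
    ds <- -r * (2 * r - 1) / s2         # d s / d eta through r, per unit L
    Lb <- pars$beta * exp(eb[id]) * logbw
    g_a <- if (has_a) rowsum_vec(s, id, n_ab) - ea / om_a else NULL
    g_b <- if (has_b) rowsum_vec(s * Lb, id, n_ab) - eb / om_b else NULL
    H_aa <- if (has_a) rowsum_vec(ds, id, n_ab) - 1 / om_a else NULL
    H_bb <- if (has_b) rowsum_vec(ds * Lb^2 + s * Lb, id, n_ab) - 1 / om_b else NULL
    H_ab <- if (has_a && has_b) rowsum_vec(ds * Lb, id, n_ab) else NULL
    list(g_a = g_a, g_b = g_b, H_aa = H_aa, H_bb = H_bb, H_ab = H_ab)
  }

  ea <- numeric(n_ab)
  eb <- numeric(n_ab)
  if (has_a || has_b) {
    ll <- joint_ll(ea, eb)
    for (it in 1:100) {
      gh <- grad_hess(ea, eb)
      if (has_a && has_b) {
        det <- gh$H_aa * gh$H_bb - gh$H_ab^2
        ok <- is.finite(det) & det > 0 & gh$H_aa < 0
        da <- ifelse(ok, -( gh$H_bb * gh$g_a - gh$H_ab * gh$g_b) / det,
                     sign(gh$g_a) * 0.1)
        db <- ifelse(ok, -(-gh$H_ab * gh$g_a + gh$H_aa * gh$g_b) / det,
                     sign(gh$g_b) * 0.1)
        gmax <- pmax(abs(gh$g_a), abs(gh$g_b))
      } else if (has_a) {
        ok <- is.finite(gh$H_aa) & gh$H_aa < 0
        da <- ifelse(ok, -gh$g_a / gh$H_aa, sign(gh$g_a) * 0.1)
        db <- 0
        gmax <- abs(gh$g_a)
      } else {
        ok <- is.finite(gh$H_bb) & gh$H_bb < 0
        da <- 0
        db <- ifelse(ok, -gh$g_b / gh$H_bb, sign(gh$g_b) * 0.1)
        gmax <- abs(gh$g_b)
      }
      if (max(gmax) < 1e-10) break
      # cap step length so exp() cannot overflow on a wild Newton step
      da[!is.finite(da)] <- 0
      db[!is.finite(db)] <- 0
      da <- sign(da) * pmin(abs(da), 3)
      db <- sign(db) * pmin(abs(db), 3)
      step <- rep(1, n_ab)
      for (h in 1:12) {
        ll_new <- joint_ll(ea + step * da, eb + step * db)
        worse <- !is.finite(ll_new) | ll_new < ll - 1e-12
        if (!any(worse)) break
        step[worse] <- step[worse] / 2
      }
      ea <- ea + step * da
      eb <- eb + step * db
      ll <- joint_ll(ea, eb)
    }
  }
  ll_hat <- joint_ll(ea, eb)
  gh <- grad_hess(ea, eb)

  d <- has_a + has_b
  if (d == 0) {
    log_marg <- ll_hat
  } else if (method == "laplace") {
    log_det_H <- if (d == 2) {
      det <- gh$H_aa * gh$H_bb - gh$H_ab^2
      if (any(det <= 0)) return(list(ofv = Inf, eta = NULL, fitted = NULL))
      log(det)
    } else if (has_a) {
      if (any(gh$H_aa >= 0)) return(list(ofv = Inf, eta = NULL, fitted = NULL))
      log(-gh$H_aa)
    } else {
      if (any(gh$H_bb >= 0)) return(list(ofv = Inf, eta = NULL, fitted = NULL))
      log(-gh$H_bb)
    }
    log_marg <- ll_hat + (d / 2) * log(2 * pi) - 0.5 * log_det_H
  } else if (d == 1) {
    # adaptive Gauss-Hermite centered on the conditional mode
    Hd <- if (has_a) -gh$H_aa else -gh$H_bb
    if (any(Hd <= 0)) return(list(ofv = Inf, eta = NULL, fitted = NULL))
    gh_nodes <- pracma::gaussHermite(agq_nodes)
    scale <- sqrt(2 / Hd)
    lse <- matrix(NA_real_, n_ab, agq_nodes)
    for (k in seq_len(agq_nodes)) {
      eta_k <- (if (has_a) ea else eb) + scale * gh_nodes$x[k]
      lk <- if (has_a) joint_ll(eta_k, eb) else joint_ll(ea, eta_k)
      lse[, k] <- log(gh_nodes$w[k]) + gh_nodes$x[k]^2 + lk
    }
    mx <- apply(lse, 1, max)
    log_marg <- log(scale) + mx + log(rowSums(exp(lse - mx)))
  } else {
    # product-rule adaptive quadrature over both effects, scaled per
    # antibody by the Cholesky factor of the inverse joint Hessian
    A <- -gh$H_aa
    B <- -gh$H_bb
    C <- -gh$H_ab
    det <- A * B - C^2
    if (any(det <= 0 | A <= 0)) return(list(ofv = Inf, eta = NULL, fitted = NULL))
    # Sigma = H^{-1}; lower Cholesky of the 2x2 inverse
    s11 <- B / det
    s21 <- -C / det
    s22 <- A / det
    L11 <- sqrt(s11)
    L21 <- s21 / L11
    L22 <- sqrt(pmax(s22 - L21^2, 1e-300))
    gh_nodes <- pracma::gaussHermite(agq_nodes)
    lse <- matrix(NA_real_, n_ab, agq_nodes^2)
    col <- 1
    for (k in seq_len(agq_nodes)) {
      for (l in seq_len(agq_nodes)) {
        z1 <- gh_nodes$x[k]
        z2 <- gh_nodes$x[l]
        ea_k <- ea + sqrt(2) * L11 * z1
        eb_k <- eb + sqrt(2) * (L21 * z1 + L22 * z2)
        lse[, col] <- log(gh_nodes$w[k]) + log(gh_nodes$w[l]) + z1^2 + z2^2 +
          joint_ll(ea_k, eb_k)
        col <- col + 1
      }
    }
    mx <- apply(lse, 1, max)
    log_marg <- log(2) + log(L11) + log(L22) + mx + log(rowSums(exp(lse - mx)))
  }

  m_hat <- pars$alpha * exp(ea[id]) * exp(pars$beta * exp(eb[id]) * logbw)
  list(
    ofv = -2 * sum(log_marg),
    eta = tibble::tibble(
      antibody = levels(ids),
      eta_alpha = if (has_a) ea else NA_real_,
      eta_beta = if (has_b) eb else NA_real_
    ),
    fitted = m_hat
  )
}

rowsum_vec <- function(x, id, n) {
  out <- numeric(n)
  agg <- rowsum(x, id)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Objective function value for given allometric parameters
#'
#' Evaluates -2 x log marginal likelihood (2*pi constants included, so only
#' differences between nested models are interpreted) at user-supplied
#' parameter values. With `omega2_alpha = 0` (and no other random effect)
#' the value collapses exactly to the fixed-effects likelihood.
#'
#' @inheritParams fit_allometry
#' @param alpha,beta,sigma2 Fixed-effect and residual-variance values
#'   (`alpha` in L/day for a 1 kg body weight; `sigma2` the proportional
#'   residual variance).
#' @param omega2_alpha,omega2_beta Random-effect variances; 0 drops the
#'   effect.
#' @return The objective function value (scalar).
#' @export
allometry_ofv <- function(data, alpha, beta, omega2_alpha = 0, omega2_beta = 0,
                          sigma2 = 0.1, species = c("monkey", "human"),
                          method = c("laplace", "agq"), agq_nodes = 31,
                          include = c("any", "complete"),
                          body_weights = species_body_weights()) {
  method <- match.arg(method)
  include <- match.arg(include)
  prep <- prep_allometry_data(data, species, include, body_weights)
  re <- c(if (omega2_alpha > 0) "alpha", if (omega2_beta > 0) "beta")
  pars <- list(alpha = alpha, beta = beta, omega2_alpha = omega2_alpha,
               omega2_beta = omega2_beta, sigma2 = sigma2)
  ofv_engine(prep, pars, re, method, agq_nodes)$ofv
}

coef_table <- function(par, random_effect, vc) {
  nm <- par_names(random_effect)
  log_scale <- nm != "beta"
  est_nat <- ifelse(log_scale, exp(par), par)
  se_est <- if (is.null(vc)) rep(NA_real_, length(par)) else sqrt(diag(vc))
  se_nat <- ifelse(log_scale, est_nat * se_est, se_est)
  lo <- ifelse(log_scale, exp(par - 1.96 * se_est), par - 1.96 * se_est)
  hi <- ifelse(log_scale, exp(par + 1.96 * se_est), par + 1.96 * se_est)
  tibble::tibble(
    term = sub("^log_", "", nm) |>
      sub(pattern = "^alpha$", replacement = "alpha_tv") |>
      sub(pattern = "^beta$", replacement = "beta_tv"),
    estimate = unname(est_nat),
    std_error = unname(se_nat),
    rse_pct = unname(100 * se_nat / abs(est_nat)),
    conf_low = unname(lo),
    conf_high = unname(hi)
  )
}

#' Compare nested allometric models by objective function drop
#'
#' The richer model is selected only when it lowers the objective function
#' by at least `threshold` (default 3.841, the chi-squared 0.05 critical
#' value at one degree of freedom) *and* its estimates are admissible.
#' Admissibility enforces the usual model-evaluation criteria
#' (convergence, reasonable error estimates): in particular, with random
#' effects on both allometric parameters and only one or two observations
#' per antibody the model is saturated and can drive the proportional
#' residual variance to the zero boundary, interpolating every cluster;
#' the resulting OFV drop reflects degeneracy, not explained variability,
#' so a full model whose residual variance collapses below `sigma2_floor`
#' (default 1e-3, i.e. a residual CV under ~3%, far below any bioanalytical
#' assay) is rejected.
#'
#' @param fit_reduced,fit_full Nested `allo_fit` objects on the same data
#'   (the full model has one extra random-effect variance).
#' @param threshold Required OFV drop.
#' @param sigma2_floor Minimum admissible residual variance for the full
#'   model.
#' @return One-row tibble: `ofv_reduced`, `ofv_full`, `delta_ofv`,
#'   `threshold`, `full_admissible`, `select_full`, `note`.
#' @export
compare_fits <- function(fit_reduced, fit_full, threshold = 3.841,
                         sigma2_floor = 1e-3) {
  if (!identical(sort(fit_reduced$species), sort(fit_full$species))) {
    abort("fits model different species sets; not nested")
  }
  extra <- setdiff(fit_full$random_effect, fit_reduced$random_effect)
  if (!length(extra) || length(setdiff(fit_reduced$random_effect, fit_full$random_effect))) {
    abort("models are not nested by one random effect")
  }
  sigma2_full <- fit_full$coefficients$estimate[
    fit_full$coefficients$term == "sigma2"]
  admissible <- fit_full$converged && sigma2_full >= sigma2_floor
  note <- if (!fit_full$converged) {
    "full model did not converge"
  } else if (sigma2_full < sigma2_floor) {
    sprintf("full model degenerate: residual variance collapsed to %.2g", sigma2_full)
  } else {
    ""
  }
  delta <- fit_reduced$ofv - fit_full$ofv
  tibble::tibble(
    ofv_reduced = fit_reduced$ofv,
    ofv_full = fit_full$ofv,
    delta_ofv = delta,
    threshold = threshold,
    full_admissible = admissible,
    select_full = delta >= threshold & admissible,
    note = note
  )
}

# ---- broom-style methods ---------------------------------------------------

#' Tidy an allometric mixed-effects fit
#'
#' @param x An `allo_fit` object.
#' @param ... Unused.
#' @return Tibble of parameter estimates with standard errors, %RSE and
#'   Wald 95% confidence intervals (log scale for `alpha_tv` and the
#'   variance components, identity for `beta_tv`).
#' @method tidy allo_fit
#' @export
tidy.allo_fit <- function(x, ...) {
  x$coefficients
}

#' One-row summary of an allometric fit
#'
#' @param x An `allo_fit` object.
#' @param ... Unused.
#' @return Tibble with `ofv`, `n_antibodies`, `n_obs`, `method`,
#'   `converged`.
#' @method glance allo_fit
#' @export
glance.allo_fit <- function(x, ...) {
  tibble::tibble(
    ofv = x$ofv,
    n_antibodies = x$n_antibodies,
    n_obs = x$n_obs,
    method = x$method,
    species = paste(x$species, collapse = "-"),
    converged = x$converged
  )
}

#' @export
print.allo_fit <- function(x, ...) {
  cat("Allometric clearance model (", paste(x$species, collapse = "-"), "), ",
      x$method, " marginal likelihood\n", sep = "")
  cat(x$n_obs, "observations on", x$n_antibodies, "antibodies; OFV",
      format(x$ofv, digits = 6),
      if (!x$converged) "(NOT converged)" else "", "\n")
  print(x$coefficients, ...)
  invisible(x)
}

#' @export
fitted.allo_fit <- function(object, ...) object$fitted

#' Observed versus model-predicted clearance
#'
#' Goodness-of-fit plot on log axes with the unity line and 2-fold bounds.
#'
#' @param object An `allo_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot allo_fit
#' @export
autoplot.allo_fit <- function(object, ...) {
  df <- object$data
  df$predicted <- object$fitted
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$cl_abs,
                                   shape = .data$species)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(2), linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = -log10(2), linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Predicted CL (L/day)", y = "Observed CL (L/day)",
                  shape = "Species")
}
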