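#' Spearman rank correlation with Fisher-transform confidence interval
#'
#' Rank correlation on average (mid) ranks. The two-sided p-value comes
#' from exact enumeration of all rank permutations when `n <= 8` and the
#' data are tie-free, otherwise from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`. The 95% CI uses the Fisher
#' z-transform with `SE = sqrt(1.06 / (n - 3))`
#' (Fieller-Hartley-Pearson), an approximation reported for orientation
#' rather than inference.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return One-row tibble: `method`, `estimate` (rho), `conf_low`,
#'   `conf_high`, `p_value`, `p_method`, `n`.
#' @export
#' @examples
#' cc <- complete_cases(mab_pk(), "monkey", "human", "CL")
#' cor_spearman(cc$value_a, cc$value_b)
cor_spearman <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 4) abort("need at least 4 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("constant input; ranks have zero variance")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 8 && !ties) {
    p <- spearman_exact_p(x, y)
    p_method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    p_method <- "t-approximation"
  }
  z <- atanh(rho)
  se_z <- sqrt(1.06 / (n - 3))
  tibble::tibble(
    method = "spearman",
    estimate = rho,
    conf_low = tanh(z - 1.96 * se_z),
    conf_high = tanh(z + 1.96 * se_z),
    p_value = min(p, 1),
    p_method = p_method,
    n = n
  )
}

# Exact two-sided permutation p-value for |rho| (tie-free, small n).
spearman_exact_p <- function(x, y) {
  n <- length(x)
  ry <- rank(y)
  obs <- abs(stats::cor(rank(x), ry))
  perms <- all_permutations(n)
  rhos <- apply(perms, 1, function(p) stats::cor(p, ry))
  mean(abs(rhos) >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[j, ], n, after = i - 1)
      row <- row + 1
    }
  }
  out
}

#' Simple linear regression summary
#'
#' Ordinary least squares of `y` on `x` with the coefficient of
#' determination and the two-sided p-value of the slope t-test.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @return One-row tibble: `method`, `estimate` (r-squared), `slope`,
#'   `intercept`, `p_value`, `n`.
#' @export
cor_ols <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1) abort("constant x; slope undefined")
  fit <- lm(y ~ x)
  ssr <- sum(fit$residuals^2)
  sst <- sum((y - mean(y))^2)
  slope <- coef(fit)[[2]]
  se_slope <- sqrt(ssr / (n - 2) / sum((x - mean(x))^2))
  p <- if (se_slope == 0) 0 else 2 * pt(-abs(slope / se_slope), df = n - 2)
  tibble::tibble(
    method = "ols",
    estimate = 1 - ssr / sst,
    slope = slope,
    intercept = coef(fit)[[1]],
    p_value = p,
    n = n
  )
}

#' Cross-species correlation table for one measure
#'
#' Spearman and least-squares results for the three species pairs
#' (monkey-human, rat-human, rat-monkey) using per-pair complete cases, the
#' layout conventionally reported for cross-species PK comparisons.
#'
#' @inheritParams complete_cases
#' @param measure `"CL"` or `"SCF"`.
#' @param censor_f_at_100 Cap bioavailability values at 100% before
#'   correlating (sensitivity analysis; default `FALSE`, values above 100%
#'   are used as experimentally determined).
#' @return Tibble with one row per (pair, method).
#' @export
#' @examples
#' species_correlation(mab_pk(), "CL")
species_correlation <- function(data, measure = "CL", censor_f_at_100 = FALSE) {
  if (censor_f_at_100) {
    data$scf_pct <- pmin(data$scf_pct, 100)
  }
  pairs <- list(c("monkey", "human"), c("rat", "human"), c("rat", "monkey"))
  purrr::map(pairs, function(p) {
    cc <- complete_cases(data, p[1], p[2], measure)
    dplyr::bind_rows(
      cor_spearman(cc$value_a, cc$value_b),
      cor_ols(cc$value_a, cc$value_b)
    ) |>
      dplyr::mutate(pair = paste(p, collapse = "-"), measure = toupper(measure),
                    .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Within-species regression of bioavailability on clearance
#'
#' Regresses SC bioavailability on log-transformed weight-normalized
#' clearance within each species (clearance spans close to an order of
#' magnitude, so the fit is on a log clearance axis).
#'
#' @inheritParams species_correlation
#' @param species Species to analyze (default all three).
#' @param log_cl Regress on `log(CL)` (default `TRUE`) rather than CL.
#' @return Tibble with one row per species: r-squared, slope, intercept,
#'   p-value, n.
#' @export
#' @examples
#' cl_f_regression(mab_pk())
cl_f_regression <- function(data, species = c("human", "monkey", "rat"),
                            log_cl = TRUE, censor_f_at_100 = FALSE) {
  if (censor_f_at_100) {
    data$scf_pct <- pmin(data$scf_pct, 100)
  }
  purrr::map(species, function(sp) {
    d <- data[data$species == sp & !is.na(data$cl_ml_h_kg) & !is.na(data$scf_pct), ]
    x <- if (log_cl) log(d$cl_ml_h_kg) else d$cl_ml_h_kg
    cor_ols(x, d$scf_pct) |>
      dplyr::mutate(species = sp, x_scale = if (log_cl) "log(CL)" else "CL",
                    .before = 1)
  }) |>
    purrr::list_rbind()
}

#' Scatter plot for a cross-species comparison
#'
#' @inheritParams complete_cases
#' @param measure `"CL"` or `"SCF"`.
#' @param fold_lines Fold-change reference lines to draw around unity
#'   (default 2 for clearance comparisons).
#' @return A ggplot object.
#' @export
plot_species_pair <- function(data, species_a, species_b, measure = "CL",
                              fold_lines = 2) {
  cc <- complete_cases(data, species_a, species_b, measure)
  lab <- if (toupper(measure) == "CL") "CL (mL/h/kg)" else "SC bioavailability (%)"
  ggplot2::ggplot(cc, ggplot2::aes(x = .data$value_a, y = .data$value_b)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = fold_lines, intercept = 0, linetype = 2) +
    ggplot2::geom_abline(slope = 1 / fold_lines, intercept = 0, linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste(species_a, lab), y = paste(species_b, lab))
}
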