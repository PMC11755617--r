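#' Full cross-species translation analysis
#'
#' Runs the complete analysis on a cross-species PK table: descriptive
#' statistics, cross-species Spearman/regression correlations for
#' clearance and SC bioavailability, allometric mixed-effects fits for the
#' four species sets (monkey-human, rat-human, rat-monkey, all three),
#' the random-effect-on-exponent model comparison, a Laplace-vs-quadrature
#' consistency check, single-species human clearance scaling with
#' fold-error summaries, the within-species clearance-bioavailability
#' regressions, and optionally a cluster bootstrap of the two-species
#' models.
#'
#' @param data Long PK tibble (default the packaged 25-antibody table).
#' @param bootstrap_n Bootstrap replicates per two-species model (0 skips
#'   the bootstrap).
#' @param seed Integer seed; required when `bootstrap_n > 0`.
#' @param censor_f_at_100 Sensitivity toggle capping bioavailability at
#'   100% in the correlation analyses.
#' @param scaling_beta Optional named vector overriding the scaling
#'   exponents, e.g. `c(monkey = 0.84, rat = 0.92)`; by default each
#'   two-species fitted exponent, rounded to two decimals, is used.
#' @return Object of class `"mab_reproduction"`, a list of tibbles/fits:
#'   `summary_stats`, `cl_correlations`, `f_correlations`,
#'   `clf_regressions`, `allometry` (parameter table across species sets),
#'   `fits`, `model_comparison`, `agq_check`, `scaling` (named
#'   `scaling_result`s), `scaling_summary`, `bootstrap` (or `NULL`).
#' @export
#' @examples
#' \donttest{
#' rep <- reproduce_study()
#' rep$scaling_summary
#' }
reproduce_study <- function(data = mab_pk(), bootstrap_n = 0, seed = NULL,
                            censor_f_at_100 = FALSE, scaling_beta = NULL) {
  if (bootstrap_n > 0 && is.null(seed)) {
    abort("`seed` is required when bootstrapping")
  }
  species_sets <- list(
    "monkey-human" = c("monkey", "human"),
    "rat-human" = c("rat", "human"),
    "rat-monkey" = c("rat", "monkey"),
    "rat-monkey-human" = c("rat", "monkey", "human")
  )
  fits <- purrr::map(species_sets, function(sp) fit_allometry(data, sp))
  allometry <- purrr::imap(fits, function(f, nm) {
    dplyr::mutate(tidy(f), species_set = nm, ofv = f$ofv, .before = 1)
  }) |> purrr::list_rbind()

  model_comparison <- purrr::imap(fits, function(f, nm) {
    full <- fit_allometry(data, f$species, random_effect = c("alpha", "beta"),
                          se = FALSE)
    dplyr::mutate(compare_fits(f, full), species_set = nm, .before = 1)
  }) |> purrr::list_rbind()

  agq_check <- purrr::imap(fits, function(f, nm) {
    est <- setNames(f$coefficients$estimate, f$coefficients$term)
    ofv_agq <- allometry_ofv(
      data, alpha = est[["alpha_tv"]], beta = est[["beta_tv"]],
      omega2_alpha = est[["omega2_alpha"]], sigma2 = est[["sigma2"]],
      species = f$species, method = "agq", agq_nodes = 63
    )
    tibble::tibble(species_set = nm, ofv_laplace = f$ofv, ofv_agq = ofv_agq,
                   abs_diff = abs(f$ofv - ofv_agq))
  }) |> purrr::list_rbind()

  # scaling uses the fitted exponents at full precision; the two-decimal
  # values are display rounding
  beta_of <- function(nm) {
    allometry$estimate[allometry$species_set == nm &
                         allometry$term == "beta_tv"]
  }
  betas <- c(monkey = unname(beta_of("monkey-human")),
             rat = unname(beta_of("rat-human")))
  if (!is.null(scaling_beta)) betas[names(scaling_beta)] <- scaling_beta
  scaling <- purrr::imap(betas, function(b, src) scale_study(data, src, b))
  scaling_summary <- purrr::map(scaling, glance) |> purrr::list_rbind()

  boot <- NULL
  if (bootstrap_n > 0) {
    boot <- purrr::imap(
      species_sets[c("monkey-human", "rat-human")],
      function(sp, nm) bootstrap_allometry(data, sp, n_replicates = bootstrap_n,
                                           seed = seed)
    )
  }

  structure(list(
    summary_stats = summarize_dataset(data),
    cl_correlations = species_correlation(data, "CL"),
    f_correlations = species_correlation(data, "SCF",
                                         censor_f_at_100 = censor_f_at_100),
    clf_regressions = cl_f_regression(data, censor_f_at_100 = censor_f_at_100),
    allometry = allometry,
    fits = fits,
    model_comparison = model_comparison,
    agq_check = agq_check,
    scaling = scaling,
    scaling_summary = scaling_summary,
    bootstrap = boot,
    settings = list(censor_f_at_100 = censor_f_at_100,
                    bootstrap_n = bootstrap_n, seed = seed)
  ), class = "mab_reproduction")
}

#' @export
print.mab_reproduction <- function(x, ...) {
  cat("Cross-species mAb PK translation analysis\n\n")
  cat("Clearance correlations (Spearman):\n")
  print(dplyr::filter(x$cl_correlations, .data$method == "spearman")[
    , c("pair", "estimate", "p_value", "n")])
  cat("\nBioavailability correlations (Spearman):\n")
  print(dplyr::filter(x$f_correlations, .data$method == "spearman")[
    , c("pair", "estimate", "p_value", "n")])
  cat("\nAllometric exponents:\n")
  print(dplyr::filter(x$allometry, .data$term == "beta_tv")[
    , c("species_set", "estimate", "rse_pct", "conf_low", "conf_high")])
  cat("\nScaling accuracy:\n")
  print(x$scaling_summary)
  invisible(x)
}
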