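#' Scale clearance to another species with a fixed allometric exponent
#'
#' Single-species scaling of weight-normalized clearance:
#' `CL_target = CL_source * (BW_target / BW_source)^(beta - 1)`, the per-kg
#' form of the absolute-clearance power law
#' `CL_target_abs = CL_source_abs * (BW_target / BW_source)^beta`.
#'
#' @param cl_per_kg Source-species clearance, mL/h/kg (vectorized).
#' @param beta Fixed allometric exponent.
#' @param source_species,target_species Species names resolved against
#'   `body_weights` (default scaling is to human).
#' @param body_weights Named body-weight vector in kg.
#' @return Scaled clearance in mL/h/kg.
#' @export
#' @examples
#' scale_human_cl(0.488, beta = 0.92, source_species = "rat")
scale_human_cl <- function(cl_per_kg, beta, source_species,
                           target_species = "human",
                           body_weights = species_body_weights()) {
  bw_s <- body_weights[[source_species]]
  bw_t <- body_weights[[target_species]]
  if (any(cl_per_kg <= 0, na.rm = TRUE) || bw_s <= 0 || bw_t <= 0) {
    abort("clearances and body weights must be positive")
  }
  cl_per_kg * (bw_t / bw_s)^(beta - 1)
}

#' Fold-error accuracy of single-species human clearance scaling
#'
#' For each antibody with clearance in both the source species and human,
#' scales the source clearance to human with [scale_human_cl()] and
#' summarizes the observed/scaled ratios. A prediction is "within 2-fold"
#' when the ratio lies between 0.5 and 2, bounds inclusive.
#'
#' @inheritParams complete_cases
#' @param source_species Non-clinical source species (`"rat"` or
#'   `"monkey"`).
#' @param beta Fixed allometric exponent used for scaling.
#' @param body_weights Named body-weight vector in kg.
#' @return Object of class `"scaling_result"`: `by_antibody` tibble
#'   (`antibody`, `observed`, `scaled`, `ratio`, `within_2fold`) and
#'   `summary` tibble (`n`, `n_within`, `pct_within`, `mean_ratio`).
#' @export
#' @examples
#' res <- scale_study(mab_pk(), "rat", beta = 0.92)
#' glance(res)
scale_study <- function(data, source_species, beta,
                        body_weights = species_body_weights()) {
  pairs <- complete_cases(data, source_species, "human", "CL")
  if (!nrow(pairs)) abort("no antibodies with both source and human clearance")
  by_ab <- pairs |>
    dplyr::transmute(
      .data$antibody,
      observed = .data$value_b,
      scaled = scale_human_cl(.data$value_a, beta, source_species,
                              body_weights = body_weights),
      ratio = .data$observed / .data$scaled,
      within_2fold = .data$ratio >= 0.5 & .data$ratio <= 2
    )
  structure(list(
    by_antibody = by_ab,
    summary = tibble::tibble(
      source_species = source_species,
      beta = beta,
      n = nrow(by_ab),
      n_within = sum(by_ab$within_2fold),
      pct_within = 100 * mean(by_ab$within_2fold),
      mean_ratio = mean(by_ab$ratio)
    )
  ), class = "scaling_result")
}

#' Fold-error summary from precomputed observed/scaled pairs
#'
#' @param observed,scaled Positive clearance vectors of equal length. The
#'   summary is invariant to a common rescaling of both.
#' @return One-row tibble: `n`, `n_within`, `pct_within`, `mean_ratio`.
#' @export
fold_error_summary <- function(observed, scaled) {
  if (!length(observed)) abort("empty input")
  if (length(observed) != length(scaled)) abort("length mismatch")
  ratio <- observed / scaled
  tibble::tibble(
    n = length(ratio),
    n_within = sum(ratio >= 0.5 & ratio <= 2),
    pct_within = 100 * mean(ratio >= 0.5 & ratio <= 2),
    mean_ratio = mean(ratio)
  )
}

#' @method tidy scaling_result
#' @export
tidy.scaling_result <- function(x, ...) x$by_antibody

#' @method glance scaling_result
#' @export
glance.scaling_result <- function(x, ...) x$summary

#' @export
print.scaling_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Human CL scaled from %s (beta = %.2f): %d/%d within 2-fold (%.0f%%), mean obs/scaled %.2f\n",
    s$source_species, s$beta, s$n_within, s$n, s$pct_within, s$mean_ratio))
  invisible(x)
}

#' Observed versus scaled human clearance
#'
#' @param object A `scaling_result` object.
#' @param ... Unused.
#' @return A ggplot object with unity and 2-fold reference lines.
#' @method autoplot scaling_result
#' @export
autoplot.scaling_result <- function(object, ...) {
  ggplot2::ggplot(object$by_antibody,
                  ggplot2::aes(x = .data$scaled, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_abline(slope = 1, intercept = log10(2), linetype = 2) +
    ggplot2::geom_abline(slope = 1, intercept = -log10(2), linetype = 2) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Scaled human CL (mL/h/kg)",
                  y = "Observed human CL (mL/h/kg)")
}
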