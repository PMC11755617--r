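#' Cluster bootstrap of the allometric mixed-effects model
#'
#' Resamples antibodies (whole clusters with all their species
#' observations) with replacement, preserving the number of clusters, and
#' refits the model on each replicate. Non-converging replicates are
#' counted, reported and excluded from the summaries, never silently
#' dropped.
#'
#' @inheritParams fit_allometry
#' @param n_replicates Number of bootstrap datasets (2000 in the full
#'   analysis; smaller values give a faster, coarser uncertainty picture).
#' @param seed Integer seed; required so the resampling is reproducible.
#' @return Object of class `"allo_boot"`: `replicates` (one row per
#'   successful replicate, parameter estimates in natural units), `summary`
#'   (per-parameter mean, SE, 2.5/97.5 percentiles), `n_replicates`,
#'   `n_failed`, `seed`, and `fit` (the point-estimate fit).
#' @export
bootstrap_allometry <- function(data, species = c("monkey", "human"),
                                n_replicates = 2000, seed,
                                random_effect = "alpha",
                                include = c("any", "complete"),
                                body_weights = species_body_weights()) {
  if (missing(seed)) abort("`seed` is required for bootstrap resampling")
  if (n_replicates < 1) abort("`n_replicates` must be at least 1")
  include <- match.arg(include)
  fit0 <- fit_allometry(data, species, random_effect = random_effect,
                        include = include, body_weights = body_weights,
                        se = FALSE)
  pool <- unique(fit0$data$antibody)
  clusters <- split(
    data[data$antibody %in% pool, , drop = FALSE],
    factor(data$antibody[data$antibody %in% pool], levels = pool)
  )
  set.seed(seed)
  start <- setNames(as.list(unpack_par(fit0$par, fit0$random_effect)),
                    c("alpha", "beta", "omega2_alpha", "omega2_beta", "sigma2"))
  reps <- purrr::map(seq_len(n_replicates), function(b) {
    idx <- sample.int(length(pool), length(pool), replace = TRUE)
    boot_data <- purrr::imap(idx, function(i, copy) {
      d <- clusters[[i]]
      d$antibody <- paste0(d$antibody, "#", copy)
      d
    }) |> purrr::list_rbind()
    fit <- tryCatch(
      fit_allometry(boot_data, species, random_effect = random_effect,
                    include = include, body_weights = body_weights,
                    start = start, se = FALSE, restarts = 1),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) return(NULL)
    est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
    tibble::tibble(replicate = b, n_antibodies = fit$n_antibodies,
                   !!!as.list(est))
  })
  ok <- purrr::compact(reps)
  if (!length(ok)) abort("all bootstrap replicates failed to converge")
  replicates <- purrr::list_rbind(ok)
  long <- tidyr::pivot_longer(replicates, -c("replicate", "n_antibodies"),
                              names_to = "term", values_to = "estimate")
  summary <- long |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      mean = mean(.data$estimate),
      se = sd(.data$estimate),
      ci_low = unname(stats::quantile(.data$estimate, 0.025)),
      ci_high = unname(stats::quantile(.data$estimate, 0.975)),
      .groups = "drop"
    )
  structure(list(
    replicates = replicates,
    summary = summary,
    n_replicates = n_replicates,
    n_failed = n_replicates - nrow(replicates),
    seed = seed,
    fit = fit0
  ), class = "allo_boot")
}

#' @method tidy allo_boot
#' @export
tidy.allo_boot <- function(x, ...) x$summary

#' @method glance allo_boot
#' @export
glance.allo_boot <- function(x, ...) {
  tibble::tibble(
    n_replicates = x$n_replicates,
    n_failed = x$n_failed,
    seed = x$seed,
    species = paste(x$fit$species, collapse = "-")
  )
}

#' @export
print.allo_boot <- function(x, ...) {
  cat("Cluster bootstrap:", x$n_replicates, "replicates (",
      x$n_failed, "failed ), seed", x$seed, "\n")
  print(x$summary, ...)
  invisible(x)
}
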