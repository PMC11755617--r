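#' Reference body weights by species
#'
#' Typical total body weights used to convert clearance between
#' weight-normalized (mL/h/kg) and absolute (L/day) units: 0.3 kg for rat,
#' 3 kg for cynomolgus monkey and 70 kg for human.
#'
#' @return Named numeric vector of body weights in kg.
#' @export
#' @examples
#' species_body_weights()
species_body_weights <- function() {
  c(rat = 0.3, monkey = 3, human = 70)
}

pk_species <- c("rat", "monkey", "human")
pk_provenance <- c("de_novo_rat_study", "regulatory_label", "internal")

#' Curated cross-species antibody pharmacokinetic table
#'
#' Loads the packaged 25-antibody dataset of weight-normalized clearance
#' (CL, mL/h/kg) and subcutaneous bioavailability (SC%F, percent) in rat,
#' cynomolgus monkey and human. Values were curated from de novo rat
#' studies, regulatory labels and internal reports; missing cells are `NA`,
#' never zero. SC%F values above 100% are experimental estimates and are
#' retained as reported.
#'
#' @param source Path to a CSV in the long dialect
#'   (`antibody,species,cl_ml_h_kg,scf_pct,provenance`), or `"packaged"`
#'   (default) for the curated table shipped with the package.
#' @return A tibble with columns `antibody` (character), `species`
#'   (factor rat/monkey/human), `cl_ml_h_kg`, `scf_pct` (numeric, `NA` when
#'   not determined) and `provenance` (character or `NA`), one row per
#'   (antibody, species) with at least one measured value. Row order follows
#'   the source table and is stable across all downstream subsetting.
#' @export
#' @examples
#' pk <- mab_pk()
#' dplyr::count(pk, species)
mab_pk <- function(source = "packaged") {
  path <- if (identical(source, "packaged")) {
    system.file("extdata", "cross_species_pk.csv", package = "mabscale",
                mustWork = TRUE)
  } else {
    source
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      antibody = readr::col_character(),
      species = readr::col_character(),
      cl_ml_h_kg = readr::col_character(),
      scf_pct = readr::col_character(),
      provenance = readr::col_character()
    )
  )
  validate_pk_long(raw)
}

#' Read a wide one-row-per-antibody pharmacokinetic table
#'
#' Reads a CSV laid out with one row per antibody and per-species value
#' columns (`rat_cl`, `monkey_cl`, `human_cl`, `rat_scf`, `monkey_scf`,
#' `human_scf`; missing cells empty or `-`) and returns the same long tibble
#' as [mab_pk()].
#'
#' @param path CSV file path.
#' @return Long-format tibble; see [mab_pk()].
#' @export
read_pk_wide <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!"antibody" %in% names(raw)) {
    abort("wide PK table must have an 'antibody' column")
  }
  long <- tidyr::pivot_longer(
    raw,
    cols = -"antibody",
    names_to = c("species", "measure"),
    names_sep = "_",
    values_to = "value"
  )
  long <- tidyr::pivot_wider(long, names_from = "measure", values_from = "value")
  long$provenance <- NA_character_
  names(long)[names(long) == "cl"] <- "cl_ml_h_kg"
  names(long)[names(long) == "scf"] <- "scf_pct"
  validate_pk_long(long)
}

# Shared schema validation for the long dialect. Numeric columns arrive as
# character so that "-" sentinels and genuinely malformed entries can be
# distinguished and reported by row.
validate_pk_long <- function(raw) {
  needed <- c("antibody", "species", "cl_ml_h_kg", "scf_pct")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    abort(paste0("PK table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  bad_sp <- setdiff(unique(raw$species), pk_species)
  if (length(bad_sp)) {
    abort(paste0("unknown species label(s): ", paste(bad_sp, collapse = ", ")))
  }
  dup <- raw |>
    dplyr::count(.data$antibody, .data$species) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("duplicate (antibody, species) rows: ",
                 paste(dup$antibody, dup$species, collapse = "; ")))
  }
  as_num <- function(x, col) {
    x[x %in% c("-", "")] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) {
      abort(paste0("non-numeric value(s) in ", col, ": ",
                   paste(unique(x[bad]), collapse = ", ")))
    }
    out
  }
  out <- tibble::tibble(
    antibody = raw$antibody,
    species = factor(raw$species, levels = pk_species),
    cl_ml_h_kg = as_num(raw$cl_ml_h_kg, "cl_ml_h_kg"),
    scf_pct = as_num(raw$scf_pct, "scf_pct"),
    provenance = if ("provenance" %in% names(raw)) raw$provenance else NA_character_
  )
  if (any(out$cl_ml_h_kg <= 0, na.rm = TRUE)) {
    abort("clearance values must be positive")
  }
  if (any(out$scf_pct <= 0, na.rm = TRUE)) {
    abort("bioavailability values must be positive")
  }
  out
}

match_measure <- function(measure) {
  measure <- toupper(measure)
  if (!measure %in% c("CL", "SCF")) {
    abort("`measure` must be \"CL\" or \"SCF\"")
  }
  if (measure == "CL") "cl_ml_h_kg" else "scf_pct"
}

#' Paired complete cases for a species pair
#'
#' Returns the antibodies with a measured value in both species, in dataset
#' order. The pair set is symmetric in the species order; only the column
#' naming follows the argument order.
#'
#' @param data Long PK tibble from [mab_pk()] or [read_pk_wide()].
#' @param species_a,species_b Distinct species names.
#' @param measure `"CL"` (clearance) or `"SCF"` (subcutaneous bioavailability).
#' @return Tibble with columns `antibody`, `value_a`, `value_b`.
#' @export
#' @examples
#' complete_cases(mab_pk(), "monkey", "human", "CL")
complete_cases <- function(data, species_a, species_b, measure = "CL") {
  col <- match_measure(measure)
  species_a <- match.arg(species_a, pk_species)
  species_b <- match.arg(species_b, pk_species)
  if (identical(species_a, species_b)) {
    abort("`species_a` and `species_b` must differ")
  }
  wide <- data |>
    dplyr::filter(.data$species %in% c(species_a, species_b)) |>
    dplyr::select("antibody", "species", value = dplyr::all_of(col)) |>
    tidyr::pivot_wider(names_from = "species", values_from = "value")
  for (sp in c(species_a, species_b)) {
    if (!sp %in% names(wide)) wide[[sp]] <- NA_real_
  }
  wide |>
    dplyr::filter(!is.na(.data[[species_a]]), !is.na(.data[[species_b]])) |>
    dplyr::transmute(
      .data$antibody,
      value_a = .data[[species_a]],
      value_b = .data[[species_b]]
    )
}

#' Convert weight-normalized clearance to absolute clearance
#'
#' @param cl_per_kg Clearance in mL/h/kg (non-negative).
#' @param body_weight Body weight in kg (positive).
#' @return Absolute clearance in L/day: `cl_per_kg * body_weight * 24 / 1000`.
#' @seealso [from_absolute_cl()] for the exact inverse.
#' @export
#' @examples
#' to_absolute_cl(0.222, 70) # typical human mAb, ~0.373 L/day
to_absolute_cl <- function(cl_per_kg, body_weight) {
  if (any(cl_per_kg < 0, na.rm = TRUE)) abort("`cl_per_kg` must be non-negative")
  if (any(body_weight <= 0, na.rm = TRUE)) abort("`body_weight` must be positive")
  cl_per_kg * body_weight * 24 / 1000
}

#' Convert absolute clearance back to weight-normalized units
#'
#' @param cl_l_day Absolute clearance in L/day (non-negative).
#' @inheritParams to_absolute_cl
#' @return Clearance in mL/h/kg.
#' @export
from_absolute_cl <- function(cl_l_day, body_weight) {
  if (any(cl_l_day < 0, na.rm = TRUE)) abort("`cl_l_day` must be non-negative")
  if (any(body_weight <= 0, na.rm = TRUE)) abort("`body_weight` must be positive")
  cl_l_day * 1000 / (24 * body_weight)
}

#' Summary statistics for one species and measure
#'
#' Arithmetic mean, range and count over the non-missing values, matching
#' the descriptive statistics conventionally reported for cross-species PK
#' tables.
#'
#' @inheritParams complete_cases
#' @param species One of `"rat"`, `"monkey"`, `"human"`.
#' @return One-row tibble: `species`, `measure`, `mean`, `min`, `max`, `n`.
#' @export
#' @examples
#' summarize_measure(mab_pk(), "human", "CL")
summarize_measure <- function(data, species, measure = "CL") {
  col <- match_measure(measure)
  species <- match.arg(species, pk_species)
  x <- data[[col]][data$species == species]
  x <- x[!is.na(x)]
  if (!length(x)) {
    abort(paste0("no non-missing ", measure, " values for ", species))
  }
  tibble::tibble(
    species = species, measure = toupper(measure),
    mean = mean(x), min = min(x), max = max(x), n = length(x)
  )
}

#' Summary statistics for every species and measure
#'
#' @inheritParams complete_cases
#' @return Tibble with one row per (species, measure) combination that has
#'   at least one measured value.
#' @export
summarize_dataset <- function(data) {
  grid <- tidyr::expand_grid(species = pk_species, measure = c("CL", "SCF"))
  purrr::pmap(grid, function(species, measure) {
    x <- data[[match_measure(measure)]][data$species == species]
    if (all(is.na(x))) NULL else summarize_measure(data, species, measure)
  }) |>
    purrr::compact() |>
    purrr::list_rbind()
}
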