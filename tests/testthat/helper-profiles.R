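# Shared fixtures built in code.

rat_schedule <- c(1, 6, 12, 24, 48, 72, 96, 120, 144, 168, 240, 336, 504,
                  672, 840, 1008)

make_profile <- function(times, conc, route = "IV", dose = 3, id = "a1",
                         lloq = 0) {
  tibble::tibble(
    animal_id = id, route = route, dose_mg_kg = dose,
    time_h = times, conc = conc, bql = conc < lloq, excluded = FALSE
  )
}

mono_profile <- function(c0 = 100, k = 0.01, times = rat_schedule, ...) {
  make_profile(times, c0 * exp(-k * times), ...)
}
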