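test_that("packaged dataset has the expected shape and spot values", {
  pk <- mab_pk()
  expect_equal(length(unique(pk$antibody)), 25)
  expect_equal(pk$cl_ml_h_kg[pk$antibody == "secukinumab" & pk$species == "rat"],
               0.137)
  # ocrelizumab has no monkey observation at all
  expect_false(any(pk$antibody == "ocrelizumab" & pk$species == "monkey"))
  expect_true(all(pk$cl_ml_h_kg > 0, na.rm = TRUE))
  expect_true(all(pk$scf_pct > 0, na.rm = TRUE))
  # bioavailability above 100% is retained as reported
  expect_true(any(pk$scf_pct > 100, na.rm = TRUE))
})

test_that("readers reject malformed tables", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("antibody,species,cl_ml_h_kg,scf_pct,provenance",
               "x,dog,0.1,50,internal"), tmp)
  expect_error(mab_pk(tmp), "unknown species")
  writeLines(c("antibody,species,cl_ml_h_kg,scf_pct,provenance",
               "x,rat,abc,50,internal"), tmp)
  expect_error(mab_pk(tmp), "non-numeric")
  writeLines(c("antibody,species,cl_ml_h_kg,scf_pct,provenance",
               "x,rat,0.1,50,internal",
               "x,rat,0.2,60,internal"), tmp)
  expect_error(mab_pk(tmp), "duplicate")
})

test_that("wide reader round-trips the long layout", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("antibody,rat_cl,monkey_cl,human_cl,rat_scf,monkey_scf,human_scf",
               "abX,0.30,0.25,0.15,60,-,50",
               "abY,0.40,,0.20,,80,"), tmp)
  w <- read_pk_wide(tmp)
  expect_equal(w$cl_ml_h_kg[w$antibody == "abX" & w$species == "rat"], 0.30)
  expect_true(is.na(w$scf_pct[w$antibody == "abX" & w$species == "monkey"]))
  expect_true(is.na(w$cl_ml_h_kg[w$antibody == "abY" & w$species == "monkey"]))
})

test_that("complete cases match the per-pair sample sizes and are symmetric", {
  pk <- mab_pk()
  sizes <- list(
    list("monkey", "human", "CL", 22), list("rat", "human", "CL", 23),
    list("rat", "monkey", "CL", 24), list("monkey", "human", "SCF", 14),
    list("rat", "human", "SCF", 13), list("rat", "monkey", "SCF", 16)
  )
  for (s in sizes) {
    expect_equal(nrow(complete_cases(pk, s[[1]], s[[2]], s[[3]])), s[[4]])
  }
  ab <- complete_cases(pk, "monkey", "human", "CL")
  ba <- complete_cases(pk, "human", "monkey", "CL")
  expect_setequal(ab$antibody, ba$antibody)
  expect_equal(ab$value_a, ba$value_b[match(ab$antibody, ba$antibody)])
  empty <- pk[0, ]
  expect_equal(nrow(complete_cases(empty, "rat", "human", "CL")), 0)
  expect_error(complete_cases(pk, "rat", "rat", "CL"), "must differ")
  expect_error(complete_cases(pk, "rat", "human", "XX"), "measure")
})

test_that("unit conversion is exact and round-trips", {
  expect_equal(to_absolute_cl(0.222, 70), 0.37296)
  expect_equal(to_absolute_cl(0, 5), 0)
  expect_equal(to_absolute_cl(0.332, 0.3), 0.0023904)
  x <- c(0.1, 0.5, 1.85)
  expect_equal(from_absolute_cl(to_absolute_cl(x, 3), 3), x)
  expect_error(to_absolute_cl(-1, 3), "non-negative")
  expect_error(from_absolute_cl(0.3, 0), "positive")
})

test_that("species summaries reproduce the descriptive statistics", {
  pk <- mab_pk()
  s <- summarize_measure(pk, "rat", "CL")
  expect_equal(round(s$mean, 3), 0.332)
  expect_equal(c(s$min, s$max, s$n), c(0.137, 0.823, 25))
  s <- summarize_measure(pk, "monkey", "CL")
  # mean of the printed (3-decimal) monkey values is 0.38846
  expect_equal(round(s$mean, 4), 0.3885)
  expect_equal(c(s$min, s$max, s$n), c(0.100, 1.85, 24))
  s <- summarize_measure(pk, "human", "CL")
  expect_equal(round(s$mean, 3), 0.222)
  expect_equal(c(s$min, s$max, s$n), c(0.080, 0.730, 23))
  s <- summarize_measure(pk, "rat", "SCF")
  expect_equal(round(s$mean, 1), 62.1)
  expect_equal(c(s$min, s$max, s$n), c(27.5, 105.2, 20))
  s <- summarize_measure(pk, "monkey", "SCF")
  expect_equal(round(s$mean, 1), 76.8)
  expect_equal(c(s$min, s$max, s$n), c(35, 112, 19))
  # human SC%F summarized from the printed table itself
  s <- summarize_measure(pk, "human", "SCF")
  expect_equal(round(s$mean, 1), 54.1)
  expect_equal(c(s$min, s$max, s$n), c(9, 89, 14))
  # single value and all-missing edge cases
  one <- mab_pk()[mab_pk()$antibody == "secukinumab" & mab_pk()$species == "rat", ]
  s1 <- summarize_measure(one, "rat", "CL")
  expect_equal(c(s1$mean, s1$min, s1$max), rep(0.137, 3))
  expect_error(summarize_measure(one, "human", "CL"), "no non-missing")
})
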