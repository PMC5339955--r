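test_that("percent growth inhibition follows blank-subtracted MTT arithmetic", {
  expect_equal(percent_growth_inhibition(0.7, 1.2, 0.2), 50)
  expect_equal(percent_growth_inhibition(1.2, 1.2, 0.2), 0)
  expect_equal(percent_growth_inhibition(0.2, 1.2, 0.2), 100)
  expect_error(percent_growth_inhibition(0.5, 0.2, 0.3), "control")
  # affine invariance: common scale and offset cancel
  set.seed(5)
  for (i in 1:10) {
    ods <- sort(runif(3, 0.1, 2))  # blank < treated < control
    k <- runif(1, 0.5, 3); off <- runif(1, 0, 1)
    expect_equal(percent_growth_inhibition(ods[2], ods[3], ods[1]),
                 percent_growth_inhibition(k * ods[2] + off, k * ods[3] + off,
                                           k * ods[1] + off))
  }
})

test_that("cytotoxicity screen counts strict-threshold exceedances", {
  gi <- read_inhibition_table(endodiv_example("monarda_mtt_gi.tsv"))
  expect_equal(dim(gi), c(28L, 4L))
  s <- cytotoxic_screen_summary(gi, threshold = 50)
  expect_equal(s$all_line_count, 11)
  expect_equal(s$any_line_count, 19)
  expect_equal(s$all_line_fraction, 11 / 28)
  expect_true(all(c("MC-14 L", "MC-24 L", "MC-7 F") %in% s$all_line_active))
  # strict ">": a value exactly at the threshold is inactive
  border <- matrix(c(50, 50, 51, 49), 2, dimnames = list(c("a", "b"), c("x", "y")))
  sb <- cytotoxic_screen_summary(border, 50)
  expect_equal(sb$any_line_count, 1)
  expect_equal(sb$all_line_count, 0)
  z <- cytotoxic_screen_summary(matrix(0, 3, 2), 50)
  expect_equal(c(z$any_line_count, z$all_line_count), c(0, 0))
  expect_error(cytotoxic_screen_summary(matrix(numeric(), 0, 0)), "empty")
})

test_that("all-line active never exceeds any-line active at any threshold", {
  gi <- read_inhibition_table(endodiv_example("monarda_mtt_gi.tsv"))
  for (thr in seq(10, 90, by = 10)) {
    s <- cytotoxic_screen_summary(gi, thr)
    expect_lte(s$all_line_count, s$any_line_count)
  }
})

test_that("4PL fit recovers noise-free parameters and honours censoring", {
  conc <- c(10, 25, 50, 100)
  for (true_ic50 in c(15, 30, 70)) {
    for (hill in c(0.8, 1, 2)) {
      fit <- fit_ic50(conc, logistic4(conc, 0, 100, hill, true_ic50))
      expect_equal(fit$ic50, true_ic50, tolerance = 1e-6)
      expect_equal(fit$censor, "exact")
      expect_equal(fit$method, "logistic4")
      expect_equal(unname(coef(fit)["hill"]), hill, tolerance = 1e-4)
      expect_equal(predict(fit, conc), logistic4(conc, 0, 100, hill, true_ic50),
                   tolerance = 1e-6)
    }
  }
  # an observed point exactly at 50% with monotone neighbours is the IC50
  exact <- fit_ic50(conc, c(30, 50, 70, 90))
  expect_equal(exact$ic50, 25, tolerance = 1e-6)
  # >=50% inhibition at the lowest tested concentration: "<10"
  low <- fit_ic50(conc, c(94, 96, 98, 99))
  expect_equal(low$censor, "below_min")
  expect_equal(low$ic50, 10)
  # still below 50% at the top of the range: ">100"
  high <- fit_ic50(conc, c(5, 10, 20, 40))
  expect_equal(high$censor, "above_max")
  expect_equal(high$ic50, 100)
  expect_error(fit_ic50(25, 50), "at least 2")
  expect_error(fit_ic50(c(10, 10), c(20, 60)), "unique")
  expect_error(fit_ic50(c(0, 10), c(20, 60)), "positive")
})

test_that("IC50 recovery under noise: median relative error below 5%", {
  set.seed(107)
  conc <- c(10, 25, 50, 100)
  n_curves <- 200
  rel_err <- numeric(0)
  censor_ok <- logical(n_curves)
  for (i in seq_len(n_curves)) {
    hill <- runif(1, 0.8, 2)
    ic50 <- runif(1, 12, 80)
    truth <- logistic4(conc, 0, 100, hill, ic50)
    y <- truth + rnorm(length(conc), 0, 2)
    fit <- fit_ic50(conc, y)
    true_censor <- if (truth[1] >= 50) "below_min"
                   else if (truth[length(truth)] < 50) "above_max" else "exact"
    censor_ok[i] <- fit$censor == true_censor
    if (fit$censor == "exact" && true_censor == "exact") {
      rel_err <- c(rel_err, abs(fit$ic50 - ic50) / ic50)
    }
  }
  expect_lt(median(rel_err), 0.05)
  expect_gt(mean(censor_ok), 0.95)
})

test_that("IC50 activity counts respect the NCI cutoff and censoring", {
  ic <- read_ic50_table(endodiv_example("monarda_ic50.tsv"))
  expect_equal(ic$censor["MC-14 L", "A549"], "lt")
  a <- ic50_activity_counts(ic, threshold = 20)
  expect_equal(a$any_line_count, 7)
  expect_equal(unname(a$per_line_count),
               c(5, 6, 4, 6))  # HCT116, A549, PC3, breast
  expect_setequal(a$any_line_active,
                  c("MC-8 L", "MC-14 L", "MC-18 L", "MC-24 L", "MC-25 L",
                    "MC-14 F", "MC-26 F"))
  # a left-censored "<10" bound counts below any threshold >= its bound
  a10 <- ic50_activity_counts(ic, threshold = 10)
  expect_true("MC-14 L" %in% a10$any_line_active)
  expect_false("MC-8 L" %in% a10$any_line_active)
})

test_that("disc-diffusion summary counts recorded zones", {
  zi <- read_zi_table(endodiv_example("monarda_zi.tsv"))
  s <- zi_screen_summary(zi)
  expect_equal(s$overall_active_count, 21)
  expect_equal(s$overall_active_fraction, 0.75)
  expect_equal(unname(s$per_pathogen_count["S. aureus"]), 14)
  expect_equal(unname(s$per_pathogen_fraction["S. aureus"]), 0.5)
  expect_false("MC-1 L" %in% s$overall_active)
  none <- zi_screen_summary(matrix(NA_real_, 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y"))))
  expect_equal(none$overall_active_count, 0)
})

test_that("MIC reading rule handles censoring and invalid wells", {
  series <- c(12.5, 25, 50, 100)
  expect_equal(mic_from_dilution(c(TRUE, FALSE, FALSE, FALSE), series),
               list(value = 25, censor = "exact"))
  expect_equal(mic_from_dilution(rep(TRUE, 4), series),
               list(value = 100, censor = "above_max"))
  expect_equal(mic_from_dilution(rep(FALSE, 4), series),
               list(value = 12.5, censor = "below_min"))
  expect_error(mic_from_dilution(c(TRUE, FALSE, TRUE, FALSE), series),
               "non-monotone")
  expect_error(mic_from_dilution(logical(0), numeric(0)), "empty")
  expect_error(mic_from_dilution(c(TRUE, FALSE), c(25, 12.5)), "ascending")
})

test_that("MIC is non-decreasing when any clear well flips to grown", {
  series <- c(12.5, 25, 50, 100)
  monotone <- lapply(0:4, function(k) rep(c(TRUE, FALSE), c(k, 4 - k)))
  for (g in monotone) {
    base <- mic_from_dilution(g, series)
    for (j in which(!g)) {
      flipped <- g; flipped[j] <- TRUE
      res <- tryCatch(mic_from_dilution(flipped, series), error = function(e) NULL)
      if (!is.null(res)) expect_gte(res$value, base$value)
    }
  }
})

test_that("broth-dilution screen counts uncensored MICs under the cutoff", {
  mic <- read_mic_table(endodiv_example("monarda_mic.tsv"))
  expect_true(mic$mbc["MC-14 L", "S. aureus"])
  expect_equal(mic$censor["MC-2 L", "K. pneumoniae"], "gt")
  s <- mic_screen_summary(mic, cutoff = 100)
  expect_equal(s$overall_active_count, 8)
  expect_equal(unname(s$per_pathogen_count["C. albicans"]), 3)
  expect_setequal(s$overall_active,
                  c("MC-2 L", "MC-8 L", "MC-14 L", "MC-16 L", "MC-18 L",
                    "MC-24 L", "MC-14 F", "MC-22 F"))
  below <- mic_screen_summary(mic, cutoff = 10)
  expect_equal(below$overall_active_count, 0)
})
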