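test_that("discordant_table counts cells correctly", {
  t1 <- discordant_table(c(1, 0, 1), c(0, 1, 1))
  expect_equal(c(t1$b, t1$c, t1$conc_exposed, t1$conc_unexposed), c(1, 1, 1, 0))
  t2 <- discordant_table(c(1, 1, 0), c(1, 1, 0))
  expect_equal(c(t2$b, t2$c), c(0, 0))
  expect_error(discordant_table(c(1, NA), c(0, 1)), "pairwise deletion")
  expect_error(discordant_table(c(2, 0), c(0, 1)), "binary")

  # brute-force recount oracle on a random 40-pair cohort
  set.seed(9)
  ce <- rbinom(40, 1, 0.6); co <- rbinom(40, 1, 0.4)
  tab <- discordant_table(ce, co)
  brute <- c(b = 0, c = 0, ce = 0, cu = 0)
  for (i in 1:40) {
    if (ce[i] == 1 && co[i] == 0) brute["b"] <- brute["b"] + 1
    if (ce[i] == 0 && co[i] == 1) brute["c"] <- brute["c"] + 1
    if (ce[i] == 1 && co[i] == 1) brute["ce"] <- brute["ce"] + 1
    if (ce[i] == 0 && co[i] == 0) brute["cu"] <- brute["cu"] + 1
  }
  expect_equal(c(tab$b, tab$c, tab$conc_exposed, tab$conc_unexposed),
               unname(brute))
  expect_equal(tab$b + tab$c + tab$conc_exposed + tab$conc_unexposed,
               tab$n_pairs)
})

test_that("McNemar variants reproduce the published p-values after rounding", {
  # discordant splits reconstructed from the published ORs and intervals
  cases <- list(list(b = 16, c = 3, p2 = 0.006),
                list(b = 17, c = 6, p2 = 0.04),
                list(b = 12, c = 3, p2 = 0.04))
  for (cs in cases) {
    m <- mcnemar_test(make_dt(cs$b, cs$c))
    expect_equal(round_up(m$p_value, 3 - (cs$p2 >= 0.01)), cs$p2)
  }
  # continuity-corrected statistic for (16, 3): (13 - 1)^2 / 19
  m <- mcnemar_test(make_dt(16, 3))
  expect_equal(m$statistic, 144 / 19)
  expect_equal(m$p_value, pchisq(144 / 19, 1, lower.tail = FALSE))

  # uncorrected variant
  m2 <- mcnemar_test(make_dt(16, 3), method = "asymptotic")
  expect_equal(m2$statistic, 169 / 19)

  # balanced discordance is exactly uninformative for the exact test
  expect_equal(mcnemar_test(make_dt(5, 5), method = "exact_central")$p_value, 1)

  expect_warning(m0 <- mcnemar_test(make_dt(0, 0, conc_exp = 4)), "no discordant")
  expect_equal(m0$p_value, 1)
})

test_that("McNemar is symmetric in b and c; exact test is conservative on the study fixtures", {
  for (meth in c("asymptotic_cc", "asymptotic", "exact_central")) {
    for (bc in list(c(16, 3), c(17, 6), c(12, 3), c(4, 4))) {
      p1 <- mcnemar_test(make_dt(bc[1], bc[2]), meth)$p_value
      p2 <- mcnemar_test(make_dt(bc[2], bc[1]), meth)$p_value
      expect_equal(p1, p2)
    }
  }
  for (bc in list(c(16, 3), c(17, 6), c(12, 3))) {
    p_exact <- mcnemar_test(make_dt(bc[1], bc[2]), "exact_central")$p_value
    p_asym <- mcnemar_test(make_dt(bc[1], bc[2]), "asymptotic")$p_value
    expect_gte(p_exact, p_asym)
  }
})

test_that("discordant-pair odds ratios reproduce every published interval at 2 decimals", {
  fixtures <- list(
    list(b = 17, c = 6, or = 2.83, lo = 1.12, hi = 7.19),
    list(b = 16, c = 3, or = 5.33, lo = 1.55, hi = 18.30),
    list(b = 12, c = 3, or = 4.00, lo = 1.13, hi = 14.17),
    list(b = 10, c = 1, or = 10.00, lo = 1.28, hi = 78.12))
  for (f in fixtures) {
    e <- conditional_or(make_dt(f$b, f$c))
    expect_equal(round_up(e$odds_ratio), f$or)
    expect_equal(round_up(e$ci_low), f$lo)
    expect_equal(round_up(e$ci_high), f$hi)
    expect_true(e$ci_low <= e$odds_ratio && e$odds_ratio <= e$ci_high)
  }
})

test_that("OR interval widens monotonically with the confidence level", {
  tab <- make_dt(12, 3)
  widths <- vapply(c(0.8, 0.9, 0.95, 0.99), function(lv) {
    e <- conditional_or(tab, level = lv)
    log(e$ci_high) - log(e$ci_low)
  }, 0)
  expect_true(all(diff(widths) > 0))
})

test_that("zero discordant cells error unless the Haldane correction is requested", {
  expect_error(conditional_or(make_dt(5, 0)), "haldane")
  expect_warning(e <- conditional_or(make_dt(5, 0), haldane = TRUE), "Haldane")
  expect_equal(e$odds_ratio, 5.5 / 0.5)
})

test_that("association_table lays out both models per SNP with group counts", {
  coh <- build_cohort(matrix(c(1L, 1L, 2L, 0L, 1L), 5, 1),
                      matrix(c(0L, 0L, 1L, 0L, 0L), 5, 1))
  at <- association_table(coh, or = TRUE)
  expect_equal(nrow(at), 2L)
  rec <- at[at$model == "alt_carrier", ]
  expect_equal(rec$carriers_case, 4L)
  expect_equal(rec$carriers_control, 1L)
  expect_equal(c(rec$b, rec$c), c(3L, 0L))
  # snp_discordant_table agrees
  tab <- snp_discordant_table(coh, coh$panel$rsid[1], "alt_carrier")
  expect_equal(c(tab$b, tab$c), c(3L, 0L))
})
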