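# a minimal candidate row, overridable per test
cand_row <- function(rsid = "rsX", model = "alt_carrier", p = 0.01,
                     cc = 10, nc = 40, ca = 25, na_ = 40, miss = 0,
                     hwe_case = 0.5, hwe_ctrl = 0.5, af = 0.3) {
  data.frame(rsid = rsid, model = model, carriers_control = cc,
             n_control = nc, carriers_case = ca, n_case = na_,
             mcnemar_p = p, missing_fraction = miss, hwe_p_case = hwe_case,
             hwe_p_control = hwe_ctrl, alt_freq_total = af,
             stringsAsFactors = FALSE)
}

test_that("risk orientation points at the class over-represented in cases", {
  # rs4961: alt carriers 63% of cases vs 35% of controls -> carriers at risk
  expect_equal(orient_risk("alt_carrier", 25 / 40, 14 / 40), c(1L, 2L))
  # rs1799998: alt carriers 50% vs 82% -> the complement (reference homozygote)
  expect_equal(orient_risk("alt_carrier", 20 / 40, 32 / 39), 0L)
  expect_equal(orient_risk("ref_carrier", 0.9, 0.5), c(0L, 1L))
  expect_error(orient_risk("alt_carrier", 0.5, 0.5), "orientation undefined")
})

test_that("the filter cascade on the published candidate table selects the published scale", {
  sc <- select_snps(noreflow_candidates(), panel = noreflow_panel())
  expect_setequal(sc$components$rsid, c("rs4961", "rs1799998", "rs1801133"))
  expect_equal(sc$risk$rs4961, c(1L, 2L))
  expect_equal(sc$risk$rs1799998, 0L)
  expect_equal(sc$risk$rs1801133, 0L)
  expect_equal(sc$components$label[sc$components$rsid == "rs4961"], "GT or TT")
  expect_equal(sc$components$label[sc$components$rsid == "rs1799998"], "CC")
  # all selections came from the alt-carrier model, as preferred
  expect_true(all(sc$components$model == "alt_carrier"))
  # audit trail covers every SNP once
  expect_equal(nrow(sc$audit), 22L)
  expect_equal(sum(sc$audit$selected), 3L)
})

test_that("selection is order-independent in the candidate list", {
  set.seed(2)
  cand <- noreflow_candidates()
  shuffled <- cand[sample.int(nrow(cand)), ]
  s1 <- select_snps(cand)
  s2 <- select_snps(shuffled)
  expect_equal(s1$components, s2$components)
})

test_that("each exclusion filter acts as specified", {
  expect_equal(nrow(select_snps(cand_row(p = 0.20))$components), 0L)
  expect_equal(nrow(select_snps(cand_row(miss = 0.09))$components), 0L)
  expect_equal(nrow(select_snps(cand_row(hwe_ctrl = 0.01))$components), 0L)
  expect_equal(nrow(select_snps(cand_row(hwe_case = 0.05))$components), 0L)  # at threshold
  expect_equal(nrow(select_snps(cand_row(af = 0.03))$components), 0L)
  expect_equal(nrow(select_snps(cand_row())$components), 1L)
  # NA filter values do not exclude
  expect_equal(nrow(select_snps(cand_row(hwe_case = NA, af = NA))$components), 1L)
  # alt-carrier preferred when both models are significant
  both <- rbind(cand_row(model = "ref_carrier", cc = 38, ca = 29),
                cand_row(model = "alt_carrier", cc = 14, ca = 25))
  expect_equal(select_snps(both)$components$model, "alt_carrier")
})

test_that("scores sum one point per risk genotype and go missing with any component", {
  coh <- build_cohort(
    rbind(c(1L, 0L, 1L),   # GT, CC, CT -> 1 + 1 + 0 = 2
          c(0L, 1L, 1L),   # all non-risk -> 0
          c(2L, 0L, 0L)),  # TT, CC, CC -> 3
    rbind(c(NA, 0L, 0L),   # missing component -> NA
          c(0L, 0L, 0L),   # GG, CC, CC -> 2
          c(1L, 1L, 1L)),  # 1
    panel = scale3_panel())
  s <- compute_scores(coh, noreflow_scale())
  expect_equal(unname(s$scores[c("case001", "case002", "case003")]), c(2L, 0L, 3L))
  expect_true(is.na(s$scores[["ctrl001"]]))
  expect_equal(unname(s$scores[c("ctrl002", "ctrl003")]), c(2L, 1L))
  expect_equal(s$n_scored, 5L)

  # monotonicity: moving any single component into its risk class never lowers a score
  sc <- noreflow_scale()
  for (j in 1:3) {
    coh2 <- coh
    rs <- sc$components$rsid[j]
    risk_dose <- sc$risk[[rs]][1]
    coh2$genotypes["case002", rs] <- risk_dose
    s2 <- compute_scores(coh2, sc)
    expect_gte(s2$scores[["case002"]], s$scores[["case002"]])
  }

  bad <- scale_definition(list(rs999 = 0L))
  expect_error(compute_scores(coh, bad), "absent from cohort panel")
})

test_that("scale definitions serialize to JSON and back", {
  dir <- withr::local_tempdir()
  sc <- noreflow_scale()
  write_scale(sc, file.path(dir, "scale.json"))
  back <- read_scale(file.path(dir, "scale.json"))
  expect_equal(back$risk[order(names(back$risk))], sc$risk[order(names(sc$risk))])
})
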