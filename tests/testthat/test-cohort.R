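pair_fixture_files <- function(dir, ages = c(65L, 66L), dup = FALSE) {
  meta <- data.frame(patient_id = c("p1", "p2"),
                     pair_id = "P1", group = c("case", "control"),
                     sex = "M", age = ages)
  if (dup) meta$patient_id <- c("p1", "p1")
  gt <- data.frame(patient_id = meta$patient_id, rs4961 = c("G/T", "G/G"))
  mf <- file.path(dir, "meta.tsv"); gf <- file.path(dir, "geno.tsv")
  write.table(meta, mf, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gt, gf, sep = "\t", quote = FALSE, row.names = FALSE)
  list(meta = mf, geno = gf)
}

test_that("read_cohort parses genotype pairs and enforces matching invariants", {
  dir <- withr::local_tempdir()
  panel <- snp_panel("rs4961", "ADD1", "G", "T")
  f <- pair_fixture_files(dir)
  coh <- read_cohort(f$geno, f$meta, panel)
  expect_equal(nrow(coh$pairs), 1L)
  expect_equal(unname(coh$genotypes[c("p1", "p2"), "rs4961"]), c(1L, 0L))

  f2 <- pair_fixture_files(dir, ages = c(60L, 70L))
  expect_error(read_cohort(f2$geno, f2$meta, panel), "P1")

  f3 <- pair_fixture_files(dir, dup = TRUE)
  expect_error(read_cohort(f3$geno, f3$meta, panel), "duplicate patient_id")
})

test_that("genotype strings are order-insensitive and off-panel alleles become missing", {
  p <- grscale:::parse_genotype_strings(c("G/T", "T/G", "T|T", "NA", "./.", "G/A"), "G", "T")
  expect_equal(as.integer(p), c(1L, 1L, 2L, NA, NA, NA))
  expect_equal(attr(p, "n_unparseable"), 1L)

  dir <- withr::local_tempdir()
  panel <- snp_panel("rs4961", "ADD1", "G", "T")
  meta <- data.frame(patient_id = c("p1", "p2"), pair_id = "P1",
                     group = c("case", "control"), sex = "F", age = c(70L, 72L))
  gt <- data.frame(patient_id = c("p1", "p2"), rs4961 = c("G/X", "T/G"))
  write.table(meta, file.path(dir, "m.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(gt, file.path(dir, "g.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(
    coh <- read_cohort(file.path(dir, "g.tsv"), file.path(dir, "m.tsv"), panel),
    "outside the panel")
  expect_true(is.na(coh$genotypes["p1", "rs4961"]))
})

test_that("missingness counts injected missing calls and complete_pairs deletes pairwise", {
  set.seed(11)
  coh <- build_cohort(matrix(1L, 40, 1), matrix(0L, 40, 1))
  rs <- coh$panel$rsid[1]
  expect_equal(missingness(coh, rs), 0)
  expect_equal(nrow(complete_pairs(coh, rs)), 40L)

  # exactly 3 of 80 missing -> 0.0375 (a 4% report); 7 of 80 -> 0.0875 (9%)
  coh3 <- coh; coh3$genotypes[c(1, 15, 44), rs] <- NA_integer_
  expect_equal(missingness(coh3, rs), 0.0375)
  coh7 <- coh; coh7$genotypes[c(1, 2, 15, 41, 44, 60, 80), rs] <- NA_integer_
  expect_equal(missingness(coh7, rs), 0.0875)

  # one missing control member drops exactly that pair
  coh1 <- coh; coh1$genotypes[41, rs] <- NA_integer_  # control of pair 1
  expect_equal(nrow(complete_pairs(coh1, rs)), 39L)

  # complement identity: complete pairs + pairs with any missing = all pairs
  any_missing <- sum(is.na(coh7$genotypes[coh7$pairs$case_id, rs]) |
                       is.na(coh7$genotypes[coh7$pairs$control_id, rs]))
  expect_equal(nrow(complete_pairs(coh7, rs)) + any_missing, nrow(coh7$pairs))

  expect_error(missingness(coh, "rs999"), "unknown rsid")
})

test_that("expected pair retention under MCAR is about (1 - rate)^2", {
  set.seed(42)
  coh <- build_cohort(matrix(1L, 40, 1), matrix(0L, 40, 1))
  rs <- coh$panel$rsid[1]
  kept <- replicate(1000, {
    c2 <- inject_missing(coh, stats::setNames(0.05, rs))
    nrow(complete_pairs(c2, rs)) / 40
  })
  expect_equal(mean(kept), 0.95^2, tolerance = 0.01)
})

test_that("write_cohort / read_cohort round-trips doses and pair structure", {
  set.seed(5)
  coh <- simulate_cohort(n_pairs = 15, seed = 5)
  dir <- withr::local_tempdir()
  gf <- file.path(dir, "g.tsv"); mf <- file.path(dir, "m.tsv")
  write_cohort(coh, gf, mf)
  back <- read_cohort(gf, mf, coh$panel)
  expect_identical(back$genotypes[rownames(coh$genotypes), colnames(coh$genotypes)],
                   coh$genotypes)
  expect_identical(back$pairs[order(back$pairs$pair_id), ],
                   coh$pairs[order(coh$pairs$pair_id), ])
})

test_that("VCF genotypes agree with the tabular encoding of the same calls", {
  dir <- withr::local_tempdir()
  vcf <- write_toy_vcf(file.path(dir, "toy.vcf"))
  expect_warning(d <- read_vcf_genotypes(vcf), "multi-allelic")
  expect_equal(dim(d), c(3L, 4L))
  expect_equal(unname(d["rs1", ]), c(0L, 1L, 2L, NA))   # 1|1 phased accepted
  expect_equal(unname(d["rs2", ]), c(1L, 1L, 0L, 2L))   # 1/0 == 0/1
  expect_equal(sum(is.na(d)), 1L)

  # same genotypes via the string parser
  expect_equal(as.integer(grscale:::parse_genotype_strings(c("G/G", "G/T", "T/T", "NA"), "G", "T")),
               unname(d["rs1", ]))

  # sample subset and missing-GT error
  d2 <- suppressWarnings(read_vcf_genotypes(vcf, samples = c("S2", "S1")))
  expect_equal(colnames(d2), c("S2", "S1"))
  vcf2 <- write_toy_vcf(file.path(dir, "nogt.vcf"), drop_gt = TRUE)
  expect_error(suppressWarnings(read_vcf_genotypes(vcf2)), "GT")
})
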