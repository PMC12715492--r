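# shared fixture builders; everything is generated in code

# matched 2x2 from its four cell counts
make_dt <- function(b, c, conc_exp = 0, conc_unexp = 0) {
  discordant_table(
    c(rep(1L, b), rep(0L, c), rep(1L, conc_exp), rep(0L, conc_unexp)),
    c(rep(0L, b), rep(1L, c), rep(1L, conc_exp), rep(0L, conc_unexp)))
}

# half-away-from-zero rounding, the convention of the published tables
round_up <- function(x, digits = 2) floor(x * 10^digits + 0.5) / 10^digits

# cohort with explicit per-pair alt doses: case_doses and ctrl_doses are
# matrices (pairs x SNPs); metadata is filled with valid matching values
build_cohort <- function(case_doses, ctrl_doses, panel = NULL) {
  case_doses <- as.matrix(case_doses); ctrl_doses <- as.matrix(ctrl_doses)
  n <- nrow(case_doses)
  k <- ncol(case_doses)
  if (is.null(panel))
    panel <- snp_panel(paste0("rs", seq_len(k)), rep("GENE", k),
                       rep("A", k), rep("G", k))
  colnames(case_doses) <- colnames(ctrl_doses) <- panel$rsid[seq_len(k)]
  ids <- c(sprintf("case%03d", 1:n), sprintf("ctrl%03d", 1:n))
  meta <- data.frame(patient_id = ids,
                     pair_id = rep(sprintf("P%03d", 1:n), 2),
                     group = rep(c("case", "control"), each = n),
                     sex = "M", age = 65L, stringsAsFactors = FALSE)
  g <- rbind(case_doses, ctrl_doses)
  rownames(g) <- ids
  matched_cohort(meta, g, panel)
}

# panel of the three published scale SNPs
scale3_panel <- function() {
  snp_panel(c("rs4961", "rs1799998", "rs1801133"),
            c("ADD1", "CYP11B2", "MTHFR"),
            c("G", "C", "C"), c("T", "T", "T"))
}

# brute-force maximizer of the 1:1 conditional log-likelihood on a grid;
# independent of the Newton fitter
grid_clogit <- function(d, lower = -5, upper = 5, step = 1e-4) {
  d <- as.matrix(d)
  ll <- function(beta) sum(stats::plogis(drop(d %*% beta), log.p = TRUE))
  if (ncol(d) == 1) {
    grid <- seq(lower, upper, by = step)
    lls <- vapply(grid, ll, 0)
    return(grid[which.max(lls)])
  }
  # two covariates: coarse scan then fine local grid
  coarse <- seq(lower, upper, by = 0.05)
  best <- c(0, 0); best_ll <- -Inf
  for (b2 in coarse) {
    lls <- vapply(coarse, function(b1) ll(c(b1, b2)), 0)
    if (max(lls) > best_ll) { best_ll <- max(lls); best <- c(coarse[which.max(lls)], b2) }
  }
  fine1 <- seq(best[1] - 0.06, best[1] + 0.06, by = step)
  fine2 <- seq(best[2] - 0.06, best[2] + 0.06, by = step)
  for (b2 in fine2) {
    lls <- vapply(fine1, function(b1) ll(c(b1, b2)), 0)
    if (max(lls) > best_ll) { best_ll <- max(lls); best <- c(fine1[which.max(lls)], b2) }
  }
  best
}

# minimal VCF v4.2 text fixture: 3 biallelic records x 4 samples plus one
# multi-allelic record
write_toy_vcf <- function(path, extra_multiallelic = TRUE, drop_gt = FALSE) {
  fmt <- if (drop_gt) "DP" else "GT"
  gval <- function(x) if (drop_gt) "10" else x
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3", "S4"), collapse = "\t"),
    paste(c("1", "100", "rs1", "G", "T", ".", "PASS", ".", fmt,
            gval("0/0"), gval("0/1"), gval("1|1"), gval("./.")), collapse = "\t"),
    paste(c("1", "200", "rs2", "A", "C", ".", "PASS", ".", fmt,
            gval("0/1"), gval("1/0"), gval("0|0"), gval("1/1")), collapse = "\t"),
    paste(c("1", "300", "rs3", "C", "G", ".", "PASS", ".", fmt,
            gval("0/0"), gval("0/0"), gval("0/1"), gval("0/1")), collapse = "\t"))
  if (extra_multiallelic)
    lines <- c(lines,
               paste(c("1", "400", "rs4", "A", "T,C", ".", "PASS", ".", fmt,
                       gval("0/1"), gval("1/2"), gval("0/0"), gval("2/2")),
                     collapse = "\t"))
  writeLines(lines, path)
  path
}
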