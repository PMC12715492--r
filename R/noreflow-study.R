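# Published summary data of the motivating study: a 1:1 matched
# case-control cohort of 80 STEMI patients (40 with the no-reflow
# phenomenon after PCI, 40 without), genotyped at 22 SNPs. Only group-level
# counts were published; the reconstruction helpers below invert them into
# genotype classes where the printed integers identify a unique group size.

#' The 22-SNP panel of the no-reflow study
#'
#' Reference/alternative allele labels as published. Note rs1403543
#' (AGTR2) is treated as diploid autosomal here, following the source
#' analysis, although the gene is biologically X-linked; the frequencies
#' in men should be read with that caveat.
#'
#' @return A \code{\link{snp_panel}} of 22 SNPs.
#' @export
noreflow_panel <- function() {
  p <- noreflow_counts()
  p <- p[p$model == "alt_carrier", ]
  snp_panel(p$rsid, p$gene, p$ref, p$alt)
}

#' Published per-group carrier counts of the no-reflow study
#'
#' One row per SNP x carrier model: the analyzed collapsed variant, its
#' count and printed percentage in the total sample, the control group
#' (phenotype absent) and the case group (phenotype present), the printed
#' McNemar p-value (NA where none was reported), and the number of
#' patients with a missing genotype at that SNP (of 80). Percentages use
#' per-group denominators restricted to determined genotypes.
#'
#' @return Data frame of 44 rows.
#' @export
noreflow_counts <- function() {
  # rsid gene ref alt | model variant total(pct) control(pct) case(pct) p | missing
  txt <- "
rs4961|ADD1|G|T|ref_carrier|GG or GT|67|84|38|95|29|73|0.03|0
rs4961|ADD1|G|T|alt_carrier|GT or TT|39|49|14|35|25|63|0.04|0
rs5443|GNB3|C|T|ref_carrier|CC or CT|74|93|36|90|38|95|0.68|0
rs5443|GNB3|C|T|alt_carrier|CT or TT|49|61|27|68|22|55|0.36|0
rs2070744|eNOS|T|C|ref_carrier|TT or TC|63|80|32|82|31|78|0.77|1
rs2070744|eNOS|T|C|alt_carrier|TC or CC|51|65|22|56|29|73|0.11|1
rs1799983|eNOS|G|T|ref_carrier|GG or GT|63|79|33|83|30|75|0.58|0
rs1799983|eNOS|G|T|alt_carrier|GT or TT|42|53|17|43|25|63|0.13|0
rs5370|EDN1|G|T|ref_carrier|GG or GT|73|96|35|95|38|97|1.00|4
rs5370|EDN1|G|T|alt_carrier|GT or TT|24|32|10|27|14|36|0.45|4
rs4762|AGT|C|T|ref_carrier|CC or CT|76|100|37|100|39|100|NA|1
rs4762|AGT|C|T|alt_carrier|CT or TT|44|56|25|64|19|48|0.19|1
rs699|AGT|T|C|ref_carrier|TT or TC|69|87|31|79|38|95|0.11|4
rs699|AGT|T|C|alt_carrier|TC or CC|32|42|16|43|16|41|0.82|4
rs5186|AGTR1|A|C|ref_carrier|AA or AC|68|89|34|89|34|89|1.00|4
rs5186|AGTR1|A|C|alt_carrier|AC or CC|32|42|19|50|13|34|0.21|4
rs1403543|AGTR2|G|A|ref_carrier|GG or GA|49|62|22|56|27|68|0.30|1
rs1403543|AGTR2|G|A|alt_carrier|GA or AA|51|65|24|62|27|68|0.79|1
rs1799998|CYP11B2|C|T|ref_carrier|CC or CT|63|80|28|72|35|88|0.18|1
rs1799998|CYP11B2|C|T|alt_carrier|CT or TT|52|66|32|82|20|50|0.006|1
rs1799963|F2|G|A|ref_carrier|GG or GA|76|100|40|100|36|100|NA|4
rs1799963|F2|G|A|alt_carrier|GA or AA|3|3.9|3|7.5|0|0|NA|4
rs6025|F5|G|A|ref_carrier|GG or GA|76|100|40|100|36|100|NA|4
rs6025|F5|G|A|alt_carrier|GA or AA|6|7.9|2|5|4|11|0.69|4
rs6046|F7|T|A|ref_carrier|TT or TA|73|94|39|98|34|89|0.25|2
rs6046|F7|T|A|alt_carrier|TA or AA|31|40|19|48|12|32|0.38|2
rs5985|F13|G|T|ref_carrier|GG or GT|68|89|33|83|35|97|0.13|4
rs5985|F13|G|T|alt_carrier|GT or TT|50|66|29|73|21|58|0.48|4
rs1800790|FGB|T|A|ref_carrier|TT or TA|67|92|33|87|34|97|0.37|7
rs1800790|FGB|T|A|alt_carrier|TA or AA|33|45|18|47|15|43|1.00|7
rs1126643|ITGA2|C|T|ref_carrier|CC or CT|61|84|31|79|30|88|0.34|7
rs1126643|ITGA2|C|T|alt_carrier|CT or TT|44|60|21|54|23|68|0.27|7
rs5918|ITGB3|T|C|ref_carrier|TT or TC|74|97|39|98|35|97|1.00|4
rs5918|ITGB3|T|C|alt_carrier|TC or CC|37|49|20|50|17|47|1.00|4
rs1799762|PAI1|5G|4G|ref_carrier|5G5G or 5G4G|50|68|29|74|21|62|0.18|7
rs1799762|PAI1|5G|4G|alt_carrier|5G4G or 4G4G|62|85|34|87|28|82|1.00|7
rs1801133|MTHFR|C|T|ref_carrier|CC or CT|72|92|38|95|34|89|0.68|2
rs1801133|MTHFR|C|T|alt_carrier|CT or TT|38|49|24|60|14|37|0.04|2
rs1801131|MTHFR|A|C|ref_carrier|AA or AC|71|93|37|95|34|92|0.62|4
rs1801131|MTHFR|A|C|alt_carrier|AC or CC|48|63|25|64|23|62|1.00|4
rs1805087|MTR|A|G|ref_carrier|AA or AG|70|96|35|95|35|97|0.56|7
rs1805087|MTR|A|G|alt_carrier|AG or GG|32|44|15|41|17|47|0.50|7
rs1801394|MTRR|A|G|ref_carrier|AA or AG|52|68|28|72|24|63|0.39|3
rs1801394|MTRR|A|G|alt_carrier|AG or GG|66|86|36|92|30|79|0.20|3
"
  d <- utils::read.table(text = txt, sep = "|", strip.white = TRUE,
                         stringsAsFactors = FALSE,
                         col.names = c("rsid", "gene", "ref", "alt", "model",
                                       "variant", "total_count", "total_pct",
                                       "control_count", "control_pct",
                                       "case_count", "case_pct", "p", "missing"))
  d
}

#' Published threshold metrics of the no-reflow genetic scale
#'
#' The scale's confusion-matrix rows at every threshold (positive when
#' score >= threshold), as published: TP/FP/TN/FN and the derived rates,
#' on the 77 patients (38 cases, 39 controls) with complete scale
#' genotypes.
#'
#' @return Data frame, one row per threshold 3..0.
#' @export
noreflow_threshold_table <- function() {
  data.frame(
    threshold = c(3, 2, 1, 0),
    prevalence = c(0.14, 0.47, 0.73, 1.00),
    tp = c(10, 24, 33, 38), fp = c(1, 12, 23, 39),
    tn = c(38, 27, 16, 0), fn = c(28, 14, 5, 0),
    accuracy = c(0.62, 0.66, 0.64, 0.49),
    sensitivity = c(0.26, 0.63, 0.87, 1.00),
    specificity = c(0.97, 0.69, 0.41, 0.00),
    ppv = c(0.91, 0.67, 0.59, 0.49),
    npv = c(0.58, 0.66, 0.76, NA),
    f_score = c(0.41, 0.65, 0.70, 0.66))
}

#' Per-group score distribution of the published scale
#'
#' Recovered from the cumulative TP/FP columns of
#' \code{\link{noreflow_threshold_table}} via
#' \code{\link{distribution_from_metrics}}.
#'
#' @return A \code{\link{score_distribution}} (38 cases, 39 controls).
#' @export
noreflow_score_distribution <- function() {
  distribution_from_metrics(noreflow_threshold_table())
}

# unique group size consistent with both printed percentages; NA when the
# printed integers admit zero or several sizes (the published table is not
# internally consistent for every SNP)
resolve_group_n <- function(dom_count, dom_pct, rec_count, rec_pct, n_max) {
  tol <- function(p) if (p %% 1 == 0) 0.5 else 0.05
  lo <- max(dom_count, rec_count, 1L)
  cand <- lo:n_max
  ok <- abs(100 * dom_count / cand - dom_pct) <= tol(dom_pct) + 1e-9 &
    abs(100 * rec_count / cand - rec_pct) <= tol(rec_pct) + 1e-9 &
    (dom_count + rec_count - cand) >= 0
  n <- cand[ok]
  if (length(n) == 1L) n else NA_integer_
}

#' Reconstructed genotype classes of the no-reflow study
#'
#' For each SNP and each group (control, case, total) attempts to recover
#' the genotype class counts from the published collapsed carrier counts:
#' the group size is inferred from the printed percentages
#' (\code{\link{resolve_group_n}}) and inverted by inclusion-exclusion
#' (\code{\link{counts_from_collapsed}}). Rows where the printed numbers
#' do not identify a unique group size carry NA. Hardy-Weinberg statistics
#' are attached per resolvable row.
#'
#' @return Data frame: rsid, group, n, hom_ref, het, hom_alt, alt_freq,
#'   hwe_chi_square, hwe_p.
#' @export
noreflow_group_genotypes <- function() {
  cnt <- noreflow_counts()
  rsids <- unique(cnt$rsid)
  rows <- lapply(rsids, function(rs) {
    dom <- cnt[cnt$rsid == rs & cnt$model == "ref_carrier", ]
    rec <- cnt[cnt$rsid == rs & cnt$model == "alt_carrier", ]
    one <- function(group, dc, dp, rc, rp, n_max) {
      n <- resolve_group_n(dc, dp, rc, rp, n_max)
      if (is.na(n)) {
        return(data.frame(rsid = rs, group = group, n = NA_integer_,
                          hom_ref = NA_integer_, het = NA_integer_,
                          hom_alt = NA_integer_, alt_freq = NA_real_,
                          hwe_chi_square = NA_real_, hwe_p = NA_real_))
      }
      g <- counts_from_collapsed(n, dc, rc)
      h <- suppressWarnings(hwe_test(g))
      data.frame(rsid = rs, group = group, n = n, hom_ref = g[[1]],
                 het = g[[2]], hom_alt = g[[3]], alt_freq = h$alt_freq,
                 hwe_chi_square = h$chi_square, hwe_p = h$p_value)
    }
    rbind(one("control", dom$control_count, dom$control_pct,
              rec$control_count, rec$control_pct, 40L),
          one("case", dom$case_count, dom$case_pct,
              rec$case_count, rec$case_pct, 40L),
          one("total", dom$total_count, dom$total_pct,
              rec$total_count, rec$total_pct, 80L))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @rdname noreflow_group_genotypes
#' @export
noreflow_total_genotypes <- function() {
  g <- noreflow_group_genotypes()
  g[g$group == "total", setdiff(names(g), "group")]
}

#' Candidate table reconstructed from the published study counts
#'
#' The published association table, reshaped into the candidate-result
#' form that \code{\link{select_snps}} consumes: per-group carrier counts
#' with their inferred denominators, the printed McNemar p-values, the
#' per-SNP missing fraction, and Hardy-Weinberg p-values / total
#' alternative allele frequencies from the genotype reconstruction (NA
#' where not resolvable).
#'
#' @return Data frame, one row per SNP x model.
#' @export
noreflow_candidates <- function() {
  cnt <- noreflow_counts()
  gg <- noreflow_group_genotypes()
  take <- function(rs, grp, col) {
    v <- gg[gg$rsid == rs & gg$group == grp, col]
    if (length(v)) v else NA
  }
  out <- data.frame(
    rsid = cnt$rsid, model = cnt$model,
    carriers_control = cnt$control_count,
    n_control = vapply(cnt$rsid, take, 0, grp = "control", col = "n"),
    carriers_case = cnt$case_count,
    n_case = vapply(cnt$rsid, take, 0, grp = "case", col = "n"),
    mcnemar_p = cnt$p,
    missing_fraction = cnt$missing / 80,
    hwe_p_case = vapply(cnt$rsid, take, 0, grp = "case", col = "hwe_p"),
    hwe_p_control = vapply(cnt$rsid, take, 0, grp = "control", col = "hwe_p"),
    alt_freq_total = vapply(cnt$rsid, take, 0, grp = "total", col = "alt_freq"),
    stringsAsFactors = FALSE)
  # where the group size is unresolvable, fall back to the percentage-implied
  # denominator for the carrier proportion (count / (pct/100)), so risk
  # orientation still follows the printed proportions
  fix <- function(n, count, pct) {
    miss <- is.na(n)
    n[miss] <- ifelse(pct[miss] > 0, round(100 * count[miss] / pct[miss]), NA)
    as.integer(n)
  }
  out$n_control <- fix(out$n_control, cnt$control_count, cnt$control_pct)
  out$n_case <- fix(out$n_case, cnt$case_count, cnt$case_pct)
  rownames(out) <- NULL
  out
}

#' The published no-reflow genetic scale
#'
#' Three SNPs, one point each: rs4961 alternative-allele carriers (GT or
#' TT), rs1799998 reference homozygote (CC), rs1801133 reference
#' homozygote (CC).
#'
#' @return A \code{\link{scale_definition}}.
#' @export
noreflow_scale <- function() {
  scale_definition(list(rs4961 = c(1L, 2L), rs1799998 = 0L, rs1801133 = 0L),
                   panel = noreflow_panel())
}
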