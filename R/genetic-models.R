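#' Binary carrier encodings of a genotype
#'
#' Case-control SNP studies often collapse the three genotype classes into
#' a binary exposure. Two collapses are used here, named by what they test:
#' \describe{
#'   \item{\code{"alt_carrier"}}{1 if the patient carries at least one
#'     alternative allele (dose 1 or 2). Sometimes labelled the "recessive"
#'     model in this design's literature.}
#'   \item{\code{"ref_carrier"}}{1 if the patient carries at least one
#'     reference allele (dose 0 or 1); the corresponding "dominant" label.}
#' }
#' Note this usage differs from conventional dominant/recessive genetic
#' model terminology, which is why the code names the carrier definition.
#'
#' @param dose integer vector of alternative-allele doses (0, 1, 2, or NA).
#' @param model \code{"alt_carrier"} or \code{"ref_carrier"}.
#' @return Integer vector of 0/1 exposures; NA propagates.
#' @examples
#' encode_genotype(0:2, "alt_carrier")  # 0 1 1
#' encode_genotype(0:2, "ref_carrier")  # 1 1 0
#' @export
encode_genotype <- function(dose, model = c("alt_carrier", "ref_carrier")) {
  model <- match.arg(model)
  bad <- !is.na(dose) & !(dose %in% 0:2)
  if (any(bad)) stop_("dose must be 0, 1, 2 or NA")
  if (model == "alt_carrier") as.integer(dose >= 1L) else as.integer(dose <= 1L)
}

#' Genotype class counts for one SNP in one group
#'
#' @param hom_ref,het,hom_alt non-negative counts of reference homozygotes,
#'   heterozygotes and alternative homozygotes.
#' @return Object of class \code{"genotype_counts"} (named integer vector
#'   with attribute \code{n}).
#' @export
genotype_counts <- function(hom_ref, het, hom_alt) {
  x <- c(hom_ref = hom_ref, het = het, hom_alt = hom_alt)
  if (!all(vapply(x, is_count, logical(1))))
    stop_("counts must be non-negative integers")
  structure(as.integer(x), names = names(x), class = "genotype_counts")
}

#' Recover genotype counts from collapsed carrier counts
#'
#' Published association tables often print only the two carrier collapses
#' (patients with >= 1 reference allele, patients with >= 1 alternative
#' allele) per group. Since the two classes overlap exactly in the
#' heterozygotes, inclusion-exclusion inverts them:
#' \code{het = ref_carriers + alt_carriers - n},
#' \code{hom_ref = n - alt_carriers}, \code{hom_alt = n - ref_carriers}.
#'
#' @param n group size (patients with a determined genotype).
#' @param ref_carriers,alt_carriers carrier counts under the two collapses.
#' @return A \code{\link{genotype_counts}}.
#' @examples
#' counts_from_collapsed(40, 38, 14)  # 26 hom_ref, 12 het, 2 hom_alt
#' @export
counts_from_collapsed <- function(n, ref_carriers, alt_carriers) {
  if (!is_count(n) || !is_count(ref_carriers) || !is_count(alt_carriers))
    stop_("n and carrier counts must be non-negative integers")
  if (ref_carriers > n || alt_carriers > n) stop_("carrier count exceeds n")
  het <- ref_carriers + alt_carriers - n
  if (het < 0)
    stop_("inconsistent collapsed counts: ref_carriers + alt_carriers < n")
  genotype_counts(n - alt_carriers, het, n - ref_carriers)
}

#' Alternative allele frequency from genotype counts
#'
#' @param counts a \code{\link{genotype_counts}} (or a length-3 vector of
#'   hom_ref, het, hom_alt counts).
#' @return Frequency in \[0, 1\].
#' @export
alt_allele_frequency <- function(counts) {
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n == 0) stop_("empty genotype counts")
  (counts[2] + 2 * counts[3]) / (2 * n)
}

#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Compares the observed genotype counts with the expectations
#' \eqn{n((1-q)^2, 2q(1-q), q^2)} at the observed alternative-allele
#' frequency \eqn{q}, using a 1-df Pearson chi-square without continuity
#' correction. A warning is raised when any expected class count falls
#' below 5 (the usual validity caveat for the asymptotic test). For a
#' monomorphic SNP (\eqn{q} of 0 or 1) there is nothing to test; the
#' statistic is 0 and p is 1, with a warning.
#'
#' @param counts a \code{\link{genotype_counts}} (or length-3 count vector).
#' @return Object of class \code{"hwe_test"}: list with \code{chi_square},
#'   \code{p_value}, \code{expected} (length-3), \code{alt_freq}, \code{n}.
#' @examples
#' hwe_test(genotype_counts(23, 10, 7))   # deviates, p ~ 0.010
#' hwe_test(genotype_counts(25, 50, 25))  # exact HWE proportions, p = 1
#' @export
hwe_test <- function(counts) {
  counts <- as.integer(counts)
  if (length(counts) != 3L || any(is.na(counts)) || any(counts < 0))
    stop_("counts must be 3 non-negative integers")
  n <- sum(counts)
  if (n == 0) stop_("empty genotype counts")
  q <- alt_allele_frequency(counts)
  if (q == 0 || q == 1) {
    warn_("monomorphic SNP: Hardy-Weinberg test is uninformative")
    expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
    return(structure(list(chi_square = 0, p_value = 1, expected = expected,
                          alt_freq = q, n = n), class = "hwe_test"))
  }
  expected <- n * c((1 - q)^2, 2 * q * (1 - q), q^2)
  if (any(expected < 5))
    warn_("expected genotype count < 5; chi-square approximation may be poor")
  chi2 <- sum((counts - expected)^2 / expected)
  structure(list(chi_square = chi2,
                 p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
                 expected = expected, alt_freq = q, n = n),
            class = "hwe_test")
}

#' @export
print.hwe_test <- function(x, ...) {
  cat(sprintf("Hardy-Weinberg chi-square test: X^2 = %.3f (1 df), p = %.4g\n",
              x$chi_square, x$p_value))
  cat(sprintf("  n = %d, alt allele frequency = %.3f\n", x$n, x$alt_freq))
  invisible(x)
}

#' Per-SNP, per-group genotype summary of a cohort
#'
#' For each SNP in the cohort and each group separately (plus the total
#' sample), tabulates the genotype classes, the alternative allele
#' frequency, and the Hardy-Weinberg chi-square test.
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @return Data frame with one row per SNP x group (\code{"case"},
#'   \code{"control"}, \code{"total"}): genotype counts, \code{n},
#'   \code{alt_freq}, \code{hwe_chi_square}, \code{hwe_p}.
#' @export
group_genotype_summary <- function(cohort) {
  groups <- list(case = cohort$meta$patient_id[cohort$meta$group == "case"],
                 control = cohort$meta$patient_id[cohort$meta$group == "control"],
                 total = cohort$meta$patient_id)
  rows <- lapply(colnames(cohort$genotypes), function(rs) {
    do.call(rbind, lapply(names(groups), function(gname) {
      g <- cohort$genotypes[groups[[gname]], rs]
      g <- g[!is.na(g)]
      cnt <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      if (sum(cnt) == 0) {
        return(data.frame(rsid = rs, group = gname, hom_ref = 0L, het = 0L,
                          hom_alt = 0L, n = 0L, alt_freq = NA_real_,
                          hwe_chi_square = NA_real_, hwe_p = NA_real_))
      }
      h <- suppressWarnings(hwe_test(cnt))
      data.frame(rsid = rs, group = gname, hom_ref = cnt[1], het = cnt[2],
                 hom_alt = cnt[3], n = sum(cnt), alt_freq = h$alt_freq,
                 hwe_chi_square = h$chi_square, hwe_p = h$p_value)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
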