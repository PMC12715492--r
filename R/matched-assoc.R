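#' Matched-pair 2x2 table for a binary exposure
#'
#' Cross-classifies each complete case-control pair by exposure of its two
#' members. The information for matched tests lives in the discordant
#' cells: \code{b} (case exposed, control not) and \code{c} (control
#' exposed, case not).
#'
#' @param case_exposure,control_exposure 0/1 vectors aligned by pair (the
#'   caller restricts to pairs with complete data, e.g. via
#'   \code{\link{complete_pairs}}; missing values are an error here).
#' @return Object of class \code{"discordant_table"}: list with counts
#'   \code{b}, \code{c}, \code{conc_exposed}, \code{conc_unexposed} and
#'   \code{n_pairs}.
#' @examples
#' discordant_table(c(1, 0, 1), c(0, 1, 1))  # b = 1, c = 1, 1 concordant exposed
#' @export
discordant_table <- function(case_exposure, control_exposure) {
  if (length(case_exposure) != length(control_exposure))
    stop_("exposure vectors must be aligned by pair (equal length)")
  if (anyNA(case_exposure) || anyNA(control_exposure))
    stop_("missing exposure: apply pairwise deletion (complete_pairs) first")
  if (!all(case_exposure %in% 0:1) || !all(control_exposure %in% 0:1))
    stop_("exposures must be binary 0/1")
  structure(list(b = sum(case_exposure == 1 & control_exposure == 0),
                 c = sum(case_exposure == 0 & control_exposure == 1),
                 conc_exposed = sum(case_exposure == 1 & control_exposure == 1),
                 conc_unexposed = sum(case_exposure == 0 & control_exposure == 0),
                 n_pairs = length(case_exposure)),
            class = "discordant_table")
}

#' @export
print.discordant_table <- function(x, ...) {
  cat(sprintf("Matched 2x2: b = %d, c = %d (discordant), %d / %d concordant exposed/unexposed\n",
              x$b, x$c, x$conc_exposed, x$conc_unexposed))
  invisible(x)
}

#' Matched 2x2 table for one SNP under a carrier model
#'
#' Convenience wrapper: encodes the SNP under the chosen carrier model,
#' deletes pairs with a missing call pairwise, and tabulates.
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param rsid SNP identifier.
#' @param model carrier model, see \code{\link{encode_genotype}}.
#' @return A \code{\link{discordant_table}}.
#' @export
snp_discordant_table <- function(cohort, rsid,
                                 model = c("alt_carrier", "ref_carrier")) {
  model <- match.arg(model)
  pr <- complete_pairs(cohort, rsid)
  g <- cohort$genotypes[, rsid]
  discordant_table(encode_genotype(g[pr$case_id], model),
                   encode_genotype(g[pr$control_id], model))
}

#' McNemar test on a matched 2x2 table
#'
#' Tests marginal homogeneity using only the discordant counts \code{b}
#' and \code{c}. Methods:
#' \describe{
#'   \item{\code{"asymptotic_cc"}}{(default) continuity-corrected
#'     chi-square \eqn{(|b-c|-1)^2/(b+c)}, 1 df.}
#'   \item{\code{"asymptotic"}}{uncorrected \eqn{(b-c)^2/(b+c)}.}
#'   \item{\code{"exact_central"}}{central binomial test,
#'     \eqn{p = \min(1, 2 P(X \le \min(b,c)))} with
#'     \eqn{X \sim Bin(b+c, 1/2)}.}
#' }
#'
#' @param table a \code{\link{discordant_table}}.
#' @param method test variant, see Details.
#' @return Object of class \code{"mcnemar_result"}: list with
#'   \code{method}, \code{statistic} (NA for the exact test),
#'   \code{p_value}, \code{b}, \code{c}.
#' @examples
#' mcnemar_test(discordant_table(c(rep(1, 16), rep(0, 3)),
#'                               c(rep(0, 16), rep(1, 3))))  # p ~ 0.006
#' @export
mcnemar_test <- function(table,
                         method = c("asymptotic_cc", "asymptotic", "exact_central")) {
  stopifnot(inherits(table, "discordant_table"))
  method <- match.arg(method)
  b <- table$b; cc <- table$c
  if (b + cc == 0) {
    warn_("no discordant pairs: McNemar test is uninformative")
    return(structure(list(method = method, statistic = NA_real_, p_value = 1,
                          b = b, c = cc), class = "mcnemar_result"))
  }
  if (method == "exact_central") {
    p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
    stat <- NA_real_
  } else {
    stat <- if (method == "asymptotic_cc") (abs(b - cc) - 1)^2 / (b + cc)
            else (b - cc)^2 / (b + cc)
    stat <- max(stat, 0)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  structure(list(method = method, statistic = stat, p_value = p,
                 b = b, c = cc), class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  if (is.na(x$statistic))
    cat(sprintf("McNemar exact (central) test: b = %d, c = %d, p = %.4g\n",
                x$b, x$c, x$p_value))
  else
    cat(sprintf("McNemar test (%s): X^2 = %.3f, b = %d, c = %d, p = %.4g\n",
                x$method, x$statistic, x$b, x$c, x$p_value))
  invisible(x)
}

#' Conditional (discordant-pair) odds ratio with Wald confidence interval
#'
#' For a 1:1 matched design the conditional maximum-likelihood odds ratio
#' for a binary exposure is \eqn{b/c}, with log-scale Wald interval
#' \eqn{\exp(\log(b/c) \pm z \sqrt{1/b + 1/c})}.
#'
#' @param table a \code{\link{discordant_table}}.
#' @param level confidence level (default 0.95).
#' @param haldane if TRUE, add 0.5 to both discordant cells when either is
#'   zero (Haldane-Anscombe correction) instead of failing; a warning is
#'   raised.
#' @return Object of class \code{"or_estimate"}: list with
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{level},
#'   \code{p_value} (from the default McNemar test on the same table).
#' @examples
#' conditional_or(discordant_table(c(rep(1, 16), rep(0, 3)),
#'                                 c(rep(0, 16), rep(1, 3))))  # OR 5.33
#' @export
conditional_or <- function(table, level = 0.95, haldane = FALSE) {
  stopifnot(inherits(table, "discordant_table"))
  check_prob(level, "level")
  b <- table$b; cc <- table$c
  if (b == 0 || cc == 0) {
    if (!haldane)
      stop_("zero discordant cell (b = ", b, ", c = ", cc,
            "): odds ratio undefined; set haldane = TRUE for a 0.5 correction")
    warn_("zero discordant cell: applying Haldane-Anscombe 0.5 correction")
    b <- b + 0.5; cc <- cc + 0.5
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  lor <- log(b / cc)
  se <- sqrt(1 / b + 1 / cc)
  p <- mcnemar_test(table)$p_value
  new_or_estimate(exp(lor), exp(lor - z * se), exp(lor + z * se), level, p)
}

new_or_estimate <- function(or, lo, hi, level, p = NA_real_) {
  structure(list(odds_ratio = or, ci_low = lo, ci_high = hi,
                 level = level, p_value = p), class = "or_estimate")
}

#' @export
print.or_estimate <- function(x, digits = 2, ...) {
  cat(sprintf("OR %.*f (%.0f%% CI %.*f-%.*f)", digits, x$odds_ratio,
              100 * x$level, digits, x$ci_low, digits, x$ci_high))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  cat("\n")
  invisible(x)
}

#' Per-SNP matched association table
#'
#' Builds the familiar published-table shape: one row per SNP x carrier
#' model with per-group carrier counts and percentages (denominators are
#' the patients with a determined genotype in that group), the McNemar
#' p-value on complete pairs, and (optionally) the discordant-pair odds
#' ratio with confidence interval.
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param method McNemar variant, see \code{\link{mcnemar_test}}.
#' @param or if TRUE add OR and CI columns (NA when a discordant cell is 0).
#' @param level confidence level for the OR interval.
#' @return Data frame with one row per SNP x model.
#' @export
association_table <- function(cohort, method = "asymptotic_cc", or = FALSE,
                              level = 0.95) {
  case_ids <- cohort$meta$patient_id[cohort$meta$group == "case"]
  ctrl_ids <- cohort$meta$patient_id[cohort$meta$group == "control"]
  rows <- lapply(colnames(cohort$genotypes), function(rs) {
    do.call(rbind, lapply(c("ref_carrier", "alt_carrier"), function(m) {
      g <- cohort$genotypes[, rs]
      e_case <- encode_genotype(g[case_ids], m)
      e_ctrl <- encode_genotype(g[ctrl_ids], m)
      tab <- snp_discordant_table(cohort, rs, m)
      mc <- if (tab$b + tab$c > 0) mcnemar_test(tab, method)$p_value else NA_real_
      row <- data.frame(rsid = rs, model = m,
                        carriers_total = sum(c(e_case, e_ctrl), na.rm = TRUE),
                        n_total = sum(!is.na(c(e_case, e_ctrl))),
                        carriers_control = sum(e_ctrl, na.rm = TRUE),
                        n_control = sum(!is.na(e_ctrl)),
                        carriers_case = sum(e_case, na.rm = TRUE),
                        n_case = sum(!is.na(e_case)),
                        b = tab$b, c = tab$c, mcnemar_p = mc)
      if (or) {
        est <- if (tab$b > 0 && tab$c > 0) conditional_or(tab, level) else
          new_or_estimate(NA_real_, NA_real_, NA_real_, level)
        row$odds_ratio <- est$odds_ratio
        row$ci_low <- est$ci_low
        row$ci_high <- est$ci_high
      }
      row
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
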