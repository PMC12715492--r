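#' Candidate association results for scale building
#'
#' Produces one row per SNP x carrier model holding everything the filter
#' cascade needs: per-group carrier counts and denominators, the McNemar
#' p-value (complete pairs), the per-SNP missing fraction, per-group
#' Hardy-Weinberg p-values, and the total-sample alternative allele
#' frequency.
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param method McNemar variant used for the significance screen.
#' @return Data frame of candidate results.
#' @export
candidate_table <- function(cohort, method = "asymptotic_cc") {
  assoc <- association_table(cohort, method = method)
  gsum <- group_genotype_summary(cohort)
  per_snp <- lapply(colnames(cohort$genotypes), function(rs) {
    rows <- assoc[assoc$rsid == rs, ]
    g <- gsum[gsum$rsid == rs, ]
    hwe_case <- g$hwe_p[g$group == "case"]
    hwe_ctrl <- g$hwe_p[g$group == "control"]
    alt_tot <- g$alt_freq[g$group == "total"]
    rows$missing_fraction <- missingness(cohort, rs)
    rows$hwe_p_case <- hwe_case
    rows$hwe_p_control <- hwe_ctrl
    rows$alt_freq_total <- alt_tot
    rows
  })
  out <- do.call(rbind, per_snp)
  rownames(out) <- NULL
  out
}

carrier_doses <- function(model) {
  switch(model, alt_carrier = c(1L, 2L), ref_carrier = c(0L, 1L),
         stop_("unknown model: ", model))
}

#' Orient a significant SNP towards the risk genotypes
#'
#' A carrier model splits genotypes into two classes; the class
#' over-represented among cases is the one scoring a point. The predicate
#' is returned as the set of alternative-allele doses it contains: e.g.
#' \code{c(1, 2)} for "carries the alternative allele", \code{0} for the
#' reference homozygote.
#'
#' @param model carrier model of the candidate (\code{"alt_carrier"} or
#'   \code{"ref_carrier"}).
#' @param prop_case,prop_control carrier proportions among cases and
#'   controls under that model.
#' @return Integer vector of risk doses.
#' @examples
#' orient_risk("alt_carrier", 25 / 40, 14 / 40)  # c(1, 2): carriers at risk
#' orient_risk("alt_carrier", 20 / 40, 32 / 39)  # 0: non-carriers at risk
#' @export
orient_risk <- function(model, prop_case, prop_control) {
  if (is.na(prop_case) || is.na(prop_control))
    stop_("carrier proportions must be computable in both groups")
  if (prop_case == prop_control)
    stop_("equal carrier proportions in cases and controls: orientation undefined")
  carrier <- carrier_doses(model)
  if (prop_case > prop_control) carrier else setdiff(0:2, carrier)
}

#' Build a point-scale definition from candidate results
#'
#' Implements the selection cascade: keep SNPs whose McNemar p-value is
#' below \code{p_threshold} in at least one carrier model; exclude SNPs
#' with missingness above \code{max_missing}, Hardy-Weinberg p at or below
#' \code{hwe_threshold} in either group, or total-sample alternative
#' allele frequency below \code{min_alt_freq}. When both models of a SNP
#' are significant the \code{alt_carrier} model is preferred. Each
#' selected SNP contributes one unweighted point, awarded for the
#' risk-oriented genotype class (see \code{\link{orient_risk}}).
#'
#' Filters only act on evidence: a filter quantity that is NA (not
#' computable from the available data) does not exclude a SNP.
#'
#' @param candidates data frame from \code{\link{candidate_table}} (or any
#'   table with the same columns, e.g. reconstructed from published
#'   summary counts).
#' @param p_threshold significance screen (default 0.05).
#' @param max_missing maximum missing-genotype fraction (default 0.05).
#' @param hwe_threshold Hardy-Weinberg exclusion level, applied in both
#'   groups (default 0.05).
#' @param min_alt_freq minimum total-sample alternative allele frequency
#'   (default 0.05).
#' @param panel optional \code{\link{snp_panel}} used to attach
#'   human-readable genotype labels.
#' @return Object of class \code{"scale_definition"}: list with
#'   \code{components} (data frame: rsid, model, risk dose set as a
#'   comma-separated string, label) , \code{risk} (named list of integer
#'   dose vectors) and \code{audit} (per SNP pass/fail of each filter).
#'   An empty selection returns a zero-component scale, not an error.
#' @export
select_snps <- function(candidates, p_threshold = 0.05, max_missing = 0.05,
                        hwe_threshold = 0.05, min_alt_freq = 0.05,
                        panel = NULL) {
  need <- c("rsid", "model", "carriers_control", "n_control", "carriers_case",
            "n_case", "mcnemar_p", "missing_fraction", "hwe_p_case",
            "hwe_p_control", "alt_freq_total")
  miss_cols <- setdiff(need, names(candidates))
  if (length(miss_cols)) stop_("candidates lack column(s): ",
                               paste(miss_cols, collapse = ", "))
  rsids <- sort(unique(candidates$rsid))
  audit <- data.frame(rsid = rsids, significant = FALSE, missing_ok = NA,
                      hwe_ok = NA, freq_ok = NA, selected = FALSE,
                      model = NA_character_, risk_doses = NA_character_,
                      stringsAsFactors = FALSE)
  comps <- list()
  for (i in seq_along(rsids)) {
    rs <- rsids[i]
    rows <- candidates[candidates$rsid == rs, , drop = FALSE]
    sig <- !is.na(rows$mcnemar_p) & rows$mcnemar_p < p_threshold
    audit$significant[i] <- any(sig)
    mf <- rows$missing_fraction[1]
    audit$missing_ok[i] <- is.na(mf) || mf <= max_missing
    hp <- c(rows$hwe_p_case[1], rows$hwe_p_control[1])
    audit$hwe_ok[i] <- all(is.na(hp) | hp > hwe_threshold)
    af <- rows$alt_freq_total[1]
    audit$freq_ok[i] <- is.na(af) || af >= min_alt_freq
    if (!any(sig) || !audit$missing_ok[i] || !audit$hwe_ok[i] || !audit$freq_ok[i])
      next
    sig_rows <- rows[sig, , drop = FALSE]
    pick <- if ("alt_carrier" %in% sig_rows$model)
      sig_rows[sig_rows$model == "alt_carrier", ][1, ] else sig_rows[1, ]
    risk <- orient_risk(pick$model,
                        pick$carriers_case / pick$n_case,
                        pick$carriers_control / pick$n_control)
    audit$selected[i] <- TRUE
    audit$model[i] <- pick$model
    audit$risk_doses[i] <- paste(risk, collapse = ",")
    comps[[rs]] <- list(model = pick$model, risk = risk)
  }
  components <- if (length(comps)) {
    data.frame(rsid = names(comps),
               model = vapply(comps, `[[`, "", "model"),
               risk_doses = vapply(comps, function(x)
                 paste(x$risk, collapse = ","), ""),
               stringsAsFactors = FALSE)
  } else {
    data.frame(rsid = character(0), model = character(0),
               risk_doses = character(0), stringsAsFactors = FALSE)
  }
  components$label <- genotype_labels(components, panel)
  rownames(components) <- NULL
  structure(list(components = components,
                 risk = lapply(comps, `[[`, "risk"),
                 audit = audit),
            class = "scale_definition")
}

genotype_labels <- function(components, panel) {
  if (is.null(panel) || nrow(components) == 0)
    return(rep(NA_character_, nrow(components)))
  vapply(seq_len(nrow(components)), function(i) {
    j <- match(components$rsid[i], panel$rsid)
    if (is.na(j)) return(NA_character_)
    gl <- c(paste0(panel$ref[j], panel$ref[j]),
            paste0(panel$ref[j], panel$alt[j]),
            paste0(panel$alt[j], panel$alt[j]))
    doses <- as.integer(strsplit(components$risk_doses[i], ",")[[1]])
    paste(gl[doses + 1L], collapse = " or ")
  }, character(1))
}

#' Construct a scale definition directly
#'
#' For pre-specified scales (e.g. one taken from a publication) rather than
#' data-driven selection.
#'
#' @param risk named list: rsid -> integer vector of alt-allele doses
#'   scoring one point.
#' @param panel optional \code{\link{snp_panel}} for genotype labels.
#' @return A \code{"scale_definition"}.
#' @examples
#' scale_definition(list(rs4961 = c(1, 2), rs1799998 = 0, rs1801133 = 0))
#' @export
scale_definition <- function(risk, panel = NULL) {
  if (length(risk) < 1L || is.null(names(risk)) || anyDuplicated(names(risk)))
    stop_("risk must be a uniquely named list of dose sets")
  risk <- lapply(risk, function(r) {
    r <- sort(unique(as.integer(r)))
    if (!length(r) || !all(r %in% 0:2)) stop_("risk doses must be within 0:2")
    r
  })
  components <- data.frame(rsid = names(risk), model = NA_character_,
                           risk_doses = vapply(risk, paste, "", collapse = ","),
                           stringsAsFactors = FALSE)
  components$label <- genotype_labels(components, panel)
  rownames(components) <- NULL
  structure(list(components = components, risk = risk, audit = NULL),
            class = "scale_definition")
}

#' @export
print.scale_definition <- function(x, ...) {
  k <- nrow(x$components)
  cat(sprintf("Genetic point scale: %d component(s), score range 0-%d\n", k, k))
  if (k) {
    lab <- ifelse(is.na(x$components$label), x$components$risk_doses,
                  x$components$label)
    cat(paste0("  ", x$components$rsid, ": ", lab, " (1 point)\n"), sep = "")
  }
  invisible(x)
}

#' Score a cohort on a point scale
#'
#' One point per component whose genotype falls in the risk class; the
#' score is missing for a patient with any missing component call.
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param scale a \code{"scale_definition"}.
#' @return List with \code{scores} (named integer vector, NA = unscorable)
#'   and \code{n_scored}.
#' @export
compute_scores <- function(cohort, scale) {
  stopifnot(inherits(scale, "scale_definition"))
  rs <- scale$components$rsid
  if (!length(rs)) stop_("empty scale")
  absent <- setdiff(rs, colnames(cohort$genotypes))
  if (length(absent)) stop_("scale SNP(s) absent from cohort panel: ",
                            paste(absent, collapse = ", "))
  pts <- vapply(rs, function(r)
    as.integer(cohort$genotypes[, r] %in% scale$risk[[r]]) +
      ifelse(is.na(cohort$genotypes[, r]), NA_integer_, 0L),
    integer(nrow(cohort$genotypes)))
  scores <- as.integer(rowSums(pts))
  names(scores) <- rownames(cohort$genotypes)
  list(scores = scores, n_scored = sum(!is.na(scores)))
}

#' Write / read a scale definition as JSON
#'
#' @param scale a \code{"scale_definition"}.
#' @param path file path.
#' @return \code{read_scale} returns a \code{"scale_definition"}.
#' @export
write_scale <- function(scale, path) {
  stopifnot(inherits(scale, "scale_definition"))
  obj <- lapply(seq_len(nrow(scale$components)), function(i) {
    list(rsid = scale$components$rsid[i],
         risk_doses = scale$risk[[scale$components$rsid[i]]],
         label = scale$components$label[i])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(scale)
}

#' @rdname write_scale
#' @export
read_scale <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  risk <- stats::setNames(lapply(obj, function(x) as.integer(unlist(x$risk_doses))),
                          vapply(obj, `[[`, "", "rsid"))
  scale_definition(risk)
}
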