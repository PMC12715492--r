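#' Run the full scale-building workflow
#'
#' Chains the analysis end to end: cohort input (read from tables,
#' simulated, or the study's reconstructed summary counts), per-SNP
#' matched association table, filter-cascade scale selection, scoring,
#' threshold metrics, ROC/AUC, and (when pair-level data exist) the
#' conditional logistic per-point odds ratio. All outputs are written as
#' CSV/JSON under \code{output_dir} and summarized in
#' \code{summary.json}.
#'
#' @param config a list, or path to a YAML file, with entries:
#'   \describe{
#'     \item{input}{list(genotype_file, metadata_file, panel_file) - read a
#'       cohort from disk; or}
#'     \item{simulate}{list of \code{\link{simulate_cohort}} arguments
#'       (e.g. n_pairs, seed); or}
#'     \item{study_fixture}{TRUE - run from the published summary counts
#'       (no pair-level stages).}
#'     \item{analysis}{optional list: mcnemar_method, p_threshold,
#'       max_missing, hwe_threshold, min_alt_freq, ci_level.}
#'     \item{output_dir}{output directory (created if needed).}
#'   }
#' @param output_dir overrides \code{config$output_dir}.
#' @return Invisibly, the summary list (also written to summary.json).
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  output_dir <- output_dir %||% config$output_dir
  if (is.null(output_dir)) stop_("no output_dir given")
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  an <- config$analysis %||% list()
  method <- an$mcnemar_method %||% "asymptotic_cc"
  level <- an$ci_level %||% 0.95
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_("stage '", name, "' failed: ", conditionMessage(e)))
  }
  emit <- function(df, file) utils::write.csv(
    df, file.path(output_dir, file), row.names = FALSE, na = "")
  summary <- list()

  if (isTRUE(config$study_fixture)) {
    candidates <- stage("associate", noreflow_candidates())
    panel <- noreflow_panel()
    cohort <- NULL
  } else {
    cohort <- stage("input", {
      if (!is.null(config$input)) {
        inp <- config$input
        for (f in c("genotype_file", "metadata_file", "panel_file"))
          if (!file.exists(inp[[f]] %||% ""))
            stop_("missing input path: ", f, " = ", inp[[f]] %||% "<unset>")
        read_cohort(inp$genotype_file, inp$metadata_file,
                    read_panel(inp$panel_file))
      } else if (!is.null(config$simulate)) {
        do.call(simulate_cohort, config$simulate)
      } else stop_("config needs one of: input, simulate, study_fixture")
    })
    panel <- cohort$panel
    emit(stage("associate", association_table(cohort, method = method,
                                              or = TRUE, level = level)),
         "association.csv")
    emit(stage("associate", group_genotype_summary(cohort)),
         "genotype_summary.csv")
    candidates <- stage("associate", candidate_table(cohort, method = method))
  }
  emit(candidates, "candidates.csv")

  scale <- stage("build-scale", select_snps(
    candidates,
    p_threshold = an$p_threshold %||% 0.05,
    max_missing = an$max_missing %||% 0.05,
    hwe_threshold = an$hwe_threshold %||% 0.05,
    min_alt_freq = an$min_alt_freq %||% 0.05,
    panel = panel))
  emit(scale$audit, "selection_audit.csv")
  write_scale(scale, file.path(output_dir, "scale.json"))
  summary$n_components <- nrow(scale$components)
  summary$scale <- stats::setNames(as.list(scale$components$risk_doses),
                                   scale$components$rsid)
  if (nrow(scale$components) == 0) {
    summary$note <- "empty scale: no SNP passed the filter cascade"
    jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    return(invisible(summary))
  }

  if (is.null(cohort)) {
    dist <- stage("evaluate", noreflow_score_distribution())
  } else {
    sc <- stage("evaluate", compute_scores(cohort, scale))
    summary$n_scored <- sc$n_scored
    cohort$meta$score <- sc$scores[cohort$meta$patient_id]
    dist <- stage("evaluate", score_distribution_from_scores(
      sc$scores[cohort$meta$patient_id], cohort$meta$group,
      max_score = nrow(scale$components)))
    cl <- stage("clogit", {
      keep <- !is.na(cohort$meta$score)
      ids <- cohort$meta$patient_id[keep]
      sub <- cohort$pairs$case_id %in% ids & cohort$pairs$control_id %in% ids
      coh2 <- cohort; coh2$pairs <- cohort$pairs[sub, ]
      clogit_cohort(coh2, "score", level = level)
    })
    emit(cl$table, "clogit_coefficients.csv")
    summary$clogit_per_point <- list(
      odds_ratio = cl$table$odds_ratio[1], ci_low = cl$table$ci_low[1],
      ci_high = cl$table$ci_high[1], p_value = cl$table$p_value[1])
  }
  emit(data.frame(score = as.integer(names(dist$cases)),
                  cases = as.integer(dist$cases),
                  controls = as.integer(dist$controls)),
       "score_distribution.csv")
  tt <- stage("evaluate", threshold_table(dist))
  emit(tt, "threshold_metrics.csv")
  roc <- stage("evaluate", roc_curve(dist, level = level))
  emit(roc$points, "roc_points.csv")
  summary$score_counts <- as.integer(dist$cases + dist$controls)
  summary$auc <- roc$auc
  summary$auc_ci <- c(roc$ci_low, roc$ci_high)
  summary$optimal_threshold <- optimal_threshold(tt)
  summary$f_at_optimum <- tt$f_score[tt$threshold == summary$optimal_threshold]
  jsonlite::write_json(summary, file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 6, pretty = TRUE)
  invisible(summary)
}
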