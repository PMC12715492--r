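#' Per-group score distribution
#'
#' Holds, for cases and controls separately, the number of patients at
#' each score value 0..K. Built either from per-patient scores
#' (\code{score_distribution_from_scores}) or directly from counts.
#'
#' @param cases,controls integer count vectors, element s+1 = number of
#'   patients with score s (equal length; padded with zeros as needed).
#' @return Object of class \code{"score_distribution"}: list with
#'   \code{cases}, \code{controls} (named count vectors), \code{max_score}.
#' @examples
#' score_distribution(c(5, 9, 14, 10), c(16, 11, 11, 1))
#' @export
score_distribution <- function(cases, controls) {
  k <- max(length(cases), length(controls)) - 1L
  pad <- function(x) { out <- rep(0L, k + 1L); out[seq_along(x)] <- as.integer(x); out }
  cases <- pad(cases); controls <- pad(controls)
  if (any(cases < 0) || any(controls < 0)) stop_("negative count")
  names(cases) <- names(controls) <- 0:k
  structure(list(cases = cases, controls = controls, max_score = k),
            class = "score_distribution")
}

#' @rdname score_distribution
#' @param scores named integer score vector (NA dropped), e.g. from
#'   \code{\link{compute_scores}}.
#' @param group character vector aligned with \code{scores}
#'   (\code{"case"}/\code{"control"}).
#' @param max_score top of the score range (default: observed maximum).
#' @export
score_distribution_from_scores <- function(scores, group,
                                           max_score = max(scores, na.rm = TRUE)) {
  keep <- !is.na(scores)
  scores <- scores[keep]; group <- group[keep]
  tab <- function(g) tabulate(scores[group == g] + 1L, nbins = max_score + 1L)
  score_distribution(tab("case"), tab("control"))
}

#' @export
print.score_distribution <- function(x, ...) {
  m <- rbind(cases = x$cases, controls = x$controls)
  cat(sprintf("Score distribution (0-%d): %d cases, %d controls\n",
              x$max_score, sum(x$cases), sum(x$controls)))
  print(m)
  invisible(x)
}

#' Confusion-matrix metrics at one score threshold
#'
#' A patient tests positive when score >= \code{threshold}. Returns the
#' confusion cells and the derived rates; NPV is NA when no patient tests
#' negative (threshold 0) and the F-score is the harmonic mean of PPV and
#' sensitivity (F1).
#'
#' @param dist a \code{\link{score_distribution}}.
#' @param threshold integer in 0..max_score.
#' @return One-row data frame: threshold, prevalence_positive, tp, fp, tn,
#'   fn, accuracy, sensitivity, specificity, ppv, npv, f_score.
#' @export
threshold_metrics <- function(dist, threshold) {
  stopifnot(inherits(dist, "score_distribution"))
  n1 <- sum(dist$cases); n2 <- sum(dist$controls)
  if (n1 + n2 == 0) stop_("empty score distribution")
  if (threshold < 0 || threshold > dist$max_score)
    stop_("threshold outside the score range")
  s <- as.integer(names(dist$cases))
  tp <- sum(dist$cases[s >= threshold]); fn <- n1 - tp
  fp <- sum(dist$controls[s >= threshold]); tn <- n2 - fp
  sens <- tp / n1
  spec <- tn / n2
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f <- if (!is.na(ppv) && ppv + sens > 0) 2 * ppv * sens / (ppv + sens) else NA_real_
  data.frame(threshold = threshold,
             prevalence_positive = (tp + fp) / (n1 + n2),
             tp = tp, fp = fp, tn = tn, fn = fn,
             accuracy = (tp + tn) / (n1 + n2),
             sensitivity = sens, specificity = spec,
             ppv = ppv, npv = npv, f_score = f)
}

#' Metrics at every threshold
#'
#' @param dist a \code{\link{score_distribution}}.
#' @return Data frame, one \code{\link{threshold_metrics}} row per
#'   threshold from max_score down to 0.
#' @export
threshold_table <- function(dist) {
  out <- do.call(rbind, lapply(dist$max_score:0, threshold_metrics, dist = dist))
  rownames(out) <- NULL
  out
}

#' Empirical ROC curve and trapezoidal AUC with Hanley-McNeil interval
#'
#' One ROC point per threshold (positive when score >= t, t descending)
#' plus the origin; the AUC is the trapezoidal integral, and its
#' confidence interval uses the Hanley-McNeil normal approximation with
#' \eqn{Q_1 = A/(2-A)}, \eqn{Q_2 = 2A^2/(1+A)}.
#'
#' @param dist a \code{\link{score_distribution}} (both groups non-empty).
#' @param level confidence level (default 0.95).
#' @return Object of class \code{"roc_result"}: list with \code{points}
#'   (data frame threshold/fpr/tpr, sorted by fpr, starting at (0,0) and
#'   ending at (1,1)), \code{auc}, \code{se}, \code{ci_low},
#'   \code{ci_high}, \code{level}.
#' @export
roc_curve <- function(dist, level = 0.95) {
  stopifnot(inherits(dist, "score_distribution"))
  check_prob(level, "level")
  n1 <- sum(dist$cases); n2 <- sum(dist$controls)
  if (n1 == 0 || n2 == 0) stop_("both groups must be non-empty")
  th <- (dist$max_score + 1L):0   # score > max is the all-negative rule
  pts <- do.call(rbind, lapply(th, function(t) {
    s <- as.integer(names(dist$cases))
    data.frame(threshold = t,
               fpr = sum(dist$controls[s >= t]) / n2,
               tpr = sum(dist$cases[s >= t]) / n1)
  }))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  z <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(points = pts, auc = auc, se = se,
                 ci_low = max(0, auc - z * se), ci_high = min(1, auc + z * se),
                 level = level),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%.0f%% CI %.3f-%.3f), %d points\n",
              x$auc, 100 * x$level, x$ci_low, x$ci_high, nrow(x$points)))
  invisible(x)
}

#' F-score-optimal threshold
#'
#' The threshold whose row maximizes the F-score; ties break toward the
#' higher threshold.
#'
#' @param metrics data frame from \code{\link{threshold_table}} (needs
#'   columns \code{threshold}, \code{f_score}).
#' @return The optimal threshold (integer).
#' @export
optimal_threshold <- function(metrics) {
  if (!nrow(metrics)) stop_("no metric rows")
  f <- metrics$f_score
  best <- which(!is.na(f) & f == max(f, na.rm = TRUE))
  max(metrics$threshold[best])
}

#' Recover per-score counts from cumulative confusion cells
#'
#' Published threshold tables print TP and FP per threshold; because
#' positivity is cumulative (score >= t), successive differences recover
#' the per-score group counts: cases at score s = TP(s) - TP(s+1).
#'
#' @param metrics data frame with columns \code{threshold}, \code{tp},
#'   \code{fp} covering every threshold 0..K.
#' @return A \code{\link{score_distribution}}.
#' @export
distribution_from_metrics <- function(metrics) {
  m <- metrics[order(metrics$threshold), ]
  k <- max(m$threshold)
  if (!identical(as.integer(m$threshold), 0:k))
    stop_("metrics must cover every threshold 0..K")
  cases <- -diff(c(m$tp, 0))      # count at score s = tp(s) - tp(s + 1)
  controls <- -diff(c(m$fp, 0))
  if (any(cases < 0) || any(controls < 0))
    stop_("tp/fp columns are not non-increasing in threshold")
  score_distribution(cases, controls)
}
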