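#' Within-pair covariate differences for 1:1 conditional logistic regression
#'
#' In a 1:1 matched design the conditional likelihood depends on the data
#' only through the per-pair differences \eqn{d_i = x_{case,i} -
#' x_{control,i}}; the per-pair nuisance intercepts cancel. Pairs with an
#' all-zero difference are retained (they contribute a constant factor).
#'
#' @param cohort a \code{\link{matched_cohort}}.
#' @param covariates character vector naming covariates: metadata columns
#'   (e.g. clinical covariates or a score added to \code{cohort$meta}),
#'   and/or \code{"age"}.
#' @return Numeric matrix, one row per pair (rownames = pair_id), one
#'   column per covariate.
#' @export
pair_differences <- function(cohort, covariates) {
  missing_cov <- setdiff(covariates, names(cohort$meta))
  if (length(missing_cov))
    stop_("covariate(s) not in cohort metadata: ",
          paste(missing_cov, collapse = ", "))
  x <- as.matrix(cohort$meta[, covariates, drop = FALSE])
  if (!is.numeric(x)) stop_("covariates must be numeric")
  rownames(x) <- cohort$meta$patient_id
  d <- x[cohort$pairs$case_id, , drop = FALSE] -
    x[cohort$pairs$control_id, , drop = FALSE]
  bad <- rowSums(is.na(d)) > 0
  if (any(bad))
    stop_("missing covariate value in pair(s): ",
          paste(cohort$pairs$pair_id[bad], collapse = ", "))
  rownames(d) <- cohort$pairs$pair_id
  colnames(d) <- covariates
  d
}

#' Conditional logistic regression for 1:1 matched sets
#'
#' Maximizes the exact conditional likelihood of a 1:1 matched
#' case-control design, \eqn{\sum_i \log \sigma(\beta^T d_i)} where
#' \eqn{d_i} is the within-pair covariate difference and \eqn{\sigma} the
#' logistic function, by Newton-Raphson with step-halving. There is no
#' intercept: it is conditioned out by the matching. The variance is the
#' inverse observed information at the optimum.
#'
#' A finite maximum does not exist under complete separation (every
#' discordant difference points the same way); this is detected and
#' reported as an error rather than returned as a huge coefficient.
#'
#' @param differences numeric matrix of per-pair differences, e.g. from
#'   \code{\link{pair_differences}} (a vector is taken as one covariate).
#' @param tol convergence tolerance on the gradient max-norm (default 1e-8).
#' @param max_iter maximum Newton iterations (default 25).
#' @return Object of class \code{"clogit_fit"}: list with \code{coef},
#'   \code{cov} (variance-covariance of \code{coef}), \code{loglik},
#'   \code{n_pairs}, \code{iterations}, \code{converged}.
#' @examples
#' # one binary covariate: the fit reproduces the discordant-pair OR b/c
#' d <- c(rep(1, 10), -1, rep(0, 29))
#' exp(clogit_fit(d)$coef)  # 10
#' @export
clogit_fit <- function(differences, tol = 1e-8, max_iter = 25L) {
  d <- as.matrix(differences)
  if (!is.numeric(d) || anyNA(d)) stop_("differences must be numeric, no NA")
  if (nrow(d) < 1L) stop_("no pairs")
  if (all(d == 0)) stop_("all pair differences are zero: no information")
  k <- ncol(d)
  if (is.null(colnames(d))) colnames(d) <- paste0("x", seq_len(k))

  loglik <- function(beta) sum(stats::plogis(drop(d %*% beta), log.p = TRUE))
  beta <- rep(0, k)
  ll <- loglik(beta)
  iter <- 0L
  converged <- FALSE
  repeat {
    eta <- drop(d %*% beta)
    mu <- stats::plogis(eta)             # sigma(eta)
    grad <- drop(crossprod(d, 1 - mu))
    info <- crossprod(d, d * (mu * (1 - mu)))
    if (max(abs(grad)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    if (sqrt(sum(beta^2)) > 10)
      stop_("complete separation: the conditional likelihood has no finite maximum")
    step <- tryCatch(solve(info, grad), error = function(e) NULL)
    if (is.null(step) || anyNA(step))
      stop_("singular information matrix: remove collinear or constant covariates")
    # step-halving keeps the concave likelihood increasing
    h <- 1
    repeat {
      cand <- beta + h * step
      ll_new <- loglik(cand)
      if (ll_new >= ll - 1e-12 || h < 2^-30) break
      h <- h / 2
    }
    beta <- cand; ll <- ll_new
    iter <- iter + 1L
  }
  if (!converged && sqrt(sum(beta^2)) > 10)
    stop_("complete separation: the conditional likelihood has no finite maximum")
  eta <- drop(d %*% beta)
  mu <- stats::plogis(eta)
  info <- crossprod(d, d * (mu * (1 - mu)))
  covm <- tryCatch(solve(info), error = function(e)
    stop_("singular information matrix at the optimum"))
  names(beta) <- colnames(d)
  dimnames(covm) <- list(colnames(d), colnames(d))
  structure(list(coef = beta, cov = covm, loglik = ll,
                 n_pairs = nrow(d), iterations = iter, converged = converged),
            class = "clogit_fit")
}

#' @export
print.clogit_fit <- function(x, ...) {
  cat(sprintf("1:1 conditional logistic regression (%d pairs, %d Newton steps%s)\n",
              x$n_pairs, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  se <- sqrt(diag(x$cov))
  tab <- data.frame(coef = x$coef, se = se, OR = exp(x$coef),
                    z = x$coef / se,
                    p = 2 * stats::pnorm(-abs(x$coef / se)))
  print(tab, digits = 4)
  cat(sprintf("log-likelihood: %.4f\n", x$loglik))
  invisible(x)
}

#' Wald odds ratio from a conditional logistic fit
#'
#' @param fit a converged \code{\link{clogit_fit}}.
#' @param coefficient name or index of the coefficient (default 1).
#' @param level confidence level (default 0.95).
#' @return An \code{"or_estimate"} (see \code{\link{conditional_or}}) with
#'   p-value from the two-sided Wald z test.
#' @export
wald_or <- function(fit, coefficient = 1L, level = 0.95) {
  stopifnot(inherits(fit, "clogit_fit"))
  if (!fit$converged) stop_("fit did not converge; no Wald interval")
  check_prob(level, "level")
  b <- fit$coef[[coefficient]]
  se <- sqrt(diag(fit$cov))[[coefficient]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- 2 * stats::pnorm(-abs(b / se))
  new_or_estimate(exp(b), exp(b - z * se), exp(b + z * se), level, p)
}

#' Conditional logistic regression on cohort covariates
#'
#' Convenience wrapper: forms within-pair differences for the named
#' covariates, fits the 1:1 conditional likelihood, and returns a
#' coefficient table (OR, CI, p per covariate) alongside the fit.
#'
#' @inheritParams pair_differences
#' @param level confidence level for the Wald intervals.
#' @return List with \code{fit} (the \code{\link{clogit_fit}}) and
#'   \code{table} (data frame: covariate, coef, se, odds_ratio, ci_low,
#'   ci_high, p_value).
#' @export
clogit_cohort <- function(cohort, covariates, level = 0.95) {
  d <- pair_differences(cohort, covariates)
  fit <- clogit_fit(d)
  se <- sqrt(diag(fit$cov))
  tab <- do.call(rbind, lapply(seq_along(covariates), function(j) {
    est <- wald_or(fit, j, level)
    data.frame(covariate = covariates[j], coef = fit$coef[[j]], se = se[[j]],
               odds_ratio = est$odds_ratio, ci_low = est$ci_low,
               ci_high = est$ci_high, p_value = est$p_value)
  }))
  rownames(tab) <- NULL
  list(fit = fit, table = tab)
}
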