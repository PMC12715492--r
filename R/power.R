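#' Discordant pairs required for a matched McNemar comparison
#'
#' Normal-approximation (Connor-type) sample-size formula for the McNemar
#' test in a 1:1 matched design. Under a conditional odds ratio \eqn{\psi}
#' a discordant pair is case-exposed with probability
#' \eqn{p_1 = \psi/(1+\psi)}; the required number of discordant pairs at
#' two-sided level \eqn{\alpha} and the given power is
#' \deqn{n_d = \lceil (z_{1-\alpha/2}/2 + z_{power}\sqrt{p_1(1-p_1)})^2 /
#'   (p_1 - 1/2)^2 \rceil.}
#'
#' @param psi detectable conditional odds ratio (> 1).
#' @param alpha two-sided type-I error rate (default 0.05).
#' @param power target power (default 0.80).
#' @return Integer number of discordant pairs.
#' @examples
#' discordant_pairs_required(4)  # 20
#' @export
discordant_pairs_required <- function(psi, alpha = 0.05, power = 0.80) {
  check_prob(alpha, "alpha"); check_prob(power, "power")
  if (!is.numeric(psi) || length(psi) != 1L || is.na(psi) || psi <= 1)
    stop_("psi must be a single odds ratio > 1")
  p1 <- psi / (1 + psi)
  za <- stats::qnorm(1 - alpha / 2)
  zb <- stats::qnorm(power)
  as.integer(ceiling((za * 0.5 + zb * sqrt(p1 * (1 - p1)))^2 / (p1 - 0.5)^2))
}

#' Total matched pairs and patients required
#'
#' Converts the required discordant pairs into total pairs by dividing by
#' the probability that a pair is discordant. With control-group exposure
#' prevalence \eqn{p_0}, the case-member exposure prevalence implied by the
#' conditional odds ratio is \eqn{p_{case} = \psi p_0 / (1 + p_0(\psi-1))},
#' and assuming exposure independence within a pair,
#' \eqn{P_{disc} = p_{case}(1-p_0) + p_0(1-p_{case})}.
#'
#' @inheritParams discordant_pairs_required
#' @param p_exposure control-group exposure prevalence in (0, 1).
#' @return List with \code{n_discordant}, \code{p_discordant},
#'   \code{n_pairs}, \code{n_patients}.
#' @examples
#' pairs_required(4, p_exposure = 0.5)  # 20 discordant, 40 pairs, 80 patients
#' @export
pairs_required <- function(psi, p_exposure, alpha = 0.05, power = 0.80) {
  check_prob(p_exposure, "p_exposure")
  nd <- discordant_pairs_required(psi, alpha = alpha, power = power)
  p_case <- psi * p_exposure / (1 + p_exposure * (psi - 1))
  p_disc <- p_case * (1 - p_exposure) + p_exposure * (1 - p_case)
  if (p_disc <= 0) stop_("discordance probability is zero")
  n_pairs <- as.integer(ceiling(nd / p_disc))
  list(n_discordant = nd, p_discordant = p_disc, n_pairs = n_pairs,
       n_patients = 2L * n_pairs)
}
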