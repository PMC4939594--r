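## Evaluation criteria of the simulation study: percentage parameter bias,
## percentage standard-error bias and empirical power, plus the closed-form
## expectations used to cross-check them.

#' Percentage parameter bias of a collection of estimates
#'
#' \eqn{100 (\bar{\hat\beta_1} - \beta_1)/\beta_1}: the mean estimate's
#' percentage deviation from the generating value. Positive bias means the
#' treatment effect is overestimated.
#'
#' @param estimates numeric vector of treatment-effect estimates.
#' @param beta1_true generating treatment effect; nonzero.
#' @return The bias in percent.
#' @export
parameter_bias_pct <- function(estimates, beta1_true) {
  stopifnot(length(estimates) >= 1L, all(is.finite(estimates)))
  if (!is.finite(beta1_true) || beta1_true == 0)
    stop("percentage bias is undefined for beta1_true = 0")
  100 * (mean(estimates) - beta1_true) / beta1_true
}

#' Percentage standard-error bias
#'
#' Compares the mean model-based standard error with the empirical standard
#' deviation of the estimates: \eqn{100(\bar{se} - sd)/sd}. Positive bias
#' means the model overstates the uncertainty of the treatment effect, which
#' costs power.
#'
#' @param mean_se mean of the model-based standard errors over replicates.
#' @param sd_estimates sample standard deviation (divisor reps - 1) of the
#'   estimates; positive.
#' @return The bias in percent.
#' @export
se_bias_pct <- function(mean_se, sd_estimates) {
  stopifnot(is.finite(mean_se), is.finite(sd_estimates))
  if (sd_estimates <= 0) stop("standard-error bias is undefined when sd_estimates is not positive")
  100 * (mean_se - sd_estimates) / sd_estimates
}

#' Empirical power as a rejection percentage
#'
#' @param rejections logical vector of per-replicate rejection decisions.
#' @return Percentage of replicates rejecting the null of no treatment effect.
#' @export
empirical_power_pct <- function(rejections) {
  stopifnot(length(rejections) >= 1L, is.logical(rejections), !anyNA(rejections))
  100 * mean(rejections)
}

#' Expected percentage bias of the unadjusted estimator under fixed imbalance
#'
#' The unadjusted estimator is the difference in arm means, whose expectation
#' under the generating model is \eqn{\beta_1 + \beta_2(\mu_{zI}-\mu_{zC})};
#' with k of the n2/2 intervention clusters covariate-positive the covariate
#' prevalence difference is \eqn{(2k - n_2/2)/(n_2/2)}. This is the exact
#' expectation of the Monte-Carlo parameter bias, used as a deterministic
#' cross-check of the simulation.
#'
#' @param beta1 generating treatment effect; nonzero.
#' @param beta2 covariate effect.
#' @param n2 total clusters (multiple of 4).
#' @param k covariate-positive intervention clusters.
#' @return The expected bias in percent.
#' @examples
#' expected_unadjusted_bias_pct(0.5, 0.8, 12, 5)   # 106.67
#' @export
expected_unadjusted_bias_pct <- function(beta1, beta2, n2, k) {
  n2 <- check_n2(n2)
  if (!is.finite(beta1) || beta1 == 0)
    stop("percentage bias is undefined for beta1 = 0")
  half <- n2 / 2
  100 * beta2 * ((k - (half - k)) / half) / beta1
}

#' Model-based standard error of the treatment effect
#'
#' \eqn{\sqrt{4(\sigma_e^2 + n_1\sigma_u^2)/(n_1 n_2 (1-\rho_{xz}^2))}}: the
#' exact GLS standard error of the treatment effect for a balanced design with
#' 0/1 treatment coding, inflated by the variance inflation factor
#' \eqn{1/(1-\rho_{xz}^2)} when treatment and covariate are correlated.
#'
#' @param n1 cluster size.
#' @param n2 number of clusters.
#' @param sigma_u2,sigma_e2 variance components.
#' @param rho_xz treatment--covariate correlation, strictly inside (-1, 1).
#' @return The standard error.
#' @export
theoretical_se <- function(n1, n2, sigma_u2, sigma_e2, rho_xz = 0) {
  stopifnot(n1 >= 1, n2 >= 1, sigma_u2 >= 0, sigma_e2 >= 0)
  if (any(abs(rho_xz) >= 1))
    stop("the treatment-effect variance diverges as |rho_xz| approaches 1")
  sqrt(4 * (sigma_e2 + n1 * sigma_u2) / (n1 * n2 * (1 - rho_xz^2)))
}

#' Nominal and attained power of the test on treatment effect
#'
#' Power to detect \code{beta1} with \code{n2} clusters of size \code{n1} at
#' ICC \code{rho} (unit total variance) and treatment--covariate correlation
#' \code{rho_xz} (zero, i.e. covariate balance, at the design stage).
#' Three computations are available:
#' \describe{
#'   \item{\code{"normal"}}{the normal approximation that also underlies the
#'     sample-size formula, so plugging in the unrounded cluster requirement
#'     returns the target power exactly;}
#'   \item{\code{"t"}}{the noncentral t with \code{df} degrees of freedom --
#'     the power the Wald t-test would attain if the standard error were
#'     estimated from the between-cluster mean square alone, noticeably below
#'     the normal value for small \code{n2};}
#'   \item{\code{"exact"}}{the attained rejection probability of the test as
#'     actually performed, with the cluster-level variance floored at zero:
#'     the squared standard error is proportional to the larger of the
#'     between-cluster mean square and the scaled within-cluster mean square,
#'     and the rejection probability is averaged over the exact joint
#'     distribution of the two independent mean squares by quadrature. At
#'     small \code{n2} the flooring depresses power by a point or two
#'     relative to the noncentral-t value.}
#' }
#'
#' @param n1 cluster size.
#' @param n2 number of clusters (possibly non-integer for \code{"normal"}).
#' @param rho intraclass correlation.
#' @param beta1 treatment effect in outcome-SD units.
#' @param alpha two-sided test level.
#' @param method \code{"normal"} (default), \code{"t"} or \code{"exact"}.
#' @param df degrees of freedom for \code{"t"} and \code{"exact"}; defaults
#'   to \code{n2 - 3}, the adjusted-model test.
#' @param rho_xz realized treatment--covariate correlation; 0 for the
#'   design-stage nominal value.
#' @return Power in percent.
#' @examples
#' nominal_power_pct(30, 12, 0.05, 0.5)                 # 85.8 (normal)
#' nominal_power_pct(30, 12, 0.05, 0.5, method = "t")   # 76.9
#' @export
nominal_power_pct <- function(n1, n2, rho, beta1, alpha = 0.05,
                              method = c("normal", "t", "exact"),
                              df = n2 - 3, rho_xz = 0) {
  method <- match.arg(method)
  se <- theoretical_se(n1, n2, sigma_u2 = rho, sigma_e2 = 1 - rho,
                       rho_xz = rho_xz)
  ncp <- abs(beta1) / se
  if (method == "normal") {
    100 * stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
  } else if (method == "t") {
    tcrit <- stats::qt(1 - alpha / 2, df)
    100 * (1 - stats::pt(tcrit, df, ncp = ncp) +
             stats::pt(-tcrit, df, ncp = ncp))
  } else {
    floored_reml_power_pct(n1, n2, rho, beta1, alpha, df, rho_xz)
  }
}

## Exact rejection probability of the two-sided Wald t-test with the
## floored-REML standard error. Independently of the estimate,
## se^2 = C * max(B, W/n1) with C = 4/(n2 (1-rho_xz^2)),
## B ~ tau chisq(d2)/d2 the between-cluster mean square (d2 = df),
## W ~ sigma_e2 chisq(d1)/d1 the within-cluster mean square
## (d1 = n2 (n1 - 1)), and beta1_hat ~ N(beta1, C tau). The rejection
## probability is averaged over (B, W) by midpoint quadrature on the
## probability scale.
floored_reml_power_pct <- function(n1, n2, rho, beta1, alpha, df, rho_xz,
                                   nodes_b = 512L, nodes_w = 65L) {
  sigma_e2 <- 1 - rho
  tau <- rho + sigma_e2 / n1
  C <- 4 / (n2 * (1 - rho_xz^2))
  d1 <- n2 * (n1 - 1)
  d2 <- df
  B <- tau * stats::qchisq((seq_len(nodes_b) - 0.5) / nodes_b, d2) / d2
  W <- sigma_e2 * stats::qchisq((seq_len(nodes_w) - 0.5) / nodes_w, d1) / d1
  se <- sqrt(C * outer(B, W / n1, pmax))
  tcrit <- stats::qt(1 - alpha / 2, d2)
  sd_b <- sqrt(C * tau)
  rej <- stats::pnorm((-tcrit * se - beta1) / sd_b) +
    stats::pnorm(-(tcrit * se - beta1) / sd_b)
  100 * mean(rej)
}
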