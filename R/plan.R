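#' Planning specification for a two-arm cluster randomized trial
#'
#' Bundles the design-stage quantities entering the sample-size formula for
#' the number of clusters: the two-sided type-I error rate, the target power,
#' the smallest treatment effect worth detecting (in outcome-SD units, the
#' total outcome variance being normalized to 1), and the treatment--covariate
#' correlation assumed at the planning stage. Planning under the assumption of
#' covariate balance corresponds to \code{rho_xz = 0}; a nonzero value inflates
#' the required number of clusters by the variance inflation factor
#' \eqn{1/(1-\rho_{xz}^2)}.
#'
#' @param alpha two-sided type-I error rate, in (0, 1).
#' @param power target power \eqn{1-\beta}, in (0, 1).
#' @param beta1 detectable treatment effect in outcome-SD units; nonzero.
#' @param rho_xz treatment--covariate correlation assumed at planning time,
#'   in (-1, 1).
#'
#' @return An object of class \code{"crt_plan"}.
#' @examples
#' crt_plan()                       # alpha 0.05, power 0.8, effect 0.5
#' crt_plan(rho_xz = 0.5)          # plan anticipating imbalance
#' @export
crt_plan <- function(alpha = 0.05, power = 0.8, beta1 = 0.5, rho_xz = 0) {
  stopifnot(length(alpha) == 1L, is.finite(alpha), alpha > 0, alpha < 1)
  stopifnot(length(power) == 1L, is.finite(power), power > 0, power < 1)
  stopifnot(length(beta1) == 1L, is.finite(beta1))
  if (beta1 == 0) stop("'beta1' must be nonzero: no finite number of clusters detects a null effect")
  stopifnot(length(rho_xz) == 1L, is.finite(rho_xz))
  if (abs(rho_xz) >= 1) stop("'rho_xz' must lie strictly between -1 and 1")
  structure(list(alpha = alpha, power = power, beta1 = beta1, rho_xz = rho_xz),
            class = "crt_plan")
}

#' @export
print.crt_plan <- function(x, ...) {
  cat("CRT planning specification\n")
  cat(sprintf("  two-sided alpha: %.3g   target power: %.3g\n", x$alpha, x$power))
  cat(sprintf("  detectable effect beta1: %.3g SD   assumed rho_xz: %.3g\n",
              x$beta1, x$rho_xz))
  invisible(x)
}

#' Number of clusters required for a target power
#'
#' Computes the number of clusters \eqn{n_2} (both arms together, 1:1
#' allocation) needed to detect the planned treatment effect with a two-sided
#' Wald test, using the normal-approximation formula
#' \deqn{n_2 = 4\,\frac{\sigma_e^2 + n_1 \sigma_u^2}{n_1 (1-\rho_{xz}^2)}
#'   \left(\frac{z_{1-\alpha/2} + z_{1-\beta}}{\beta_1}\right)^2,}
#' with the total variance normalized so that \eqn{\sigma_u^2 = \rho} and
#' \eqn{\sigma_e^2 = 1-\rho}. The raw (non-integer) value is rounded up to the
#' nearest multiple of 4, so that each arm holds an even number of clusters and
#' a 50/50 binary cluster-level covariate can be perfectly balanced within
#' arms. A configurable floor (\code{min_n2}, default 8) guards the small-cell
#' regime where the formula yields so few clusters that extreme imbalance
#' quantiles would make treatment and covariate perfectly collinear.
#'
#' @param n1 common cluster size (subjects per cluster), at least 1.
#' @param rho intraclass correlation coefficient, in [0, 1).
#' @param plan a \code{\link{crt_plan}}.
#' @param min_n2 minimum number of clusters after rounding; multiple of 4.
#'
#' @return A list with components \code{raw} (the unrounded value),
#'   \code{n2} (the rounded cluster count actually used) and
#'   \code{floored} (\code{TRUE} when \code{min_n2} was binding).
#' @examples
#' required_clusters(30, 0.05)   # raw 10.26 -> 12 clusters
#' required_clusters(5, 0.1)     # raw 35.16 -> 36 clusters
#' @export
required_clusters <- function(n1, rho, plan = crt_plan(), min_n2 = 8L) {
  stopifnot(inherits(plan, "crt_plan"))
  stopifnot(length(n1) == 1L, is.finite(n1), n1 >= 1)
  stopifnot(length(rho) == 1L, is.finite(rho), rho >= 0, rho < 1)
  stopifnot(length(min_n2) == 1L, min_n2 >= 4, min_n2 %% 4 == 0)
  sigma_u2 <- rho
  sigma_e2 <- 1 - rho
  zsum <- stats::qnorm(1 - plan$alpha / 2) + stats::qnorm(plan$power)
  raw <- 4 * (sigma_e2 + n1 * sigma_u2) / (n1 * (1 - plan$rho_xz^2)) *
    (zsum / plan$beta1)^2
  n2 <- 4 * ceiling(raw / 4)
  floored <- n2 < min_n2
  if (floored) n2 <- as.integer(min_n2)
  list(raw = raw, n2 = as.integer(n2), floored = floored)
}
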