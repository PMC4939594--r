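#' Arm means of outcome and covariate
#'
#' Exact arithmetic means of the outcome and of the binary covariate in the
#' intervention and control arms. The unadjusted treatment-effect estimator is
#' \code{ybar_I - ybar_C}; the covariate-adjusted estimator subtracts
#' \code{beta2_hat * (zbar_I - zbar_C)}.
#'
#' @param trial a \code{"crt_trial"}.
#' @return A list with components \code{ybar_I}, \code{ybar_C}, \code{zbar_I},
#'   \code{zbar_C}.
#' @export
arm_means <- function(trial) {
  stopifnot(inherits(trial, "crt_trial"))
  d <- trial$design
  int <- d$x == 1L
  list(ybar_I = mean(trial$y[, int]),
       ybar_C = mean(trial$y[, !int]),
       zbar_I = mean(d$z[int]),
       zbar_C = mean(d$z[!int]))
}

## Closed-form REML for a balanced two-level design with cluster-level
## regressors. The restricted likelihood factorizes into an independent
## within-cluster part, SSW ~ sigma_e2 * chisq(n2 (n1-1)), and a
## between-cluster part in which the cluster means are iid around X beta with
## variance tau = sigma_u2 + sigma_e2 / n1. The unconstrained REML maximizer
## is therefore the pooled within-cluster mean square and the OLS residual
## mean square of the cluster means; sigma_u2 is recovered by subtraction and
## floored at zero when the between mean square falls below sigma_e2 / n1.
reml_closed_form <- function(ybar, ssw, n1, n2, X) {
  p <- ncol(X)
  sigma_e2 <- ssw / (n2 * (n1 - 1))
  qrX <- qr(X)
  if (qrX$rank < p) stop("fixed-effect design is rank deficient: treatment and covariate are collinear")
  beta <- qr.coef(qrX, ybar)
  rss <- sum(qr.resid(qrX, ybar)^2)
  B <- rss / (n2 - p)
  sigma_u2 <- max(0, B - sigma_e2 / n1)
  list(beta = beta, sigma_u2 = sigma_u2, sigma_e2 = sigma_e2, between_ms = B)
}

#' REML variance components of a balanced two-level trial
#'
#' Estimates \eqn{\sigma_e^2} by the pooled within-cluster mean square and
#' \eqn{\sigma_u^2} from the residual mean square of an OLS fit of the cluster
#' means on the fixed-effect design (intercept + treatment, plus the covariate
#' when \code{adjusted}), floored at zero. For a balanced design with
#' cluster-level regressors this is exactly the REML solution whenever the
#' unconstrained maximizer is interior.
#'
#' @param trial a \code{"crt_trial"}.
#' @param adjusted include the covariate in the fixed-effect design?
#' @return A list with \code{sigma_u2} and \code{sigma_e2}.
#' @export
reml_components <- function(trial, adjusted = TRUE) {
  stopifnot(inherits(trial, "crt_trial"))
  d <- trial$design
  if (d$n1 < 2) stop("within-cluster variance is not estimable with n1 = 1")
  ybar <- colMeans(trial$y)
  ssw <- sum(sweep(trial$y, 2L, ybar)^2)
  X <- if (adjusted) cbind(1, d$x, d$z) else cbind(1, d$x)
  fit <- reml_closed_form(ybar, ssw, d$n1, d$n2, X)
  list(sigma_u2 = fit$sigma_u2, sigma_e2 = fit$sigma_e2)
}

#' Fit the adjusted or unadjusted linear mixed model to one trial
#'
#' Fits the two-level random-intercept model by closed-form REML (see
#' \code{\link{reml_components}}) and estimates the fixed effects by
#' generalized least squares, which for a balanced design with cluster-level
#' regressors coincides with OLS on the cluster means. The model-based
#' standard error of the treatment effect is
#' \deqn{se(\hat\beta_1) = \sqrt{\frac{4(\hat\sigma_e^2 + n_1\hat\sigma_u^2)}
#'   {n_1 n_2 (1 - r_{xz}^2)}},}
#' with \eqn{r_{xz}} the realized treatment--covariate correlation (zero for
#' the unadjusted model, whose denominator carries no inflation term); this is
#' the exact GLS variance for 0/1 treatment coding. The treatment effect is
#' tested with a two-sided Wald t-test on \eqn{n_2 - 3} (adjusted) or
#' \eqn{n_2 - 2} (unadjusted) degrees of freedom.
#'
#' @param trial a \code{"crt_trial"}.
#' @param adjusted fit the covariate-adjusted model (\code{TRUE}, default) or
#'   the unadjusted model that ignores the covariate.
#' @param alpha two-sided test level for the rejection decision.
#' @return An object of class \code{"crt_lmm"} with the treatment-effect
#'   estimate, its model-based standard error, the covariate-effect estimate
#'   (adjusted model only), REML variance components, degrees of freedom, t
#'   statistic, p value and rejection decision.
#' @examples
#' d <- crt_design(5, 0.1, q = 0.9)
#' tr <- simulate_trial(d, crt_params(beta2 = 0.5, rho = 0.1), seed = 2)
#' crt_lmm(tr)                    # covariate-adjusted
#' crt_lmm(tr, adjusted = FALSE)  # ignoring the covariate
#' @export
crt_lmm <- function(trial, adjusted = TRUE, alpha = 0.05) {
  stopifnot(inherits(trial, "crt_trial"))
  stopifnot(length(alpha) == 1L, alpha > 0, alpha < 1)
  d <- trial$design
  if (d$n1 < 2) stop("within-cluster variance is not estimable with n1 = 1")
  if (adjusted && abs(d$rho_xz) >= 1)
    stop("treatment and covariate are perfectly collinear; the adjusted model is not identifiable")
  ybar <- colMeans(trial$y)
  ssw <- sum(sweep(trial$y, 2L, ybar)^2)
  X <- if (adjusted) cbind(1, d$x, d$z) else cbind(1, d$x)
  fit <- reml_closed_form(ybar, ssw, d$n1, d$n2, X)
  r_xz <- if (adjusted) d$rho_xz else 0
  se <- sqrt(4 * (fit$sigma_e2 + d$n1 * fit$sigma_u2) /
               (d$n1 * d$n2 * (1 - r_xz^2)))
  df <- d$n2 - ncol(X)
  tstat <- fit$beta[2L] / se
  pval <- 2 * stats::pt(-abs(tstat), df)
  structure(list(model = if (adjusted) "adjusted" else "unadjusted",
                 coefficients = stats::setNames(as.vector(fit$beta),
                   if (adjusted) c("(Intercept)", "x", "z") else c("(Intercept)", "x")),
                 beta1_hat = unname(fit$beta[2L]),
                 beta2_hat = if (adjusted) unname(fit$beta[3L]) else NA_real_,
                 se_beta1 = se,
                 sigma_u2_hat = fit$sigma_u2,
                 sigma_e2_hat = fit$sigma_e2,
                 df = df, t_stat = unname(tstat), p_value = unname(pval),
                 reject = unname(abs(tstat) > stats::qt(1 - alpha / 2, df)),
                 alpha = alpha, r_xz = r_xz,
                 n1 = d$n1, n2 = d$n2),
            class = "crt_lmm")
}

#' @export
coef.crt_lmm <- function(object, ...) object$coefficients

#' @export
print.crt_lmm <- function(x, ...) {
  cat(sprintf("%s linear mixed model (closed-form REML, %d clusters x %d subjects)\n",
              if (x$model == "adjusted") "Covariate-adjusted" else "Unadjusted",
              x$n2, x$n1))
  cat(sprintf("  treatment effect: %.4f (se %.4f), t = %.3f on %d df, p = %.4g\n",
              x$beta1_hat, x$se_beta1, x$t_stat, x$df, x$p_value))
  if (x$model == "adjusted")
    cat(sprintf("  covariate effect: %.4f\n", x$beta2_hat))
  cat(sprintf("  variance components: sigma_u2 = %.4f, sigma_e2 = %.4f\n",
              x$sigma_u2_hat, x$sigma_e2_hat))
  invisible(x)
}

#' @export
summary.crt_lmm <- function(object, ...) {
  structure(list(fit = object), class = "summary.crt_lmm")
}

#' @export
print.summary.crt_lmm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  H0: no treatment effect %s at alpha = %.3g (two-sided)\n",
              if (f$reject) "rejected" else "not rejected", f$alpha))
  icc <- f$sigma_u2_hat / (f$sigma_u2_hat + f$sigma_e2_hat)
  cat(sprintf("  estimated ICC: %.4f; realized rho_xz used in the SE: %.3g\n",
              icc, f$r_xz))
  invisible(x)
}
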