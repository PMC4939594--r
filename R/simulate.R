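#' Parameters of the data-generating two-level mixed model
#'
#' The outcome of subject \eqn{i} in cluster \eqn{j} is
#' \deqn{y_{ij} = \beta_0 + \beta_1 x_j + \beta_2 z_j + u_j + e_{ij},}
#' with independent normal random effects \eqn{u_j \sim N(0, \sigma_u^2)} at
#' the cluster level and \eqn{e_{ij} \sim N(0, \sigma_e^2)} at the subject
#' level. By default the total error variance is normalized to
#' \eqn{\sigma_u^2 + \sigma_e^2 = 1}, so supplying the intraclass correlation
#' \code{rho} sets \code{sigma_u2 = rho} and \code{sigma_e2 = 1 - rho};
#' explicit variance components may be given instead. The intercept defaults
#' to 0 — every quantity computed downstream is location-invariant.
#'
#' @param beta1 treatment effect (outcome-SD units when the variance is
#'   normalized).
#' @param beta2 cluster-level covariate effect.
#' @param rho intraclass correlation; shorthand for unit-variance components.
#' @param sigma_u2,sigma_e2 explicit variance components; override \code{rho}.
#' @param beta0 intercept.
#' @return An object of class \code{"crt_params"}.
#' @examples
#' crt_params(beta1 = 0.5, beta2 = 0.8, rho = 0.05)
#' @export
crt_params <- function(beta1 = 0.5, beta2 = 0, rho = NULL,
                       sigma_u2 = NULL, sigma_e2 = NULL, beta0 = 0) {
  if (is.null(sigma_u2) != is.null(sigma_e2))
    stop("supply both 'sigma_u2' and 'sigma_e2', or neither")
  if (is.null(sigma_u2)) {
    if (is.null(rho)) stop("supply 'rho' or explicit variance components")
    stopifnot(length(rho) == 1L, is.finite(rho), rho >= 0, rho < 1)
    sigma_u2 <- rho
    sigma_e2 <- 1 - rho
  }
  stopifnot(is.finite(sigma_u2), sigma_u2 >= 0, is.finite(sigma_e2), sigma_e2 >= 0)
  stopifnot(is.finite(beta0), is.finite(beta1), is.finite(beta2))
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 sigma_u2 = sigma_u2, sigma_e2 = sigma_e2),
            class = "crt_params")
}

#' @export
print.crt_params <- function(x, ...) {
  cat("Two-level mixed-model parameters\n")
  cat(sprintf("  beta0 = %.3g, beta1 = %.3g, beta2 = %.3g\n",
              x$beta0, x$beta1, x$beta2))
  cat(sprintf("  sigma_u2 = %.3g, sigma_e2 = %.3g (ICC %.3g)\n",
              x$sigma_u2, x$sigma_e2,
              x$sigma_u2 / (x$sigma_u2 + x$sigma_e2)))
  invisible(x)
}

#' Generate one trial from the two-level mixed model
#'
#' Draws cluster effects then subject errors (in that order, one block per
#' trial) and assembles the outcomes for the fixed design. The covariate
#' pattern is part of the design and is never resampled: each simulated trial
#' conditions on the same fixed degree of imbalance.
#'
#' @param design a \code{\link{crt_design}}.
#' @param params a \code{\link{crt_params}}.
#' @param seed optional integer; when supplied the RNG is seeded first, so the
#'   same seed reproduces the trial exactly.
#' @return An object of class \code{"crt_trial"}: the design plus an
#'   \code{n1 x n2} outcome matrix \code{y} (subjects in rows, clusters in
#'   columns).
#' @examples
#' d <- crt_design(5, 0.1, q = 0.5)
#' tr <- simulate_trial(d, crt_params(beta2 = 0.5, rho = 0.1), seed = 1)
#' head(as.data.frame(tr))
#' @export
simulate_trial <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "crt_design"), inherits(params, "crt_params"))
  if (!is.null(seed)) set.seed(seed)
  n1 <- design$n1; n2 <- design$n2
  u <- stats::rnorm(n2, 0, sqrt(params$sigma_u2))
  e <- stats::rnorm(n1 * n2, 0, sqrt(params$sigma_e2))
  mu <- params$beta0 + params$beta1 * design$x + params$beta2 * design$z
  y <- matrix(e, n1, n2)
  y <- sweep(y, 2L, mu + u, "+")
  structure(list(design = design, params = params, y = y),
            class = "crt_trial")
}

#' Generate a reproducible stream of replicate trials
#'
#' Seeds the RNG once, then draws \code{reps} trials back to back; each trial
#' consumes one contiguous block of the random number stream (cluster effects
#' first, subject errors second), so the i-th trial of a stream is a pure
#' function of \code{(seed, i)}. The vectorized study runner consumes the
#' stream in exactly the same order and therefore reproduces these trials
#' bitwise (its fitted summaries agree with per-trial \code{\link{crt_lmm}}
#' fits to numerical precision).
#'
#' @inheritParams simulate_trial
#' @param reps number of replicate trials, at least 1.
#' @param seed integer seed for the whole stream.
#' @return A list of \code{reps} \code{"crt_trial"} objects.
#' @export
replicate_trials <- function(design, params, reps, seed) {
  stopifnot(length(reps) == 1L, reps >= 1, reps == round(reps))
  set.seed(seed)
  lapply(seq_len(reps), function(i) simulate_trial(design, params))
}

#' @export
as.data.frame.crt_trial <- function(x, ...) {
  n1 <- x$design$n1; n2 <- x$design$n2
  data.frame(cluster = rep(seq_len(n2), each = n1),
             subject = rep(seq_len(n1), times = n2),
             x = rep(x$design$x, each = n1),
             z = rep(x$design$z, each = n1),
             y = as.vector(x$y))
}

#' @export
print.crt_trial <- function(x, ...) {
  cat(sprintf("Simulated cluster randomized trial: %d clusters x %d subjects\n",
              x$design$n2, x$design$n1))
  cat(sprintf("  q = %.3g (k = %d, rho_xz = %.3g); beta1 = %.3g, beta2 = %.3g\n",
              x$design$q, x$design$k, x$design$rho_xz,
              x$params$beta1, x$params$beta2))
  invisible(x)
}

#' Write a trial to CSV in long format
#'
#' One row per subject with columns cluster, subject, x, z, y; handy for
#' refitting a generated trial in external mixed-model software.
#'
#' @param trial a \code{"crt_trial"}.
#' @param path file path to write to.
#' @return The path, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "crt_trial"))
  utils::write.csv(as.data.frame(trial), path, row.names = FALSE)
  invisible(path)
}
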