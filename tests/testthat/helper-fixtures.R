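# Fixtures built in code: a hand-computable toy trial and a constructor for
# small designs with an arbitrary cluster count (bypassing sample-size
# planning, which ties n2 to n1 and rho).

# Design with n2 clusters, half randomized to intervention, k of them
# covariate-positive (intervention arm first, positives first within arm).
manual_design <- function(n1, n2, k, rho = 0) {
  half <- n2 %/% 2L
  x <- rep(c(1L, 0L), each = half)
  z <- integer(n2)
  if (k > 0) z[seq_len(k)] <- 1L
  if (half - k > 0) z[half + seq_len(half - k)] <- 1L
  structure(list(n1 = as.integer(n1), n2 = as.integer(n2), raw_n2 = NA_real_,
                 rho = rho, q = NA_real_, k = as.integer(k),
                 rho_xz = 4 * k / n2 - 1, x = x, z = z, plan = crt_plan(),
                 min_n2_applied = FALSE),
            class = "crt_design")
}

manual_trial <- function(design, y, params = crt_params(rho = 0)) {
  structure(list(design = design, params = params,
                 y = matrix(y, design$n1, design$n2)),
            class = "crt_trial")
}

# 4 clusters of 2 subjects, x = (0,0,1,1), z = (0,1,0,1); cluster outcomes
# {1,3},{2,4},{3,5},{6,8}. Worked by hand: within SS = 8 on 4 df so
# sigma_e2_hat = 2; adjusted cluster-mean OLS on (2,3,4,7) gives
# beta = (2, 3, 2) with RSS 1 on 1 df; unadjusted OLS gives beta1 = 3 with
# RSS 5 on 2 df.
toy_trial <- function() {
  d <- manual_design(2, 4, 1)
  d$x <- c(0L, 0L, 1L, 1L)           # control arm first in this fixture
  d$z <- c(0L, 1L, 0L, 1L)
  manual_trial(d, c(1, 3, 2, 4, 3, 5, 6, 8))
}

# Random small trial for oracle comparisons.
random_trial <- function(n1 = sample(c(2L, 5L), 1L),
                         n2 = sample(c(8L, 12L), 1L)) {
  k <- sample.int(n2 / 2 - 1L, 1L)   # keep x and z non-collinear
  d <- manual_design(n1, n2, k, rho = 0.2)
  p <- crt_params(beta1 = stats::rnorm(1), beta2 = stats::rnorm(1),
                  sigma_u2 = stats::runif(1, 0.05, 0.5),
                  sigma_e2 = stats::runif(1, 0.3, 1.5))
  simulate_trial(d, p)
}

# Independent REML oracle: dense-matrix restricted log-likelihood for the
# two-level random-intercept model, numerically maximized over the variance
# components with nlminb. No balanced-design shortcuts: V is formed per
# subject and the REML criterion evaluated with generic linear algebra.
oracle_reml <- function(trial, adjusted = TRUE) {
  df <- as.data.frame(trial)
  y <- df$y
  N <- length(y)
  X <- if (adjusted) cbind(1, df$x, df$z) else cbind(1, df$x)
  Z <- stats::model.matrix(~ 0 + factor(df$cluster))
  ZZt <- tcrossprod(Z)
  negll <- function(th) {
    V <- th[1] * ZZt + th[2] * diag(N)
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    logdetV <- 2 * sum(log(diag(ch)))
    Vi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Vi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtViX <- crossprod(X, Vi_X)
    beta <- solve(XtViX, crossprod(X, Vi_y))
    r <- y - X %*% beta
    Vi_r <- backsolve(ch, forwardsolve(t(ch), r))
    0.5 * (logdetV + determinant(XtViX)$modulus[1] + sum(r * Vi_r))
  }
  # profile sigma_e2 out: with V = sigma_e2 (r ZZ' + I), the REML criterion
  # reduces to a smooth 1-D function of the variance ratio r, which optimize()
  # pins down to near machine precision
  p <- ncol(X)
  profiled <- function(tlog) {
    W <- exp(tlog) * ZZt + diag(N)
    ch <- chol(W)
    Wi_X <- backsolve(ch, forwardsolve(t(ch), X))
    Wi_y <- backsolve(ch, forwardsolve(t(ch), y))
    XtWiX <- crossprod(X, Wi_X)
    beta <- solve(XtWiX, crossprod(X, Wi_y))
    r <- y - X %*% beta
    Wi_r <- backsolve(ch, forwardsolve(t(ch), r))
    s2 <- sum(r * Wi_r) / (N - p)
    (N - p) * log(s2) + 2 * sum(log(diag(ch))) +
      determinant(XtWiX)$modulus[1]
  }
  opt <- stats::optimize(profiled, c(-25, 6), tol = 1e-12)
  ratio <- exp(opt$minimum)
  W <- ratio * ZZt + diag(N)
  XtWiX <- crossprod(X, solve(W, X))
  beta0 <- solve(XtWiX, crossprod(X, solve(W, y)))
  s2 <- sum((y - X %*% beta0) * solve(W, y - X %*% beta0)) / (N - p)
  th <- c(ratio * s2, s2)
  # cross-check against the unprofiled 2-D criterion
  stopifnot(negll(th) <= stats::nlminb(c(0.2, 0.5), negll,
                                       lower = c(0, 1e-10))$objective + 1e-6)
  V <- th[1] * ZZt + th[2] * diag(N)
  XtViX <- crossprod(X, solve(V, X))
  beta <- solve(XtViX, crossprod(X, solve(V, y)))
  list(sigma_u2 = th[1], sigma_e2 = th[2], beta = as.vector(beta),
       se_beta1 = sqrt(solve(XtViX)[2, 2]))
}
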