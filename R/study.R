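## Factorial simulation study: grid construction, per-condition Monte Carlo,
## aggregation and threshold verification.

#' Factorial grid of simulation conditions
#'
#' Full Cartesian product of cluster size, intraclass correlation, covariate
#' effect size and imbalance quantile, in a fixed deterministic order, with
#' the study constants (treatment effect, test level, target power,
#' intercept) attached to every row. The default levels give the 3 x 3 x 3 x 7
#' = 189 conditions of the core study.
#'
#' @param n1 cluster sizes.
#' @param rho intraclass correlation coefficients.
#' @param beta2 covariate effect sizes.
#' @param q hypergeometric imbalance quantiles.
#' @param beta1 treatment effect used both to generate and to plan.
#' @param alpha two-sided test level.
#' @param power_target design-stage power.
#' @param beta0 intercept of the generating model.
#' @return A data frame with one row per condition and a \code{condition}
#'   index column.
#' @examples
#' nrow(crt_grid())   # 189
#' @export
crt_grid <- function(n1 = c(5, 30, 50), rho = c(0.01, 0.05, 0.1),
                     beta2 = c(0.2, 0.5, 0.8),
                     q = c(0.025, 0.05, 0.1, 0.5, 0.9, 0.95, 0.975),
                     beta1 = 0.5, alpha = 0.05, power_target = 0.8,
                     beta0 = 0) {
  for (nm in c("n1", "rho", "beta2", "q")) {
    v <- get(nm)
    if (length(v) < 1L || anyNA(v)) stop("factor set '", nm, "' must be non-empty and free of NA")
    if (anyDuplicated(v)) stop("factor set '", nm, "' has duplicated levels")
  }
  g <- expand.grid(n1 = n1, rho = rho, beta2 = beta2, q = q,
                   KEEP.OUT.ATTRS = FALSE)
  g$beta1 <- beta1
  g$alpha <- alpha
  g$power_target <- power_target
  g$beta0 <- beta0
  cbind(condition = seq_len(nrow(g)), g)
}

## Seed for one condition, derived from the master seed and an integer key
## encoding the factor tuple itself (not the execution order), so conditions
## can be run singly, reordered or in parallel with identical streams.
## All arithmetic stays below 2^53 and the result below 2^31 - 1.
condition_seed <- function(master_seed, n1, rho, beta2, q) {
  key <- ((n1 * 1000 + round(rho * 1000)) * 1000 + round(beta2 * 1000)) *
    10000 + round(q * 10000)
  m <- 2147483647
  as.integer(((as.numeric(master_seed) %% m) * 48271 + key) %% m)
}

## Vectorized generation + closed-form fits for one condition. Replicate r
## consumes the r-th contiguous block of the seeded normal stream (cluster
## effects first, then subject errors), which reproduces replicate_trials()
## followed by crt_lmm() bitwise.
sim_condition_fits <- function(design, params, reps, seed, alpha = 0.05) {
  n1 <- design$n1; n2 <- design$n2
  L <- n2 + n1 * n2
  set.seed(seed)
  D <- matrix(stats::rnorm(L * reps), L, reps)
  U <- D[seq_len(n2), , drop = FALSE] * sqrt(params$sigma_u2)
  E <- D[n2 + seq_len(n1 * n2), , drop = FALSE] * sqrt(params$sigma_e2)
  mu <- params$beta0 + params$beta1 * design$x + params$beta2 * design$z
  ebar <- matrix(.colMeans(E, n1, n2 * reps), n2, reps)
  wss <- .colSums(E^2, n1, n2 * reps) - n1 * as.vector(ebar)^2
  ssw <- .colSums(matrix(wss, n2, reps), n2, reps)
  M <- mu + U + ebar                       # cluster means, n2 x reps
  sigma_e2 <- ssw / (n2 * (n1 - 1))

  one_model <- function(adjusted) {
    X <- if (adjusted) cbind(1, design$x, design$z) else cbind(1, design$x)
    p <- ncol(X)
    coefs <- solve(crossprod(X), crossprod(X, M))
    RSS <- .colSums((M - X %*% coefs)^2, n2, reps)
    su2 <- pmax(0, RSS / (n2 - p) - sigma_e2 / n1)
    r_xz <- if (adjusted) design$rho_xz else 0
    se <- sqrt(4 * (sigma_e2 + n1 * su2) / (n1 * n2 * (1 - r_xz^2)))
    tstat <- coefs[2L, ] / se
    list(est = coefs[2L, ], se = se, sigma_u2 = su2, sigma_e2 = sigma_e2,
         t = tstat, reject = abs(tstat) > stats::qt(1 - alpha / 2, n2 - p),
         df = n2 - p)
  }
  out <- list(unadjusted = one_model(FALSE))
  if (abs(design$rho_xz) < 1) out$adjusted <- one_model(TRUE)
  out
}

summarize_model <- function(fits, cond, design, reps, model) {
  est <- fits$est
  sd_est <- stats::sd(est)
  mean_se <- mean(fits$se)
  power <- empirical_power_pct(fits$reject)
  data.frame(
    condition = cond$condition, n1 = cond$n1, rho = cond$rho,
    beta2 = cond$beta2, q = cond$q, n2 = design$n2, k = design$k,
    rho_xz = design$rho_xz, raw_n2 = design$raw_n2,
    min_n2_applied = design$min_n2_applied,
    model = model, reps = reps, failures = 0L,
    mean_beta1_hat = mean(est),
    parameter_bias_pct = parameter_bias_pct(est, cond$beta1),
    bias_mcse_pct = 100 * sd_est / (sqrt(reps) * abs(cond$beta1)),
    mean_se = mean_se, sd_beta1_hat = sd_est,
    se_bias_pct = se_bias_pct(mean_se, sd_est),
    se_bias_mcse_pct = 100 * sqrt(stats::var(fits$se) / (reps * sd_est^2) +
                                    (mean_se / sd_est)^2 / (2 * (reps - 1))),
    empirical_power_pct = power,
    power_mcse_pct = sqrt(power * (100 - power) / reps),
    expected_bias_pct = if (model == "unadjusted")
      expected_unadjusted_bias_pct(cond$beta1, cond$beta2, design$n2, design$k)
    else 0,
    nominal_power_pct = nominal_power_pct(cond$n1, design$n2, cond$rho,
                                          cond$beta1, cond$alpha),
    nominal_power_t_pct = nominal_power_pct(cond$n1, design$n2, cond$rho,
                                            cond$beta1, cond$alpha,
                                            method = "t", df = design$n2 - 3),
    stringsAsFactors = FALSE)
}

#' Run the Monte-Carlo simulation for one condition
#'
#' Builds the design (cluster count planned under covariate balance, degree of
#' imbalance fixed at the condition's hypergeometric quantile), generates
#' \code{reps} trials from the covariate-adjusted generating model, fits both
#' the adjusted and the unadjusted linear mixed model to every trial by
#' closed-form REML, and aggregates the three evaluation criteria. Fully
#' deterministic given \code{(condition, reps, master_seed)}; the per-condition
#' seed depends on the factor tuple, not on execution order.
#'
#' @param condition a one-row data frame (or list) with at least \code{n1},
#'   \code{rho}, \code{beta2}, \code{q}; constants \code{beta1}, \code{alpha},
#'   \code{power_target}, \code{beta0} default to the core-study values when
#'   absent. Rows of \code{\link{crt_grid}} qualify.
#' @param reps replicates (at least 2).
#' @param master_seed integer master seed for the whole study.
#' @param min_n2 minimum planned cluster count (multiple of 4).
#' @return A data frame with one row per model (adjusted, unadjusted) carrying
#'   the condition, design, bias, standard-error and power summaries together
#'   with their Monte-Carlo standard errors. If an extreme quantile forces
#'   perfect treatment--covariate collinearity the adjusted row reports all
#'   replicates as failures instead of estimates.
#' @examples
#' run_condition(list(n1 = 5, rho = 0.1, beta2 = 0.5, q = 0.9), reps = 200,
#'               master_seed = 1)
#' @export
run_condition <- function(condition, reps = 5000, master_seed = 1L,
                          min_n2 = 8L) {
  stopifnot(reps >= 2, reps == round(reps))
  cond <- as.list(condition)
  defaults <- list(beta1 = 0.5, alpha = 0.05, power_target = 0.8, beta0 = 0,
                   condition = NA_integer_)
  for (nm in names(defaults)) if (is.null(cond[[nm]])) cond[[nm]] <- defaults[[nm]]
  for (nm in c("n1", "rho", "beta2", "q"))
    if (is.null(cond[[nm]])) stop("condition is missing factor '", nm, "'")
  plan <- crt_plan(alpha = cond$alpha, power = cond$power_target,
                   beta1 = cond$beta1, rho_xz = 0)
  design <- crt_design(cond$n1, cond$rho, cond$q, plan, min_n2,
                       allow_collinear = TRUE)
  seed <- condition_seed(master_seed, cond$n1, cond$rho, cond$beta2, cond$q)
  params <- crt_params(beta1 = cond$beta1, beta2 = cond$beta2,
                       rho = cond$rho, beta0 = cond$beta0)
  fits <- sim_condition_fits(design, params, reps, seed, alpha = cond$alpha)
  rows <- list(summarize_model(fits$unadjusted, cond, design, reps, "unadjusted"))
  if (!is.null(fits$adjusted)) {
    rows <- c(list(summarize_model(fits$adjusted, cond, design, reps, "adjusted")),
              rows)
  } else {
    ## perfectly collinear quantile: every adjusted replicate fails
    failed <- rows[[1L]]
    failed$model <- "adjusted"
    failed$failures <- as.integer(reps)
    failed$reps <- 0L
    num <- c("mean_beta1_hat", "parameter_bias_pct", "bias_mcse_pct",
             "mean_se", "sd_beta1_hat", "se_bias_pct", "se_bias_mcse_pct",
             "empirical_power_pct", "power_mcse_pct", "expected_bias_pct")
    failed[num] <- NA_real_
    rows <- c(list(failed), rows)
  }
  do.call(rbind, rows)
}

#' Run the full factorial study
#'
#' Executes \code{\link{run_condition}} for every row of the grid and stacks
#' the summaries into a long-format table (one row per condition per model).
#' When \code{out} is given the table is written as CSV alongside a companion
#' JSON metadata file recording the grid, seed, replicate count, package
#' version and any conditions where the minimum-cluster floor was applied.
#'
#' @param grid a condition grid from \code{\link{crt_grid}}.
#' @param reps replicates per condition.
#' @param master_seed integer master seed.
#' @param out optional path of the results CSV.
#' @param min_n2 minimum planned cluster count.
#' @param verbose print per-condition progress?
#' @return The results data frame, invisibly when written to \code{out}.
#' @export
run_study <- function(grid = crt_grid(), reps = 5000, master_seed = 1L,
                      out = NULL, min_n2 = 8L, verbose = FALSE) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows[[i]] <- run_condition(grid[i, , drop = FALSE], reps, master_seed,
                               min_n2)
    if (verbose && i %% 10L == 0L)
      message(sprintf("condition %d / %d", i, nrow(grid)))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  if (!is.null(out)) {
    utils::write.csv(results, out, row.names = FALSE)
    meta <- list(
      package = "crtimbalance",
      version = as.character(utils::packageVersion("crtimbalance")),
      reps = reps, master_seed = master_seed, min_n2 = min_n2,
      conditions = nrow(grid),
      factor_levels = list(n1 = sort(unique(grid$n1)),
                           rho = sort(unique(grid$rho)),
                           beta2 = sort(unique(grid$beta2)),
                           q = sort(unique(grid$q))),
      constants = list(beta1 = unique(grid$beta1),
                       alpha = unique(grid$alpha),
                       power_target = unique(grid$power_target),
                       beta0 = unique(grid$beta0)),
      min_n2_conditions = unique(results$condition[results$min_n2_applied]))
    jsonlite::write_json(meta, sub("\\.csv$", "", out) %+% "-meta.json",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(results))
  }
  results
}

`%+%` <- function(a, b) paste0(a, b)

#' Verify a results table against the acceptability thresholds
#'
#' Flags conditions whose absolute parameter bias exceeds 10 % or whose
#' absolute standard-error bias exceeds 5 % (the conventional acceptability
#' bounds for simulation studies of estimator performance), per model, and
#' reports the grid-wide extrema: the signed parameter and standard-error
#' biases of largest magnitude per model and the adjusted model's largest
#' power shortfall relative to the t-based nominal power (the power the
#' design-stage test attains at covariate balance, which is what the
#' empirical power approaches there; the normal-approximation nominal value
#' overstates it at small cluster counts).
#'
#' @param results a results table from \code{\link{run_study}}.
#' @param param_tol acceptability bound on |parameter bias|, percent.
#' @param se_tol acceptability bound on |standard-error bias|, percent.
#' @return An object of class \code{"crt_verification"}: a list with
#'   \code{flags} (offending rows) and \code{extrema}.
#' @export
verify_report <- function(results, param_tol = 10, se_tol = 5) {
  needed <- c("condition", "model", "parameter_bias_pct", "se_bias_pct",
              "empirical_power_pct", "nominal_power_pct",
              "nominal_power_t_pct", "n1", "rho")
  if (!is.data.frame(results) || nrow(results) == 0L ||
      !all(needed %in% names(results)))
    stop("malformed results table: expected a non-empty data frame with columns ",
         paste(needed, collapse = ", "))
  flags <- results[which(abs(results$parameter_bias_pct) > param_tol |
                           abs(results$se_bias_pct) > se_tol), , drop = FALSE]
  signed_extreme <- function(v) v[which.max(abs(v))]
  extrema <- list()
  for (m in unique(results$model)) {
    sub <- results[results$model == m & !is.na(results$parameter_bias_pct),
                   , drop = FALSE]
    if (nrow(sub) == 0L) next
    extrema[[m]] <- list(
      parameter_bias_pct = signed_extreme(sub$parameter_bias_pct),
      se_bias_pct = signed_extreme(sub$se_bias_pct))
    if (m == "adjusted") {
      ## power loss is measured against the t-based nominal value: that is
      ## the power the design-stage test actually attains at balance, and the
      ## reference the empirical curves are compared to
      loss <- sub$nominal_power_t_pct - sub$empirical_power_pct
      i <- which.max(loss)
      extrema[[m]]$max_power_loss_pct <- loss[i]
      extrema[[m]]$max_power_loss_at <- sub[i, c("n1", "rho", "beta2", "q")]
    }
  }
  structure(list(flags = flags, extrema = extrema,
                 param_tol = param_tol, se_tol = se_tol),
            class = "crt_verification")
}

#' @export
print.crt_verification <- function(x, ...) {
  cat("Verification against acceptability thresholds (|parameter bias| <",
      x$param_tol, "%, |SE bias| <", x$se_tol, "%)\n")
  for (m in names(x$extrema)) {
    e <- x$extrema[[m]]
    cat(sprintf("  %-10s extreme parameter bias %7.2f %%, extreme SE bias %7.2f %%\n",
                m, e$parameter_bias_pct, e$se_bias_pct))
    if (!is.null(e$max_power_loss_pct))
      cat(sprintf("  %-10s max power loss vs nominal %.2f points (n1=%g, rho=%g, beta2=%g, q=%g)\n",
                  "", e$max_power_loss_pct, e$max_power_loss_at$n1,
                  e$max_power_loss_at$rho, e$max_power_loss_at$beta2,
                  e$max_power_loss_at$q))
  }
  nf <- nrow(x$flags)
  cat(if (nf == 0L) "  no conditions flagged\n"
      else sprintf("  %d condition-model rows flagged\n", nf))
  invisible(x)
}

#' Read a study configuration file
#'
#' YAML with optional blocks \code{factor_levels} (\code{n1}, \code{rho},
#' \code{beta2}, \code{q}), \code{constants} (\code{beta1}, \code{alpha},
#' \code{power_target}, \code{beta0}) and \code{run} (\code{reps},
#' \code{seed}, \code{min_n2}); anything omitted falls back to the core-study
#' defaults.
#'
#' @param path path to the YAML file.
#' @return A list with elements \code{grid} (via \code{\link{crt_grid}}),
#'   \code{reps}, \code{seed} and \code{min_n2}.
#' @export
read_study_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  fl <- cfg$factor_levels
  co <- cfg$constants
  run <- cfg$run
  pick <- function(block, nm, default) {
    v <- block[[nm]]
    if (is.null(v)) default else v
  }
  grid <- crt_grid(
    n1 = pick(fl, "n1", c(5, 30, 50)),
    rho = pick(fl, "rho", c(0.01, 0.05, 0.1)),
    beta2 = pick(fl, "beta2", c(0.2, 0.5, 0.8)),
    q = pick(fl, "q", c(0.025, 0.05, 0.1, 0.5, 0.9, 0.95, 0.975)),
    beta1 = pick(co, "beta1", 0.5),
    alpha = pick(co, "alpha", 0.05),
    power_target = pick(co, "power_target", 0.8),
    beta0 = pick(co, "beta0", 0))
  list(grid = grid,
       reps = pick(run, "reps", 5000),
       seed = pick(run, "seed", 1L),
       min_n2 = pick(run, "min_n2", 8L))
}
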