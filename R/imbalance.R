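## Imbalance of a 50/50 binary cluster-level covariate under 1:1 cluster
## randomization. With n2 clusters, n2/2 covariate-positive, and n2/2
## randomized to intervention, the number K of covariate-positive clusters in
## the intervention arm is hypergeometric(n2, n2/2, n2/2); the degree of
## imbalance is expressed as a quantile of that distribution.

check_n2 <- function(n2) {
  stopifnot(length(n2) == 1L, is.finite(n2))
  if (n2 <= 0 || n2 %% 4 != 0)
    stop("'n2' must be a positive multiple of 4 so that each arm can hold ",
         "equally many covariate-positive and -negative clusters at balance")
  as.integer(n2)
}

#' Distribution of the covariate-positive count in the intervention arm
#'
#' Under complete 1:1 randomization of \code{n2} clusters, half of which carry
#' the covariate, the count of covariate-positive clusters assigned to the
#' intervention arm follows a hypergeometric distribution with population
#' \code{n2}, \code{n2/2} successes and \code{n2/2} draws.
#' \code{imbalance_pmf} gives its probability mass function and
#' \code{imbalance_quantile} the smallest count \code{k} whose cumulative
#' probability reaches \code{q}; the median quantile \code{q = 0.5} returns
#' \code{n2/4}, i.e. perfect balance.
#'
#' @param n2 total number of clusters; positive multiple of 4.
#' @param k count of covariate-positive intervention clusters, in
#'   \code{0:(n2/2)}.
#' @param q quantile level, strictly between 0 and 1.
#'
#' @return \code{imbalance_pmf}: the probability P(K = k).
#'   \code{imbalance_quantile}: the integer count k.
#' @examples
#' imbalance_pmf(4, 1)             # 2/3
#' imbalance_quantile(20, 0.95)    # 7, i.e. 70% covariate-positive
#' imbalance_quantile(200, 0.95)   # 56, i.e. 56%
#' @export
imbalance_pmf <- function(n2, k) {
  n2 <- check_n2(n2)
  stopifnot(length(k) >= 1L, all(is.finite(k)), all(k == round(k)))
  if (any(k < 0) || any(k > n2 / 2))
    stop("'k' must lie between 0 and n2/2")
  stats::dhyper(k, m = n2 / 2, n = n2 / 2, k = n2 / 2)
}

#' @rdname imbalance_pmf
#' @export
imbalance_quantile <- function(n2, q) {
  n2 <- check_n2(n2)
  stopifnot(length(q) == 1L, is.finite(q))
  if (q <= 0 || q >= 1) stop("'q' must lie strictly between 0 and 1")
  as.integer(stats::qhyper(q, m = n2 / 2, n = n2 / 2, k = n2 / 2))
}

#' Treatment--covariate correlation implied by an imbalance count
#'
#' With a 50/50 covariate and 1:1 allocation over \code{n2} clusters, the
#' Pearson correlation between the binary treatment indicator and the binary
#' covariate is determined by the count \code{k} of covariate-positive
#' intervention clusters alone: \eqn{\rho_{xz} = 4k/n_2 - 1}.
#'
#' @inheritParams imbalance_pmf
#' @return The correlation, in [-1, 1].
#' @examples
#' rho_xz_from_k(20, 5)   # 0: perfect balance
#' rho_xz_from_k(12, 5)   # 2/3: strong positive imbalance
#' @export
rho_xz_from_k <- function(n2, k) {
  n2 <- check_n2(n2)
  stopifnot(length(k) >= 1L, all(is.finite(k)), all(k == round(k)))
  if (any(k < 0) || any(k > n2 / 2))
    stop("'k' must lie between 0 and n2/2")
  4 * k / n2 - 1
}

#' Build a fully realized trial design at a fixed degree of imbalance
#'
#' Plans the number of clusters with \code{\link{required_clusters}} under the
#' assumption of covariate balance (\code{rho_xz = 0} in the plan, as is usual
#' design practice), then fixes the degree of covariate imbalance at the
#' hypergeometric quantile \code{q}: \code{k = imbalance_quantile(n2, q)}
#' covariate-positive clusters are placed in the intervention arm and the
#' remaining \code{n2/2 - k} in the control arm. Cluster ordering is
#' deterministic (intervention arm first, covariate-positive clusters first
#' within each arm); the ordering is exchangeable under the model, so nothing
#' downstream depends on it.
#'
#' @inheritParams required_clusters
#' @param q hypergeometric imbalance quantile in (0, 1); 0.5 gives perfect
#'   balance.
#' @param allow_collinear permit \code{rho_xz = ±1} designs (on which only the
#'   unadjusted model is identifiable) instead of raising an error; used by
#'   the study runner to count rather than abort collinear conditions.
#' @return An object of class \code{"crt_design"}: a list with the cluster
#'   size \code{n1}, cluster count \code{n2} (and unrounded \code{raw_n2}),
#'   ICC \code{rho}, per-cluster treatment indicator \code{x} and covariate
#'   indicator \code{z}, imbalance count \code{k}, quantile \code{q}, realized
#'   correlation \code{rho_xz}, and whether the \code{min_n2} floor was
#'   applied.
#' @examples
#' crt_design(30, 0.05, q = 0.5)     # 12 clusters, balanced
#' crt_design(30, 0.05, q = 0.975)   # same size, rho_xz = 2/3
#' @export
crt_design <- function(n1, rho, q, plan = crt_plan(), min_n2 = 8L,
                       allow_collinear = FALSE) {
  stopifnot(length(n1) == 1L, is.finite(n1), n1 >= 1, n1 == round(n1))
  plan_bal <- crt_plan(alpha = plan$alpha, power = plan$power,
                       beta1 = plan$beta1, rho_xz = 0)
  size <- required_clusters(n1, rho, plan_bal, min_n2 = min_n2)
  n2 <- size$n2
  k <- imbalance_quantile(n2, q)
  r <- rho_xz_from_k(n2, k)
  if (abs(r) >= 1 && !allow_collinear)
    stop("degree of imbalance q = ", q, " makes treatment and covariate ",
         "perfectly collinear at n2 = ", n2,
         "; raise 'min_n2' to keep the adjusted model identifiable")
  half <- n2 %/% 2L
  x <- rep(c(1L, 0L), each = half)
  z <- integer(n2)
  if (k > 0) z[seq_len(k)] <- 1L                      # intervention arm
  m_ctrl <- half - k                                   # control arm
  if (m_ctrl > 0) z[half + seq_len(m_ctrl)] <- 1L
  structure(list(n1 = as.integer(n1), n2 = n2, raw_n2 = size$raw,
                 rho = rho, q = q, k = k, rho_xz = r, x = x, z = z,
                 plan = plan_bal, min_n2_applied = size$floored),
            class = "crt_design")
}

#' @export
print.crt_design <- function(x, ...) {
  cat("Cluster randomized trial design\n")
  cat(sprintf("  %d clusters of size %d (raw requirement %.2f), ICC %.3g\n",
              x$n2, x$n1, x$raw_n2, x$rho))
  cat(sprintf("  imbalance quantile q = %.3g: %d of %d intervention clusters covariate-positive\n",
              x$q, x$k, x$n2 %/% 2L))
  cat(sprintf("  realized treatment-covariate correlation rho_xz = %.4g\n", x$rho_xz))
  if (x$min_n2_applied)
    cat("  note: cluster count raised to the configured minimum\n")
  invisible(x)
}

#' Tabulate planned designs over a grid of scenarios
#'
#' Convenience wrapper producing one row per (n1, rho, q) combination with the
#' planned and rounded cluster count, the imbalance count and the realized
#' treatment--covariate correlation; suitable for export with
#' \code{write.csv}.
#'
#' @param n1 vector of cluster sizes.
#' @param rho vector of intraclass correlation coefficients.
#' @param q vector of imbalance quantiles.
#' @inheritParams required_clusters
#' @return A data frame with columns \code{n1, rho, q, raw_n2, n2, k, rho_xz}.
#' @export
planning_table <- function(n1, rho, q, plan = crt_plan(), min_n2 = 8L) {
  grid <- expand.grid(n1 = n1, rho = rho, q = q, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- crt_design(grid$n1[i], grid$rho[i], grid$q[i], plan, min_n2)
    data.frame(n1 = d$n1, rho = d$rho, q = d$q, raw_n2 = d$raw_n2,
               n2 = d$n2, k = d$k, rho_xz = d$rho_xz)
  })
  do.call(rbind, rows)
}
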