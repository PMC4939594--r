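test_that("imbalance pmf matches brute-force enumeration of randomizations", {
  # enumerate all C(4,2) = 6 intervention-arm subsets of 4 clusters, 2 of
  # which are covariate-positive, and count subsets with exactly one positive
  subsets <- utils::combn(4, 2)
  positives <- c(TRUE, TRUE, FALSE, FALSE)
  counts <- apply(subsets, 2, function(s) sum(positives[s]))
  for (k in 0:2)
    expect_equal(imbalance_pmf(4, k), mean(counts == k), tolerance = 1e-12)
  expect_equal(imbalance_pmf(20, 7),
               choose(10, 7) * choose(10, 3) / choose(20, 10),
               tolerance = 1e-12)
})

test_that("imbalance pmf normalizes and rejects invalid input", {
  for (n2 in c(4L, 8L, 12L, 20L, 36L, 200L))
    expect_equal(sum(imbalance_pmf(n2, 0:(n2 / 2))), 1, tolerance = 1e-12)
  expect_error(imbalance_pmf(10, 2), "multiple of 4")
  expect_error(imbalance_pmf(-8, 2), "multiple of 4")
  expect_error(imbalance_pmf(20, 11), "between 0 and n2/2")
})

test_that("imbalance quantile reproduces the printed percentage anchors", {
  expect_identical(imbalance_quantile(20, 0.95), 7L)    # 70 % of the arm
  expect_identical(imbalance_quantile(200, 0.95), 56L)  # 56 % of the arm
  expect_identical(imbalance_quantile(20, 0.5), 5L)     # the expectation n2/4
  expect_error(imbalance_quantile(20, 0), "strictly between")
  expect_error(imbalance_quantile(20, 1), "strictly between")
})

test_that("quantile and CDF are dual and the quantile is monotone in q", {
  qs <- c(0.01, 0.025, 0.05, 0.1, 0.3, 0.5, 0.7, 0.9, 0.95, 0.975, 0.999)
  for (n2 in c(8L, 12L, 20L, 28L, 36L, 200L)) {
    cdf <- cumsum(imbalance_pmf(n2, 0:(n2 / 2)))
    ks <- vapply(qs, function(q) imbalance_quantile(n2, q), integer(1))
    expect_true(all(diff(ks) >= 0))
    expect_identical(imbalance_quantile(n2, 0.5), as.integer(n2 / 4))
    for (i in seq_along(qs)) {
      k <- ks[i]
      expect_gte(cdf[k + 1], qs[i])
      if (k > 0) expect_lt(cdf[k], qs[i])
    }
  }
})

test_that("rho_xz_from_k equals the Pearson correlation of the implied vectors", {
  expect_equal(rho_xz_from_k(20, 5), 0)
  expect_equal(rho_xz_from_k(8, 4), 1)
  expect_equal(rho_xz_from_k(12, 5), 2 / 3, tolerance = 1e-12)
  for (n2 in c(8L, 12L, 20L)) {
    for (k in 1:(n2 / 2 - 1)) {
      d <- manual_design(2, n2, k)
      expect_equal(rho_xz_from_k(n2, k), stats::cor(d$x, d$z),
                   tolerance = 1e-12)
    }
  }
})

test_that("required cluster counts match the design-effect formula", {
  zsum <- qnorm(0.975) + qnorm(0.8)
  # standard CRT form: 4 * design effect / n1 * (z-sum / beta1)^2 at sigma2 = 1
  deff <- function(n1, rho) 1 + (n1 - 1) * rho
  for (case in list(c(30, 0.05), c(5, 0.1), c(5, 0.01), c(50, 0.1))) {
    rc <- required_clusters(case[1], case[2])
    expect_equal(rc$raw, 4 * deff(case[1], case[2]) / case[1] * (zsum / 0.5)^2,
                 tolerance = 1e-12)
  }
  expect_equal(required_clusters(30, 0.05)$raw, 10.25587, tolerance = 1e-6)
  expect_identical(required_clusters(30, 0.05)$n2, 12L)
  expect_equal(required_clusters(5, 0.1)$raw, 35.16298, tolerance = 1e-6)
  expect_identical(required_clusters(5, 0.1)$n2, 36L)
  expect_identical(required_clusters(5, 0.01)$n2, 28L)
})

test_that("planning anticipates imbalance through the variance inflation factor", {
  for (rho in c(0.01, 0.1)) {
    bal <- required_clusters(30, rho, crt_plan(rho_xz = 0))
    imb <- required_clusters(30, rho, crt_plan(rho_xz = 0.5))
    expect_equal(imb$raw / bal$raw, 1 / (1 - 0.25), tolerance = 1e-12)
  }
  expect_error(crt_plan(rho_xz = 1), "strictly between")
})

test_that("required clusters are monotone in the ICC and floored at min_n2", {
  raws <- vapply(c(0.01, 0.05, 0.1, 0.3), function(r)
    required_clusters(30, r)$raw, numeric(1))
  expect_true(all(diff(raws) > 0))
  rc <- required_clusters(50, 0.01)          # raw 3.74: formula alone gives 4
  expect_lt(rc$raw, 8)
  expect_identical(rc$n2, 8L)
  expect_true(rc$floored)
  expect_false(required_clusters(30, 0.05)$floored)
})

test_that("realized designs satisfy their structural invariants", {
  cases <- expand.grid(n1 = c(5, 30, 50), rho = c(0.01, 0.1),
                       q = c(0.025, 0.5, 0.975))
  for (i in seq_len(nrow(cases))) {
    d <- crt_design(cases$n1[i], cases$rho[i], cases$q[i])
    expect_identical(d$n2 %% 4L, 0L)
    expect_identical(sum(d$x), d$n2 %/% 2L)
    expect_identical(sum(d$z), d$n2 %/% 2L)
    expect_identical(sum(d$x == 1L & d$z == 1L), d$k)
    expect_identical(d$k, imbalance_quantile(d$n2, d$q))
    expect_equal(d$rho_xz, stats::cor(d$x, d$z), tolerance = 1e-12)
  }
})

test_that("design composition reproduces the worked planning examples", {
  d <- crt_design(30, 0.05, q = 0.5)
  expect_identical(c(d$n2, d$k), c(12L, 3L))
  expect_equal(d$rho_xz, 0)
  d <- crt_design(30, 0.05, q = 0.975)
  expect_identical(d$k, 5L)
  expect_equal(d$rho_xz, 2 / 3, tolerance = 1e-12)
  expect_identical(crt_design(5, 0.01, q = 0.5)$n2, 28L)
})

test_that("collinear quantiles error unless the minimum cluster count prevents them", {
  # n1 = 50, rho = 0.01 gives n2 = 4 from the formula alone; at q = 0.975 the
  # quantile is k = 2 = n2/2, i.e. x and z identical
  expect_error(crt_design(50, 0.01, q = 0.975, min_n2 = 4L), "collinear")
  expect_silent(d <- crt_design(50, 0.01, q = 0.975, min_n2 = 8L))
  expect_lt(abs(d$rho_xz), 1)
})

test_that("complete randomization reproduces the hypergeometric imbalance law", {
  set.seed(401)
  n2 <- 12L
  sims <- replicate(20000, {
    arm <- sample.int(n2, n2 / 2)
    sum(arm <= n2 / 2)     # first n2/2 clusters are the covariate-positives
  })
  pmf <- imbalance_pmf(n2, 0:(n2 / 2))
  emp <- tabulate(sims + 1L, nbins = n2 / 2 + 1) / length(sims)
  mcse <- sqrt(pmf * (1 - pmf) / length(sims))
  expect_true(all(abs(emp - pmf) < 4 * mcse + 1e-12))
})

test_that("planning tables export one row per scenario", {
  tab <- planning_table(n1 = c(5, 30), rho = c(0.01, 0.1), q = c(0.5, 0.95))
  expect_identical(nrow(tab), 8L)
  expect_named(tab, c("n1", "rho", "q", "raw_n2", "n2", "k", "rho_xz"))
  expect_true(all(tab$n2 %% 4 == 0))
})
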