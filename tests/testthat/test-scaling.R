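test_that("hurwitz zeta matches closed forms, pracma and the recurrence", {
  expect_equal(hurwitz_zeta(2, 1), pi^2 / 6, tolerance = 1e-13)
  expect_equal(hurwitz_zeta(4, 1), pi^4 / 90, tolerance = 1e-13)
  for (s in c(1.5, 2.26, 3.5)) {
    expect_equal(hurwitz_zeta(s, 1), pracma::zeta(s), tolerance = 1e-12)
    # zeta(s, a) = zeta(s, 1) - sum_{j<a} j^-s
    for (a in c(2, 10, 57)) {
      expect_lt(abs(hurwitz_zeta(s, a) -
                      (hurwitz_zeta(s, 1) - sum((1:(a - 1))^(-s)))),
                1e-11)
    }
  }
  expect_error(hurwitz_zeta(0.9, 1), "s > 1")
})

test_that("log-log slope fit recovers noiseless exponents exactly", {
  for (gamma in c(0, 0.5, 1, 2.26)) {
    k <- c(1L, 2L, 4L, 8L, 16L)
    prof <- degree_profile(k, 3.7 * k^(-gamma), rep(1L, 5L), "p")
    fit <- fit_loglog_slope(prof)
    expect_equal(fit$exponent, gamma, tolerance = 1e-12)
    expect_lt(fit$ks_stat, 1e-12)
  }
  const <- degree_profile(c(1L, 2L, 4L), rep(0.3, 3L), rep(1L, 3L), "c")
  expect_equal(fit_loglog_slope(const)$exponent, 0, tolerance = 1e-12)
  too_few <- degree_profile(c(1L, 2L), c(1, 0.5), c(1L, 1L), "c")
  expect_error(fit_loglog_slope(too_few), "insufficient support")
})

test_that("ravasz clustering profile shows the k^-1 hierarchical signature", {
  fit <- fit_loglog_slope(clustering_by_degree(ravasz_network(3L, 5L)))
  expect_gt(fit$exponent, 0.85)
  expect_lt(fit$exponent, 1.15)
})

test_that("discrete MLE recovers generating exponents and rejects uniforms", {
  x <- powerlaw_samples(2.5, 1L, 10000L, rng_seed = 7L)
  fit <- fit_powerlaw_mle(x, n_boot = 0L)
  expect_gt(fit$exponent, 2.4)
  expect_lt(fit$exponent, 2.6)

  # bias over seeds for several exponents (Monte-Carlo vs sampling oracle)
  for (alpha in c(2.2, 3.0)) {
    est <- vapply(1:5, function(s) {
      fit_powerlaw_mle(powerlaw_samples(alpha, 1L, 10000L, rng_seed = s),
                       n_boot = 0L)$exponent
    }, 0)
    expect_lt(abs(mean(est) - alpha), 0.05)
  }

  set.seed(31)
  unif <- sample(1:100, 10000L, replace = TRUE)
  fu <- fit_powerlaw_mle(unif, n_boot = 100L, rng_seed = 3L)
  expect_lt(fu$p_value, 0.1)

  expect_error(fit_powerlaw_mle(rep(3L, 100L)), "degenerate support")
  expect_error(fit_powerlaw_mle(1:10), ">= 50 samples")
})

test_that("bootstrap p-value is reproducible under a fixed seed", {
  x <- powerlaw_samples(2.5, 1L, 2000L, rng_seed = 11L)
  f1 <- fit_powerlaw_mle(x, n_boot = 50L, rng_seed = 5L)
  f2 <- fit_powerlaw_mle(x, n_boot = 50L, rng_seed = 5L)
  expect_identical(f1$p_value, f2$p_value)
})

test_that("topology classification applies the decision rules", {
  mk <- function(measure, exponent, ks = 0.05, p = NA_real_) {
    powerlaw_fit(measure, exponent, method = "loglog_ols", ks_stat = ks,
                 p_value = p, n_points = 10L)
  }
  fits <- list(p = mk("p", 2.5), c = mk("c", 1.0), cn = mk("cn", -0.4),
               cb = mk("cb", -2), cc = mk("cc", -0.1), ce = mk("ce", -1))
  cls <- classify_topology(fits)
  expect_equal(cls$topology_class, "hierarchical_scale_free")
  expect_true(cls$assortative)

  fits$c <- mk("c", 0.01)
  cls2 <- classify_topology(fits, thresholds = list(flat_band = 0.05))
  expect_equal(cls2$topology_class, "scale_free")

  # poor-quality decaying c downgrades; loosening gof_max restores it
  fits$c <- mk("c", 1.0, ks = 0.8)
  tight <- classify_topology(fits, thresholds = list(gof_max = 0.33))
  loose <- classify_topology(fits, thresholds = list(gof_max = 1.0))
  expect_equal(tight$topology_class, "unclassified")
  expect_equal(loose$topology_class, "hierarchical_scale_free")

  # class is a pure function of the stored fits + thresholds
  redo <- classify_topology(loose$fits, loose$thresholds)
  expect_equal(redo$topology_class, loose$topology_class)
})

test_that("MLE route cross-checks against igraph's independent plfit", {
  x <- powerlaw_samples(2.5, 1L, 5000L, rng_seed = 21L)
  ours <- fit_powerlaw_mle(x, n_boot = 0L)
  theirs <- igraph::fit_power_law(x, implementation = "plfit")
  expect_equal(ours$exponent, theirs$alpha, tolerance = 0.05)
})
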