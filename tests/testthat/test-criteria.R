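test_that("DAC equals one exactly when the expert is the benchmark", {
  set.seed(41)
  for (i in 1:5) {
    n <- sample(c(20, 50, 100), 1)
    s <- sample(0:n, 1)
    for (m in distance_measures(study_only = TRUE)$name) {
      res <- dac(beta_shape(1, 1), binomial_sample(n, s), m, bins = 500)
      expect_identical(res$dac, 1)
      expect_false(res$conflict)  # strict > flagging
    }
  }
})

test_that("DAC flag arithmetic follows the ratio rule", {
  r <- dac_result(0.89, 1.26)
  expect_equal(r$dac, 0.89 / 1.26, tolerance = 1e-12)
  expect_equal(round(r$dac, 3), 0.706)
  expect_false(r$conflict)
  expect_true(dac_result(1.26, 0.89)$conflict)
  expect_error(dac_result(0.5, 1e-14), "degenerate benchmark")
})

test_that("a precise off-center expert conflicts with centered data under the DAC", {
  res <- dac(beta_shape(20, 80), binomial_sample(100, 50),
             "kullback_leibler", bins = 2000)
  expect_true(res$conflict)
  expect_gt(res$dac, 1)
  # both distances agree with the closed-form Beta KL oracle
  post <- beta_shape(51, 51)
  expect_equal(res$numerator, kl_beta(post, beta_shape(20, 80)),
               tolerance = 1e-3)
  expect_equal(res$denominator, kl_beta(post, beta_shape(1, 1)),
               tolerance = 1e-4)
})

test_that("DAC rejects data that cannot move the benchmark", {
  expect_error(dac(beta_shape(2, 2), binomial_sample(0, 0)),
               "degenerate benchmark")
})

test_that("prior-to-posterior discrepancy is extremal at extreme outcomes", {
  expect_identical(nott_discrepancy(beta_shape(2, 2),
                                    binomial_sample(0, 0)), 0)
  dmap <- vapply(0:10, function(s) {
    nott_discrepancy(beta_shape(2, 2), binomial_sample(10, s),
                     "kullback_leibler", bins = 800)
  }, numeric(1))
  # the symmetric outcome moves the symmetric prior least
  expect_equal(which.min(dmap), 6L)            # s = 5
  expect_true(which.max(dmap) %in% c(1L, 11L)) # s = 10, tied with s = 0
  expect_gte(dmap[11], max(dmap[2:10]))
  expect_equal(dmap[1], dmap[11], tolerance = 1e-10)
})

test_that("exact surprise p-values follow the enumeration definition", {
  # uniform prior predictive: every p is a multiple of 1/11
  for (s in c(0, 3, 5)) {
    res <- nott_p(beta_shape(1, 1), 10, s, "hellinger", bins = 500)
    k <- res$p_value * 11
    expect_lt(abs(k - round(k)), 1e-9)
  }
  # observing the discrepancy-minimizing outcome gives p = 1
  res <- nott_p(beta_shape(2, 2), 10, 5, "kullback_leibler", bins = 500)
  expect_equal(res$p_value, 1, tolerance = 1e-12)
  # independent oracle for Beta(2,2), n = 10, s = 10: rank the closed-form
  # prior-to-posterior KLs and sum the quadrature Beta-Binomial masses
  prior <- beta_shape(2, 2)
  d_cf <- vapply(0:10, function(s) {
    kl_beta(beta_shape(2 + s, 2 + 10 - s), prior)
  }, numeric(1))
  pmf <- beta_binomial_pmf_quadrature(10, prior)
  p_oracle <- sum(pmf[d_cf >= d_cf[11]])
  res10 <- nott_p(prior, 10, 10, "kullback_leibler", bins = 2000)
  expect_equal(res10$p_value, p_oracle, tolerance = 1e-6)
  # exceedance set is the symmetric pair {0, 10}: p just above 0.05
  expect_equal(res10$p_value, 2 * beta_binomial_pmf(10, prior)[11],
               tolerance = 1e-9)
  expect_false(res10$conflict)
})

test_that("exact p is bounded below by the smallest positive predictive mass", {
  res <- nott_p(beta_shape(3, 9), 25, 25, "kullback_leibler", bins = 500)
  pmf <- beta_binomial_pmf(25, beta_shape(3, 9))
  expect_gte(res$p_value, min(pmf[pmf > 0]))
})

test_that("n = 0 data give p = 1 and no conflict", {
  res <- nott_p(beta_shape(4, 4), 0, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$conflict)
  expect_equal(res$observed_discrepancy, 0)
})

test_that("Monte Carlo backend is seeded and agrees with enumeration", {
  a <- nott_p(beta_shape(3, 7), 20, 18, method = "mc", draws = 5000,
              seed = 101, bins = 500)
  b <- nott_p(beta_shape(3, 7), 20, 18, method = "mc", draws = 5000,
              seed = 101, bins = 500)
  expect_identical(a$p_value, b$p_value)
  expect_equal(a$method, "monte_carlo")
  set.seed(61)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    s <- sample(0:n, 1)
    expert <- beta_shape(runif(1, 0.8, 30), runif(1, 0.8, 30))
    pe <- nott_p(expert, n, s, bins = 400)$p_value
    pm <- nott_p(expert, n, s, method = "mc", draws = 1e4, seed = i,
                 bins = 400)$p_value
    bound <- 3 * sqrt(pe * (1 - pe) / 1e4)
    expect_lte(abs(pm - pe), max(bound, 1e-12))
  }
})

test_that("matching locations never trigger the surprise criterion", {
  # expert centered where the data fall: no conflict for any measure whose
  # discrepancy respects stochastic ordering (divergence and euclidean are
  # the documented anomalies)
  ms <- setdiff(distance_measures(study_only = TRUE)$name,
                c("divergence", "euclidean"))
  for (conc in c(10, 200)) {
    for (n in c(50, 200)) {
      expert <- beta_shape(conc / 2, conc / 2)
      for (m in ms) {
        res <- nott_p(expert, n, n / 2, m, bins = 2000)
        expect_false(res$conflict)
      }
    }
  }
})

test_that("DAC tracks the information-uncertainty mismatch at a matching location", {
  # location fixed at the truth, s = n/2: the ratio is smallest where the
  # expert's concentration matches the benchmark posterior's (n + 2) and
  # grows monotonically with overconfidence beyond it (conflict in
  # information uncertainty)
  concs <- seq(10, 200, by = 10)
  vals <- vapply(concs, function(conc) {
    dac(beta_shape_lc(0.5, conc), binomial_sample(100, 50),
        "kullback_leibler", bins = 2000)$dac
  }, numeric(1))
  expect_equal(concs[which.min(vals)], 100)
  over <- vals[concs >= 110]
  expect_true(all(diff(over) > -1e-9))
  under <- vals[concs <= 100]
  expect_true(all(diff(under) < 1e-9))
})

test_that("conflict_check appends both criteria to a case table", {
  out <- conflict_check(
    tibble::tibble(alpha = c(1, 30), beta = c(1, 70), n = 50, s = 25),
    bins = 400)
  expect_s3_class(out, "tbl_df")
  expect_named(out, c("alpha", "beta", "n", "s", "measure", "dac",
                      "dac_conflict", "nott_p", "nott_conflict"))
  expect_equal(out$dac[1], 1)
  expect_true(out$dac_conflict[2])
})
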