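test_that("the registry lists the study measures in canonical order", {
  reg <- distance_measures()
  expect_equal(nrow(reg), 14)
  expect_equal(reg$name[1:2], c("total_variation", "hellinger"))
  expect_equal(reg$name[10], "divergence")
  expect_equal(nrow(distance_measures(study_only = TRUE)), 12)
  expect_equal(reg$name[!reg$symmetric], c("kullback_leibler", "renyi"))
  expect_equal(reg$name[reg$derived_from_similarity],
               c("intersection", "harmonic_mean"))
})

test_that("every measure vanishes on identical densities", {
  for (g in list(discretize_beta(beta_shape(2, 5), 400),
                 discretize_beta(beta_shape(0.7, 9), 400))) {
    for (m in distance_measures()$name) {
      expect_lt(abs(prob_distance(g, g, m, order = 0.5)), 1e-12)
    }
  }
})

test_that("hand-derived distances between Beta(1,1) and Beta(2,2) are reproduced", {
  p <- discretize_beta(beta_shape(1, 1), 2000)
  q <- discretize_beta(beta_shape(2, 2), 2000)
  # 0.5 * integral |1 - 6 theta (1 - theta)| = sqrt(3)/9
  expect_equal(prob_distance(p, q, "total_variation"), sqrt(3) / 9,
               tolerance = 1e-4 / (sqrt(3) / 9))
  # sup |theta - (3 theta^2 - 2 theta^3)| attained at 1/2 +- sqrt(3)/6
  expect_equal(prob_distance(p, q, "kolmogorov"), sqrt(3) / 18,
               tolerance = 1e-4 / (sqrt(3) / 18))
  # Jeffreys is the sum of the two closed-form KLs
  expect_equal(prob_distance(p, q, "jeffreys"), 1 / 3,
               tolerance = 1e-3 / (1 / 3))
  expect_equal(prob_distance(q, p, "kullback_leibler"), log(6) - 5 / 3,
               tolerance = 1e-4 / (log(6) - 5 / 3))
})

test_that("algebraic identities among measures hold to near machine precision", {
  for (pair in random_shape_pairs(10, seed = 8)) {
    p <- discretize_beta(pair$p, 1000)
    q <- discretize_beta(pair$q, 1000)
    d <- function(m, ...) prob_distance(p, q, m, ...)
    tv <- d("total_variation")
    expect_equal(d("sorensen"), tv, tolerance = 1e-10)
    expect_equal(d("manhattan"), 2 * tv, tolerance = 1e-10)
    bhat <- d("bhattacharyya")
    expect_equal(d("hellinger"), 2 * sqrt(1 - exp(-bhat)), tolerance = 1e-10)
    expect_equal(d("jeffreys"),
                 d("kullback_leibler") +
                   prob_distance(q, p, "kullback_leibler"),
                 tolerance = 1e-10)
    expect_equal(d("renyi", order = 0.5), 2 * bhat, tolerance = 1e-10)
  }
})

test_that("inequality bounds hold on a random shape sweep", {
  for (pair in random_shape_pairs(12, seed = 17)) {
    p <- discretize_beta(pair$p, 1000)
    q <- discretize_beta(pair$q, 1000)
    tv <- prob_distance(p, q, "total_variation")
    kl <- prob_distance(p, q, "kullback_leibler")
    expect_lte(tv, sqrt(kl / 2) + 1e-12)                  # Pinsker
    expect_lte(prob_distance(p, q, "kolmogorov"), tv + 1e-12)
    expect_lte(prob_distance(p, q, "jensen_shannon"), log(2) + 1e-12)
    for (m in c("intersection", "harmonic_mean", "total_variation",
                "sorensen")) {
      v <- prob_distance(p, q, m)
      expect_gte(v, 0); expect_lte(v, 1 + 1e-12)
    }
  }
})

test_that("symmetric measures are symmetric to machine precision", {
  reg <- distance_measures()
  for (pair in random_shape_pairs(4, seed = 29)) {
    p <- discretize_beta(pair$p, 500)
    q <- discretize_beta(pair$q, 500)
    for (m in reg$name[reg$symmetric]) {
      expect_equal(prob_distance(p, q, m), prob_distance(q, p, m),
                   tolerance = 1e-14)
    }
  }
})

test_that("mismatched binnings are rejected", {
  p <- discretize_beta(beta_shape(2, 2), 100)
  q <- discretize_beta(beta_shape(2, 2), 200)
  expect_error(prob_distance(p, q, "hellinger"), "grid mismatch")
})

test_that("measures with continuous limits are stable under grid refinement", {
  stable <- c("kullback_leibler", "total_variation", "hellinger",
              "kolmogorov", "bhattacharyya", "jeffreys", "jensen_shannon")
  for (pair in random_shape_pairs(4, seed = 55)) {
    g1 <- list(p = discretize_beta(pair$p, 2000), q = discretize_beta(pair$q, 2000))
    g2 <- list(p = discretize_beta(pair$p, 4000), q = discretize_beta(pair$q, 4000))
    for (m in stable) {
      expect_lt(abs(prob_distance(g1$p, g1$q, m) -
                      prob_distance(g2$p, g2$q, m)), 1e-3)
    }
  }
})

test_that("numeric KL matches the closed form where the grid resolves both densities", {
  # within the decision-relevant regime (divergences up to ~2 nats) the
  # B = 2000 discretization agrees with the digamma identity to 1e-4
  set.seed(77)
  checked <- 0
  while (checked < 60) {
    p <- beta_shape(runif(1, 0.5, 200), runif(1, 0.5, 200))
    q <- beta_shape(runif(1, 0.5, 200), runif(1, 0.5, 200))
    v <- kl_beta(p, q)
    if (v > 2) next
    checked <- checked + 1
    num <- prob_distance(discretize_beta(p, 2000), discretize_beta(q, 2000),
                         "kullback_leibler")
    expect_lt(abs(num - v), 1e-4)
  }
})

test_that("density mode rescales the dimensionful measures", {
  p <- discretize_beta(beta_shape(3, 5), 400)
  q <- discretize_beta(beta_shape(5, 3), 400)
  expect_equal(prob_distance(p, q, "total_variation", mode = "density"),
               400 * prob_distance(p, q, "total_variation"),
               tolerance = 1e-10)
  # hellinger is scale-homogeneous of degree 1/2 in the vectors
  expect_equal(prob_distance(p, q, "hellinger", mode = "density"),
               sqrt(400) * prob_distance(p, q, "hellinger"),
               tolerance = 1e-10)
})
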