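test_that("population K has the correct endpoints and enumeration value", {
  pi <- c(0.5, 0.5)
  expect_equal(trueFleissK(pi, 0), 0)
  expect_equal(trueFleissK(pi, 1), 1)

  # exhaustive enumeration over (latent, rating1, rating2) outcomes
  gamma <- 0.5
  pAgree <- 0
  for (t in 1:2) for (r1 in 1:2) for (r2 in 1:2) {
    pr <- function(r) gamma * (r == t) + (1 - gamma) * pi[r]
    pAgree <- pAgree + pi[t] * pr(r1) * pr(r2) * (r1 == r2)
  }
  Pe <- sum(pi^2)
  expect_equal(trueFleissK(pi, gamma), (pAgree - Pe) / (1 - Pe),
               tolerance = 1e-12)

  expect_error(trueFleissK(c(1, 0), 0.5), "degenerate")
})

test_that("gamma calibration round-trips through the population value", {
  for (pi in list(c(0.5, 0.5), c(0.2, 0.3, 0.5), c(0.1, 0.15, 0.2, 0.25, 0.3)))
    for (target in c(0.4, 0.7, 0.9)) {
      g <- calibrateGamma(pi, target)
      expect_equal(trueFleissK(pi, g), target, tolerance = 1e-9)
    }
  expect_identical(calibrateGamma(c(0.5, 0.5), 0), 0)
  expect_error(calibrateGamma(c(0.5, 0.5), 1), "targetK")
})

test_that("finite-sample true alpha applies the exact identity", {
  g <- calibrateGamma(c(0.5, 0.5), 0.4)
  expect_equal(trueAlpha(c(0.5, 0.5), g, 100, 5), 1 - 0.6 * 499 / 500,
               tolerance = 1e-9)
  expect_equal(trueAlpha(c(0.5, 0.5), 1, 37, 3), 1)
  # |alpha - K| is bounded by (1 - K)/n..
  kT <- trueFleissK(c(0.2, 0.3, 0.5), 0.6)
  aT <- trueAlpha(c(0.2, 0.3, 0.5), 0.6, 50, 3)
  expect_lte(abs(aT - kT), (1 - kT) / 150 + 1e-12)
})

test_that("latent-class generator matches its analytic agreement rate", {
  sc <- agreementScenario(100000, 2, 3, pi = c(0.2, 0.3, 0.5), gamma = 0.55)
  rt <- latentClassSample(sc, seed = 404)
  v <- ratingValues(rt)
  agree <- mean(v[, 1] == v[, 2])
  # analytic pairwise agreement P_a from the population coefficient
  Pe <- sum(sc@pi^2)
  Pa <- sc@kTrue * (1 - Pe) + Pe
  mcse <- sqrt(Pa * (1 - Pa) / nrow(v))
  expect_lt(abs(agree - Pa), 3 * mcse)

  # gamma = 1: all raters echo the latent class
  one <- latentClassSample(agreementScenario(20, 4, 3, gamma = 1), seed = 1)
  expect_equal(estimateValue(fleissK(one)), 1)
  expect_equal(estimateValue(krippAlpha(one)), 1)
})

test_that("MCAR deletion removes exactly the prescribed cell count", {
  sc <- agreementScenario(100, 5, 2, "low")
  rt <- latentClassSample(sc, seed = 8)
  expect_identical(applyMCAR(rt, 0, seed = 1), rt)
  del <- applyMCAR(rt, 0.10, seed = 1)
  expect_identical(sum(is.na(ratingValues(del))), 50L)
  expect_error(applyMCAR(rt, 1), "proportion")

  # complete-case survival at 50% deletion matches the hypergeometric rate
  pComplete <- prod((250 - 0:4) / (500 - 0:4))
  expected <- 100 * pComplete
  set.seed(77)
  nc <- replicate(1000, {
    d <- applyMCAR(rt, 0.50)
    sum(rowSums(!is.na(ratingValues(d))) == 5)
  })
  se <- sd(nc) / sqrt(length(nc))
  expect_lt(abs(mean(nc) - expected), 3 * se)
})

test_that("scenario grids enumerate the factorial design", {
  full <- scenarioGrid("full")
  expect_identical(nrow(full), 81L)
  expect_true(all(full$k_true >= 0.40 - 1e-9 & full$k_true <= 0.93))
  expect_true(all(full$alpha_true >= 0.40 - 1e-9 & full$alpha_true <= 0.93))

  mis <- scenarioGrid("missing")
  expect_identical(nrow(mis), 9L)
  expect_setequal(unique(mis$proportion), c(0.10, 0.25, 0.50))
  expect_true(all(mis$N == 100L))

  sc3 <- missingScenario("III")
  expect_identical(c(nSubjects(sc3), nRaters(sc3), nCategories(sc3)),
                   c(100L, 10L, 3L))
})

test_that("perfect-fidelity scenarios give zero bias and full coverage", {
  sc <- agreementScenario(15, 3, 2, gamma = 1)
  res <- runScenario(sc, runs = 10, B = 50, seed = 4,
                     methods = c("alpha_bootstrap", "k_bootstrap",
                                 "k_asymptotic", "alpha_coincidence"))
  expect_equal(res$mean_bias_pct, rep(0, 4), tolerance = 1e-12)
  expect_equal(res$coverage_pct, rep(100, 4))
  expect_identical(res$failures, rep(0L, 4))
})

test_that("scenario runs are reproducible from the master seed", {
  sc <- agreementScenario(25, 3, 2, "moderate")
  r1 <- runScenario(sc, runs = 8, B = 80, seed = 99)
  r2 <- runScenario(sc, runs = 8, B = 80, seed = 99)
  expect_identical(r1, r2)
  r3 <- runScenario(sc, runs = 8, B = 80, seed = 100)
  expect_false(identical(r1$mean_estimate, r3$mean_estimate))
})

test_that("heavy missingness is counted as per-method failures", {
  sc <- missingScenario("III")
  expect_warning(
    res <- runScenario(sc, proportion = 0.5, runs = 15, B = 50, seed = 2,
                       methods = c("alpha_bootstrap", "k_bootstrap")),
    "failures exceed 1%")
  expect_identical(res$failures[res$method == "alpha_bootstrap"], 0L)
  expect_gt(res$failures[res$method == "k_bootstrap"], 10L)
})
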