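test_that("coincidence matrix reproduces the hand enumeration", {
  cm <- coincidenceMatrix(workedExample())
  expect_equal(unname(coincidenceValues(cm)), rbind(c(4, 1), c(1, 2)))
  expect_equal(unname(marginals(cm)), c(5, 3))
  expect_equal(grandTotal(cm), 8)
  expect_identical(excludedUnits(cm), 0L)
})

test_that("subjects with fewer than two ratings are excluded", {
  v <- rbind(c(1, NA, NA), c(1, 2, NA), c(2, 2, 2))
  cm <- coincidenceMatrix(ratingTable(v, k = 2))
  expect_identical(excludedUnits(cm), 1L)
  expect_equal(grandTotal(cm), 2 + 3)  # m = 2 and m = 3 retained

  lonely <- ratingTable(rbind(c(1, NA), c(NA, 2)), k = 2)
  expect_error(coincidenceMatrix(lonely), "at least 2 ratings")
})

test_that("complete data gives grand total N * n", {
  set.seed(5)
  v <- randomRatings(30, 4, 3)
  expect_equal(grandTotal(coincidenceMatrix(ratingTable(v, k = 3))), 120)
})

test_that("coincidence matrix equals explicit ordered-pair enumeration", {
  set.seed(314)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    v <- randomRatings(sample(4:15, 1), sample(2:6, 1), k, pMissing = 0.2)
    rt <- tryCatch(ratingTable(v, k = k), error = function(e) NULL)
    if (is.null(rt)) next
    ora <- oracleCoincidence(v, k)
    cm <- tryCatch(coincidenceMatrix(rt), error = function(e) NULL)
    if (is.null(cm)) {
      expect_true(all(rowSums(!is.na(v)) < 2))
      next
    }
    expect_equal(unname(coincidenceValues(cm)), ora$o, tolerance = 1e-12)
    expect_identical(excludedUnits(cm), ora$excluded)
  }
})

test_that("ordinal distance follows the rank-interval formula", {
  expect_equal(ordinalDelta(1, 3, c(4, 2, 2)), 25)
  expect_equal(ordinalDelta(1, 2, c(4, 2, 2)), 9)
  expect_equal(ordinalDelta(2, 2, c(4, 2, 2)), 0)
  d <- deltaMatrix("ordinal", marginals = c(4, 2, 2))
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 3))
  expect_equal(deltaMatrix("nominal", k = 3), 1 - diag(3))
})

test_that("worked example alpha and the complete-data identity hold", {
  est <- krippAlpha(workedExample())
  expect_lt(abs(estimateValue(est) - 0.533333), 5e-7)
  expect_equal(components(est)$Do, 0.25)
  expect_equal(components(est)$De, 30 / 56, tolerance = 1e-12)

  # 1 - alpha = (1 - K)(n.. - 1)/n.. on complete nominal data
  set.seed(2024)
  for (rep in 1:50) {
    N <- sample(3:15, 1); n <- sample(2:5, 1); k <- sample(2:4, 1)
    v <- randomRatings(N, n, k)
    rt <- ratingTable(v, k = k)
    K <- suppressWarnings(estimateValue(fleissK(rt)))
    A <- suppressWarnings(estimateValue(krippAlpha(rt)))
    ntot <- N * n
    expect_equal(1 - A, (1 - K) * (ntot - 1) / ntot, tolerance = 1e-10)
    expect_lte(abs(A - K), 2 / ntot + 1e-10)
  }
})

test_that("perfect agreement gives alpha 1 and degenerate data is flagged", {
  perfect <- ratingTable(matrix(rep(c(1L, 2L, 1L), each = 3), 3, 3,
                                byrow = TRUE), k = 2)
  expect_equal(estimateValue(krippAlpha(perfect)), 1)
  expect_false(isDegenerate(krippAlpha(perfect)))

  mono <- ratingTable(matrix(1L, 4, 3), k = 3)
  expect_warning(est <- krippAlpha(mono), "convention")
  expect_true(isDegenerate(est))
  expect_equal(estimateValue(est), 1)
})

test_that("ordinal metric rewards adjacent-rank disagreement", {
  rt <- ordinalClusterSample(50, 4, 4, fidelity = 0.6, seed = 88)
  aNom <- estimateValue(krippAlpha(rt, metric = "nominal"))
  aOrd <- estimateValue(krippAlpha(rt, metric = "ordinal"))
  expect_gt(aOrd, aNom)
})

test_that("alpha accepts a CoincidenceMatrix directly", {
  rt <- workedExample()
  viaCM <- krippAlpha(coincidenceMatrix(rt), metric = "nominal")
  expect_equal(estimateValue(viaCM), estimateValue(krippAlpha(rt)),
               tolerance = 1e-12)
})
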