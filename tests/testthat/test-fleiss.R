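test_that("worked four-subject example reproduces the hand evaluation", {
  est <- fleissK(workedExample())
  expect_lt(abs(estimateValue(est) - 0.466667), 5e-7)
  cmp <- components(est)
  expect_equal(cmp$Pbar, 0.75)
  expect_equal(cmp$pj, c(0.625, 0.375))
  expect_equal(cmp$Pe, 0.53125)
  expect_identical(nSubjects(est), 4L)
})

test_that("perfect and inverse agreement hit the range endpoints", {
  perfect <- ratingTable(matrix(rep(c(1L, 2L, 1L), each = 4), 3, 4,
                                byrow = TRUE), k = 2)
  expect_equal(estimateValue(fleissK(perfect)), 1)

  inverse <- ratingTable(matrix(rep(c(1L, 2L), 6), 6, 2, byrow = TRUE))
  expect_equal(estimateValue(fleissK(inverse)), -1)
})

test_that("mean observed agreement equals the pairwise brute-force oracle", {
  set.seed(99)
  for (rep in 1:25) {
    v <- randomRatings(sample(4:12, 1), sample(2:5, 1), sample(2:4, 1))
    est <- fleissK(ratingTable(v, k = max(v)))
    expect_equal(components(est)$Pbar, oraclePbar(v), tolerance = 1e-12)
  }
})

test_that("complete-case rule drops partially rated subjects only for K", {
  v <- rbind(c(1, 1, 1), c(2, 2, 2), c(1, NA, 2), c(1, 1, 2))
  rt <- ratingTable(v, k = 2)
  expect_identical(nSubjects(fleissK(rt)), 3L)       # row 3 dropped
  expect_identical(nSubjects(krippAlpha(rt)), 4L)    # row 3 kept (2 ratings)

  few <- ratingTable(rbind(c(1, NA), c(NA, 2), c(1, 2)), k = 2)
  err <- tryCatch(fleissK(few), error = identity)
  expect_s3_class(err, "agreeEstimationError")
  expect_identical(err$nRetained, 1L)
})

test_that("single-category data is degenerate with value 1 by convention", {
  rt <- ratingTable(matrix(1L, 5, 3), k = 2)
  expect_warning(est <- fleissK(rt), "convention")
  expect_equal(estimateValue(est), 1)
  expect_true(isDegenerate(est))
  expect_error(suppressWarnings(fleissKSE(rt)), "single category")
})

test_that("standard error matches its closed form and an independent oracle", {
  # k = 2 with balanced margins: the cross term vanishes, se = sqrt(2/(Nn(n-1)))
  v <- rbind(matrix(1L, 50, 5), matrix(2L, 50, 5))
  se <- fleissKSE(ratingTable(v, k = 2))
  expect_equal(se, sqrt(2 / (100 * 5 * 4)), tolerance = 1e-12)
  expect_equal(se, 0.031623, tolerance = 1e-5)

  # doubling N at fixed margins scales se by 1/sqrt(2)
  se2 <- fleissKSE(ratingTable(rbind(v, v), k = 2))
  expect_equal(se2 / se, 1 / sqrt(2), tolerance = 1e-12)

  # random tables against an independently written transcription
  set.seed(123)
  for (rep in 1:20) {
    v <- randomRatings(sample(10:40, 1), sample(3:6, 1), sample(2:5, 1))
    expect_equal(fleissKSE(ratingTable(v, k = max(v))), oracleFleissSE(v),
                 tolerance = 1e-12)
  }
})
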