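test_that("asymptotic interval matches the normal-quantile formula", {
  ci <- asymptoticCI(0.5, 0.031623)
  expect_equal(ciLower(ci), 0.438, tolerance = 1e-3)
  expect_equal(ciUpper(ci), 0.562, tolerance = 1e-3)
  expect_equal(ciUpper(ci) - 0.5, 1.959964 * 0.031623, tolerance = 1e-5)

  zero <- asymptoticCI(0.3, 0)
  expect_identical(ciLower(zero), ciUpper(zero))

  # bounds are not truncated to [-1, 1]
  wide <- asymptoticCI(0.95, 0.2)
  expect_gt(ciUpper(wide), 1)
})

test_that("percentile interval reads the prescribed order statistics", {
  bt <- subjectBootstrap(workedExample(), "fleiss_k", B = 1000, seed = 5)
  s <- replicates(bt)
  expect_identical(length(s), 1000L)
  expect_false(is.unsorted(s))
  expect_identical(ciLower(bt), s[25])
  expect_identical(ciUpper(bt), s[975])
})

test_that("bootstrap replicates equal an independent resampling loop", {
  rt <- workedExample()
  seed <- 2718L
  B <- 500L
  bt <- subjectBootstrap(rt, "fleiss_k", B = B, seed = seed)

  # independent loop: same RNG stream, estimator re-derived from scratch
  v <- ratingValues(rt)
  set.seed(seed)
  repl <- numeric(B)
  for (b in seq_len(B)) {
    vb <- v[sample.int(4, 4, replace = TRUE), ]
    tab <- sapply(1:2, function(j) rowSums(vb == j))
    Pi <- (rowSums(tab^2) - 2) / 2
    pj <- colSums(tab) / 8
    Pe <- sum(pj^2)
    repl[b] <- if (1 - Pe < 1e-10) 1 else (mean(Pi) - Pe) / (1 - Pe)
  }
  expect_equal(replicates(bt), sort(repl), tolerance = 1e-12)
  expect_identical(ciLower(bt), sort(repl)[ceiling(B * 0.025)])
})

test_that("identical seeds reproduce both bootstrap variants exactly", {
  set.seed(1); v <- randomRatings(20, 4, 3, pMissing = 0.1)
  rt <- ratingTable(v, k = 3)
  b1 <- subjectBootstrap(rt, "krippendorff_alpha", B = 300, seed = 11)
  b2 <- subjectBootstrap(rt, "krippendorff_alpha", B = 300, seed = 11)
  expect_identical(replicates(b1), replicates(b2))
  expect_identical(ciLower(b1), ciLower(b2))

  c1 <- coincidenceBootstrap(rt, B = 300, seed = 11)
  c2 <- coincidenceBootstrap(rt, B = 300, seed = 11)
  expect_identical(replicates(c1), replicates(c2))

  b3 <- subjectBootstrap(rt, "krippendorff_alpha", B = 300, seed = 12)
  expect_false(identical(replicates(b1), replicates(b3)))
})

test_that("all-identical ratings collapse every interval to [1, 1]", {
  rt <- ratingTable(matrix(rep(c(1L, 2L), 6), 4, 3), k = 2)
  for (est in c("fleiss_k", "krippendorff_alpha")) {
    bt <- subjectBootstrap(rt, est, B = 100, seed = 3)
    expect_identical(c(ciLower(bt), ciUpper(bt)), c(1, 1))
  }
  cb <- coincidenceBootstrap(rt, B = 100, seed = 3)
  expect_identical(c(ciLower(cb), ciUpper(cb)), c(1, 1))
})

test_that("degenerate replicates are kept, counted, and valued 1", {
  # tiny table where resampling often leaves a single category
  rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(1, 2)), k = 2)
  bt <- subjectBootstrap(rt, "fleiss_k", B = 400, seed = 9)
  expect_identical(length(replicates(bt)), 400L)
  expect_gt(bt@distribution@nDegenerate, 0L)
})

test_that("hypothesis flags compare the lower bound to thresholds", {
  ci <- new("ConfidenceInterval", lower = 0.65, upper = 0.90,
            method = "subject_bootstrap", level = 0.95)
  expect_identical(unname(hypothesisFlags(ci, c(0, 0.6))), c(TRUE, TRUE))
  ci2 <- new("ConfidenceInterval", lower = 0.51, upper = 0.80,
             method = "subject_bootstrap", level = 0.95)
  expect_false(hypothesisFlags(ci2, 0.6)[["above_0.6"]])
  ci3 <- new("ConfidenceInterval", lower = -0.1, upper = 0.2,
             method = "asymptotic", level = 0.95)
  expect_false(hypothesisFlags(ci3, 0)[["above_0"]])
})

test_that("null-based asymptotic interval is narrower than the bootstrap with many raters", {
  # the Fleiss-Nee-Landis standard error shrinks with n(n-1) under the null;
  # off the null it understates the sampling variation, so the asymptotic
  # interval is the narrower (and undercovering) one
  sc <- agreementScenario(100, 10, 3, "moderate")
  set.seed(21)
  widthA <- widthB <- numeric(25)
  for (r in 1:25) {
    rt <- latentClassSample(sc)
    ciA <- asymptoticCI(fleissK(rt), fleissKSE(rt))
    bt <- subjectBootstrap(rt, "fleiss_k", B = 300)
    widthA[r] <- ciUpper(ciA) - ciLower(ciA)
    widthB[r] <- ciUpper(bt) - ciLower(bt)
  }
  expect_lt(mean(widthA), mean(widthB))
})
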