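## Default category probabilities per k, honouring the constraint that all
## entries lie between 0.1 and 0.5.
.defaultPi <- function(k) {
  switch(as.character(k),
         "2" = c(0.5, 0.5),
         "3" = c(0.2, 0.3, 0.5),
         "5" = c(0.1, 0.15, 0.2, 0.25, 0.3),
         rep(1 / k, k))
}

## Agreement-level anchors on the Fleiss' K scale.
.agreementAnchor <- c(low = 0.40, moderate = 0.70, high = 0.90)

## Deterministic child-seed derivation: keeps every derived seed a positive
## integer below 2^31 and exactly representable in doubles.
.childSeed <- function(master, ...) {
  s <- as.double(master) %% 2147483647
  for (x in c(...)) {
    s <- (s * 69069 + as.double(x) + 1) %% 2147483647
    s <- (s * 69069 + 12345) %% 2147483647
  }
  as.integer(s) + 1L
}

#' Population Fleiss' K of the latent-class rating generator
#'
#' Under the generator each subject has a latent category
#' \eqn{T \sim Categorical(\pi)} and each rater independently reports T with
#' fidelity probability \eqn{\gamma}, otherwise an independent draw from
#' \eqn{Categorical(\pi)}. The marginal rating distribution is then still
#' \eqn{\pi}, two raters agree with probability
#' \eqn{P_a = \sum_t \pi_t \sum_j q_j(t)^2} where
#' \eqn{q_j(t) = \gamma 1[j = t] + (1 - \gamma) \pi_j}, and the population
#' coefficient is \eqn{(P_a - P_e) / (1 - P_e)} with
#' \eqn{P_e = \sum_j \pi_j^2}.
#'
#' @param pi category probability vector (sums to 1, no entry equal to 1).
#' @param gamma fidelity probability in [0, 1].
#' @return the population Fleiss' K (a number in [0, 1] for gamma in [0, 1]).
#' @examples
#' trueFleissK(c(0.5, 0.5), 0.5)
#' @export
trueFleissK <- function(pi, gamma) {
  stopifnot(length(pi) >= 2, abs(sum(pi) - 1) < 1e-8,
            gamma >= 0, gamma <= 1)
  Pe <- sum(pi^2)
  if (1 - Pe < 1e-12)
    stop("degenerate 'pi': a single category has probability 1")
  k <- length(pi)
  Pa <- 0
  for (t in seq_len(k)) {
    q <- (1 - gamma) * pi
    q[t] <- q[t] + gamma
    Pa <- Pa + pi[t] * sum(q^2)
  }
  (Pa - Pe) / (1 - Pe)
}

#' Finite-sample true alpha of the generator
#'
#' Krippendorff's alpha uses the actual number of pairable values in its
#' chance term, so on complete nominal data it relates to Fleiss' K through
#' the exact identity \eqn{1 - \alpha = (1 - K)(n_{..} - 1)/n_{..}} with
#' \eqn{n_{..} = N n}. The true alpha of a scenario is the population K
#' pushed through that identity at the scenario's sample size.
#'
#' @inheritParams trueFleissK
#' @param N,n subjects and raters of the scenario.
#' @return the finite-sample true alpha.
#' @examples
#' trueAlpha(c(0.5, 0.5), calibrateGamma(c(0.5, 0.5), 0.4), 100, 5)  # 0.4012
#' @export
trueAlpha <- function(pi, gamma, N, n) {
  ntot <- N * n
  1 - (1 - trueFleissK(pi, gamma)) * (ntot - 1) / ntot
}

#' Calibrate the generator fidelity to a target coefficient
#'
#' \code{trueFleissK(pi, gamma)} is continuous and strictly increasing in
#' gamma from 0 (pure chance) to 1 (perfect agreement); this inverts it by
#' root-finding so scenarios can be specified on the coefficient scale.
#'
#' @inheritParams trueFleissK
#' @param targetK desired population Fleiss' K, in [0, 1).
#' @return gamma such that \code{trueFleissK(pi, gamma) == targetK} to
#'   within 1e-9.
#' @examples
#' calibrateGamma(c(0.5, 0.5), 0.7)
#' @export
calibrateGamma <- function(pi, targetK) {
  stopifnot(targetK >= 0, targetK < 1)
  if (targetK == 0) return(0)
  f <- function(g) trueFleissK(pi, g) - targetK
  stats::uniroot(f, c(0, 1), tol = 1e-12)$root
}

#' Define a simulation scenario
#'
#' @param N,n,k subjects, raters, categories.
#' @param agreement \code{"low"}, \code{"moderate"} or \code{"high"};
#'   calibrated to population K of 0.40, 0.70 and 0.90 respectively.
#' @param pi category probabilities (default: a spread over [0.1, 0.5]
#'   depending on k).
#' @param gamma optional explicit fidelity, overriding the agreement anchor.
#' @return an \code{\linkS4class{AgreementScenario}} with its analytic true
#'   values attached.
#' @examples
#' agreementScenario(100, 5, 2, "low")
#' @export
agreementScenario <- function(N, n, k,
                              agreement = c("low", "moderate", "high"),
                              pi = NULL, gamma = NULL) {
  if (is.null(pi)) pi <- .defaultPi(k)
  if (is.null(gamma)) {
    agreement <- match.arg(agreement)
    gamma <- calibrateGamma(pi, .agreementAnchor[[agreement]])
  } else {
    agreement <- if (!missing(agreement)) match.arg(agreement) else "custom"
  }
  kTrue <- trueFleissK(pi, gamma)
  new("AgreementScenario", N = as.integer(N), n = as.integer(n),
      k = as.integer(k), agreement = agreement, pi = pi, gamma = gamma,
      kTrue = kTrue, alphaTrue = trueAlpha(pi, gamma, N, n))
}

#' @rdname accessors
setMethod("trueValues", "AgreementScenario", function(x)
  c(k_true = x@kTrue, alpha_true = x@alphaTrue))
#' @rdname accessors
setMethod("nSubjects", "AgreementScenario", function(x) x@N)
#' @rdname accessors
setMethod("nRaters", "AgreementScenario", function(x) x@n)
#' @rdname accessors
setMethod("nCategories", "AgreementScenario", function(x) x@k)

## raw generator on integer codes; RNG state managed by the caller
.latentSampleValues <- function(N, n, k, pi, gamma) {
  latent <- sample.int(k, N, replace = TRUE, prob = pi)
  M <- matrix(sample.int(k, N * n, replace = TRUE, prob = pi), N, n)
  keep <- matrix(stats::runif(N * n) < gamma, N, n)
  M[keep] <- latent[row(M)[keep]]
  M
}

#' Draw a rating table from a scenario
#'
#' @param scenario an \code{\linkS4class{AgreementScenario}}.
#' @param seed integer seed (\code{NULL}: current RNG state).
#' @return a complete \code{\linkS4class{RatingTable}}.
#' @examples
#' latentClassSample(agreementScenario(10, 3, 2, "high"), seed = 1)
#' @export
latentClassSample <- function(scenario, seed = NULL) {
  stopifnot(is(scenario, "AgreementScenario"))
  if (!is.null(seed)) set.seed(seed)
  ratingTable(.latentSampleValues(scenario@N, scenario@n, scenario@k,
                                  scenario@pi, scenario@gamma),
              k = scenario@k)
}

#' Delete cells completely at random
#'
#' Sets exactly \code{floor(proportion * N * n)} cells, chosen uniformly
#' without replacement over all cells, to missing — the MCAR mechanism of
#' the simulation study.
#'
#' @param ratings a \code{\linkS4class{RatingTable}}.
#' @param proportion proportion of cells to delete, in [0, 1).
#' @param seed integer seed (\code{NULL}: current RNG state).
#' @return the \code{RatingTable} with missing cells.
#' @export
applyMCAR <- function(ratings, proportion, seed = NULL) {
  stopifnot(is(ratings, "RatingTable"))
  if (proportion < 0 || proportion >= 1)
    stop("'proportion' must lie in [0, 1)")
  if (proportion == 0) return(ratings)
  if (!is.null(seed)) set.seed(seed)
  v <- ratings@values
  nDel <- floor(proportion * length(v))
  v[sample.int(length(v), nDel)] <- NA_integer_
  ratingTable(v, k = ratings@k, scale = ratings@scale,
              categories = ratings@categories)
}

#' Enumerate the simulation scenario grids
#'
#' \code{"full"} crosses N in \{50, 100, 200\}, n in \{3, 5, 10\}, k in
#' \{2, 3, 5\} and the three agreement levels: 81 scenarios, all with
#' complete data. \code{"missing"} returns the three missing-data scenarios
#' (I: N = 100, n = 5, k = 2, low; II: N = 100, n = 5, k = 5, high;
#' III: N = 100, n = 10, k = 3, moderate) crossed with deletion proportions
#' \{0.10, 0.25, 0.50\}.
#'
#' @param kind \code{"full"} or \code{"missing"}.
#' @return a data.frame with one row per scenario (and, for
#'   \code{"missing"}, per deletion proportion), including the calibrated
#'   true values.
#' @examples
#' nrow(scenarioGrid("full"))     # 81
#' @export
scenarioGrid <- function(kind = c("full", "missing")) {
  kind <- match.arg(kind)
  if (kind == "full") {
    g <- expand.grid(N = c(50L, 100L, 200L), n = c(3L, 5L, 10L),
                     k = c(2L, 3L, 5L),
                     agreement = c("low", "moderate", "high"),
                     stringsAsFactors = FALSE)
    g$proportion <- 0
  } else {
    base <- data.frame(scenario = c("I", "II", "III"),
                       N = 100L, n = c(5L, 5L, 10L), k = c(2L, 5L, 3L),
                       agreement = c("low", "high", "moderate"),
                       stringsAsFactors = FALSE)
    g <- merge(base, data.frame(proportion = c(0.10, 0.25, 0.50)))
    g <- g[order(g$scenario, g$proportion), ]
    rownames(g) <- NULL
  }
  tv <- t(vapply(seq_len(nrow(g)), function(i) {
    sc <- agreementScenario(g$N[i], g$n[i], g$k[i], g$agreement[i])
    c(sc@kTrue, sc@alphaTrue)
  }, numeric(2)))
  g$k_true <- tv[, 1]
  g$alpha_true <- tv[, 2]
  g
}

#' The three named missing-data scenarios
#'
#' @param id \code{"I"}, \code{"II"} or \code{"III"}.
#' @return the corresponding \code{\linkS4class{AgreementScenario}}
#'   (all have N = 100).
#' @export
missingScenario <- function(id = c("I", "II", "III")) {
  id <- match.arg(id)
  switch(id,
         I = agreementScenario(100, 5, 2, "low"),
         II = agreementScenario(100, 5, 5, "high"),
         III = agreementScenario(100, 10, 3, "moderate"))
}

## coincidence-bootstrap replicate values on the counts representation;
## RNG state managed by the caller
.coincBootValues <- function(counts, m, kind, B) {
  k <- ncol(counts)
  o <- matrix(colSums(.coincContrib(counts, m)), k, k)
  nc <- rowSums(o)
  ntot <- sum(nc)
  if (ntot < 2) .estimationError("fewer than 2 pairable values")
  delta <- deltaMatrix(kind, marginals = nc, k = k)
  De <- sum(outer(nc, nc) * delta) / (ntot * (ntot - 1))
  mRet <- m[m >= 2]
  M <- sum(mRet * (mRet - 1) / 2)
  if (De < .DEGEN_TOL)
    return(list(values = rep(1, B), nDegenerate = as.integer(B), De = De))
  draws <- stats::rmultinom(B, M, prob = as.vector(o) / ntot)
  Dob <- as.vector(crossprod(as.vector(delta), draws)) / M
  list(values = 1 - Dob / De, nDegenerate = 0L, De = De)
}

#' Run one simulation scenario
#'
#' Per simulation run: draw a complete table from the scenario, delete the
#' requested proportion of cells MCAR, estimate Krippendorff's alpha (on all
#' subjects with at least two ratings) and Fleiss' K (complete cases), and
#' build the requested confidence intervals. Aggregates the percentage bias
#' (relative to the scenario's analytic true value: alpha_true for alpha
#' methods, k_true for K methods) and the empirical coverage probability per
#' method. Runs in which a method's estimator or bootstrap is undefined
#' (e.g. fewer than two complete cases at heavy missingness) count as
#' failures for that method and are excluded from its aggregates; a warning
#' is issued when failures exceed 1\% of runs.
#'
#' @param scenario an \code{\linkS4class{AgreementScenario}}.
#' @param proportion MCAR deletion proportion in [0, 1) (default 0).
#' @param runs number of simulation runs.
#' @param B bootstrap replicates per run.
#' @param level two-sided confidence level.
#' @param seed master seed; child seeds for each run's data, and one level
#'   deeper for each bootstrap, are derived deterministically from it.
#' @param methods subset of \code{"alpha_bootstrap"}, \code{"k_bootstrap"},
#'   \code{"k_asymptotic"}, \code{"alpha_coincidence"}.
#' @return a data.frame (one row per method) with columns
#'   \code{mean_estimate}, \code{true_value}, \code{mean_bias_pct},
#'   \code{coverage_pct}, \code{runs}, \code{successes}, \code{failures};
#'   the scenario and settings are attached as attributes.
#' @examples
#' sc <- agreementScenario(20, 3, 2, "high")
#' runScenario(sc, runs = 5, B = 50, seed = 1)
#' @export
runScenario <- function(scenario, proportion = 0, runs = 1000L, B = 1000L,
                        level = 0.95, seed = 1L,
                        methods = c("alpha_bootstrap", "k_bootstrap",
                                    "k_asymptotic")) {
  stopifnot(is(scenario, "AgreementScenario"), runs >= 1)
  methods <- match.arg(methods, c("alpha_bootstrap", "k_bootstrap",
                                  "k_asymptotic", "alpha_coincidence"),
                       several.ok = TRUE)
  N <- scenario@N; n <- scenario@n; k <- scenario@k
  kTrue <- scenario@kTrue; aTrue <- scenario@alphaTrue
  est <- matrix(NA_real_, runs, length(methods),
                dimnames = list(NULL, methods))
  cov <- matrix(NA, runs, length(methods), dimnames = list(NULL, methods))
  z <- stats::qnorm(1 - (1 - level) / 2)
  for (r in seq_len(runs)) {
    set.seed(.childSeed(seed, r, 0L))
    M <- .latentSampleValues(N, n, k, scenario@pi, scenario@gamma)
    if (proportion > 0) {
      nDel <- floor(proportion * N * n)
      M[sample.int(N * n, nDel)] <- NA_integer_
    }
    counts <- .tallyCounts(M, k)
    m <- rowSums(counts)
    fl <- tryCatch(.fleissFromCounts(counts, m, n), error = function(e) NULL)
    al <- tryCatch(.alphaFromCounts(counts, m, "nominal"),
                   error = function(e) NULL)
    for (meth in methods) {
      val <- switch(meth,
        k_bootstrap = , k_asymptotic = if (is.null(fl)) NULL else fl$value,
        alpha_bootstrap = , alpha_coincidence =
          if (is.null(al)) NULL else al$value)
      if (is.null(val)) next
      ci <- tryCatch(switch(meth,
        k_asymptotic = {
          if (fl$degenerate) c(1, 1)
          else {
            se <- .fleissSE(fl$pj, fl$Nret, n)
            c(val - z * se, val + z * se)
          }
        },
        k_bootstrap = {
          set.seed(.childSeed(seed, r, 1L))
          s <- sort(.subjectBootFast(counts, m, n, B, "fleiss_k",
                                     "nominal")$values)
          ic <- .percentileCI(s, level, "subject_bootstrap")
          c(ic@lower, ic@upper)
        },
        alpha_bootstrap = {
          set.seed(.childSeed(seed, r, 2L))
          s <- sort(.subjectBootFast(counts, m, n, B, "krippendorff_alpha",
                                     "nominal")$values)
          ic <- .percentileCI(s, level, "subject_bootstrap")
          c(ic@lower, ic@upper)
        },
        alpha_coincidence = {
          set.seed(.childSeed(seed, r, 3L))
          s <- sort(.coincBootValues(counts, m, "nominal", B)$values)
          ic <- .percentileCI(s, level, "coincidence_bootstrap")
          c(ic@lower, ic@upper)
        }), error = function(e) NULL)
      if (is.null(ci)) next
      truth <- if (startsWith(meth, "k_")) kTrue else aTrue
      est[r, meth] <- val
      cov[r, meth] <- ci[1] <= truth && truth <= ci[2]
    }
  }
  succ <- colSums(!is.na(est))
  fail <- runs - succ
  if (any(fail > 0.01 * runs))
    warning(sprintf("failures exceed 1%% of runs for: %s",
                    paste(methods[fail > 0.01 * runs], collapse = ", ")))
  truth <- ifelse(startsWith(methods, "k_"), kTrue, aTrue)
  meanEst <- colMeans(est, na.rm = TRUE)
  out <- data.frame(
    method = methods,
    mean_estimate = as.numeric(meanEst),
    true_value = truth,
    mean_bias_pct = 100 * (as.numeric(meanEst) - truth) / truth,
    coverage_pct = 100 * colMeans(cov, na.rm = TRUE),
    runs = runs,
    successes = as.integer(succ),
    failures = as.integer(fail),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "scenario") <- scenario
  attr(out, "settings") <- list(proportion = proportion, B = B,
                                level = level, seed = seed)
  out
}
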