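#' Asymptotic confidence interval for Fleiss' K
#'
#' The normal-theory two-sided interval \eqn{K \pm z_{1-\alpha/2}\, se(K)}.
#' The bounds are deliberately not truncated to [-1, 1], matching the
#' textbook formula. Because the standard error is valid only under the null
#' hypothesis of zero agreement, this interval undercovers badly when the
#' true coefficient is far from zero; it is provided for comparison and the
#' bootstrap interval should be preferred.
#'
#' @param estimate point estimate (an \code{AgreementEstimate} or a number).
#' @param se standard error, e.g. from \code{\link{fleissKSE}}.
#' @param level two-sided confidence level (default 0.95).
#' @return a \code{\linkS4class{ConfidenceInterval}}.
#' @examples
#' asymptoticCI(0.5, 0.031623)      # [0.438, 0.562]
#' @export
asymptoticCI <- function(estimate, se, level = 0.95) {
  if (is(estimate, "AgreementEstimate")) estimate <- estimate@value
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  new("ConfidenceInterval", lower = estimate - z * se,
      upper = estimate + z * se, method = "asymptotic", level = level)
}

## Percentile interval from sorted replicates: 1-based order statistics at
## ceiling(B * a/2) and ceiling(B * (1 - a/2)); for B = 1000, level 0.95
## these are the 25th and 975th values.
.percentileCI <- function(sorted, level, method) {
  B <- length(sorted)
  a <- 1 - level
  lo <- max(1L, ceiling(B * a / 2))
  hi <- min(B, ceiling(B * (1 - a / 2)))
  new("ConfidenceInterval", lower = sorted[lo], upper = sorted[hi],
      method = method, level = level)
}

.bootstrapError <- function(msg) {
  stop(errorCondition(msg, class = c("agreeBootstrapError", "error")))
}

## Shared replicate engine for the subject bootstrap. Operates on the counts
## representation; assumes the RNG state is already set by the caller.
## Returns unsorted replicate values plus the degenerate count.
##
## Each estimator resamples its own analysis set: for Fleiss' K the
## complete-case deletion produces the dataset K is computed on, so the
## bootstrap draws subjects from those complete cases; for alpha every
## subject row is drawn and the (< 2 ratings) exclusion is re-applied
## within each replicate.
.subjectBootFast <- function(counts, m, n, B, estimator, kind,
                             retryCap = 100L) {
  k <- ncol(counts)
  wantK <- estimator == "fleiss_k"
  if (wantK) {
    complete <- which(m == n)
    cc <- counts[complete, , drop = FALSE]
    N <- nrow(cc)
    Pi <- (rowSums(cc^2) - n) / (n * (n - 1))
  } else {
    N <- nrow(counts)
    Oc <- .coincContrib(counts, m)
    mRet <- ifelse(m >= 2, m, 0)
    nominalDelta <- if (kind == "nominal") 1 - diag(k) else NULL
  }
  vals <- numeric(B)
  nDegen <- 0L
  for (b in seq_len(B)) {
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > retryCap)
        .bootstrapError(sprintf(
          "bootstrap replicate %d not estimable after %d redraws", b,
          retryCap))
      idx <- sample.int(N, N, replace = TRUE)
      w <- tabulate(idx, N)
      if (wantK) {
        Pbar <- sum(w * Pi) / N
        pj <- as.vector(crossprod(w, cc)) / (N * n)
        Pe <- sum(pj^2)
        if ((1 - Pe) < .DEGEN_TOL) {
          vals[b] <- 1; nDegen <- nDegen + 1L
        } else vals[b] <- (Pbar - Pe) / (1 - Pe)
      } else {
        ntot <- sum(w * mRet)
        if (ntot < 2) next
        o <- matrix(crossprod(w, Oc), k, k)
        nc <- rowSums(o)
        delta <- if (kind == "nominal") nominalDelta else
          deltaMatrix("ordinal", marginals = nc, k = k)
        Do <- sum(o * delta) / ntot
        De <- sum(outer(nc, nc) * delta) / (ntot * (ntot - 1))
        if (De < .DEGEN_TOL) {
          vals[b] <- 1; nDegen <- nDegen + 1L
        } else vals[b] <- 1 - Do / De
      }
      break
    }
  }
  list(values = vals, nDegenerate = nDegen)
}

#' Subject-resampling percentile bootstrap for K and alpha
#'
#' The standard bootstrap for clustered rating data: each replicate draws
#' subjects with replacement, keeping every rater's rating of a drawn
#' subject together, re-estimates the coefficient, and the two-sided
#' percentile interval is read from the sorted replicate vector at the
#' 1-based order statistics \code{ceiling(B * a/2)} and
#' \code{ceiling(B * (1 - a/2))}. Each estimator resamples its own
#' analysis set: Fleiss' K is defined on the complete-case dataset, so its
#' bootstrap draws from the complete cases; alpha's bootstrap draws from
#' all subject rows and re-applies its fewer-than-two-ratings exclusion
#' within each replicate. Replicates on which the estimator is undefined
#' (e.g. no pairable values after resampling, for alpha under heavy
#' missingness) are redrawn, up to 100 attempts per replicate slot;
#' replicates where a single category survives evaluate to 1 by the
#' degeneracy convention and are counted in the distribution's
#' \code{nDegenerate}.
#'
#' @param ratings a \code{\linkS4class{RatingTable}}.
#' @param estimator \code{"fleiss_k"} or \code{"krippendorff_alpha"}.
#' @param metric distance metric for alpha (\code{NULL}: the table's scale).
#' @param B number of bootstrap replicates (default 1000).
#' @param level two-sided confidence level (default 0.95).
#' @param seed integer seed making the replicate stream reproducible;
#'   \code{NULL} uses the current RNG state.
#' @return an \code{\linkS4class{AgreementBootstrap}}.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' subjectBootstrap(rt, "fleiss_k", B = 200, seed = 7)
#' @export
subjectBootstrap <- function(ratings,
                             estimator = c("fleiss_k", "krippendorff_alpha"),
                             metric = NULL, B = 1000L, level = 0.95,
                             seed = NULL) {
  estimator <- match.arg(estimator)
  stopifnot(is(ratings, "RatingTable"), B >= 1, level > 0, level < 1)
  if (is.null(metric)) metric <- ratings@scale
  metric <- match.arg(metric, c("nominal", "ordinal"))
  d <- .asCounts(ratings)
  ## fail early if the estimator is undefined on the full data
  if (estimator == "fleiss_k") .fleissFromCounts(d$counts, d$m, d$n)
  else .alphaFromCounts(d$counts, d$m, metric)
  if (!is.null(seed)) set.seed(seed)
  bt <- .subjectBootFast(d$counts, d$m, d$n, B, estimator, metric)
  sorted <- sort(bt$values)
  dist <- new("BootstrapDistribution", estimates = sorted,
              nDegenerate = bt$nDegenerate)
  ci <- .percentileCI(sorted, level, "subject_bootstrap")
  new("AgreementBootstrap", distribution = dist, interval = ci,
      estimator = estimator)
}

#' Krippendorff's coincidence-matrix bootstrap for alpha
#'
#' Krippendorff's original bootstrap algorithm, implemented for comparison
#' with the subject bootstrap. It differs from subject resampling in three
#' ways: rating counts per subject enter as weights (through the
#' coincidence matrix itself, whose cells carry the \code{1/(m_u - 1)}
#' weighting), resampling is of pairable-value coincidences from the
#' coincidence matrix rather than of subjects, and the expected disagreement
#' \eqn{D_e} stays fixed at its full-data value while only \eqn{D_o} is
#' recomputed. Each replicate draws \eqn{M = \sum_u m_u (m_u - 1) / 2} pairs
#' (the number of distinct pairable comparisons) with cell probabilities
#' \eqn{o_{cc'} / n_{..}} and sets \eqn{\alpha_b = 1 - D_{o,b} / D_e}.
#'
#' Because pair draws ignore the within-subject dependence between rater
#' pairs, the replicate spread understates the sampling variance of alpha
#' and the resulting intervals undercover markedly; the simulation engine
#' quantifies this.
#'
#' @inheritParams subjectBootstrap
#' @return an \code{\linkS4class{AgreementBootstrap}}.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' coincidenceBootstrap(rt, B = 200, seed = 7)
#' @export
coincidenceBootstrap <- function(ratings, metric = NULL, B = 1000L,
                                 level = 0.95, seed = NULL) {
  stopifnot(is(ratings, "RatingTable"), B >= 1, level > 0, level < 1)
  if (is.null(metric)) metric <- ratings@scale
  metric <- match.arg(metric, c("nominal", "ordinal"))
  d <- .asCounts(ratings)
  .alphaFromCounts(d$counts, d$m, metric)  # fail early if not estimable
  if (!is.null(seed)) set.seed(seed)
  bt <- .coincBootValues(d$counts, d$m, metric, B)
  sorted <- sort(bt$values)
  dist <- new("BootstrapDistribution", estimates = sorted,
              nDegenerate = bt$nDegenerate)
  ci <- .percentileCI(sorted, level, "coincidence_bootstrap")
  new("AgreementBootstrap", distribution = dist, interval = ci,
      estimator = "krippendorff_alpha")
}

#' One-sided conclusions from a confidence interval
#'
#' Reliability hypotheses are usually settled by the lower confidence bound:
#' agreement beyond chance needs the lower limit above 0, substantial
#' agreement (Landis-Koch) above 0.6. For each threshold t this reports
#' whether \code{lower > t}.
#'
#' @param ci a \code{\linkS4class{ConfidenceInterval}} (or an
#'   \code{AgreementBootstrap}, whose interval is used).
#' @param thresholds numeric thresholds (default 0 and 0.6).
#' @return named logical vector, names \code{above_<t>}.
#' @examples
#' hypothesisFlags(asymptoticCI(0.75, 0.05))
#' @export
hypothesisFlags <- function(ci, thresholds = c(0, 0.6)) {
  if (is(ci, "AgreementBootstrap")) ci <- ci@interval
  stopifnot(is(ci, "ConfidenceInterval"))
  out <- ci@lower > thresholds
  names(out) <- paste0("above_", format(thresholds, trim = TRUE))
  out
}
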