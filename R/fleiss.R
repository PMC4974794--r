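## Numerical tolerance used for degeneracy checks (1 - P_e near zero).
.DEGEN_TOL <- 1e-10

.estimationError <- function(msg, nRetained = NA_integer_) {
  stop(errorCondition(msg, nRetained = nRetained,
                      class = c("agreeEstimationError", "error")))
}

## Core Fleiss' K on a counts matrix; complete cases (m_i = n) only.
## Returns a plain list so the simulation loop can avoid S4 overhead.
.fleissFromCounts <- function(counts, m, n) {
  keep <- m == n
  Nret <- sum(keep)
  if (Nret < 2L)
    .estimationError(sprintf(
      "Fleiss' K needs at least 2 complete-case subjects (have %d)", Nret),
      as.integer(Nret))
  cc <- counts[keep, , drop = FALSE]
  Pi <- (rowSums(cc^2) - n) / (n * (n - 1))
  Pbar <- mean(Pi)
  pj <- colSums(cc) / (Nret * n)
  Pe <- sum(pj^2)
  degenerate <- (1 - Pe) < .DEGEN_TOL
  value <- if (degenerate) 1 else (Pbar - Pe) / (1 - Pe)
  list(value = value, Pi = Pi, Pbar = Pbar, pj = pj, Pe = Pe,
       Nret = as.integer(Nret), degenerate = degenerate)
}

#' Fleiss' K for multiple raters and categories
#'
#' The multi-rater generalisation of Scott's pi: observed agreement corrected
#' for the agreement expected by chance, \eqn{K = (P - P_e)/(1 - P_e)}, where
#' \eqn{P} is the mean per-subject proportion of agreeing rater pairs and
#' \eqn{P_e = \sum_j p_j^2} the chance agreement from the marginal category
#' proportions. K cannot use partially rated subjects: every subject with
#' fewer than \code{n} ratings is dropped before estimation (complete-case
#' analysis).
#'
#' When only a single category occurs in the retained data both numerator and
#' denominator vanish; the estimate is then 1 by convention (agreement is
#' trivially perfect), flagged via \code{isDegenerate()}, with a warning.
#'
#' @param x a \code{\linkS4class{RatingTable}} or
#'   \code{\linkS4class{CategoryCounts}}.
#' @return an \code{\linkS4class{AgreementEstimate}} whose components hold
#'   the per-subject agreements \code{Pi}, their mean \code{Pbar}, marginal
#'   proportions \code{pj} and chance agreement \code{Pe}.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' fleissK(rt)                      # 0.466667
#' @seealso \code{\link{fleissKSE}}, \code{\link{krippAlpha}}
#' @export
fleissK <- function(x) {
  d <- .asCounts(x)
  f <- .fleissFromCounts(d$counts, d$m, d$n)
  if (f$degenerate)
    warning("single category used everywhere: Fleiss' K is 1 by convention")
  new("AgreementEstimate", value = f$value, method = "fleiss_k",
      components = list(Pi = f$Pi, Pbar = f$Pbar, pj = f$pj, Pe = f$Pe),
      nSubjectsUsed = f$Nret, degenerate = f$degenerate)
}

## Fleiss-Nee-Landis standard error from the marginal proportions.
.fleissSE <- function(pj, Nret, n) {
  qj <- pj * (1 - pj)
  sq <- sum(qj)
  if (sq < .DEGEN_TOL)
    .estimationError("standard error undefined: a single category is used")
  sqrt(2 / (Nret * n * (n - 1))) * sqrt(sq^2 - sum(qj * (1 - 2 * pj))) / sq
}

#' Standard error of Fleiss' K under the null of chance agreement
#'
#' The corrected large-sample variance formula of Fleiss, Nee and Landis:
#' with \eqn{q_j = p_j (1 - p_j)},
#' \deqn{se(K) = \sqrt{2 / (N n (n-1))} \;
#'   \sqrt{(\sum_j q_j)^2 - \sum_j q_j (1 - 2 p_j)} \; / \; \sum_j q_j .}
#' This standard error is derived under the hypothesis that the underlying
#' coefficient is zero; it is only appropriate for testing that hypothesis,
#' which is why the asymptotic interval built from it undercovers for shifted
#' hypotheses (see the package vignette).
#'
#' @inheritParams fleissK
#' @return the standard error (a single number).
#' @examples
#' cnt <- rbind(c(1, 1), c(2, 0), c(0, 2), c(1, 1))
#' fleissKSE(new("CategoryCounts", counts = cnt,
#'               rowTotals = rowSums(cnt), nRaters = 2L))
#' @export
fleissKSE <- function(x) {
  d <- .asCounts(x)
  keep <- d$m == d$n
  Nret <- sum(keep)
  if (Nret < 2L)
    .estimationError(sprintf(
      "Fleiss' K needs at least 2 complete-case subjects (have %d)", Nret),
      as.integer(Nret))
  pj <- colSums(d$counts[keep, , drop = FALSE]) / (Nret * d$n)
  .fleissSE(pj, Nret, d$n)
}
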