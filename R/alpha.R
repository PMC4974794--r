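## Per-subject coincidence contributions, one flattened k x k block per row.
## Subjects with m_u < 2 contribute a zero row (they are not pairable).
.coincContrib <- function(counts, m) {
  N <- nrow(counts); k <- ncol(counts)
  out <- matrix(0, N, k * k)
  for (u in which(m >= 2)) {
    nu <- counts[u, ]
    ou <- outer(nu, nu)
    diag(ou) <- nu * (nu - 1)
    out[u, ] <- ou / (m[u] - 1)
  }
  out
}

#' Coincidence matrix of pairable values
#'
#' Builds Krippendorff's k x k coincidence matrix: within each subject with
#' \code{m_u >= 2} ratings, every ordered pair of ratings (c, c') adds
#' \code{1/(m_u - 1)} to cell o_cc', so that each pairable value is counted
#' once in the grand total \code{n.. = sum_u m_u}. Subjects with fewer than
#' two ratings carry no pairable values and are excluded (their number is
#' kept in \code{excludedUnits}).
#'
#' @inheritParams fleissK
#' @return a \code{\linkS4class{CoincidenceMatrix}}.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' coincidenceMatrix(rt)
#' @export
coincidenceMatrix <- function(x) {
  d <- .asCounts(x)
  k <- ncol(d$counts)
  retained <- d$m >= 2
  if (!any(retained))
    .estimationError("no subject has at least 2 ratings", 0L)
  o <- matrix(colSums(.coincContrib(d$counts, d$m)), k, k)
  new("CoincidenceMatrix", o = o, marginals = rowSums(o),
      grandTotal = sum(o), excludedUnits = as.integer(sum(!retained)))
}

#' Distance matrices for the alpha metrics
#'
#' \code{deltaMatrix} returns the full k x k matrix of squared category
#' distances used in Krippendorff's alpha. For the nominal metric every
#' distinct pair has distance 1. For the ordinal metric the distance between
#' rank categories c <= c' is
#' \deqn{\delta^2(c, c') = \Big(\sum_{g=c}^{c'} n_g - \frac{n_c + n_{c'}}{2}\Big)^2,}
#' computed from the coincidence-matrix marginals \code{n_c} of the retained
#' data (Krippendorff's convention), so that distances adapt to how often
#' each rank is used.
#'
#' @param kind \code{"nominal"} or \code{"ordinal"}.
#' @param marginals coincidence marginals n_c (required for
#'   \code{"ordinal"}; ignored for \code{"nominal"} apart from its length).
#' @param k number of categories (defaults to \code{length(marginals)}).
#' @return a symmetric k x k matrix with zero diagonal.
#' @examples
#' deltaMatrix("ordinal", marginals = c(4, 2, 2))
#' @export
deltaMatrix <- function(kind = c("nominal", "ordinal"), marginals = NULL,
                        k = length(marginals)) {
  kind <- match.arg(kind)
  if (kind == "nominal") {
    stopifnot(k >= 2)
    return(1 - diag(k))
  }
  stopifnot(!is.null(marginals), k == length(marginals))
  cum <- cumsum(marginals)
  delta <- matrix(0, k, k)
  for (a in seq_len(k - 1)) {
    for (b in seq(a + 1, k)) {
      s <- cum[b] - if (a > 1) cum[a - 1] else 0
      delta[a, b] <- delta[b, a] <- (s - (marginals[a] + marginals[b]) / 2)^2
    }
  }
  delta
}

#' @describeIn deltaMatrix single-pair ordinal distance
#' @param c,cPrime category codes (rank positions).
#' @export
ordinalDelta <- function(c, cPrime, marginals) {
  deltaMatrix("ordinal", marginals)[c, cPrime]
}

## D_o, D_e and alpha from a coincidence matrix and a delta matrix.
.alphaFromCoinc <- function(o, nc, ntot, delta) {
  if (ntot < 2) .estimationError("fewer than 2 pairable values")
  Do <- sum(o * delta) / ntot
  De <- sum(outer(nc, nc) * delta) / (ntot * (ntot - 1))
  if (De < .DEGEN_TOL)
    return(list(value = 1, Do = Do, De = De, degenerate = TRUE))
  list(value = 1 - Do / De, Do = Do, De = De, degenerate = FALSE)
}

## Fast path used by the bootstrap/simulation loops: counts -> alpha pieces.
.alphaFromCounts <- function(counts, m, kind) {
  retained <- m >= 2
  if (!any(retained)) .estimationError("no subject has at least 2 ratings", 0L)
  k <- ncol(counts)
  o <- matrix(colSums(.coincContrib(counts, m)), k, k)
  nc <- rowSums(o)
  ntot <- sum(nc)
  delta <- deltaMatrix(kind, marginals = nc, k = k)
  c(.alphaFromCoinc(o, nc, ntot, delta),
    list(nUsed = as.integer(sum(retained))))
}

#' Krippendorff's alpha
#'
#' Observed disagreement corrected for the disagreement expected by chance:
#' \eqn{\alpha = 1 - D_o / D_e} with
#' \deqn{D_o = \sum_{c, c'} o_{cc'} \delta^2(c, c') / n_{..}, \qquad
#'       D_e = \sum_{c, c'} n_c n_{c'} \delta^2(c, c') / (n_{..} (n_{..} - 1)),}
#' computed from the coincidence matrix. The chance term uses the actual
#' number of pairable values \eqn{n_{..}} (a finite-sample correction absent
#' from Fleiss' K). Subjects need at least two ratings to contribute, which
#' is how alpha accommodates missing ratings without discarding whole
#' subjects.
#'
#' @param x a \code{\linkS4class{RatingTable}},
#'   \code{\linkS4class{CategoryCounts}} or
#'   \code{\linkS4class{CoincidenceMatrix}}.
#' @param metric \code{"nominal"} or \code{"ordinal"}; defaults to the
#'   table's declared scale when \code{x} is a \code{RatingTable}.
#' @return an \code{\linkS4class{AgreementEstimate}} whose components hold
#'   \code{Do} and \code{De}. When all ratings fall in one category alpha is
#'   0/0 and is set to 1 by convention with \code{isDegenerate()} TRUE.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' krippAlpha(rt)                   # 0.533333
#' @export
krippAlpha <- function(x, metric = NULL) {
  if (is(x, "CoincidenceMatrix")) {
    if (is.null(metric)) metric <- "nominal"
    metric <- match.arg(metric, c("nominal", "ordinal"))
    delta <- deltaMatrix(metric, marginals = x@marginals, k = ncol(x@o))
    a <- .alphaFromCoinc(x@o, x@marginals, x@grandTotal, delta)
    nUsed <- NA_integer_
  } else {
    if (is.null(metric))
      metric <- if (is(x, "RatingTable")) x@scale else "nominal"
    metric <- match.arg(metric, c("nominal", "ordinal"))
    d <- .asCounts(x)
    a <- .alphaFromCounts(d$counts, d$m, metric)
    nUsed <- a$nUsed
  }
  if (a$degenerate)
    warning("single category used everywhere: alpha is 1 by convention")
  new("AgreementEstimate", value = a$value, method = "krippendorff_alpha",
      components = list(Do = a$Do, De = a$De, metric = metric),
      nSubjectsUsed = if (is.na(nUsed)) 0L else nUsed,
      degenerate = a$degenerate)
}
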