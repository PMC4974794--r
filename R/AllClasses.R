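#' @import methods
NULL

#' RatingTable: subjects-by-raters categorical ratings
#'
#' The universal input container: an \code{N x n} integer matrix of category
#' codes in \code{1..k}, with \code{NA} marking a missing rating (a subject a
#' rater did not assess). Category codes are 1-based ranks; for an ordinal
#' scale the code order is the rank order.
#'
#' @slot values integer matrix, subjects in rows, raters in columns; entries
#'   in \code{1..k} or \code{NA}.
#' @slot k number of categories (>= 2); fixed by the category set, not by
#'   which codes happen to occur.
#' @slot scale \code{"nominal"} or \code{"ordinal"}.
#' @slot categories character labels of the \code{k} categories, in code
#'   order.
#'
#' @seealso \code{\link{ratingTable}}, \code{\link{encodeRatings}}
#' @name RatingTable-class
#' @aliases RatingTable-class
#' @exportClass RatingTable
setClass("RatingTable",
  representation(
    values = "matrix",
    k = "integer",
    scale = "character",
    categories = "character"
  )
)

setValidity("RatingTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "'values' must be a numeric matrix")
  if (length(object@k) != 1L || is.na(object@k) || object@k < 2L)
    msg <- c(msg, "'k' must be a single integer >= 2")
  if (ncol(v) < 2L) msg <- c(msg, "at least 2 raters (columns) are required")
  if (nrow(v) < 1L) msg <- c(msg, "at least 1 subject (row) is required")
  obs <- v[!is.na(v)]
  if (length(obs) && (any(obs != as.integer(obs)) || any(obs < 1L) ||
                      any(obs > object@k)))
    msg <- c(msg, sprintf("non-missing cells must be integers in [1, %d]",
                          object@k))
  if (!object@scale %in% c("nominal", "ordinal"))
    msg <- c(msg, "'scale' must be \"nominal\" or \"ordinal\"")
  if (length(object@categories) != object@k)
    msg <- c(msg, "'categories' must have length k")
  if (length(msg)) msg else TRUE
})

#' CategoryCounts: per-subject category tallies
#'
#' The sufficient statistic for Fleiss' K: \code{counts[i, j]} is the number
#' of raters that assigned subject \code{i} to category \code{j}; row totals
#' \code{m_i} give the number of ratings per subject (\code{m_i < nRaters}
#' when ratings are missing).
#'
#' @slot counts N x k integer matrix of tallies n_ij.
#' @slot rowTotals numeric vector m_i = rowSums(counts).
#' @slot nRaters number of raters n in the originating table.
#'
#' @name CategoryCounts-class
#' @aliases CategoryCounts-class
#' @exportClass CategoryCounts
setClass("CategoryCounts",
  representation(
    counts = "matrix",
    rowTotals = "numeric",
    nRaters = "integer"
  )
)

setValidity("CategoryCounts", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(unname(rowSums(object@counts)),
                        unname(object@rowTotals))))
    msg <- c(msg, "rowTotals must equal rowSums(counts)")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (any(object@rowTotals > object@nRaters))
    msg <- c(msg, "no subject can have more ratings than raters")
  if (length(msg)) msg else TRUE
})

#' CoincidenceMatrix: pairable-value coincidences
#'
#' The sufficient statistic for Krippendorff's alpha. Each subject with
#' \code{m_u >= 2} ratings contributes its within-subject ordered value pairs,
#' weighted by \code{1/(m_u - 1)}; subjects with fewer than two ratings are
#' excluded and counted in \code{excludedUnits}.
#'
#' @slot o symmetric k x k matrix of coincidence weights o_cc'.
#' @slot marginals n_c = rowSums(o).
#' @slot grandTotal n.. = sum of all pairable values (= sum over retained
#'   subjects of m_u).
#' @slot excludedUnits number of subjects dropped for having < 2 ratings.
#'
#' @name CoincidenceMatrix-class
#' @aliases CoincidenceMatrix-class
#' @exportClass CoincidenceMatrix
setClass("CoincidenceMatrix",
  representation(
    o = "matrix",
    marginals = "numeric",
    grandTotal = "numeric",
    excludedUnits = "integer"
  )
)

setValidity("CoincidenceMatrix", function(object) {
  msg <- character()
  if (!isTRUE(all.equal(object@o, t(object@o))))
    msg <- c(msg, "coincidence matrix must be symmetric")
  if (any(object@o < -1e-12)) msg <- c(msg, "coincidences must be >= 0")
  if (!isTRUE(all.equal(unname(rowSums(object@o)), unname(object@marginals))))
    msg <- c(msg, "marginals must equal rowSums(o)")
  if (!isTRUE(all.equal(sum(object@marginals), object@grandTotal)))
    msg <- c(msg, "grandTotal must equal sum(marginals)")
  if (length(msg)) msg else TRUE
})

#' AgreementEstimate: a chance-corrected agreement coefficient
#'
#' @slot value the coefficient, in [-1, 1].
#' @slot method \code{"fleiss_k"} or \code{"krippendorff_alpha"}.
#' @slot components named list of the building blocks: for Fleiss' K the
#'   per-subject agreements P_i, their mean, the marginal proportions p_j and
#'   the chance agreement P_e; for alpha the observed and expected
#'   disagreement D_o, D_e.
#' @slot nSubjectsUsed subjects entering the estimate (complete cases for K;
#'   subjects with >= 2 ratings for alpha).
#' @slot degenerate TRUE when only a single category occurs and the value 1
#'   is assigned by convention (agreement is trivially perfect).
#'
#' @name AgreementEstimate-class
#' @aliases AgreementEstimate-class
#' @exportClass AgreementEstimate
setClass("AgreementEstimate",
  representation(
    value = "numeric",
    method = "character",
    components = "list",
    nSubjectsUsed = "integer",
    degenerate = "logical"
  )
)

setValidity("AgreementEstimate", function(object) {
  msg <- character()
  if (length(object@value) != 1L || is.na(object@value))
    msg <- c(msg, "'value' must be a single number")
  else if (object@value < -1 - 1e-10 || object@value > 1 + 1e-10)
    msg <- c(msg, "'value' must lie in [-1, 1]")
  if (!object@method %in% c("fleiss_k", "krippendorff_alpha"))
    msg <- c(msg, "unknown estimation method")
  if (length(msg)) msg else TRUE
})

#' ConfidenceInterval for an agreement coefficient
#'
#' @slot lower,upper interval bounds (the asymptotic interval is deliberately
#'   not truncated to [-1, 1]).
#' @slot method \code{"asymptotic"}, \code{"subject_bootstrap"} or
#'   \code{"coincidence_bootstrap"}.
#' @slot level two-sided confidence level.
#'
#' @name ConfidenceInterval-class
#' @aliases ConfidenceInterval-class
#' @exportClass ConfidenceInterval
setClass("ConfidenceInterval",
  representation(
    lower = "numeric",
    upper = "numeric",
    method = "character",
    level = "numeric"
  )
)

setValidity("ConfidenceInterval", function(object) {
  msg <- character()
  if (object@lower > object@upper + 1e-12)
    msg <- c(msg, "lower bound exceeds upper bound")
  if (object@level <= 0 || object@level >= 1)
    msg <- c(msg, "'level' must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' BootstrapDistribution of replicate coefficient estimates
#'
#' @slot estimates replicate values, sorted ascending.
#' @slot nDegenerate number of replicates that evaluated to 1 by the
#'   single-category convention.
#'
#' @name BootstrapDistribution-class
#' @aliases BootstrapDistribution-class
#' @exportClass BootstrapDistribution
setClass("BootstrapDistribution",
  representation(
    estimates = "numeric",
    nDegenerate = "integer"
  )
)

setValidity("BootstrapDistribution", function(object) {
  if (is.unsorted(object@estimates)) "estimates must be sorted ascending"
  else TRUE
})

#' AgreementBootstrap: a bootstrap distribution plus its percentile interval
#'
#' @slot distribution the \code{\linkS4class{BootstrapDistribution}}.
#' @slot interval the percentile \code{\linkS4class{ConfidenceInterval}}.
#' @slot estimator which coefficient was resampled.
#'
#' @name AgreementBootstrap-class
#' @aliases AgreementBootstrap-class
#' @exportClass AgreementBootstrap
setClass("AgreementBootstrap",
  representation(
    distribution = "BootstrapDistribution",
    interval = "ConfidenceInterval",
    estimator = "character"
  )
)

#' AgreementScenario: a simulation configuration with analytic true values
#'
#' Parameters of the latent-class rating generator: each subject carries a
#' latent category T ~ Categorical(pi); each rater independently reports T
#' with fidelity probability gamma and otherwise an independent draw from
#' Categorical(pi). The population Fleiss' K and the finite-sample true alpha
#' are stored alongside.
#'
#' @slot N,n,k subjects, raters, categories.
#' @slot agreement \code{"low"}, \code{"moderate"} or \code{"high"} (or
#'   \code{"custom"} when gamma is supplied directly).
#' @slot pi category probability vector (length k, sums to 1).
#' @slot gamma rater fidelity probability in [0, 1].
#' @slot kTrue population Fleiss' K of the generator.
#' @slot alphaTrue finite-sample true alpha at n.. = N * n.
#'
#' @name AgreementScenario-class
#' @aliases AgreementScenario-class
#' @exportClass AgreementScenario
setClass("AgreementScenario",
  representation(
    N = "integer",
    n = "integer",
    k = "integer",
    agreement = "character",
    pi = "numeric",
    gamma = "numeric",
    kTrue = "numeric",
    alphaTrue = "numeric"
  )
)

setValidity("AgreementScenario", function(object) {
  msg <- character()
  if (abs(sum(object@pi) - 1) > 1e-8) msg <- c(msg, "'pi' must sum to 1")
  if (length(object@pi) != object@k) msg <- c(msg, "'pi' must have length k")
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "'gamma' must lie in [0, 1]")
  if (object@N < 1L || object@n < 2L || object@k < 2L)
    msg <- c(msg, "need N >= 1, n >= 2, k >= 2")
  if (length(msg)) msg else TRUE
})
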