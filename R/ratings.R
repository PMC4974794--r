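#' Construct a RatingTable from coded values
#'
#' @param values numeric matrix, subjects in rows, raters in columns, entries
#'   in \code{1..k} or \code{NA} for missing.
#' @param k number of categories; defaults to the largest observed code.
#' @param scale \code{"nominal"} or \code{"ordinal"}; on an ordinal scale the
#'   numeric code order is the rank order.
#' @param categories optional character labels for the k categories.
#' @return a \code{\linkS4class{RatingTable}}.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' fleissK(rt)
#' @export
ratingTable <- function(values, k = NULL,
                        scale = c("nominal", "ordinal"),
                        categories = NULL) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(k)) {
    obs <- values[!is.na(values)]
    if (!length(obs)) stop("cannot infer 'k' from an all-missing table")
    k <- max(obs)
  }
  k <- as.integer(k)
  if (is.null(categories)) categories <- as.character(seq_len(k))
  new("RatingTable", values = values, k = k, scale = scale,
      categories = as.character(categories))
}

#' Encode a table of rating labels as a RatingTable
#'
#' Maps arbitrary labels (character or factor) to integer category codes
#' \code{1..k} following a user-supplied category order, which also defines
#' ordinal rank. Cells matching a missing code become \code{NA}.
#'
#' @param raw a matrix or data.frame of labels, subjects in rows, raters in
#'   columns.
#' @param categoryOrder character vector of the category labels in code
#'   (= rank) order; must cover every non-missing label.
#' @param missingCodes labels treated as missing; defaults to \code{""},
#'   \code{"NA"} and \code{"."}.
#' @param scale \code{"nominal"} or \code{"ordinal"}.
#' @return a \code{\linkS4class{RatingTable}}.
#' @examples
#' encodeRatings(rbind(c("pos", "neg")), categoryOrder = c("neg", "pos"))
#' @export
encodeRatings <- function(raw, categoryOrder,
                          missingCodes = c("", "NA", "."),
                          scale = c("nominal", "ordinal")) {
  scale <- match.arg(scale)
  raw <- as.matrix(raw)
  lab <- trimws(as.character(raw))
  dim(lab) <- dim(raw)
  if (length(categoryOrder) < 2L)
    stop("'categoryOrder' must list at least 2 categories")
  if (anyDuplicated(categoryOrder))
    stop("'categoryOrder' contains duplicated labels")
  if (ncol(lab) < 2L) stop("at least 2 raters (columns) are required")
  lab[lab %in% missingCodes] <- NA_character_
  codes <- match(lab, categoryOrder)
  bad <- which(!is.na(lab) & is.na(codes))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(lab))
    stop(sprintf(
      "unknown label \"%s\" at subject %d, rater %d (not in categoryOrder)",
      lab[bad[1L]], ij[1L], ij[2L]))
  }
  dim(codes) <- dim(lab)
  ratingTable(codes, k = length(categoryOrder), scale = scale,
              categories = categoryOrder)
}

## n_ij tally for a coded matrix; the workhorse behind countMatrix() and the
## simulation loop (kept free of S4 dispatch for speed).
.tallyCounts <- function(values, k) {
  counts <- matrix(0L, nrow(values), k)
  for (j in seq_len(k))
    counts[, j] <- as.integer(rowSums(values == j, na.rm = TRUE))
  counts
}

#' Tally ratings into per-subject category counts
#'
#' @param ratings a \code{\linkS4class{RatingTable}}.
#' @return a \code{\linkS4class{CategoryCounts}} with \code{counts[i, j]} =
#'   number of raters assigning subject i to category j.
#' @export
countMatrix <- function(ratings) {
  stopifnot(is(ratings, "RatingTable"))
  counts <- .tallyCounts(ratings@values, ratings@k)
  new("CategoryCounts", counts = counts,
      rowTotals = as.numeric(rowSums(counts)),
      nRaters = ncol(ratings@values))
}

## coerce RatingTable / CategoryCounts to the (counts, m, n) triple
.asCounts <- function(x) {
  if (is(x, "RatingTable")) x <- countMatrix(x)
  stopifnot(is(x, "CategoryCounts"))
  list(counts = x@counts, m = x@rowTotals, n = x@nRaters)
}

## ---- accessors ----

#' @rdname accessors
setMethod("nSubjects", "RatingTable", function(x) nrow(x@values))
#' @rdname accessors
setMethod("nRaters", "RatingTable", function(x) ncol(x@values))
#' @rdname accessors
setMethod("nCategories", "RatingTable", function(x) x@k)
#' @rdname accessors
setMethod("ratingValues", "RatingTable", function(x) x@values)
#' @rdname accessors
setMethod("ratingScale", "RatingTable", function(x) x@scale)
#' @rdname accessors
setMethod("categoryLabels", "RatingTable", function(x) x@categories)

#' @rdname accessors
setMethod("nSubjects", "CategoryCounts", function(x) nrow(x@counts))
#' @rdname accessors
setMethod("nRaters", "CategoryCounts", function(x) x@nRaters)
#' @rdname accessors
setMethod("nCategories", "CategoryCounts", function(x) ncol(x@counts))
#' @rdname accessors
setMethod("countValues", "CategoryCounts", function(x) x@counts)
#' @rdname accessors
setMethod("rowTotals", "CategoryCounts", function(x) x@rowTotals)

#' @rdname accessors
setMethod("coincidenceValues", "CoincidenceMatrix", function(x) x@o)
#' @rdname accessors
setMethod("marginals", "CoincidenceMatrix", function(x) x@marginals)
#' @rdname accessors
setMethod("grandTotal", "CoincidenceMatrix", function(x) x@grandTotal)
#' @rdname accessors
setMethod("excludedUnits", "CoincidenceMatrix", function(x) x@excludedUnits)
#' @rdname accessors
setMethod("nCategories", "CoincidenceMatrix", function(x) ncol(x@o))

#' @rdname accessors
setMethod("estimateValue", "AgreementEstimate", function(x) x@value)
#' @rdname accessors
setMethod("estimateMethod", "AgreementEstimate", function(x) x@method)
#' @rdname accessors
setMethod("components", "AgreementEstimate", function(x) x@components)
#' @rdname accessors
setMethod("isDegenerate", "AgreementEstimate", function(x) x@degenerate)
#' @rdname accessors
setMethod("nSubjects", "AgreementEstimate", function(x) x@nSubjectsUsed)

#' @rdname accessors
setMethod("ciLower", "ConfidenceInterval", function(x) x@lower)
#' @rdname accessors
setMethod("ciUpper", "ConfidenceInterval", function(x) x@upper)
#' @rdname accessors
setMethod("ciLevel", "ConfidenceInterval", function(x) x@level)

#' @rdname accessors
setMethod("replicates", "BootstrapDistribution", function(x) x@estimates)
#' @rdname accessors
setMethod("isDegenerate", "BootstrapDistribution",
          function(x) x@nDegenerate > 0L)
#' @rdname accessors
setMethod("replicates", "AgreementBootstrap",
          function(x) x@distribution@estimates)
#' @rdname accessors
setMethod("interval", "AgreementBootstrap", function(x) x@interval)
#' @rdname accessors
setMethod("ciLower", "AgreementBootstrap", function(x) x@interval@lower)
#' @rdname accessors
setMethod("ciUpper", "AgreementBootstrap", function(x) x@interval@upper)

## ---- show methods ----

setMethod("show", "RatingTable", function(object) {
  miss <- sum(is.na(object@values))
  cat(sprintf("RatingTable: %d subjects x %d raters, %d categories (%s)\n",
              nrow(object@values), ncol(object@values), object@k,
              object@scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", miss,
              100 * miss / length(object@values)))
})

setMethod("show", "CategoryCounts", function(object) {
  cat(sprintf("CategoryCounts: %d subjects x %d categories, n = %d raters\n",
              nrow(object@counts), ncol(object@counts), object@nRaters))
  cat(sprintf("  complete cases (m_i = n): %d\n",
              sum(object@rowTotals == object@nRaters)))
})

setMethod("show", "CoincidenceMatrix", function(object) {
  cat(sprintf("CoincidenceMatrix: %d categories, n.. = %g pairable values\n",
              ncol(object@o), object@grandTotal))
  cat(sprintf("  excluded units (< 2 ratings): %d\n", object@excludedUnits))
})

setMethod("show", "AgreementEstimate", function(object) {
  lbl <- c(fleiss_k = "Fleiss' K", krippendorff_alpha = "Krippendorff's alpha")
  cat(sprintf("%s = %.6f  (%d subjects used%s)\n",
              lbl[[object@method]], object@value, object@nSubjectsUsed,
              if (object@degenerate) "; degenerate: single category" else ""))
})

setMethod("show", "ConfidenceInterval", function(object) {
  cat(sprintf("%g%% CI (%s): [%.4f, %.4f]\n", 100 * object@level,
              object@method, object@lower, object@upper))
})

setMethod("show", "AgreementBootstrap", function(object) {
  cat(sprintf("Bootstrap (%s, B = %d): ", object@estimator,
              length(object@distribution@estimates)))
  show(object@interval)
  if (object@distribution@nDegenerate > 0L)
    cat(sprintf("  degenerate replicates: %d\n",
                object@distribution@nDegenerate))
})

setMethod("show", "AgreementScenario", function(object) {
  cat(sprintf(
    "AgreementScenario: N = %d, n = %d, k = %d, agreement = %s\n",
    object@N, object@n, object@k, object@agreement))
  cat(sprintf("  pi = (%s), gamma = %.4f\n",
              paste(format(object@pi), collapse = ", "), object@gamma))
  cat(sprintf("  true K = %.4f, true alpha = %.4f\n",
              object@kTrue, object@alphaTrue))
})
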