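.sepForPath <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a wide rating table from CSV/TSV
#'
#' Rows are subjects and columns are raters (use \code{transpose} for the
#' other layout); cells are category labels. The delimiter is inferred from
#' the file extension (.csv: comma, otherwise tab).
#'
#' @param path file path.
#' @param missingCodes labels treated as missing (default \code{""},
#'   \code{"NA"}, \code{"."}).
#' @param categories category labels in code (= rank) order; required for an
#'   ordinal scale, defaults to the sorted observed labels for a nominal one.
#' @param scale \code{"nominal"} or \code{"ordinal"}.
#' @param header does the file carry a header row of rater names?
#' @param transpose set TRUE when raters are rows and subjects are columns.
#' @return a \code{\linkS4class{RatingTable}}.
#' @export
readRatings <- function(path, missingCodes = c("", "NA", "."),
                        categories = NULL,
                        scale = c("nominal", "ordinal"),
                        header = FALSE, transpose = FALSE) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- tryCatch(
    utils::read.table(path, sep = .sepForPath(path), header = header,
                      colClasses = "character", na.strings = character(),
                      check.names = FALSE, fill = FALSE,
                      blank.lines.skip = TRUE),
    error = function(e) stop(sprintf(
      "could not parse %s as a rectangular table: %s", path,
      conditionMessage(e))))
  raw <- as.matrix(raw)
  if (transpose) raw <- t(raw)
  lab <- trimws(raw)
  obs <- lab[!(lab %in% missingCodes)]
  if (!length(obs)) stop("table contains no non-missing ratings")
  if (is.null(categories)) {
    if (scale == "ordinal")
      stop("an ordinal scale needs an explicit 'categories' rank order")
    categories <- sort(unique(obs))
  }
  encodeRatings(raw, categoryOrder = categories,
                missingCodes = missingCodes, scale = scale)
}

#' Estimate agreement coefficients with confidence intervals
#'
#' The one-stop analysis entry point: computes the requested coefficients on
#' one rating table, attaches the requested confidence intervals, and
#' returns a report that echoes every setting needed to reproduce the run.
#'
#' The asymptotic interval exists only for Fleiss' K (the sampling
#' distribution of alpha is unknown); requesting it for alpha alone is an
#' error, and requesting it at all draws a warning because its standard
#' error is valid only under the null hypothesis of zero agreement.
#'
#' @param ratings a \code{\linkS4class{RatingTable}}.
#' @param measures \code{"both"}, \code{"k"} or \code{"alpha"}.
#' @param ci \code{"bootstrap"}, \code{"asymptotic"}, \code{"both"} or
#'   \code{"none"}.
#' @param metric distance metric for alpha (\code{NULL}: the table's scale).
#' @param B bootstrap replicates (default 1000).
#' @param level two-sided confidence level (default 0.95).
#' @param seed integer seed for the bootstrap streams.
#' @return an \code{EstimateReport}: a list with one entry per coefficient
#'   (point estimate, intervals, subjects used/excluded) plus the settings
#'   echo, printable and serialisable with \code{\link{reportJSON}}.
#' @examples
#' rt <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
#' estimateAgreement(rt, B = 200, seed = 42)
#' @export
estimateAgreement <- function(ratings,
                              measures = c("both", "k", "alpha"),
                              ci = c("bootstrap", "asymptotic", "both",
                                     "none"),
                              metric = NULL, B = 1000L, level = 0.95,
                              seed = NULL) {
  measures <- match.arg(measures)
  ci <- match.arg(ci)
  stopifnot(is(ratings, "RatingTable"))
  if (is.null(metric)) metric <- ratings@scale
  metric <- match.arg(metric, c("nominal", "ordinal"))
  wantK <- measures %in% c("both", "k")
  wantA <- measures %in% c("both", "alpha")
  wantAsymp <- ci %in% c("asymptotic", "both")
  wantBoot <- ci %in% c("bootstrap", "both")
  if (wantAsymp && !wantK)
    stop("no asymptotic interval exists for Krippendorff's alpha; ",
         "use ci = \"bootstrap\"")
  if (wantAsymp)
    warning("the asymptotic interval is only valid for testing zero ",
            "agreement; prefer the bootstrap interval")
  if (metric == "ordinal" && wantK)
    warning("Fleiss' K is a nominal-scale coefficient; the ordinal metric ",
            "applies to alpha only")
  N <- nrow(ratings@values)
  nMissing <- sum(is.na(ratings@values))
  out <- list()
  if (wantK) {
    kEst <- fleissK(ratings)
    cis <- list()
    if (wantAsymp)
      cis$asymptotic <- if (kEst@degenerate)
        new("ConfidenceInterval", lower = 1, upper = 1,
            method = "asymptotic", level = level)
      else asymptoticCI(kEst, fleissKSE(ratings), level)
    if (wantBoot)
      cis$subject_bootstrap <- subjectBootstrap(
        ratings, "fleiss_k", B = B, level = level,
        seed = if (is.null(seed)) NULL else .childSeed(seed, 1L))@interval
    out$fleiss_k <- list(estimate = kEst@value,
                         degenerate = kEst@degenerate,
                         subjects_used = kEst@nSubjectsUsed,
                         subjects_excluded = N - kEst@nSubjectsUsed,
                         ci = cis)
  }
  if (wantA) {
    aEst <- krippAlpha(ratings, metric = metric)
    cis <- list()
    if (wantBoot)
      cis$subject_bootstrap <- subjectBootstrap(
        ratings, "krippendorff_alpha", metric = metric, B = B,
        level = level,
        seed = if (is.null(seed)) NULL else .childSeed(seed, 2L))@interval
    out$krippendorff_alpha <- list(estimate = aEst@value,
                                   degenerate = aEst@degenerate,
                                   subjects_used = aEst@nSubjectsUsed,
                                   subjects_excluded = N - aEst@nSubjectsUsed,
                                   metric = metric,
                                   ci = cis)
  }
  out$data <- list(subjects = N, raters = ncol(ratings@values),
                   categories = ratings@k, scale = ratings@scale,
                   category_labels = ratings@categories,
                   missing_cells = nMissing)
  out$settings <- list(B = B, level = level, seed = seed, metric = metric,
                       ci = ci)
  class(out) <- "EstimateReport"
  out
}

#' @export
print.EstimateReport <- function(x, ...) {
  d <- x$data
  cat(sprintf("Agreement report: %d subjects x %d raters, %d categories (%s), %d missing cells\n",
              d$subjects, d$raters, d$categories, d$scale, d$missing_cells))
  fmtci <- function(ci) sprintf("[%.4f, %.4f] (%s)", ci@lower, ci@upper,
                                ci@method)
  for (nm in intersect(c("fleiss_k", "krippendorff_alpha"), names(x))) {
    e <- x[[nm]]
    lbl <- c(fleiss_k = "Fleiss' K", krippendorff_alpha =
               "Krippendorff's alpha")[[nm]]
    cat(sprintf("  %s = %.6f  (%d subjects used, %d excluded)%s\n", lbl,
                e$estimate, e$subjects_used, e$subjects_excluded,
                if (isTRUE(e$degenerate)) " [degenerate]" else ""))
    for (ci in e$ci) cat("    ", fmtci(ci), "\n", sep = "")
  }
  cat(sprintf("  settings: B = %d, level = %g, seed = %s\n",
              x$settings$B, x$settings$level,
              if (is.null(x$settings$seed)) "NULL" else x$settings$seed))
  invisible(x)
}

#' Serialise an EstimateReport to JSON
#'
#' @param report an \code{EstimateReport} from
#'   \code{\link{estimateAgreement}}.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
reportJSON <- function(report, path = NULL) {
  stopifnot(inherits(report, "EstimateReport"))
  ser <- unclass(report)
  for (nm in intersect(c("fleiss_k", "krippendorff_alpha"), names(ser)))
    ser[[nm]]$ci <- lapply(ser[[nm]]$ci, function(ci)
      list(lower = ci@lower, upper = ci@upper, method = ci@method,
           level = ci@level))
  ser$spec_version <- "1.0"
  js <- jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a RatingTable to CSV/TSV
#'
#' @param ratings a \code{\linkS4class{RatingTable}}.
#' @param path output path; delimiter inferred from the extension.
#' @param labels write category labels instead of integer codes.
#' @return the path, invisibly.
#' @export
writeRatings <- function(ratings, path, labels = TRUE) {
  stopifnot(is(ratings, "RatingTable"))
  v <- ratings@values
  out <- if (labels) {
    lv <- matrix(ratings@categories[v], nrow(v), ncol(v))
    lv[is.na(v)] <- ""
    lv
  } else {
    ch <- matrix(as.character(v), nrow(v), ncol(v))
    ch[is.na(v)] <- ""
    ch
  }
  utils::write.table(out, path, sep = .sepForPath(path), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, na = "")
  invisible(path)
}

## Latent ordinal generator with clustered (adjacent-rank) disagreements:
## raters report the latent rank with probability `fidelity`, otherwise a
## neighbouring rank (+-1, clipped to [1, k]). Disagreements are thus close
## on the ordinal scale, the situation in which the ordinal alpha metric
## exceeds the nominal one.
.ordinalClusterValues <- function(N, n, k, fidelity) {
  latent <- sample.int(k, N, replace = TRUE)
  M <- matrix(rep(latent, n), N, n)
  miss <- matrix(stats::runif(N * n) >= fidelity, N, n)
  shift <- matrix(sample(c(-1L, 1L), N * n, replace = TRUE), N, n)
  M[miss] <- pmin(pmax(M[miss] + shift[miss], 1L), k)
  M
}

#' Generate an ordinal rating table with adjacent-rank disagreements
#'
#' Emulates ordinal assessments (e.g. staining-intensity scores) in which
#' raters who disagree are typically one rank apart. On such data the
#' ordinal alpha metric rewards near-misses and exceeds the nominal alpha.
#'
#' @param N,n,k subjects, raters, rank categories.
#' @param fidelity probability a rater reports the latent rank exactly.
#' @param seed integer seed (\code{NULL}: current RNG state).
#' @return an ordinal \code{\linkS4class{RatingTable}}.
#' @export
ordinalClusterSample <- function(N, n, k, fidelity = 0.6, seed = NULL) {
  stopifnot(N >= 1, n >= 2, k >= 2, fidelity >= 0, fidelity <= 1)
  if (!is.null(seed)) set.seed(seed)
  ratingTable(.ordinalClusterValues(N, n, k, fidelity), k = k,
              scale = "ordinal")
}

#' Write the reference fixture set
#'
#' Writes small CSV rating tables with JSON sidecars of expected estimates:
#' the 4-subject worked example (K = 0.466667, alpha = 0.533333), a
#' perfect-agreement and an inverse-agreement table (analytic values), and a
#' 50 x 4 case-study-shaped pair — one nominal, one ordinal with clustered
#' disagreements — with 10\% of cells deleted MCAR, whose sidecar values are
#' computed at generation time.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed for the generated case-study-shaped tables.
#' @return invisibly, the written file paths.
#' @export
writeFixtures <- function(dir, seed = 20160805L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create directory: %s", dir))
  paths <- character()
  put <- function(name, ratings, expected) {
    csv <- file.path(dir, paste0(name, ".csv"))
    writeRatings(ratings, csv, labels = FALSE)
    side <- file.path(dir, paste0(name, "_expected.json"))
    writeLines(jsonlite::toJSON(expected, auto_unbox = TRUE, digits = NA),
               side)
    paths <<- c(paths, csv, side)
  }
  worked <- ratingTable(rbind(c(1, 1), c(1, 1), c(2, 2), c(1, 2)))
  put("worked_example", worked,
      list(fleiss_k = 7 / 15, krippendorff_alpha = 8 / 15))
  perfect <- ratingTable(matrix(rep(rep(1:2, 5), 3), 10, 3), k = 2)
  put("perfect_agreement", perfect,
      list(fleiss_k = 1, krippendorff_alpha = 1))
  Ninv <- 10L
  inverse <- ratingTable(matrix(rep(c(1L, 2L), each = Ninv), Ninv, 2), k = 2)
  put("inverse_agreement", inverse,
      list(fleiss_k = -1,
           krippendorff_alpha = -(Ninv - 1) / Ninv))
  sc <- agreementScenario(50, 4, 4, "moderate", pi = rep(0.25, 4))
  nom <- applyMCAR(latentClassSample(sc, seed = .childSeed(seed, 1L)), 0.10,
                   seed = .childSeed(seed, 2L))
  put("case_study_nominal", nom,
      list(fleiss_k = fleissK(nom)@value,
           krippendorff_alpha = krippAlpha(nom)@value))
  ordc <- applyMCAR(ordinalClusterSample(50, 4, 4, fidelity = 0.6,
                                         seed = .childSeed(seed, 3L)), 0.10,
                    seed = .childSeed(seed, 4L))
  put("case_study_ordinal", ordc,
      list(krippendorff_alpha_nominal = krippAlpha(ordc,
                                                   metric = "nominal")@value,
           krippendorff_alpha_ordinal = krippAlpha(ordc,
                                                   metric = "ordinal")@value))
  invisible(paths)
}
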