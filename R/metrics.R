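#' Concordance index for affinity regression
#'
#' Fraction of correctly ordered prediction pairs among pairs with
#' distinct true affinities; tied predictions score 0.5. Equals 1 for a
#' perfectly concordant ranking, 0 for a perfectly discordant one, and has
#' expectation 0.5 for predictions independent of the labels. Invariant
#' under strictly monotone transforms of the predictions.
#'
#' @param yTrue,yPred equal-length numeric vectors (length >= 2).
#' @return CI in \[0, 1\], with attribute `nPairs` giving the number of
#'   comparable pairs.
#' @examples
#' concordanceIndex(c(1, 2, 3), c(10, 20, 30))  # 1
#' @export
concordanceIndex <- function(yTrue, yPred) {
  n <- length(yTrue)
  if (length(yPred) != n) stop("length mismatch")
  if (n < 2L) stop("need at least two observations")
  dt <- outer(yTrue, yTrue, "-")
  dp <- outer(yPred, yPred, "-")
  up <- upper.tri(dt)
  comparable <- up & dt != 0
  nPairs <- sum(comparable)
  if (!nPairs) stop("all true values tied: concordance index undefined")
  agree <- sign(dt[comparable]) * sign(dp[comparable])
  ci <- (sum(agree > 0) + 0.5 * sum(agree == 0)) / nPairs
  structure(ci, nPairs = nPairs)
}

#' Mean squared error
#'
#' @param yTrue,yPred equal-length numeric vectors.
#' @return mean of squared residuals.
#' @export
meanSquaredError <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (!length(yTrue)) stop("need at least one observation")
  mean((yTrue - yPred)^2)
}

#' rm2 external-validation metric
#'
#' `rm2 = r^2 * (1 - sqrt(|r^2 - r0^2|))`, where `r^2` is the squared
#' Pearson correlation of predictions and observations and `r0^2` is the
#' coefficient of determination of the least-squares fit of predictions on
#' observations constrained through the origin. Penalizes predictions
#' whose correlation is good but whose through-origin agreement is not;
#' `rm2 <= r^2` always, with equality when `r0^2 = r^2` (e.g. predictions
#' exactly proportional to observations).
#'
#' @param yTrue,yPred numeric vectors of length >= 3 with non-zero
#'   variance.
#' @return rm2 value.
#' @export
rm2 <- function(yTrue, yPred) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  if (length(yTrue) < 3L) stop("need at least three observations")
  if (stats::sd(yTrue) == 0 || stats::sd(yPred) == 0)
    stop("zero variance: rm2 undefined")
  r2 <- stats::cor(yTrue, yPred)^2
  k <- sum(yTrue * yPred) / sum(yTrue^2)   # slope through the origin
  r02 <- 1 - sum((yPred - k * yTrue)^2) / sum((yPred - mean(yPred))^2)
  d <- abs(r2 - r02)
  if (d < 1e-12) d <- 0   # sqrt() would blow float dust up to ~1e-6
  r2 * (1 - sqrt(d))
}

#' Area under the precision-recall curve
#'
#' True affinities are binarized at `threshold` (positive = binder,
#' `yTrue >= threshold`); predictions act as ranking scores. The curve is
#' traversed from the highest score down, one point per distinct score
#' value, and integrated stepwise: `sum((R_k - R_{k-1}) * P_k)`. Constant
#' scores therefore give the positive prevalence. Common binarization
#' thresholds: pKd >= 7 for Kd-type data, score >= 12.1 for KIBA-type
#' data.
#'
#' @param yTrue numeric affinities.
#' @param yPred numeric prediction scores.
#' @param threshold binarization cutoff on `yTrue`.
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(yTrue, yPred, threshold = 7) {
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  lab <- yTrue >= threshold
  if (all(lab) || !any(lab))
    stop("single-class labels after binarization: AUPR undefined")
  o <- order(yPred, decreasing = TRUE)
  lab <- lab[o]; sc <- yPred[o]
  newBlock <- c(TRUE, sc[-1] != sc[-length(sc)])
  tp <- cumsum(lab); fp <- cumsum(!lab)
  cut <- which(c(newBlock[-1], TRUE))     # last index of each score block
  prec <- tp[cut] / (tp[cut] + fp[cut])
  rec <- tp[cut] / sum(lab)
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate per-fold predictions into a MetricsReport
#'
#' Computes CI, MSE, rm2 and AUPR for each fold and aggregates them as
#' fold means with sample-standard-deviation dispersion.
#'
#' @param foldResults list of `list(yTrue=, yPred=)` per fold.
#' @param auprThreshold binarization threshold passed to [aupr()]; folds
#'   where binarization yields a single class report `NA` for AUPR and are
#'   dropped from its aggregate.
#' @return a [MetricsReport-class].
#' @export
evaluatePredictions <- function(foldResults, auprThreshold = 7) {
  per <- lapply(foldResults, function(f) {
    ci <- concordanceIndex(f$yTrue, f$yPred)
    a <- tryCatch(aupr(f$yTrue, f$yPred, auprThreshold),
                  error = function(e) NA_real_)
    data.frame(ci = as.numeric(ci), mse = meanSquaredError(f$yTrue, f$yPred),
               rm2 = rm2(f$yTrue, f$yPred), aupr = a,
               nPairsCI = attr(ci, "nPairs"))
  })
  per <- do.call(rbind, per)
  rownames(per) <- paste0("fold", seq_len(nrow(per)))
  methods::new("MetricsReport",
               ci = mean(per$ci), mse = mean(per$mse), rm2 = mean(per$rm2),
               aupr = mean(per$aupr, na.rm = TRUE),
               perFold = per, nPairsCI = sum(per$nPairsCI))
}

setMethod("show", "MetricsReport", function(object) {
  disp <- function(x) if (nrow(object@perFold) > 1L)
    sprintf(" (%.3f)", stats::sd(x)) else ""
  cat(sprintf("MetricsReport over %d fold(s):\n", nrow(object@perFold)))
  cat(sprintf("  CI   %.4f%s\n", object@ci, disp(object@perFold$ci)))
  cat(sprintf("  MSE  %.4f%s\n", object@mse, disp(object@perFold$mse)))
  cat(sprintf("  rm2  %.4f%s\n", object@rm2, disp(object@perFold$rm2)))
  cat(sprintf("  AUPR %.4f%s\n", object@aupr,
              disp(stats::na.omit(object@perFold$aupr))))
  cat(sprintf("  comparable pairs (CI): %d\n", as.integer(object@nPairsCI)))
})

#' Serialize a MetricsReport to JSON
#'
#' @param report a [MetricsReport-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  jsonlite::write_json(
    list(aggregate = list(ci = report@ci, mse = report@mse,
                          rm2 = report@rm2, aupr = report@aupr,
                          nPairsCI = report@nPairsCI),
         perFold = report@perFold),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
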