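#' Mahalanobis-distance outlier screening in PCA score space
#'
#' With many more wavelengths than samples the raw spectral covariance is
#' singular, so distances are computed in the PCA score subspace retaining
#' the smallest number of components whose cumulative explained variance
#' reaches `varianceKept`.  The score covariance is diagonal by
#' construction, making the Mahalanobis distance a sum of squared
#' standardized scores, approximately chi-square distributed on
#' `subspaceDims` degrees of freedom for well-behaved data.
#'
#' Two flagging rules are provided.  `"chauvenet"` flags sample `i` when the
#' expected number of equally extreme samples is below one half,
#' `n * P(D > d_i) < 0.5`; `"quantile95"` flags squared distances above the
#' chi-square 95% quantile.
#'
#' @param spectra a `SpectraSet` with at least 5 samples
#' @param varianceKept fraction of variance the PCA subspace must explain
#'   (in (0, 1], default 0.99)
#' @param rule `"chauvenet"` (default) or `"quantile95"`
#' @return an [OutlierReport-class]
#' @export
mahalanobisOutliers <- function(spectra, varianceKept = 0.99,
                                rule = c("chauvenet", "quantile95")) {
  rule <- match.arg(rule)
  X <- absorbance(spectra)
  n <- nrow(X)
  if (n < 5) stop("outlier screening requires at least 5 samples")
  if (varianceKept <= 0 || varianceKept > 1)
    stop("varianceKept must be in (0, 1]")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  sv <- svd(Xc, nu = min(n, ncol(X)), nv = 0)
  ev <- sv$d^2 / (n - 1)
  ev <- ev[ev > max(ev) * 1e-12]
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= varianceKept)[1]
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k, k)
  d2 <- rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/"))
  d <- sqrt(d2)
  names(d) <- sampleIds(spectra)
  if (rule == "chauvenet") {
    flagged <- names(d)[n * pchisq(d2, df = k, lower.tail = FALSE) < 0.5]
    threshold <- sqrt(qchisq(1 - 0.5 / n, df = k))
  } else {
    threshold <- sqrt(qchisq(0.95, df = k))
    flagged <- names(d)[d > threshold]
  }
  new("OutlierReport", distances = d, threshold = threshold,
      flagged = flagged, subspaceDims = as.integer(k), rule = rule)
}

#' Kennard-Stone calibration/prediction partition
#'
#' Deterministic max-min algorithm: seed with the pair of samples at maximum
#' Euclidean distance, then repeatedly add the sample whose minimum distance
#' to the already-selected set is largest, until the requested calibration
#' size is reached.  Ties are broken by the lower sample index.  Distances
#' are computed on whatever spectra are supplied (typically the same
#' pretreated spectra used for modelling).
#'
#' @param spectra a `SpectraSet` with at least 3 samples
#' @param calibrationFraction fraction of samples for the calibration set
#'   (calibration size = `round(fraction * n)`); ignored when
#'   `calibrationSize` is given
#' @param calibrationSize optional explicit calibration-set size (allows
#'   forcing e.g. 75 of 111 where rounding would give 74)
#' @return a [SplitResult-class]
#' @export
kennardStone <- function(spectra, calibrationFraction = 2 / 3,
                         calibrationSize = NULL) {
  X <- absorbance(spectra)
  n <- nrow(X)
  if (n < 3) stop("Kennard-Stone requires at least 3 samples")
  if (is.null(calibrationSize)) {
    if (calibrationFraction <= 0 || calibrationFraction >= 1)
      stop("calibrationFraction must be in (0, 1)")
    m <- round(calibrationFraction * n)
  } else {
    m <- as.integer(calibrationSize)
    if (m < 2 || m > n) stop("calibrationSize out of range")
  }
  m <- max(m, 2L)
  D <- as.matrix(dist(X))
  # seed pair: maximum distance, ties -> lexicographically smallest (i, j)
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[order(pmin(best[, 1], best[, 2]), pmax(best[, 1], best[, 2])), ,
               drop = FALSE]
  sel <- sort(best[1, ])
  remaining <- setdiff(seq_len(n), sel)
  while (length(sel) < m) {
    minDist <- apply(D[remaining, sel, drop = FALSE], 1, min)
    pick <- remaining[which.max(minDist)]  # which.max: first index on ties
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
  }
  ids <- sampleIds(spectra)
  new("SplitResult", calibrationIds = ids[sort(sel)],
      predictionIds = ids[sort(remaining)],
      ratioRequested = if (is.null(calibrationSize)) calibrationFraction
                       else m / n)
}
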