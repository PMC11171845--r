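#' Exponentially decreasing function (EDF) retention ratio
#'
#' The forced-removal schedule of CARS: at Monte-Carlo run `i` of `N`, the
#' fraction of the `p` wavelengths kept is `r_i = a * exp(-k * i)` with
#' `a = (p/2)^(1/(N-1))` and `k = log(p/2)/(N-1)`, so that `r_1 = 1` (all
#' variables survive the first run) and `ceil(r_N * p) = 2` (two variables
#' at the last run).  The kept count is `ceil(r_i * p)`.
#'
#' @param i run index (1..N)
#' @param N total number of Monte-Carlo runs (>= 2)
#' @param p number of wavelength variables (>= 2)
#' @return list with `ratio` and `kept`
#' @examples
#' edfRatio(1, 100, 1557)$kept    # 1557
#' edfRatio(100, 100, 1557)$kept  # 2
#' @export
edfRatio <- function(i, N, p) {
  if (any(i < 1) || any(i > N)) stop("run index out of range")
  if (N < 2) stop("N must be >= 2")
  if (p < 2) stop("p must be >= 2")
  k <- log(p / 2) / (N - 1)
  a <- (p / 2)^(1 / (N - 1))
  r <- a * exp(-k * i)
  list(ratio = r, kept = as.integer(ceiling(r * p)))
}

#' CARS configuration
#'
#' @param nRuns number of Monte-Carlo sampling runs (default 100)
#' @param sampleFraction fraction of calibration samples drawn without
#'   replacement per run (default 0.8)
#' @param cvFolds folds of the per-run RMSECV evaluation (default 10)
#' @param maxLvs latent-variable cap for inner model fits (default 20)
#' @param recordCoefPath keep the full regression-coefficient path in the
#'   trace? (default TRUE; a `p x nRuns` matrix)
#' @param seed RNG seed
#' @return list of class `carsConfig`
#' @export
carsConfig <- function(nRuns = 100L, sampleFraction = 0.8, cvFolds = 10L,
                       maxLvs = 20L, recordCoefPath = TRUE, seed = 1L) {
  if (nRuns < 2) stop("nRuns must be >= 2")
  if (sampleFraction <= 0 || sampleFraction >= 1)
    stop("sampleFraction must be in (0, 1)")
  structure(list(nRuns = as.integer(nRuns), sampleFraction = sampleFraction,
                 cvFolds = as.integer(cvFolds), maxLvs = as.integer(maxLvs),
                 recordCoefPath = isTRUE(recordCoefPath),
                 seed = as.integer(seed)),
            class = "carsConfig")
}

# cross-validated RMSECV (min over LV counts) of a PLS model on a column
# subset; returns c(rmsecv, chosenLvs)
subsetRmsecv <- function(X, y, cols, maxLvs, folds) {
  Xs <- X[, cols, drop = FALSE]
  n <- nrow(Xs)
  folds <- min(folds, n)
  assignment <- (seq_len(n) - 1L) %% folds
  cap <- max(1L, min(maxLvs, n - max(tabulate(assignment + 1L, folds)) - 1L,
                     length(cols)))
  curve <- as.numeric(cppPlsCv(Xs, y, cap, folds, as.integer(assignment)))
  c(min(curve), which.min(curve))
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' For each Monte-Carlo run `i` of `N`: (1) draw `floor(fraction * n)`
#' calibration samples without replacement and fit a PLS model on the
#' currently active wavelengths (latent variables chosen by inner
#' cross-validation on the subsample, capped at `maxLvs`); (2) forced
#' removal by the exponentially decreasing function -- keep the
#' `ceil(r_i * p)` variables with the largest absolute regression
#' coefficients; (3) adaptive reweighted sampling -- draw that many
#' variables with replacement with probability proportional to the weights
#' `w_j = |b_j| / sum|b_j|`, the active set becoming the unique drawn
#' variables.  Each run's active set is scored by K-fold RMSECV on the full
#' calibration set; the subset with the smallest RMSECV wins.
#'
#' The trace records per-run kept counts (non-increasing), RMSECV values,
#' chosen LVs, the best run index and optionally the coefficient path.  If
#' the active set collapses below 2 variables the procedure stops early
#' with a note in the trace.
#'
#' @param X calibration predictor matrix (samples x wavelengths), pretreated
#' @param y calibration reference values
#' @param config a [carsConfig()]
#' @return a [SelectionResult-class]
#' @export
carsSelect <- function(X, y, config = carsConfig()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 10) stop("CARS requires at least 10 samples")
  if (p < 2) stop("CARS requires at least 2 wavelengths")
  if (sd(y) < 1e-12) stop("zero-variance response")
  set.seed(config$seed)
  N <- config$nRuns
  m <- floor(config$sampleFraction * n)
  active <- seq_len(p)
  keptCount <- integer(0)
  rmsecvTrace <- numeric(0)
  lvTrace <- integer(0)
  activeSets <- vector("list", N)
  coefPath <- if (config$recordCoefPath) matrix(NA_real_, p, N) else NULL
  note <- NULL
  for (i in seq_len(N)) {
    sub <- sort(sample.int(n, m))
    Xs <- X[sub, active, drop = FALSE]
    ys <- y[sub]
    innerFolds <- min(config$cvFolds, m)
    assignment <- (seq_len(m) - 1L) %% innerFolds
    cap <- max(1L, min(config$maxLvs, m - max(tabulate(assignment + 1L,
                                                       innerFolds)) - 1L,
                       length(active)))
    curve <- as.numeric(cppPlsCv(Xs, ys, cap, innerFolds,
                                 as.integer(assignment)))
    fit <- cppPlsFit(Xs, ys, which.min(curve))
    b <- as.numeric(fit$B[, ncol(fit$B)])
    if (!is.null(coefPath)) coefPath[active, i] <- b
    w <- abs(b)
    if (sum(w) == 0) w <- rep(1, length(w))
    w <- w / sum(w)
    keep <- min(edfRatio(i, N, p)$kept, length(active))
    edfSurvivors <- active[order(abs(b), decreasing = TRUE)[seq_len(keep)]]
    wSurv <- w[match(edfSurvivors, active)]
    draw <- sample(edfSurvivors, size = keep, replace = TRUE,
                   prob = wSurv / sum(wSurv))
    active <- sort(unique(draw))
    keptCount[i] <- length(active)
    if (length(active) < 2) {
      note <- sprintf("active set collapsed to %d variable(s) at run %d",
                      length(active), i)
      keptCount <- keptCount[seq_len(i - 1L)]
      break
    }
    sc <- subsetRmsecv(X, y, active, config$maxLvs, config$cvFolds)
    rmsecvTrace[i] <- sc[1]
    lvTrace[i] <- as.integer(sc[2])
    activeSets[[i]] <- active
  }
  done <- length(rmsecvTrace)
  if (!done) stop("CARS terminated before any subset could be scored")
  bestRun <- which.min(rmsecvTrace)
  selected <- activeSets[[bestRun]]
  trace <- list(keptCount = keptCount, rmsecv = rmsecvTrace,
                chosenLvs = lvTrace, bestRun = bestRun, note = note)
  if (!is.null(coefPath)) trace$coefPath <- coefPath[, seq_len(done), drop = FALSE]
  new("SelectionResult", selectedIndices = as.integer(selected),
      method = "cars", rmsecv = rmsecvTrace[bestRun], trace = trace,
      seed = as.integer(config$seed))
}

#' GA configuration
#'
#' Genetic-algorithm wavelength selection settings.  The published protocol
#' runs the GA 100 times, counts how often each wavelength appears in a
#' run's best chromosome, keeps wavelengths with frequency >= 4, and repeats
#' the whole procedure five times, reporting the repeat with the median
#' final RMSECV.  GA internals (tournament selection of size 2, single-point
#' crossover, bit-flip mutation, elitism of 1) follow common GA-PLS toolbox
#' defaults.
#'
#' @param nRuns independent GA runs whose best chromosomes are pooled
#'   (default 100)
#' @param population chromosomes per generation (default 30)
#' @param generations generations per run (default 100)
#' @param crossoverProb single-point crossover probability (default 0.5)
#' @param mutationProb per-gene bit-flip probability (default 0.01)
#' @param frequencyThreshold minimum selection frequency (default 4)
#' @param nRepeats repeats of the whole procedure; the repeat with the
#'   median final RMSECV is returned (default 5)
#' @param initProb probability a gene starts active (default 0.1)
#' @param cvFolds,maxLvs inner cross-validation settings for the fitness
#' @param window mean-binning window applied to the spectra before the GA
#'   (1 = operate on individual wavelengths, the default; selected bins are
#'   expanded back to their constituent wavelength indices)
#' @param seed RNG seed
#' @return list of class `gaConfig`
#' @export
gaConfig <- function(nRuns = 100L, population = 30L, generations = 100L,
                     crossoverProb = 0.5, mutationProb = 0.01,
                     frequencyThreshold = 4L, nRepeats = 5L, initProb = 0.1,
                     cvFolds = 10L, maxLvs = 20L, window = 1L, seed = 1L) {
  if (frequencyThreshold < 0) stop("frequencyThreshold must be >= 0")
  if (crossoverProb < 0 || crossoverProb > 1 ||
      mutationProb < 0 || mutationProb > 1)
    stop("probabilities must lie in [0, 1]")
  structure(list(nRuns = as.integer(nRuns), population = as.integer(population),
                 generations = as.integer(generations),
                 crossoverProb = crossoverProb, mutationProb = mutationProb,
                 frequencyThreshold = as.integer(frequencyThreshold),
                 nRepeats = as.integer(nRepeats), initProb = initProb,
                 cvFolds = as.integer(cvFolds), maxLvs = as.integer(maxLvs),
                 window = as.integer(window), seed = as.integer(seed)),
            class = "gaConfig")
}

# one GA run: returns the best chromosome (logical vector) found
gaRun <- function(X, y, config) {
  p <- ncol(X)
  pop <- matrix(runif(config$population * p) < config$initProb,
                config$population, p)
  # every chromosome needs at least one active gene
  empty <- which(rowSums(pop) == 0)
  for (i in empty) pop[i, sample.int(p, 1)] <- TRUE
  fitnessOf <- function(chrom) {
    cols <- which(chrom)
    if (!length(cols)) return(Inf)
    subsetRmsecv(X, y, cols, config$maxLvs, config$cvFolds)[1]
  }
  fitness <- apply(pop, 1, fitnessOf)
  for (g in seq_len(config$generations)) {
    newPop <- matrix(FALSE, config$population, p)
    newFit <- numeric(config$population)
    elite <- which.min(fitness)
    newPop[1, ] <- pop[elite, ]
    newFit[1] <- fitness[elite]
    i <- 2L
    while (i <= config$population) {
      pick <- function() {
        cand <- sample.int(config$population, 2)
        cand[which.min(fitness[cand])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      if (runif(1) < config$crossoverProb && p >= 2) {
        cut <- sample.int(p - 1L, 1)
        c1 <- c(p1[seq_len(cut)], p2[(cut + 1L):p])
        c2 <- c(p2[seq_len(cut)], p1[(cut + 1L):p])
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i > config$population) break
        flip <- runif(p) < config$mutationProb
        child <- xor(child, flip)
        if (!any(child)) child[sample.int(p, 1)] <- TRUE
        newPop[i, ] <- child
        newFit[i] <- fitnessOf(child)
        i <- i + 1L
      }
    }
    pop <- newPop
    fitness <- newFit
  }
  pop[which.min(fitness), ]
}

#' Genetic-algorithm wavelength selection
#'
#' Binary-chromosome GA over wavelength variables with fitness equal to the
#' cross-validated RMSE of a PLS model restricted to the chromosome's
#' active variables.  `nRuns` independent runs each contribute their best
#' chromosome; a wavelength's frequency is the number of runs whose best
#' chromosome includes it, and wavelengths at or above
#' `frequencyThreshold` are selected.  The whole procedure is repeated
#' `nRepeats` times and the repeat whose final subset RMSECV is the median
#' of the repeats is returned.
#'
#' With `window > 1` the spectra are mean-binned into consecutive windows
#' before the GA and the selected bins are expanded back to their
#' constituent wavelength indices.
#'
#' @inheritParams carsSelect
#' @param config a [gaConfig()]
#' @return a [SelectionResult-class]
#' @export
gaSelect <- function(X, y, config = gaConfig()) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p0 <- ncol(X)
  if (n < 10) stop("GA selection requires at least 10 samples")
  if (sd(y) < 1e-12) stop("zero-variance response")
  w <- config$window
  if (w > 1L) {
    nb <- ceiling(p0 / w)
    bins <- split(seq_len(p0), rep(seq_len(nb), each = w)[seq_len(p0)])
    Xg <- vapply(bins, function(ix) rowMeans(X[, ix, drop = FALSE]),
                 numeric(n))
  } else {
    bins <- as.list(seq_len(p0))
    Xg <- X
  }
  p <- ncol(Xg)
  set.seed(config$seed)
  repeatSeeds <- sample.int(.Machine$integer.max, config$nRepeats)
  repeats <- vector("list", config$nRepeats)
  for (r in seq_len(config$nRepeats)) {
    set.seed(repeatSeeds[r])
    freq <- integer(p)
    for (run in seq_len(config$nRuns)) {
      best <- gaRun(Xg, y, config)
      freq <- freq + as.integer(best)
    }
    # threshold 0 degenerates to "every wavelength ever chosen by a run"
    selBins <- which(freq >= max(config$frequencyThreshold, 1L))
    if (!length(selBins))
      stop("empty selection after thresholding; decrease frequencyThreshold")
    sc <- subsetRmsecv(Xg, y, selBins, config$maxLvs, config$cvFolds)
    repeats[[r]] <- list(freq = freq, selBins = selBins, rmsecv = sc[1],
                         lvs = as.integer(sc[2]))
  }
  rms <- vapply(repeats, `[[`, numeric(1), "rmsecv")
  medianRep <- order(rms)[ceiling(length(rms) / 2)]
  chosen <- repeats[[medianRep]]
  selected <- sort(unique(unlist(bins[chosen$selBins])))
  freqFull <- integer(p0)
  for (j in seq_len(p)) freqFull[bins[[j]]] <- chosen$freq[j]
  new("SelectionResult", selectedIndices = as.integer(selected),
      method = "ga", rmsecv = chosen$rmsecv,
      trace = list(frequency = freqFull, binFrequency = chosen$freq,
                   window = w, repeatRmsecv = rms, medianRepeat = medianRep,
                   chosenLvs = chosen$lvs,
                   threshold = config$frequencyThreshold),
      seed = as.integer(config$seed))
}

#' @rdname nirpls-generics
#' @param axis wavelength axis (nm) used to translate indices
#' @export
setMethod("selectedWavelengths", "SelectionResult", function(x, axis) {
  axis[x@selectedIndices]
})
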