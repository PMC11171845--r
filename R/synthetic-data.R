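#' Radical-scavenging clearance capacity
#'
#' The clearance (scavenging) capacity used by both the ABTS and the DPPH
#' assay: `100 * (a0 - (a1 - a2)) / a0`, where `a0` is the absorbance of the
#' blank (working liquid without sample), `a1` the sample mixed with the
#' working liquid and `a2` the sample alone (its intrinsic absorbance).  The
#' value is not clamped: pathological absorbances can push it outside
#' `[0, 100]`, exactly as the formula allows.
#'
#' @param a0 blank absorbance (> 0)
#' @param a1 absorbance of sample + working liquid
#' @param a2 absorbance of sample alone
#' @return clearance capacity in percent (vectorized)
#' @examples
#' clearanceCapacity(0.70, 0.40, 0.05)  # 50
#' @export
clearanceCapacity <- function(a0, a1, a2) {
  if (any(!is.finite(a0)) || any(a0 <= 0))
    stop("invalid measurement: blank absorbance a0 must be > 0")
  100 * (a0 - (a1 - a2)) / a0
}

#' FRAP concentration from the standard curve
#'
#' Inverts the FeSO4 standard curve `A = 0.0019 * c + 0.0044` (r2 = 0.9995)
#' to convert an absorbance at 593 nm into a FeSO4-equivalent concentration
#' in umol/L.  The curve was established over 50-500 uM; results outside
#' that interval carry an `outOfRange` attribute set to `TRUE`.
#'
#' @param absorbance numeric absorbance value(s)
#' @return concentration in umol/L with attribute `outOfRange` (logical,
#'   same length)
#' @examples
#' frapConcentration(0.1944)  # 100 uM
#' @export
frapConcentration <- function(absorbance) {
  conc <- (absorbance - 0.0044) / 0.0019
  # epsilon guards against flagging the exact range endpoints after the
  # floating-point inversion
  out <- conc < 50 - 1e-9 | conc > 500 + 1e-9
  structure(conc, outOfRange = out)
}

#' Describe one spectral component of the synthetic mixture
#'
#' A component is a chemical constituent with a set of Gaussian absorption
#' bands (center, width, height per unit concentration) and linear response
#' coefficients mapping its concentration into the three reference assays.
#'
#' @param bandCenters band centers in nm
#' @param bandWidths Gaussian standard deviations in nm (same length, > 0)
#' @param bandHeights peak absorbance per unit concentration (same length)
#' @param concLow,concHigh concentration range sampled uniformly (a.u.)
#' @param effectAbts,effectFrap,effectDpph linear response coefficients of
#'   this component on each assay (0 = the assay does not see it)
#' @return a list of class `componentSpec`
#' @export
componentSpec <- function(bandCenters, bandWidths, bandHeights,
                          concLow = 0, concHigh = 1,
                          effectAbts = 0, effectFrap = 0, effectDpph = 0) {
  stopifnot(length(bandCenters) == length(bandWidths),
            length(bandCenters) == length(bandHeights))
  if (any(bandWidths <= 0)) stop("band widths must be > 0")
  if (concLow >= concHigh) stop("concLow must be < concHigh")
  structure(list(bandCenters = as.numeric(bandCenters),
                 bandWidths = as.numeric(bandWidths),
                 bandHeights = as.numeric(bandHeights),
                 concLow = concLow, concHigh = concHigh,
                 effects = c(abts = effectAbts, frap = effectFrap,
                             dpph = effectDpph)),
            class = "componentSpec")
}

#' Default three-component band system
#'
#' Mirrors the absorption structure of powdered-herb NIR spectra: an O-H
#' component with bands at 1440 and 1940 nm (water/polysaccharide hydroxyls),
#' a C-H overtone component at 1210 and 1730 nm, and a C-H combination
#' component at 2280 and 2330 nm.  Each component contributes to all three
#' assays with distinct weights so that every band system is informative.
#'
#' @return list of three `componentSpec`s
#' @export
defaultComponents <- function() {
  list(
    oh = componentSpec(c(1440, 1940), c(45, 55), c(0.45, 0.60),
                       effectAbts = 1.0, effectFrap = 0.8, effectDpph = 0.9),
    ch_overtone = componentSpec(c(1210, 1730), c(30, 40), c(0.25, 0.35),
                                effectAbts = 0.6, effectFrap = 1.0,
                                effectDpph = 0.4),
    ch_comb = componentSpec(c(2280, 2330), c(35, 35), c(0.30, 0.30),
                            effectAbts = 0.3, effectFrap = 0.5,
                            effectDpph = 1.0)
  )
}

#' Configuration of the synthetic spectra generator
#'
#' Defaults state the world the generator emulates: 111 samples on a
#' 1557-point grid uniform in wavenumber from 10000 to 4000 cm-1 (stored
#' ascending in nm, i.e. 1000-2500 nm, matching the FT-instrument
#' convention and the full-spectrum variable count), three informative band
#' systems, per-spectrum multiplicative gain (sd 0.10) and additive offset
#' (sd 0.05 AU) scatter artifacts, white instrumental noise (sd 0.002 AU)
#' and assay noise at 5% of each reference range.  Reference values are
#' rescaled into the observed assay ranges: ABTS 7.4-11.7%, FRAP
#' 14.0-47.7 umol/L, DPPH 11.4-30.2%.
#'
#' @param nSamples number of samples (>= 4)
#' @param gridPoints number of wavelength points
#' @param wnHigh,wnLow wavenumber endpoints in cm-1 (grid is uniform here)
#' @param components list of [componentSpec()]s (>= 1)
#' @param scatterMultSd sd of the per-spectrum multiplicative gain
#' @param scatterAddSd sd of the per-spectrum additive offset (AU)
#' @param noiseSd sd of white instrumental noise (AU)
#' @param assayNoiseSd assay noise as a fraction of each reference range
#' @param targetRanges named list of length-2 ranges per analyte
#' @param seed integer RNG seed
#' @return a list of class `syntheticConfig`
#' @export
syntheticConfig <- function(nSamples = 111L, gridPoints = 1557L,
                            wnHigh = 10000, wnLow = 4000,
                            components = defaultComponents(),
                            scatterMultSd = 0.10, scatterAddSd = 0.05,
                            noiseSd = 0.002, assayNoiseSd = 0.05,
                            targetRanges = list(abts = c(7.4, 11.7),
                                                frap = c(14.0, 47.7),
                                                dpph = c(11.4, 30.2)),
                            seed = 1L) {
  if (nSamples < 4) stop("nSamples must be >= 4")
  if (scatterMultSd < 0 || scatterAddSd < 0 || noiseSd < 0 || assayNoiseSd < 0)
    stop("all sd parameters must be >= 0")
  if (!length(components)) stop("at least one component is required")
  grid_nm <- sort(1e7 / seq(wnHigh, wnLow, length.out = gridPoints))
  span <- range(grid_nm)
  for (cmp in components) {
    if (any(cmp$bandCenters < span[1] | cmp$bandCenters > span[2]))
      stop("band centers must lie within the wavelength grid span")
  }
  structure(list(nSamples = as.integer(nSamples), grid = grid_nm,
                 components = components, scatterMultSd = scatterMultSd,
                 scatterAddSd = scatterAddSd, noiseSd = noiseSd,
                 assayNoiseSd = assayNoiseSd, targetRanges = targetRanges,
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

# Gaussian band profile of one component over the grid, per unit concentration
componentProfile <- function(cmp, grid) {
  prof <- numeric(length(grid))
  for (b in seq_along(cmp$bandCenters)) {
    prof <- prof + cmp$bandHeights[b] *
      exp(-(grid - cmp$bandCenters[b])^2 / (2 * cmp$bandWidths[b]^2))
  }
  prof
}

#' Simulate a spectra set with matching reference values
#'
#' Draws per-sample concentrations uniformly per component, builds clean
#' spectra as the concentration-weighted sum of Gaussian band profiles
#' (Beer-Lambert mixing), corrupts each spectrum with a multiplicative gain
#' `(1 + m_i)`, an additive offset `o_i` and white noise, and derives
#' reference values as a linear combination of the concentrations plus assay
#' noise, min-max rescaled into the configured target ranges.  Fully
#' reproducible for a fixed seed.
#'
#' The ground truth reports, per component with any nonzero assay effect,
#' the wavelength indices within +/- 2 band widths of each of its band
#' centers, plus the drawn concentration matrix.
#'
#' @param config a [syntheticConfig()]
#' @return list with elements `spectra` (`SpectraSet`), `references`
#'   (`ReferenceTable`) and `groundTruth` (list: `informativeIndices`,
#'   `componentBands`, `concentrations`, `seed`, `config`)
#' @export
simulateSpectra <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(config$seed)
  n <- config$nSamples
  grid <- config$grid
  p <- length(grid)
  comps <- config$components
  k <- length(comps)

  conc <- vapply(comps, function(cmp) runif(n, cmp$concLow, cmp$concHigh),
                 numeric(n))
  conc <- matrix(conc, nrow = n, ncol = k)
  colnames(conc) <- names(comps)
  profiles <- t(vapply(comps, componentProfile, numeric(p), grid = grid))
  clean <- conc %*% profiles

  gain <- 1 + rnorm(n, 0, config$scatterMultSd)
  offset <- rnorm(n, 0, config$scatterAddSd)
  noise <- if (config$noiseSd > 0)
    matrix(rnorm(n * p, 0, config$noiseSd), n, p) else 0
  X <- clean * gain + offset + noise

  ids <- sprintf("sample_%03d", seq_len(n))
  spectra <- SpectraSet(grid, X, ids)

  effects <- vapply(comps, function(cmp) cmp$effects, numeric(3))
  refs <- list()
  for (assay in c("abts", "frap", "dpph")) {
    z <- as.numeric(conc %*% effects[assay, ])
    zr <- diff(range(z))
    if (config$assayNoiseSd > 0 && zr > 0)
      z <- z + rnorm(n, 0, config$assayNoiseSd * zr)
    tr <- config$targetRanges[[assay]]
    zr <- diff(range(z))
    refs[[assay]] <- if (zr > 0)
      tr[1] + (z - min(z)) / zr * diff(tr) else rep(mean(tr), n)
  }
  references <- ReferenceTable(ids, abts = refs$abts, frap = refs$frap,
                               dpph = refs$dpph)

  componentBands <- lapply(comps, function(cmp) {
    if (all(cmp$effects == 0)) return(NULL)
    lapply(seq_along(cmp$bandCenters), function(b) {
      which(abs(grid - cmp$bandCenters[b]) <= 2 * cmp$bandWidths[b])
    })
  })
  componentBands <- componentBands[!vapply(componentBands, is.null, logical(1))]
  informative <- sort(unique(unlist(componentBands)))

  list(spectra = spectra, references = references,
       groundTruth = list(informativeIndices = informative,
                          componentBands = componentBands,
                          concentrations = conc,
                          seed = config$seed, config = config))
}
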