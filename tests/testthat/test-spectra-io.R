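test_that("spectra CSV round-trips within 1e-12", {
  sim <- simulateSpectra(smallConfig(seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  writeSpectra(sim$spectra, f)
  back <- readSpectra(f)
  expect_equal(wavelengths(back), wavelengths(sim$spectra), tolerance = 1e-12)
  expect_equal(absorbance(back), absorbance(sim$spectra), tolerance = 1e-12)
  expect_identical(sampleIds(back), sampleIds(sim$spectra))
})

test_that("gzip spectra files round-trip transparently", {
  sim <- simulateSpectra(smallConfig(seed = 5))
  f <- withr::local_tempfile(fileext = ".csv.gz")
  writeSpectra(sim$spectra, f)
  back <- readSpectra(f)
  expect_equal(absorbance(back), absorbance(sim$spectra), tolerance = 1e-12)
})

test_that("malformed spectra files raise format errors naming the culprit", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,1100,1200", "a,1,2", "a,3,4"), f)
  expect_error(readSpectra(f), "duplicate sample ID 'a'")
  writeLines(c("sample_id,1100,banana", "a,1,2"), f)
  expect_error(readSpectra(f), "non-numeric wavelength")
  writeLines(c("sample_id,1100,1200", "a,1,oops", "b,3,4"), f)
  expect_error(readSpectra(f), "non-numeric or missing cell")
  writeLines(c("sample_id,1100,1100", "a,1,2"), f)
  expect_error(readSpectra(f), "not strictly monotonic")
})

test_that("a descending axis is re-sorted ascending with a notice", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,1300,1200,1100", "a,3,2,1"), f)
  expect_message(ss <- readSpectra(f), "re-sorted")
  expect_equal(wavelengths(ss), c(1100, 1200, 1300))
  expect_equal(as.numeric(absorbance(ss)), c(1, 2, 3))
})

test_that("reference tables round-trip and tolerate missing analytes", {
  rt <- ReferenceTable(c("s1", "s2", "s3"), abts = c(8, 9, 10),
                       dpph = c(12, 20, 28))
  f <- withr::local_tempfile(fileext = ".csv")
  writeReferences(rt, f)
  back <- readReferences(f)
  expect_identical(sort(analytes(back)), c("abts", "dpph"))
  expect_error(referenceValues(back, "frap"), "absent")
  expect_equal(referenceValues(back), referenceValues(rt), tolerance = 1e-12)
})

test_that("reference join is order-independent", {
  sim <- simulateSpectra(smallConfig(seed = 6))
  refs <- sim$references
  shuffled <- do.call(ReferenceTable, c(
    list(sampleIds = rev(sampleIds(refs))),
    lapply(referenceValues(refs)[rev(seq_along(sampleIds(refs))), ], identity)))
  aligned <- alignReferences(sim$spectra, shuffled)
  expect_equal(referenceValues(aligned, "abts"),
               referenceValues(refs, "abts"))
})

test_that("model serialization reproduces predictions from file alone", {
  sim <- simulateSpectra(smallConfig(seed = 11))
  y <- referenceValues(sim$references, "frap")
  tr <- trainPls(sim$spectra, y, preprocessorSpec("msc"),
                 wavelengthIndices = seq(5, 150, by = 3), maxLvs = 6,
                 folds = 5, analyte = "frap")
  f <- withr::local_tempfile(fileext = ".json")
  saveModel(tr$model, f)
  back <- loadModel(f)
  expect_equal(predict(back, sim$spectra), predict(tr$model, sim$spectra),
               tolerance = 1e-12)
  expect_identical(back@nLvs, tr$model@nLvs)
  expect_identical(back@preprocessor@method, "msc")
  expect_equal(back@preprocessor@mscReference,
               tr$model@preprocessor@mscReference, tolerance = 1e-12)
})

test_that("evaluation reports round-trip through JSON", {
  rep <- new("EvaluationReport", analyte = "abts", model = "Full-PLS",
             r2C = 0.836, rmsec = 0.37, rmsecv = 0.61, slopeC = 0.84,
             r2Rand = 0.042, cr2P = 0.8147, r2P = 0.649, rmsep = 0.57,
             slopeP = 0.68, r2m = 0.641, nCal = 75L, nPred = 36L,
             nLvs = 15L, nVariables = 1557L,
             gates = c(r2m = TRUE, cr2p = TRUE))
  f <- withr::local_tempfile(fileext = ".json")
  writeReport(rep, f)
  back <- readReport(f)
  for (s in c("r2C", "rmsec", "rmsecv", "slopeC", "r2Rand", "cr2P", "r2P",
              "rmsep", "slopeP", "r2m"))
    expect_equal(slot(back, s), slot(rep, s), tolerance = 1e-12)
  expect_identical(back@nCal, rep@nCal)
  expect_identical(back@gates, rep@gates)
})

test_that("ground truth sidecar is valid JSON with the expected fields", {
  sim <- simulateSpectra(smallConfig(seed = 3))
  f <- withr::local_tempfile(fileext = ".json")
  writeGroundTruth(sim$groundTruth, f)
  obj <- jsonlite::fromJSON(f)
  expect_identical(obj$format, "nirpls-ground-truth")
  expect_equal(obj$seed, 3)
  expect_equal(sort(obj$informativeIndices),
               sim$groundTruth$informativeIndices)
  expect_equal(obj$config$nSamples, 40)
})
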