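test_that("binVisits aggregates by category rule: mean labs, max flags, summed counts", {
    feats <- toyFeatures()
    vals <- rbind(c(4.0, 0, 2), c(6.0, 1, 3), c(NA, NA, NA))
    colnames(vals) <- feats$name
    rec <- toyRecord(times = c(1.5, 4.0, 8.0), values = vals)
    s <- binVisits(rec, feats)
    expect_equal(unname(s@values[1, "lab_a"]), 5.0)   # mean of 4 and 6
    expect_equal(unname(s@values[1, "flag_b"]), 1)    # 0 then 1 -> present
    expect_equal(unname(s@values[1, "count_c"]), 5)   # 2 + 3
    expect_true(is.na(s@values[2, "lab_a"]))      # visit all-missing
    expect_false(s@observedMask[2, "lab_a"])
})

test_that("binVisits mean aggregation is permutation-invariant and bounded by bins", {
    feats <- toyFeatures()
    vals <- rbind(c(1, 1, 0), c(5, 0, 1), c(3, 0, 2))
    colnames(vals) <- feats$name
    recA <- toyRecord(times = c(0.5, 2.5, 4.5), values = vals)
    recB <- toyRecord(times = c(0.5, 2.5, 4.5), values = vals[c(3, 1, 2), ])
    expect_equal(binVisits(recA, feats)@values, binVisits(recB, feats)@values)
    expect_lte(sum(!is.na(binVisits(recA, feats)@values[, "lab_a"])), 2)
})

test_that("visits outside the patient timeline are rejected", {
    feats <- toyFeatures()
    vals <- matrix(1, 1, 3, dimnames = list(NULL, feats$name))
    # at record construction
    expect_error(toyRecord(12.5, vals, nObsBins = 2), "visit times")
    # and at binning onto a shorter grid
    rec <- toyRecord(8.0, vals, nObsBins = 2)
    expect_error(binVisits(rec, feats, nBins = 1), "timeline")
})

test_that("imputeSeries interpolates interior gaps and extrapolates edges", {
    feats <- data.frame(name = "lab_a", category = "lab",
                        type = "continuous", stringsAsFactors = FALSE)
    s <- toySeries(matrix(c(1.0, NA, 3.0), 3, 1,
                          dimnames = list(NULL, "lab_a")))
    out <- imputeSeries(s, feats)
    expect_equal(unname(out@values[2, 1]), 2.0)   # midpoint
    # single observed value: constant everywhere
    s1 <- toySeries(matrix(c(NA, 4.0, NA), 3, 1,
                           dimnames = list(NULL, "lab_a")))
    expect_equal(imputeSeries(s1, feats)@values[, 1], rep(4.0, 3))
    # fully observed series returned unchanged
    s2 <- toySeries(matrix(c(1, 2, 5), 3, 1, dimnames = list(NULL, "lab_a")))
    expect_equal(imputeSeries(s2, feats)@values, s2@values)
})

test_that("imputation is idempotent and exact on collinear observations", {
    feats <- data.frame(name = "lab_a", category = "lab",
                        type = "continuous", stringsAsFactors = FALSE)
    # observed points on the line v = 2b + 1, bins 2 and 5 observed
    v <- rep(NA_real_, 6); v[c(2, 5)] <- 2 * c(2, 5) + 1
    s <- toySeries(matrix(v, 6, 1, dimnames = list(NULL, "lab_a")))
    once <- imputeSeries(s, feats)
    expect_equal(once@values[, 1], 2 * (1:6) + 1, tolerance = 1e-9)
    twice <- imputeSeries(once, feats)
    expect_equal(twice@values, once@values)
    # observed cells untouched even when off the least-squares line
    v2 <- c(10, NA, 1, NA, 1, NA)
    s2 <- toySeries(matrix(v2, 6, 1, dimnames = list(NULL, "lab_a")))
    out2 <- imputeSeries(s2, feats)
    expect_equal(out2@values[c(1, 3, 5), 1], c(10, 1, 1))
})

test_that("binary features are clipped to [0, 1] after imputation", {
    feats <- data.frame(name = "flag_b", category = "manifestation",
                        type = "binary", stringsAsFactors = FALSE)
    v <- c(0, 1, NA, NA)  # extrapolated trailing values would exceed 1
    s <- toySeries(matrix(v, 4, 1, dimnames = list(NULL, "flag_b")))
    out <- imputeSeries(s, feats)
    expect_true(all(out@values >= 0 & out@values <= 1))
})

test_that("a never-observed feature falls back to the cohort mean with a warning", {
    feats <- data.frame(name = "lab_a", category = "lab",
                        type = "continuous", stringsAsFactors = FALSE)
    s <- toySeries(matrix(NA_real_, 3, 1, dimnames = list(NULL, "lab_a")))
    expect_warning(out <- imputeSeries(s, feats,
                                       cohortMeans = c(lab_a = 2.5)),
                   "never observed")
    expect_equal(out@values[, 1], rep(2.5, 3))
})

test_that("binCohort produces fully imputed series in both processing orders", {
    for (ord in c("bin_first", "impute_first")) {
        bc <- suppressWarnings(binCohort(generateCohort(tinyConfig()),
                                         order = ord))
        expect_true(bc@imputed)
        for (s in bc@series) {
            expect_false(anyNA(s@values))
            expect_equal(nrow(s@values), 6)
        }
    }
})

test_that("a binned cohort round-trips through wide CSV with its mask", {
    bc <- tinyBinned()
    dir <- withr::local_tempdir()
    writeBinnedCohort(bc, dir)
    back <- readBinnedCohort(dir)
    expect_equal(length(back@series), length(bc@series))
    i <- 3
    expect_equal(back@series[[i]]@values, bc@series[[i]]@values)
    expect_equal(back@series[[i]]@observedMask, bc@series[[i]]@observedMask)
    expect_equal(back@series[[i]]@events, bc@series[[i]]@events)
    expect_true(back@imputed)
})
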