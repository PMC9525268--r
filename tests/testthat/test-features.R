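test_that("the full Differential layout has 5 + 52k + 52(k-1) columns", {
    bc <- tinyBinned()
    wd <- extractWindows(bc, taskSpec(24, 12))  # k = 4
    dm <- buildDifferential(wd)
    expect_equal(ncol(dm@values), 5 + 52 * 4 + 52 * 3)  # 369
    expect_equal(nrow(dm@schema), ncol(dm@values))
    tagCounts <- table(dm@schema$tag)
    expect_equal(as.integer(tagCounts[c("demographic", "raw", "delta")]),
                 c(5L, 208L, 156L))
    # compact layout: first-step raw + deltas only
    dmC <- buildDifferential(wd, layout = "compact")
    expect_equal(ncol(dmC@values), 5 + 52 + 52 * 3)
})

test_that("delta columns are exact step differences", {
    seqA <- matrix(c(2, 5, 1, 1), 2, 2,
                   dimnames = list(NULL, c("f01", "f02")))
    seqB <- matrix(c(3, 3, 0, 4), 2, 2,
                   dimnames = list(NULL, c("f01", "f02")))
    wd <- toyWindowed(list(seqA, seqB), labels = c(1, 0), yMonths = 6)
    dm <- buildDifferential(wd)
    expect_equal(unname(dm@values[, "f01_d1"]), c(3, 0))   # 5-2, 3-3
    expect_equal(unname(dm@values[, "f02_d1"]), c(0, 4))
    # constant sequence has all-zero deltas
    wdc <- toyWindowed(list(matrix(2, 3, 2,
                                   dimnames = list(NULL, c("f01", "f02")))),
                       labels = 0)
    dmc <- buildDifferential(wdc)
    expect_true(all(dmc@values[, dmc@schema$tag == "delta"] == 0))
    # k = 1 has no delta columns
    wd1 <- toyWindowed(list(matrix(1, 1, 2,
                                   dimnames = list(NULL, c("f01", "f02")))),
                       labels = 0)
    expect_false("delta" %in% buildDifferential(wd1)@schema$tag)
})

test_that("raw@0 plus the summed deltas reconstructs raw@last for every row", {
    bc <- tinyBinned()
    wd <- extractWindows(bc, taskSpec(18, 6))
    dm <- buildDifferential(wd)
    sch <- dm@schema
    for (f in featureInfo(wd)$name[c(1, 20, 52)]) {
        first <- dm@values[, sch$tag == "raw" & sch$feature == f &
                             sch$step == 0]
        last <- dm@values[, sch$tag == "raw" & sch$feature == f &
                            sch$step == dm@k - 1]
        deltas <- dm@values[, sch$tag == "delta" & sch$feature == f,
                            drop = FALSE]
        expect_equal(first + rowSums(deltas), last, tolerance = 1e-12)
    }
})

test_that("the LSTM tensor carries clinical steps plus repeated demographics", {
    bc <- tinyBinned()
    wd <- extractWindows(bc, taskSpec(24, 12))
    st <- buildLstmTensor(wd)
    expect_equal(dim(st@values), c(nInstances(wd), 4, 57))
    # clinical block equals the window sequence exactly
    expect_equal(st@values[, , 1:52], wd@sequences)
    # demographics identical at every step
    for (t in 2:4)
        expect_equal(st@values[, t, 53:57], st@values[, 1, 53:57])
    expect_equal(unname(st@values[3, 1, 53:57]),
                 unname(wd@demographics[3, ]))
})

test_that("standardization z-scores continuous columns and passes binaries through", {
    x <- cbind(cont = c(1, 2, 3), bin = c(0, 1, 1), flat = c(4, 4, 4))
    sc <- fitScaler(x)
    out <- applyScaler(sc, x)
    expect_equal(unname(out[, "cont"]), c(-1, 0, 1))
    expect_equal(unname(out[, "bin"]), c(0, 1, 1))      # untouched
    expect_equal(unname(out[, "flat"]), c(0, 0, 0))     # centered, scale 1
    # train-fitted transform applied to identical data is identical
    expect_equal(applyScaler(sc, x), out)
    # population z-scores at sample-sd scaling: sd(1,2,3) = 1
    expect_equal(unname(out[, "cont"]) * stats::sd(c(1, 2, 3)),
                 c(1, 2, 3) - 2)
})

test_that("tensor standardization pools statistics over instances and steps", {
    arr <- array(0, dim = c(2, 2, 2))
    arr[, , 1] <- matrix(c(1, 3, 2, 4), 2)   # values 1..4
    arr[, , 2] <- 4                          # constant feature
    st <- new("SequenceTensor", values = arr, labels = c(0L, 1L))
    out <- applyScaler(fitScaler(st), st)
    flat <- as.vector(out@values[, , 1])
    expect_equal(mean(flat), 0)
    expect_equal(out@values[, , 2], arr[, , 2] - 4)  # zero-variance: centered
})

test_that("a design matrix round-trips through CSV with schema order preserved", {
    bc <- tinyBinned()
    wd <- extractWindows(bc, taskSpec(12, 6))
    dm <- buildDifferential(wd)
    path <- file.path(withr::local_tempdir(), "dm.csv")
    writeDesignMatrix(dm, path)
    back <- readDesignMatrix(path)
    expect_equal(back@schema$name, dm@schema$name)
    expect_equal(back@schema$tag, dm@schema$tag)
    expect_equal(back@values, dm@values)
    expect_equal(back@labels, dm@labels)
    expect_equal(back@k, dm@k)
})
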