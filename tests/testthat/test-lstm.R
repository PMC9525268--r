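zeroParams <- function(h, d) {
    p <- lstmInit(d, h, seed = 1)
    for (nm in c("Wi", "Wf", "Wo", "Wc")) p[[nm]][] <- 0
    for (nm in c("bi", "bf", "bo", "bc")) p[[nm]][] <- 0
    p$wOut[] <- 0; p$bOut <- 0
    p
}

test_that("the zero-weight cell reduces to its closed form", {
    p <- zeroParams(h = 3, d = 4)
    cPrev <- c(0.5, -1, 2)
    out <- lstmCell(p, x = rnorm(4), hPrev = rnorm(3), cPrev = cPrev)
    expect_equal(out$i, rep(0.5, 3))
    expect_equal(out$f, rep(0.5, 3))
    expect_equal(out$o, rep(0.5, 3))
    expect_equal(out$cTilde, rep(0, 3))
    expect_equal(out$C, 0.5 * cPrev)
    expect_equal(out$h, 0.5 * tanh(0.5 * cPrev))
})

test_that("the unit-weight scalar cell at zero input is fully quiescent", {
    p <- zeroParams(h = 1, d = 1)
    p$Wi[] <- 1; p$Wf[] <- 1; p$Wo[] <- 1; p$Wc[] <- 1
    out <- lstmCell(p, x = 0, hPrev = 0, cPrev = 0)
    expect_equal(out$i, 0.5)
    expect_equal(out$f, 0.5)
    expect_equal(out$o, 0.5)
    expect_equal(out$C, 0)
    expect_equal(out$h, 0)
})

test_that("the hidden-size-1 cell matches an independent scalar evaluation", {
    set.seed(42)
    for (trial in 1:12) {
        w <- lapply(1:4, function(i) rnorm(2, sd = 0.8))
        b <- rnorm(4, sd = 0.5)
        x <- rnorm(1); hPrev <- rnorm(1, sd = 0.5); cPrev <- rnorm(1)
        p <- zeroParams(1, 1)
        p$Wi[] <- w[[1]]; p$Wf[] <- w[[2]]; p$Wo[] <- w[[3]]; p$Wc[] <- w[[4]]
        p$bi <- b[1]; p$bf <- b[2]; p$bo <- b[3]; p$bc <- b[4]
        got <- lstmCell(p, x, hPrev, cPrev)
        want <- scalarLstmOracle(w[[1]], b[1], w[[2]], b[2], w[[3]], b[3],
                                 w[[4]], b[4], x, hPrev, cPrev)
        expect_equal(got$h, want$h, tolerance = 1e-10)
        expect_equal(got$C, want$C, tolerance = 1e-10)
    }
})

test_that("gates stay strictly inside (0, 1) for extreme finite inputs", {
    p <- lstmInit(2, 3, seed = 2)
    out <- lstmCell(p, x = c(50, -50), hPrev = c(1, -1, 0.5),
                    cPrev = c(10, -10, 0))
    for (g in list(out$i, out$f, out$o))
        expect_true(all(g > 0 & g < 1))
    expect_true(all(out$h > -1 & out$h < 1))
    expect_error(lstmCell(p, x = c(1, 2, 3), hPrev = rep(0, 3),
                          cPrev = rep(0, 3)), "shape")
})

test_that("the forward pass chains cells and maps the last state to a probability", {
    # all-zero weights: logit 0, probability 1/2 for any sequence
    p <- zeroParams(2, 3)
    expect_equal(lstmForward(p, matrix(rnorm(12), 4, 3)), 0.5)
    # k = 1 equals a single cell step through the output layer
    p2 <- lstmInit(3, 2, seed = 5)
    x <- rnorm(3)
    cell <- lstmCell(p2, x, rep(0, 2), rep(0, 2))
    expect_equal(lstmForward(p2, matrix(x, 1)),
                 plogis(sum(p2$wOut * cell$h) + p2$bOut))
    # k = 2 scalar network equals two chained scalar-oracle evaluations
    p1 <- zeroParams(1, 1)
    p1$Wi[] <- c(0.3, 0.7); p1$Wf[] <- c(-0.2, 0.4)
    p1$Wo[] <- c(0.5, -0.6); p1$Wc[] <- c(0.1, 0.9)
    p1$bi <- 0.1; p1$bf <- -0.3; p1$bo <- 0.2; p1$bc <- 0
    p1$wOut <- 1.5; p1$bOut <- -0.4
    xs <- c(0.8, -1.1)
    s1 <- scalarLstmOracle(c(0.3, 0.7), 0.1, c(-0.2, 0.4), -0.3,
                           c(0.5, -0.6), 0.2, c(0.1, 0.9), 0,
                           xs[1], 0, 0)
    s2 <- scalarLstmOracle(c(0.3, 0.7), 0.1, c(-0.2, 0.4), -0.3,
                           c(0.5, -0.6), 0.2, c(0.1, 0.9), 0,
                           xs[2], s1$h, s1$C)
    expect_equal(lstmForward(p1, matrix(xs, 2, 1)),
                 plogis(1.5 * s2$h - 0.4), tolerance = 1e-10)
    expect_error(lstmForward(p1, matrix(numeric(), 0, 1)), "at least one")
})

test_that("analytic gradients match finite differences", {
    set.seed(11)
    n <- 4; k <- 3; d <- 2; h <- 2
    X <- array(rnorm(n * k * d), dim = c(n, k, d))
    y <- c(0, 1, 1, 0)
    params <- lstmInit(d, h, seed = 3)
    gr <- slehorizon:::lstmGradients(params, X, y)
    eps <- 1e-6
    for (nm in c("Wi", "Wf", "Wc", "bo", "wOut", "bOut")) {
        target <- params[[nm]]
        for (idx in seq_len(min(length(target), 4))) {
            up <- params; up[[nm]][idx] <- up[[nm]][idx] + eps
            dn <- params; dn[[nm]][idx] <- dn[[nm]][idx] - eps
            num <- (slehorizon:::lstmGradients(up, X, y)$loss -
                    slehorizon:::lstmGradients(dn, X, y)$loss) / (2 * eps)
            expect_equal(gr$grads[[nm]][idx], num, tolerance = 1e-5)
        }
    }
})

test_that("batched prediction agrees with the single-sequence forward pass", {
    set.seed(6)
    p <- lstmInit(4, 3, seed = 9)
    X <- array(rnorm(5 * 2 * 4), dim = c(5, 2, 4))
    model <- structure(list(params = p, hiddenSize = 3,
                            config = trainConfig(epochs = 1)),
                       class = "lstmModel")
    batch <- predictLstm(model, X)
    single <- vapply(1:5, function(i) lstmForward(p, X[i, , ]), numeric(1))
    expect_equal(batch, single, tolerance = 1e-12)
})

test_that("training separates a learnable toy task and is seed-deterministic", {
    wd <- separableWindowed(n = 120, k = 3, p = 2, seed = 21)
    st <- buildLstmTensor(wd)
    trainIdx <- seq(1, 120, by = 2)
    testIdx <- setdiff(1:120, trainIdx)
    cfg <- trainConfig(epochs = 40, batchSize = 16, learningRate = 0.05,
                       seed = 2)
    fit <- trainLstm(slehorizon:::tensorSubset(st, trainIdx), cfg,
                     hiddenSize = 4)
    # training loss decreases over the run
    expect_lt(fit$losses[length(fit$losses)], fit$losses[1])
    pred <- predictLstm(fit, slehorizon:::tensorSubset(st, testIdx))
    acc <- mean((pred >= 0.5) == (instanceLabels(st)[testIdx] == 1))
    expect_gte(acc, 0.95)
    # identical seed and data reproduce identical parameters
    fit2 <- trainLstm(slehorizon:::tensorSubset(st, trainIdx), cfg,
                      hiddenSize = 4)
    expect_identical(fit$params, fit2$params)
})

test_that("shuffled labels yield chance-level held-out AUC", {
    set.seed(33)
    n <- 600
    labels <- sample(rep(0:1, n / 2))
    seqs <- lapply(seq_len(n), function(i)
        matrix(rnorm(2 * 3), 2, 3,
               dimnames = list(NULL, c("f01", "f02", "f03"))))
    st <- buildLstmTensor(toyWindowed(seqs, labels, yMonths = 6))
    trainIdx <- 1:400
    fit <- trainLstm(slehorizon:::tensorSubset(st, trainIdx),
                     trainConfig(epochs = 10, batchSize = 40,
                                 learningRate = 0.01, seed = 4),
                     hiddenSize = 4)
    auc <- aucRank(labels[401:600],
                   predictLstm(fit, slehorizon:::tensorSubset(st, 401:600)))
    expect_gte(auc, 0.4)
    expect_lte(auc, 0.6)
})
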