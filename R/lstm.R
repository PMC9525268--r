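#' LSTM training configuration
#'
#' Defaults follow the study's training regime: 50 epochs, mini-batches
#' of 72 sequences, Adam with learning rate 0.0001, minimizing binary
#' cross-entropy between the final-step output and the class labels.
#'
#' @param epochs number of passes over the training data.
#' @param batchSize mini-batch size.
#' @param learningRate Adam step size.
#' @param seed RNG seed for weight initialization and batch shuffling.
#' @return a list of class `"lstmTrainConfig"`.
#' @export
trainConfig <- function(epochs = 50, batchSize = 72,
                        learningRate = 1e-4, seed = 1) {
    stopifnot(epochs >= 1, batchSize >= 1, learningRate > 0)
    structure(list(epochs = epochs, batchSize = batchSize,
                   learningRate = learningRate, seed = seed),
              class = "lstmTrainConfig")
}

#' Initialize LSTM parameters
#'
#' Gate weight matrices `Wi`, `Wf`, `Wo`, `Wc` are `hiddenSize x
#' (hiddenSize + inputSize)` and act on the concatenation
#' `[h_(t-1), x_t]`; biases are zero except the forget-gate bias,
#' initialized at 1 so early training retains cell state. The output
#' layer is an affine map from the last hidden state to a single
#' logit. Weights are drawn uniformly in
#' `±1/sqrt(hiddenSize + inputSize)`.
#'
#' @param inputSize per-step input dimension (57 for the default
#'   52-clinical + 5-demographic panel).
#' @param hiddenSize number of hidden units.
#' @param seed RNG seed.
#' @return a list of class `"lstmParams"`.
#' @export
lstmInit <- function(inputSize, hiddenSize, seed = 1) {
    withSeed(seed, {
        s <- 1 / sqrt(hiddenSize + inputSize)
        mat <- function() matrix(stats::runif(hiddenSize *
                                              (hiddenSize + inputSize),
                                              -s, s),
                                 hiddenSize, hiddenSize + inputSize)
        structure(list(
            Wi = mat(), Wf = mat(), Wo = mat(), Wc = mat(),
            bi = numeric(hiddenSize), bf = rep(1, hiddenSize),
            bo = numeric(hiddenSize), bc = numeric(hiddenSize),
            wOut = stats::runif(hiddenSize, -s, s), bOut = 0,
            hiddenSize = hiddenSize, inputSize = inputSize),
            class = "lstmParams")
    })
}

#' One LSTM cell step
#'
#' Exact composition of the gate equations on the concatenated input
#' `z = [hPrev, x]`:
#' \deqn{i = \sigma(W_i z + b_i),\quad f = \sigma(W_f z + b_f),\quad
#'       o = \sigma(W_o z + b_o),}
#' \deqn{\tilde C = \tanh(W_c z + b_c),\quad
#'       C = f \circ C_{prev} + i \circ \tilde C,\quad
#'       h = o \circ \tanh(C),}
#' with \eqn{\circ} the elementwise product. All gates lie strictly in
#' (0, 1) and `h` in (-1, 1) for finite inputs.
#'
#' @param params an `"lstmParams"` list from [lstmInit()].
#' @param x input vector of length `inputSize`.
#' @param hPrev,cPrev previous hidden and cell state
#'   (length `hiddenSize`).
#' @return list with elements `h`, `C`, and the gate activations `i`,
#'   `f`, `o`, `cTilde`.
#' @export
lstmCell <- function(params, x, hPrev, cPrev) {
    h <- params$hiddenSize
    if (length(x) != params$inputSize || length(hPrev) != h ||
        length(cPrev) != h)
        stop("shape mismatch in lstmCell inputs")
    z <- c(hPrev, x)
    i <- sigmoid(drop(params$Wi %*% z) + params$bi)
    f <- sigmoid(drop(params$Wf %*% z) + params$bf)
    o <- sigmoid(drop(params$Wo %*% z) + params$bo)
    cTilde <- tanh(drop(params$Wc %*% z) + params$bc)
    C <- f * cPrev + i * cTilde
    list(h = o * tanh(C), C = C, i = i, f = f, o = o, cTilde = cTilde)
}

#' Forward pass over a full sequence
#'
#' Applies [lstmCell()] across the `k` steps of one sequence (the same
#' weights at every step), starting from zero hidden and cell states,
#' and maps the final hidden state through the affine output layer and
#' a logistic to a class-1 probability.
#'
#' @param params an `"lstmParams"` list.
#' @param sequence `k x inputSize` numeric matrix (rows are steps).
#' @return class-1 probability in (0, 1).
#' @export
lstmForward <- function(params, sequence) {
    sequence <- rbind(sequence)
    if (nrow(sequence) == 0) stop("sequence must have at least one step")
    h <- numeric(params$hiddenSize)
    C <- numeric(params$hiddenSize)
    for (t in seq_len(nrow(sequence))) {
        step <- lstmCell(params, sequence[t, ], h, C)
        h <- step$h
        C <- step$C
    }
    sigmoid(sum(params$wOut * h) + params$bOut)
}

# Batched forward over an n x k x d array; returns probabilities plus
# the per-step caches needed for backpropagation through time.
lstmForwardBatch <- function(params, X) {
    n <- dim(X)[1]; k <- dim(X)[2]; h <- params$hiddenSize
    H <- matrix(0, n, h); C <- matrix(0, n, h)
    cache <- vector("list", k)
    for (t in seq_len(k)) {
        Xt <- matrix(X[, t, ], n)
        Z <- cbind(H, Xt)
        I <- sigmoid(Z %*% t(params$Wi) + rep(params$bi, each = n))
        Fg <- sigmoid(Z %*% t(params$Wf) + rep(params$bf, each = n))
        O <- sigmoid(Z %*% t(params$Wo) + rep(params$bo, each = n))
        G <- tanh(Z %*% t(params$Wc) + rep(params$bc, each = n))
        Cnew <- Fg * C + I * G
        Hc <- tanh(Cnew)
        cache[[t]] <- list(Z = Z, I = I, Fg = Fg, O = O, G = G,
                           Cprev = C, Cnew = Cnew, Hc = Hc)
        C <- Cnew
        H <- O * Hc
    }
    logits <- drop(H %*% params$wOut) + params$bOut
    list(prob = sigmoid(logits), H = H, cache = cache)
}

# Mean binary cross-entropy loss and its gradients w.r.t. every
# parameter, by backpropagation through time.
lstmGradients <- function(params, X, y) {
    n <- dim(X)[1]; k <- dim(X)[2]; h <- params$hiddenSize
    fwd <- lstmForwardBatch(params, X)
    p <- pmin(pmax(fwd$prob, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
    dlogit <- (fwd$prob - y) / n
    g <- list(Wi = 0 * params$Wi, Wf = 0 * params$Wf, Wo = 0 * params$Wo,
              Wc = 0 * params$Wc, bi = 0 * params$bi, bf = 0 * params$bf,
              bo = 0 * params$bo, bc = 0 * params$bc,
              wOut = drop(t(fwd$H) %*% dlogit), bOut = sum(dlogit))
    dH <- outer(dlogit, params$wOut)
    dC <- matrix(0, n, h)
    for (t in rev(seq_len(k))) {
        cc <- cache <- fwd$cache[[t]]
        dO <- dH * cc$Hc
        dC <- dC + dH * cc$O * (1 - cc$Hc^2)
        dF <- dC * cc$Cprev
        dI <- dC * cc$G
        dG <- dC * cc$I
        dCprev <- dC * cc$Fg
        ai <- dI * cc$I * (1 - cc$I)
        af <- dF * cc$Fg * (1 - cc$Fg)
        ao <- dO * cc$O * (1 - cc$O)
        ag <- dG * (1 - cc$G^2)
        g$Wi <- g$Wi + t(ai) %*% cc$Z
        g$Wf <- g$Wf + t(af) %*% cc$Z
        g$Wo <- g$Wo + t(ao) %*% cc$Z
        g$Wc <- g$Wc + t(ag) %*% cc$Z
        g$bi <- g$bi + colSums(ai)
        g$bf <- g$bf + colSums(af)
        g$bo <- g$bo + colSums(ao)
        g$bc <- g$bc + colSums(ag)
        dZ <- ai %*% params$Wi + af %*% params$Wf + ao %*% params$Wo +
              ag %*% params$Wc
        dH <- dZ[, seq_len(h), drop = FALSE]
        dC <- dCprev
    }
    list(loss = loss, grads = g)
}

#' Train the LSTM sequence classifier
#'
#' Mini-batch gradient training of the single-layer LSTM with an
#' affine+logistic output at the last step, minimizing binary
#' cross-entropy with Adam. The caller is responsible for class
#' rebalancing (see [oversampleIndices()]): pass the already
#' rebalanced tensor. Training is reproducible given the config seed.
#'
#' @param tensor a [SequenceTensor-class] (rebalanced training data).
#' @param config a [trainConfig()] list.
#' @param hiddenSize number of hidden units (default 32).
#' @return a list of class `"lstmModel"`: `params`, `config`,
#'   `hiddenSize` and per-epoch mean training `losses`.
#' @export
trainLstm <- function(tensor, config = trainConfig(), hiddenSize = 32) {
    stopifnot(is(tensor, "SequenceTensor"))
    X <- tensor@values
    y <- tensor@labels
    n <- dim(X)[1]
    params <- lstmInit(dim(X)[3], hiddenSize, seed = config$seed)
    state <- NULL
    losses <- numeric(config$epochs)
    withSeed(config$seed + 1, {
        for (epoch in seq_len(config$epochs)) {
            idx <- sample(n)
            batchLoss <- c()
            for (b in seq(1, n, by = config$batchSize)) {
                take <- idx[b:min(b + config$batchSize - 1, n)]
                gr <- lstmGradients(params,
                                    X[take, , , drop = FALSE], y[take])
                if (!is.finite(gr$loss))
                    stop("non-finite training loss; lower the learning rate")
                upd <- adamUpdate(params, gr$grads, state,
                                  config$learningRate)
                params <- upd$params
                state <- upd$state
                batchLoss <- c(batchLoss, gr$loss)
            }
            losses[epoch] <- mean(batchLoss)
        }
    })
    structure(list(params = params, config = config,
                   hiddenSize = hiddenSize, losses = losses),
              class = "lstmModel")
}

# One Adam step over every parameter tensor.
adamUpdate <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    keys <- names(grads)
    if (is.null(state))
        state <- list(t = 0,
                      m = lapply(grads, function(x) 0 * x),
                      v = lapply(grads, function(x) 0 * x))
    state$t <- state$t + 1
    for (key in keys) {
        state$m[[key]] <- beta1 * state$m[[key]] + (1 - beta1) * grads[[key]]
        state$v[[key]] <- beta2 * state$v[[key]] +
            (1 - beta2) * grads[[key]]^2
        mHat <- state$m[[key]] / (1 - beta1^state$t)
        vHat <- state$v[[key]] / (1 - beta2^state$t)
        params[[key]] <- params[[key]] - lr * mHat / (sqrt(vHat) + eps)
    }
    list(params = params, state = state)
}

#' Predict with a trained LSTM
#'
#' @param model an `"lstmModel"` from [trainLstm()].
#' @param tensor a [SequenceTensor-class] or bare `n x k x d` array.
#' @return numeric vector of class-1 probabilities.
#' @export
predictLstm <- function(model, tensor) {
    X <- if (is(tensor, "SequenceTensor")) tensor@values else tensor
    if (dim(X)[3] != model$params$inputSize)
        stop("input feature dimension does not match the fitted model")
    lstmForwardBatch(model$params, X)$prob
}

#' @export
print.lstmModel <- function(x, ...) {
    cat(sprintf(
        "LSTM classifier: %d hidden units, input size %d\n",
        x$hiddenSize, x$params$inputSize))
    cat(sprintf("  trained %d epochs (batch %d, lr %g); loss %.4f -> %.4f\n",
                x$config$epochs, x$config$batchSize, x$config$learningRate,
                x$losses[1], x$losses[length(x$losses)]))
    invisible(x)
}
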