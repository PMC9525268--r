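#' Specify the six-learner voting ensemble
#'
#' The Differential classifier is a majority-voting ensemble of six
#' non-temporal base learners: decision tree (`"tree"`), random forest
#' (`"forest"`), logistic regression (`"logistic"`, ridge-penalized),
#' naive Bayes (`"nbayes"`), a one-hidden-layer feed-forward neural
#' network (`"nnet"`), and an RBF support-vector machine (`"svm"`)
#' with probability outputs. With soft voting (the default) a bag's
#' score is the mean of the learners' class-1 probabilities, which
#' keeps the aggregated score continuous for AUC; hard voting uses the
#' fraction of learners predicting class 1. Scale-sensitive learners
#' (logistic, nnet, svm) receive standardized features; tree, forest
#' and naive Bayes see the raw panel.
#'
#' @param learners subset of the six family names (default all six).
#' @param params named list of per-family hyperparameters; missing
#'   entries fall back to [defaultEnsembleParams()].
#' @param voting `"soft"` or `"hard"`.
#' @param seed RNG seed for the stochastic learners.
#' @return an [EnsembleSpec-class].
#' @export
ensembleSpec <- function(learners = c("tree", "forest", "logistic",
                                      "nbayes", "nnet", "svm"),
                         params = list(), voting = c("soft", "hard"),
                         seed = 1) {
    voting <- match.arg(voting)
    defaults <- defaultEnsembleParams()
    for (nm in names(params))
        defaults[[nm]] <- utils::modifyList(defaults[[nm]], params[[nm]])
    new("EnsembleSpec", learners = learners, params = defaults,
        voting = voting, seed = seed)
}

#' Default hyperparameters and search grid of the base learners
#'
#' `defaultEnsembleParams()` gives one setting per family;
#' `defaultEnsembleGrid()` the small per-family grid searched by the
#' inner cross-validation loop: tree depth \{3, 5, 10\}; forest (100
#' trees) with node-depth limit \{5, unlimited\}; ridge-logistic
#' penalty \{0.1, 1, 10\}; naive Bayes (no grid); network hidden units
#' \{16, 64\}; SVM cost \{0.1, 1, 10\}.
#'
#' @return a named list (params) or a named list of value vectors
#'   (grid).
#' @export
defaultEnsembleParams <- function() {
    list(tree = list(maxdepth = 5),
         forest = list(ntree = 100, maxnodes = NULL),
         logistic = list(lambda = 0.1),
         nbayes = list(),
         nnet = list(size = 16, decay = 0.1, maxit = 150),
         svm = list(cost = 1))
}

#' @rdname defaultEnsembleParams
#' @export
defaultEnsembleGrid <- function() {
    list(tree = list(maxdepth = c(3, 5, 10)),
         forest = list(maxnodes = list(32, NULL)),
         logistic = list(lambda = c(0.1, 1, 10)),
         nnet = list(size = c(16, 64)),
         svm = list(cost = c(0.1, 1, 10)))
}

# Fit one base learner on (x, y); y is a 0/1 integer vector.
fitLearner <- function(family, x, y, params) {
    yf <- factor(y, levels = c(0, 1), labels = c("neg", "pos"))
    switch(family,
        tree = {
            df <- data.frame(x, check.names = FALSE)
            df$.y <- yf
            rpart::rpart(.y ~ ., data = df, method = "class",
                         control = rpart::rpart.control(
                             maxdepth = params$maxdepth, cp = 0.001))
        },
        forest = {
            args <- list(x = x, y = yf, ntree = params$ntree)
            if (!is.null(params$maxnodes)) args$maxnodes <- params$maxnodes
            do.call(randomForest::randomForest, args)
        },
        logistic = glmnet::glmnet(x, yf, family = "binomial", alpha = 0,
                                  lambda = params$lambda,
                                  standardize = FALSE),
        nbayes = e1071::naiveBayes(x = data.frame(x, check.names = FALSE),
                                   y = yf),
        nnet = nnet::nnet(x, matrix(y, ncol = 1), size = params$size,
                          decay = params$decay, maxit = params$maxit,
                          entropy = TRUE, trace = FALSE,
                          MaxNWts = 1e6),
        svm = e1071::svm(x, yf, kernel = "radial", cost = params$cost,
                         probability = TRUE, scale = FALSE),
        stop("unknown learner family: ", family))
}

# Class-1 probability of a fitted base learner on new rows.
predictLearner <- function(family, fit, x) {
    switch(family,
        tree = stats::predict(fit, data.frame(x, check.names = FALSE),
                              type = "prob")[, "pos"],
        forest = stats::predict(fit, x, type = "prob")[, "pos"],
        logistic = as.numeric(stats::predict(fit, x, type = "response")),
        nbayes = stats::predict(fit, data.frame(x, check.names = FALSE),
                                type = "raw")[, "pos"],
        nnet = as.numeric(stats::predict(fit, x)),
        svm = {
            pr <- stats::predict(fit, x, probability = TRUE)
            attr(pr, "probabilities")[, "pos"]
        })
}

#' Fit the bagged voting ensemble
#'
#' Fits one six-learner ensemble per balanced bag: for every bag in
#' `bags`, each base-learner family is trained on the bag's rows, and
#' the bag's score for an instance is the (soft) mean of the learners'
#' class-1 probabilities or the (hard) fraction of learners voting
#' class 1. Prediction averages the bag scores over all bags
#' ([predictBagged()]). The scaler for scale-sensitive learners is fit
#' on the supplied training rows only.
#'
#' @param dm a [DesignMatrix-class] of *training* rows.
#' @param bags a [BagSet-class] indexing into `dm`'s rows.
#' @param spec an [EnsembleSpec-class].
#' @return a [BaggedModel-class].
#' @export
fitBaggedEnsemble <- function(dm, bags, spec = ensembleSpec()) {
    stopifnot(is(dm, "DesignMatrix"), is(bags, "BagSet"))
    if (max(unlist(bags@bags)) > nrow(dm@values))
        stop("bags index beyond the design matrix rows")
    scaler <- fitScaler(dm@values)
    scaled <- applyScaler(scaler, dm@values)
    fits <- withSeed(spec@seed, lapply(bags@bags, function(idx) {
        y <- dm@labels[idx]
        if (length(unique(y)) < 2) stop("bag contains a single class")
        lapply(stats::setNames(spec@learners, spec@learners),
               function(family) {
            x <- if (family %in% c("logistic", "nnet", "svm"))
                scaled[idx, , drop = FALSE] else dm@values[idx, , drop = FALSE]
            fitLearner(family, x, y, spec@params[[family]])
        })
    }))
    new("BaggedModel", fits = fits, spec = spec, scaler = scaler,
        columns = colnames(dm@values))
}

#' Predict with a bagged voting ensemble
#'
#' The score of an instance is the mean over bags of the per-bag
#' ensemble scores; the predicted label is 1 iff the score is at
#' least 0.5.
#'
#' @param model a [BaggedModel-class].
#' @param newdata a [DesignMatrix-class] or numeric matrix with the
#'   same column schema as the training matrix.
#' @return list with `scores` (mean class-1 probability per row) and
#'   `labels` (0/1 at threshold 0.5).
#' @export
predictBagged <- function(model, newdata) {
    x <- if (is(newdata, "DesignMatrix")) newdata@values else newdata
    if (!identical(colnames(x), model@columns))
        stop("column schema does not match the fitted model")
    scaled <- applyScaler(model@scaler, x)
    hard <- model@spec@voting == "hard"
    bagScores <- vapply(model@fits, function(ensemble) {
        probs <- vapply(names(ensemble), function(family) {
            xi <- if (family %in% c("logistic", "nnet", "svm")) scaled else x
            predictLearner(family, ensemble[[family]], xi)
        }, numeric(nrow(x)))
        probs <- matrix(probs, nrow = nrow(x))
        if (hard) rowMeans(probs >= 0.5) else rowMeans(probs)
    }, numeric(nrow(x)))
    scores <- rowMeans(matrix(bagScores, nrow = nrow(x)))
    list(scores = scores, labels = as.integer(scores >= 0.5))
}
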