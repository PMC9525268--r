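#' Cross-validation plan
#'
#' The evaluation framework is nested cross-validation: an outer loop
#' estimates out-of-sample performance (mean of the outer-fold
#' scores), and an inner loop on each outer-training set selects
#' hyperparameters by mean AUC. The study design uses 20 outer and 20
#' inner folds; smaller fold counts are accepted for desk-scale runs.
#' Stratification (default on) keeps per-fold class-1 counts within
#' one of each other, which at 1-6\% prevalence prevents
#' positive-free folds with undefined recall/AUC.
#'
#' @param outerFolds,innerFolds fold counts.
#' @param stratified stratify folds by class.
#' @param groupByPatient keep all windows of a patient in one fold
#'   (overlapping windows share content; this guards the split).
#' @param seed RNG seed for fold assignment.
#' @return a [CVPlan-class].
#' @export
cvPlan <- function(outerFolds = 20, innerFolds = 20, stratified = TRUE,
                   groupByPatient = FALSE, seed = 1) {
    new("CVPlan", outerFolds = outerFolds, innerFolds = innerFolds,
        stratified = stratified, groupByPatient = groupByPatient,
        seed = seed)
}

#' Assign instances to cross-validation folds
#'
#' Folds are disjoint, cover every instance, and differ in size by at
#' most one. With `stratified = TRUE` the per-fold class-1 counts also
#' differ by at most one. If the minority class has fewer instances
#' than `k`, the fold count is reduced automatically (with a warning).
#' With `groups`, whole groups are assigned to folds (greedily
#' balancing fold sizes) and stratification applies at the group
#' level.
#'
#' @param labels 0/1 vector.
#' @param k number of folds.
#' @param stratified balance class-1 counts across folds.
#' @param groups optional grouping vector (e.g. patient ids).
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..k`.
#' @export
makeFolds <- function(labels, k, stratified = TRUE, groups = NULL,
                      seed = 1) {
    n <- length(labels)
    if (stratified) {
        minority <- min(table(factor(labels, levels = c(0, 1))))
        if (is.null(groups) && minority < k) {
            k <- max(2, minority)
            warning(sprintf(
                "minority class smaller than fold count; reduced to %d folds",
                k))
        }
    }
    withSeed(seed, {
        fold <- integer(n)
        if (!is.null(groups)) {
            ug <- unique(groups)
            ug <- sample(ug)
            sizes <- numeric(k)
            gfold <- integer(length(ug))
            ord <- order(-vapply(ug, function(g) sum(groups == g),
                                 numeric(1)))
            for (gi in ord) {
                f <- which.min(sizes)
                gfold[gi] <- f
                sizes[f] <- sizes[f] + sum(groups == ug[gi])
            }
            fold <- gfold[match(groups, ug)]
        } else if (stratified) {
            slots <- rep(seq_len(k), length.out = n)
            pos <- sample(which(labels == 1))
            neg <- sample(which(labels == 0))
            fold[c(pos, neg)] <- slots
        } else {
            fold <- sample(rep(seq_len(k), length.out = n))
        }
        fold
    })
}

# Row subsets of the flat and sequence containers.
dmSubset <- function(dm, idx) {
    new("DesignMatrix", values = dm@values[idx, , drop = FALSE],
        schema = dm@schema, labels = dm@labels[idx], k = dm@k)
}

tensorSubset <- function(st, idx) {
    new("SequenceTensor", values = st@values[idx, , , drop = FALSE],
        labels = st@labels[idx])
}

# Fit the requested model family on the training rows and score the
# test rows. Returns scores plus the indices whose data entered model
# fitting (for the leakage audit).
fitAndScore <- function(model, dm, tensor, labels, train, test, candidate,
                        nBags, spec, tConfig, foldSeed) {
    if (model == "differential") {
        bags <- makeBags(labels[train], nBags = nBags, seed = foldSeed)
        fitSpec <- ensembleSpec(learners = spec@learners,
                                params = candidate, voting = spec@voting,
                                seed = foldSeed)
        fit <- fitBaggedEnsemble(dmSubset(dm, train), bags, fitSpec)
        scores <- predictBagged(fit, dm@values[test, , drop = FALSE])$scores
        used <- train[sort(unique(unlist(bags@bags)))]
        # the scaler inside fitBaggedEnsemble saw every training row
        list(scores = scores, used = union(used, train))
    } else {
        ov <- oversampleIndices(labels[train])
        hidden <- if (!is.null(candidate$hiddenSize)) candidate$hiddenSize
                  else 32
        cfg <- trainConfig(epochs = tConfig$epochs,
                           batchSize = tConfig$batchSize,
                           learningRate = tConfig$learningRate,
                           seed = foldSeed)
        scaler <- fitScaler(tensorSubset(tensor, train))
        fit <- trainLstm(applyScaler(scaler,
                                     tensorSubset(tensor, train[ov])),
                         config = cfg, hiddenSize = hidden)
        scores <- predictLstm(fit, applyScaler(scaler,
                                               tensorSubset(tensor, test)))
        list(scores = scores, used = train[sort(unique(ov))])
    }
}

#' Nested cross-validation of one model on one task
#'
#' For each outer fold: an inner cross-validation over the candidate
#' hyperparameter settings on the outer-training data selects the
#' setting with the highest mean inner AUC; one final model is then
#' refit on the full outer-training data with that setting and scored
#' on the held-out fold. Class rebalancing is applied strictly inside
#' training data: the Differential model draws balanced bags from the
#' outer-training rows, the LSTM oversamples them; feature
#' standardization is likewise fit on training rows only. The returned
#' `leakage` record lists, per outer fold, the test indices and every
#' index whose data entered model fitting, so the no-leakage property
#' can be audited.
#'
#' @param wd a [WindowedDataset-class].
#' @param model `"differential"` or `"lstm"`.
#' @param plan a [CVPlan-class].
#' @param grid list of candidate hyperparameter settings (each a named
#'   list: per-family parameter overrides for the ensemble, or
#'   `hiddenSize` for the LSTM). A single-element grid skips the inner
#'   loop.
#' @param nBags number of balanced bags (Differential).
#' @param spec base [EnsembleSpec-class] giving learner families and
#'   voting mode.
#' @param tConfig a [trainConfig()] (LSTM).
#' @param layout Differential design-matrix layout.
#' @return list with `perFold` (data.frame of per-fold metrics),
#'   `mean` (mean over folds, NA-aware), `chosen` (per-fold selected
#'   candidate index), `folds`, and `leakage`.
#' @export
nestedCV <- function(wd, model = c("differential", "lstm"),
                     plan = cvPlan(), grid = list(list()),
                     nBags = 100, spec = ensembleSpec(),
                     tConfig = trainConfig(), layout = "full") {
    model <- match.arg(model)
    labels <- wd@labels
    dm <- NULL; tensor <- NULL
    if (model == "differential") dm <- buildDifferential(wd, layout = layout)
    else tensor <- buildLstmTensor(wd)
    groups <- if (plan@groupByPatient) wd@patientIds else NULL
    fold <- makeFolds(labels, plan@outerFolds, stratified = plan@stratified,
                      groups = groups, seed = plan@seed)
    nOuter <- max(fold)
    perFold <- NULL; chosen <- integer(nOuter); leakage <- vector("list", nOuter)
    for (i in seq_len(nOuter)) {
        train <- which(fold != i)
        test <- which(fold == i)
        best <- 1L
        if (length(grid) > 1) {
            innerFold <- makeFolds(labels[train], plan@innerFolds,
                                   stratified = plan@stratified,
                                   seed = plan@seed + 100 + i)
            meanAuc <- vapply(seq_along(grid), function(ci) {
                aucs <- vapply(seq_len(max(innerFold)), function(j) {
                    itr <- train[innerFold != j]
                    ite <- train[innerFold == j]
                    sc <- fitAndScore(model, dm, tensor, labels, itr, ite,
                                      grid[[ci]], nBags, spec, tConfig,
                                      foldSeed = plan@seed + 7919 * i + j)
                    aucRank(labels[ite], sc$scores)
                }, numeric(1))
                mean(aucs, na.rm = TRUE)
            }, numeric(1))
            best <- which.max(meanAuc)
        }
        chosen[i] <- best
        res <- fitAndScore(model, dm, tensor, labels, train, test,
                           grid[[best]], nBags, spec, tConfig,
                           foldSeed = plan@seed + 7919 * i)
        leakage[[i]] <- list(test = test, used = res$used)
        perFold <- rbind(perFold,
                         as.data.frame(t(computeMetrics(labels[test],
                                                        res$scores))))
    }
    list(perFold = perFold,
         mean = colMeans(perFold, na.rm = TRUE),
         chosen = chosen, folds = fold, leakage = leakage)
}

#' Run both models over the full X-by-Y task grid
#'
#' Full factorial evaluation: for every observation window in `xList`,
#' horizon in `yList` and model in `models`, windows are extracted and
#' [nestedCV()] is run; mean metrics land in one table. A failing cell
#' is recorded (metrics `NA`) and the run continues.
#'
#' @param binned a fully imputed [BinnedCohort-class].
#' @param xList,yList window lengths and horizons in months.
#' @param models character subset of `c("differential", "lstm")`.
#' @param plan a [CVPlan-class].
#' @param ... further arguments to [nestedCV()] (`grid`, `nBags`,
#'   `spec`, `tConfig`, `layout`).
#' @return a [MetricsGrid-class].
#' @export
runGrid <- function(binned, xList = c(6, 12, 18, 24, 30, 36),
                    yList = c(3, 6, 9, 12),
                    models = c("differential", "lstm"),
                    plan = cvPlan(), ...) {
    table <- NULL; perFold <- list()
    for (x in xList) for (y in yList) {
        wd <- extractWindows(binned, taskSpec(x, y))
        cc <- classCounts(wd)
        for (model in models) {
            key <- sprintf("X%d_Y%d_%s", x, y, model)
            row <- data.frame(xMonths = x, yMonths = y, model = model,
                              total = unname(cc["total"]),
                              class1 = unname(cc["class1"]))
            res <- tryCatch(nestedCV(wd, model = model, plan = plan, ...),
                            error = function(e) e)
            if (inherits(res, "error")) {
                warning(sprintf("cell %s failed: %s", key,
                                conditionMessage(res)))
                row <- cbind(row, as.data.frame(t(
                    stats::setNames(rep(NA_real_, 7),
                                    c("accuracy", "recall", "specificity",
                                      "auc", "ppv", "f1", "fbeta")))))
            } else {
                row <- cbind(row, as.data.frame(t(res$mean)))
                perFold[[key]] <- res$perFold
            }
            table <- rbind(table, row)
        }
    }
    new("MetricsGrid", table = table, perFold = perFold)
}

#' LSTM-minus-Differential comparison for one metric
#'
#' @param grid a [MetricsGrid-class] holding both models.
#' @param metric metric column name (e.g. `"auc"`).
#' @return data.frame with columns `xMonths`, `yMonths`, `D`
#'   (Differential), `L` (LSTM) and `LD` (`L - D`).
#' @export
ldTable <- function(grid, metric = "auc") {
    tab <- grid@table
    d <- tab[tab$model == "differential", c("xMonths", "yMonths", metric)]
    l <- tab[tab$model == "lstm", c("xMonths", "yMonths", metric)]
    names(d)[3] <- "D"; names(l)[3] <- "L"
    out <- merge(d, l, by = c("xMonths", "yMonths"), all = TRUE)
    out$LD <- out$L - out$D
    out[order(out$xMonths, out$yMonths), ]
}

#' Render a metrics grid as CSV and markdown tables
#'
#' One table per metric with Differential (`D`), LSTM (`L`) and `L-D`
#' columns per horizon. With `dir` given, `<metric>.csv` and
#' `<metric>.md` files are written; rendering a persisted grid twice
#' is byte-identical.
#'
#' @param grid a [MetricsGrid-class].
#' @param metrics metric columns to render.
#' @param dir optional output directory.
#' @return named list of per-metric data.frames, invisibly if `dir`
#'   is given.
#' @export
reportGrid <- function(grid, metrics = c("accuracy", "recall",
                                         "specificity", "auc", "ppv",
                                         "f1", "fbeta"),
                       dir = NULL) {
    out <- lapply(stats::setNames(metrics, metrics), ldTable, grid = grid)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        for (m in metrics) {
            utils::write.csv(out[[m]], file.path(dir, paste0(m, ".csv")),
                             row.names = FALSE)
            tab <- out[[m]]
            lines <- c(sprintf("## %s", m), "",
                       "| X (months) | Y (months) | D | L | L-D |",
                       "|---|---|---|---|---|",
                       sprintf("| %d | %d | %.3f | %.3f | %.3f |",
                               tab$xMonths, tab$yMonths, tab$D, tab$L,
                               tab$LD))
            writeLines(lines, file.path(dir, paste0(m, ".md")))
        }
        return(invisible(out))
    }
    out
}
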