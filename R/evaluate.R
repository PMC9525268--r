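#' Single held-out-split evaluation of one model on one task
#'
#' A lighter alternative to full [nestedCV()] for calibration checks
#' and worked examples: instances are split once into a stratified
#' training and held-out portion, the model is fitted on the training
#' portion with its rebalancing scheme (balanced bags for the
#' Differential ensemble, minority oversampling for the LSTM) and all
#' preprocessing statistics fitted inside the training portion, and
#' metrics are computed on the held-out portion.
#'
#' @param wd a [WindowedDataset-class].
#' @param model `"differential"` or `"lstm"`.
#' @param testFraction held-out fraction (default 0.25).
#' @param nBags balanced bags for the Differential model.
#' @param spec base [EnsembleSpec-class].
#' @param tConfig [trainConfig()] for the LSTM.
#' @param hiddenSize LSTM hidden units.
#' @param layout Differential design-matrix layout.
#' @param groupByPatient split at the patient level, so no patient has
#'   windows on both sides. Recommended whenever window label
#'   intervals overlap (horizon longer than the 6-month step), since
#'   instance-level splits then share label information between
#'   training and held-out windows of one patient.
#' @param seed RNG seed for the split and the fit.
#' @return list with `metrics` (from [computeMetrics()]), `scores`,
#'   `testIdx`, `trainIdx`.
#' @export
quickEvaluate <- function(wd, model = c("differential", "lstm"),
                          testFraction = 0.25, nBags = 100,
                          spec = ensembleSpec(), tConfig = trainConfig(),
                          hiddenSize = 32, layout = "full",
                          groupByPatient = FALSE, seed = 1) {
    model <- match.arg(model)
    labels <- wd@labels
    groups <- if (groupByPatient) wd@patientIds else NULL
    fold <- makeFolds(labels, max(2, round(1 / testFraction)),
                      stratified = TRUE, groups = groups, seed = seed)
    test <- which(fold == 1)
    train <- which(fold != 1)
    dm <- NULL; tensor <- NULL
    if (model == "differential") dm <- buildDifferential(wd, layout = layout)
    else tensor <- buildLstmTensor(wd)
    candidate <- if (model == "lstm") list(hiddenSize = hiddenSize)
                 else list()
    res <- fitAndScore(model, dm, tensor, labels, train, test,
                       candidate, nBags, spec, tConfig, foldSeed = seed)
    list(metrics = computeMetrics(labels[test], res$scores),
         scores = res$scores, testIdx = test, trainIdx = train)
}
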