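#' @import methods
NULL

#' Configuration of a synthetic lupus cohort
#'
#' `CohortConfig` bundles every parameter of the synthetic cohort
#' generator: cohort size, feature-panel layout, timeline geometry,
#' visit/missingness process, the latent disease-activity process and
#' the hospitalization hazard linking activity (and its recent change)
#' to events. Build one with [cohortConfig()].
#'
#' @slot nPatients number of patients.
#' @slot nDemographic number of static demographic features.
#' @slot nClinical number of time-stamped clinical features.
#' @slot categorySizes named integer vector (manifestation, medication,
#'   lab, utilization) summing to `nClinical`.
#' @slot nObsBins number of 6-month observation bins per patient.
#' @slot followupMonths months of outcome follow-up after the last bin.
#' @slot visitRate expected visits per 6-month bin (Poisson mean).
#' @slot missingProb per-feature per-visit missingness probability.
#' @slot hazardBase baseline monthly hospitalization log-odds.
#' @slot betaLevel hazard effect of the latent activity level.
#' @slot betaDelta hazard effect of the 6-month activity change.
#' @slot interceptSd,driftSd,arPhi,arSd latent-trajectory parameters:
#'   patient intercept SD, per-6-month drift SD, AR(1) coefficient and
#'   innovation SD of the monthly deviation process.
#' @slot labNoiseSd observation noise SD for laboratory features.
#' @slot variableLength if `TRUE`, patients get between
#'   `ceiling(nObsBins / 2)` and `nObsBins` observation bins.
#' @slot seed integer RNG seed; generation is a pure function of the
#'   full configuration including the seed.
#' @export
setClass("CohortConfig", representation(
    nPatients = "numeric", nDemographic = "numeric", nClinical = "numeric",
    categorySizes = "numeric", nObsBins = "numeric", followupMonths = "numeric",
    visitRate = "numeric", missingProb = "numeric",
    hazardBase = "numeric", betaLevel = "numeric", betaDelta = "numeric",
    interceptSd = "numeric", driftSd = "numeric",
    arPhi = "numeric", arSd = "numeric", labNoiseSd = "numeric",
    variableLength = "logical", seed = "numeric"
))

setValidity("CohortConfig", function(object) {
    msg <- character()
    if (object@nPatients < 1) msg <- c(msg, "nPatients must be positive")
    if (sum(object@categorySizes) != object@nClinical)
        msg <- c(msg, "categorySizes must sum to nClinical")
    if (!identical(sort(names(object@categorySizes)),
                   sort(c("manifestation", "medication", "lab", "utilization"))))
        msg <- c(msg, "categorySizes must be named manifestation/medication/lab/utilization")
    if (object@nObsBins < 1) msg <- c(msg, "nObsBins must be >= 1")
    if (object@followupMonths < 0) msg <- c(msg, "followupMonths must be >= 0")
    if (object@missingProb < 0 || object@missingProb > 1)
        msg <- c(msg, "missingProb must lie in [0, 1]")
    if (object@visitRate < 0) msg <- c(msg, "visitRate must be >= 0")
    if (abs(object@arPhi) >= 1) msg <- c(msg, "arPhi must lie in (-1, 1)")
    if (length(msg)) msg else TRUE
})

#' One patient's longitudinal record
#'
#' Demographics (static), irregular time-stamped visits with possibly
#' missing feature values, and dated hospitalization events. Visit times
#' are months from the patient's time origin and lie inside the
#' observation period; event times may extend into follow-up.
#'
#' @slot patientId character scalar.
#' @slot demographics named numeric vector (no missing values).
#' @slot visitTimes numeric vector of visit times in months, sorted.
#' @slot visitValues matrix `length(visitTimes) x nClinical`; `NA` marks
#'   a feature not recorded at that visit.
#' @slot events numeric vector of hospitalization times in months.
#' @slot nObsBins number of 6-month observation bins this record spans.
#' @export
setClass("PatientRecord", representation(
    patientId = "character", demographics = "numeric",
    visitTimes = "numeric", visitValues = "matrix",
    events = "numeric", nObsBins = "numeric"
))

setValidity("PatientRecord", function(object) {
    msg <- character()
    if (anyNA(object@demographics)) msg <- c(msg, "demographics must not contain NA")
    if (length(object@visitTimes) != nrow(object@visitValues))
        msg <- c(msg, "visitTimes length must equal nrow(visitValues)")
    if (length(object@visitTimes) &&
        (min(object@visitTimes) < 0 || max(object@visitTimes) >= 6 * object@nObsBins))
        msg <- c(msg, "visit times must lie in [0, 6 * nObsBins)")
    if (length(msg)) msg else TRUE
})

#' A synthetic (or imported) longitudinal cohort
#'
#' A list of [PatientRecord-class] objects plus the shared clinical
#' feature annotation (name, category, type) and, for generated
#' cohorts, the generating [CohortConfig-class].
#'
#' @slot patients list of `PatientRecord`.
#' @slot features data.frame with columns `name`, `category`
#'   (manifestation/medication/lab/utilization), `type`
#'   (binary/continuous/count) and the generator's per-feature
#'   parameters (`loading`, `offset`, `threshold`).
#' @slot config the generating `CohortConfig`.
#' @export
setClass("SLECohort", representation(
    patients = "list", features = "data.frame", config = "CohortConfig"
))

#' Regular 6-month-binned per-patient series
#'
#' The result of aggregating a patient's irregular visits onto a fixed
#' 6-month grid ([binVisits()]), optionally fully imputed
#' ([imputeSeries()]). `values` rows are bins, columns clinical
#' features; `observedMask` marks cells backed by at least one visit
#' observation (imputation never alters those cells).
#'
#' @slot patientId character scalar.
#' @slot binMonths bin width in months (6).
#' @slot values `nBins x nClinical` numeric matrix; may contain `NA`
#'   before imputation, never after.
#' @slot observedMask logical matrix of the same shape.
#' @slot demographics named numeric vector.
#' @slot events numeric vector of event times in months.
#' @export
setClass("RegularSeries", representation(
    patientId = "character", binMonths = "numeric", values = "matrix",
    observedMask = "matrix", demographics = "numeric", events = "numeric"
))

setValidity("RegularSeries", function(object) {
    if (!identical(dim(object@values), dim(object@observedMask)))
        return("values and observedMask must have identical dimensions")
    TRUE
})

#' A cohort on the regular 6-month grid
#'
#' @slot series list of [RegularSeries-class].
#' @slot features clinical feature annotation (as in
#'   [SLECohort-class]).
#' @slot imputed `TRUE` once every series is fully imputed.
#' @slot binMonths bin width in months.
#' @export
setClass("BinnedCohort", representation(
    series = "list", features = "data.frame",
    imputed = "logical", binMonths = "numeric"
))

#' An observation-window / prediction-horizon task
#'
#' A prediction task "use `xMonths` of binned clinical history to
#' predict hospitalization within the `yMonths` after the window". The
#' window length in bins is `k = xMonths / 6`.
#'
#' @slot xMonths observation window length in months (multiple of 6).
#' @slot yMonths prediction horizon in months.
#' @slot k window length in 6-month bins.
#' @export
setClass("TaskSpec", representation(
    xMonths = "numeric", yMonths = "numeric", k = "numeric"
))

setValidity("TaskSpec", function(object) {
    msg <- character()
    if (object@xMonths %% 6 != 0) msg <- c(msg, "xMonths must be a multiple of 6")
    if (object@yMonths <= 0) msg <- c(msg, "yMonths must be positive")
    if (object@k != object@xMonths / 6) msg <- c(msg, "k must equal xMonths / 6")
    if (length(msg)) msg else TRUE
})

#' Labeled sliding-window instances for one task
#'
#' All `k`-bin sequences extracted step-wise from every patient, each
#' labeled by whether an SLE hospitalization occurred within `yMonths`
#' after the window end.
#'
#' @slot task the [TaskSpec-class].
#' @slot sequences numeric array `n x k x nClinical`.
#' @slot demographics numeric matrix `n x nDemographic`.
#' @slot labels integer vector of 0/1 outcome labels.
#' @slot patientIds,startBins provenance of each instance.
#' @slot features clinical feature annotation.
#' @export
setClass("WindowedDataset", representation(
    task = "TaskSpec", sequences = "array", demographics = "matrix",
    labels = "integer", patientIds = "character", startBins = "integer",
    features = "data.frame"
))

setValidity("WindowedDataset", function(object) {
    n <- dim(object@sequences)[1]
    if (length(object@labels) != n || nrow(object@demographics) != n ||
        length(object@patientIds) != n || length(object@startBins) != n)
        return("instance dimensions are inconsistent")
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
        return("labels must be 0/1")
    TRUE
})

#' Flat design matrix for the Differential approach
#'
#' Each row is one window instance laid out as demographics, the raw
#' clinical features at every step, and the lagged change (delta)
#' variables between consecutive steps. The `schema` tags every column.
#'
#' @slot values `n x p` numeric matrix.
#' @slot schema data.frame with columns `name`, `tag` (one of
#'   `demographic`, `raw`, `delta`), `step`, `feature`.
#' @slot labels integer 0/1 vector.
#' @slot k window length in bins.
#' @export
setClass("DesignMatrix", representation(
    values = "matrix", schema = "data.frame", labels = "integer",
    k = "numeric"
))

setValidity("DesignMatrix", function(object) {
    if (ncol(object@values) != nrow(object@schema))
        return("schema must describe every column")
    if (nrow(object@values) != length(object@labels))
        return("labels must match rows")
    TRUE
})

#' Equal-length sequence tensor for the LSTM
#'
#' `n x k x (nClinical + nDemographic)` array: clinical features at
#' each step with the static demographics appended (repeated) at every
#' step.
#'
#' @slot values the 3-d array.
#' @slot labels integer 0/1 vector.
#' @export
setClass("SequenceTensor", representation(
    values = "array", labels = "integer"
))

setValidity("SequenceTensor", function(object) {
    if (dim(object@values)[1] != length(object@labels))
        return("labels must match first tensor dimension")
    TRUE
})

#' Balanced bootstrap bags for class-imbalanced training
#'
#' Each bag holds the indices of all minority instances plus an equal
#' number of majority instances sampled with replacement from the whole
#' majority population, so every bag is exactly class-balanced.
#'
#' @slot bags list of integer index vectors into the parent dataset.
#' @slot minority integer indices of the minority class.
#' @slot seed RNG seed used to draw the bags.
#' @export
setClass("BagSet", representation(
    bags = "list", minority = "integer", seed = "numeric"
))

#' Specification of the six-learner voting ensemble
#'
#' @slot learners character vector naming the base-learner families;
#'   the full set is decision tree, random forest, logistic regression,
#'   naive Bayes, feed-forward neural network and support-vector
#'   machine.
#' @slot params named list of per-family hyperparameters.
#' @slot voting `"soft"` (mean class-1 probability) or `"hard"`
#'   (fraction of learners voting class 1).
#' @slot seed RNG seed for stochastic learners.
#' @export
setClass("EnsembleSpec", representation(
    learners = "character", params = "list", voting = "character",
    seed = "numeric"
))

setValidity("EnsembleSpec", function(object) {
    known <- c("tree", "forest", "logistic", "nbayes", "nnet", "svm")
    if (!length(object@learners) || !all(object@learners %in% known))
        return(paste("learners must be a non-empty subset of:",
                     paste(known, collapse = ", ")))
    if (!object@voting %in% c("soft", "hard"))
        return("voting must be 'soft' or 'hard'")
    TRUE
})

#' A bagged voting ensemble fitted on balanced bags
#'
#' @slot fits list (one element per bag) of lists of fitted base
#'   learners.
#' @slot spec the [EnsembleSpec-class] used.
#' @slot scaler the standardization fitted on the training rows (or
#'   `NULL`), applied to scale-sensitive learners.
#' @slot columns column names of the training design matrix, used to
#'   reject schema-mismatched prediction inputs.
#' @export
setClass("BaggedModel", representation(
    fits = "list", spec = "EnsembleSpec", scaler = "ANY",
    columns = "character"
))

#' Nested cross-validation plan
#'
#' @slot outerFolds,innerFolds fold counts for the outer performance
#'   loop and the inner hyperparameter-selection loop.
#' @slot stratified keep per-fold class-1 counts within one of each
#'   other.
#' @slot groupByPatient if `TRUE`, all windows of a patient share a
#'   fold (guards against content overlap between folds).
#' @slot seed RNG seed for fold assignment.
#' @export
setClass("CVPlan", representation(
    outerFolds = "numeric", innerFolds = "numeric", stratified = "logical",
    groupByPatient = "logical", seed = "numeric"
))

setValidity("CVPlan", function(object) {
    if (object@outerFolds < 2 || object@innerFolds < 2)
        return("fold counts must be >= 2")
    TRUE
})

#' Evaluation results over the X-by-Y task grid
#'
#' Mean-over-outer-folds metrics per (observation window, horizon,
#' model) cell, with per-fold detail, supporting the LSTM-minus-
#' Differential ("L-D") comparison.
#'
#' @slot table data.frame with columns `xMonths`, `yMonths`, `model`,
#'   one column per metric, plus instance counts.
#' @slot perFold list of per-cell data.frames of per-fold metrics.
#' @export
setClass("MetricsGrid", representation(
    table = "data.frame", perFold = "list"
))
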