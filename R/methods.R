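# Accessors and show methods.

#' @describeIn nInstances windows in a WindowedDataset
#' @export
setMethod("nInstances", "WindowedDataset", function(x) dim(x@sequences)[1])

#' @describeIn nInstances rows of a DesignMatrix
#' @export
setMethod("nInstances", "DesignMatrix", function(x) nrow(x@values))

#' @describeIn nInstances sequences in a SequenceTensor
#' @export
setMethod("nInstances", "SequenceTensor", function(x) dim(x@values)[1])

#' @describeIn instanceLabels labels of a WindowedDataset
#' @export
setMethod("instanceLabels", "WindowedDataset", function(x) x@labels)

#' @describeIn instanceLabels labels of a DesignMatrix
#' @export
setMethod("instanceLabels", "DesignMatrix", function(x) x@labels)

#' @describeIn instanceLabels labels of a SequenceTensor
#' @export
setMethod("instanceLabels", "SequenceTensor", function(x) x@labels)

#' @describeIn featureInfo annotation of an SLECohort
#' @export
setMethod("featureInfo", "SLECohort", function(x) x@features)

#' @describeIn featureInfo annotation of a BinnedCohort
#' @export
setMethod("featureInfo", "BinnedCohort", function(x) x@features)

#' @describeIn featureInfo annotation of a WindowedDataset
#' @export
setMethod("featureInfo", "WindowedDataset", function(x) x@features)

#' @describeIn classCounts totals of a WindowedDataset
#' @export
setMethod("classCounts", "WindowedDataset", function(x)
    c(total = length(x@labels), class1 = sum(x@labels == 1L)))

#' @describeIn classCounts totals of a DesignMatrix
#' @export
setMethod("classCounts", "DesignMatrix", function(x)
    c(total = length(x@labels), class1 = sum(x@labels == 1L)))

#' @describeIn bagIndices index lists of a BagSet
#' @export
setMethod("bagIndices", "BagSet", function(x) x@bags)

#' @describeIn metricsTable table of a MetricsGrid
#' @export
setMethod("metricsTable", "MetricsGrid", function(x) x@table)

#' Number of patients in a cohort
#' @param cohort an [SLECohort-class] or [BinnedCohort-class].
#' @return integer count.
#' @export
nPatients <- function(cohort) {
    if (is(cohort, "SLECohort")) length(cohort@patients)
    else length(cohort@series)
}

setMethod("show", "CohortConfig", function(object) {
    cat(sprintf(
        "CohortConfig: %d patients, %d clinical + %d demographic features\n",
        object@nPatients, object@nClinical, object@nDemographic))
    cat(sprintf("  timeline: %d x 6-month bins + %d months follow-up\n",
                object@nObsBins, object@followupMonths))
    cat(sprintf(
        "  hazard: base %.2f, level effect %.2f, change effect %.2f\n",
        object@hazardBase, object@betaLevel, object@betaDelta))
})

setMethod("show", "SLECohort", function(object) {
    nev <- sum(vapply(object@patients, function(p) length(p@events),
                      numeric(1)))
    cat(sprintf(
        "SLECohort: %d patients, %d clinical features, %d events\n",
        length(object@patients), nrow(object@features), nev))
})

setMethod("show", "RegularSeries", function(object) {
    cat(sprintf(
        "RegularSeries %s: %d bins x %d features (%d observed, %s)\n",
        object@patientId, nrow(object@values), ncol(object@values),
        sum(object@observedMask),
        if (anyNA(object@values)) "not imputed" else "fully imputed"))
})

setMethod("show", "BinnedCohort", function(object) {
    cat(sprintf("BinnedCohort: %d patients on a %d-month grid (%s)\n",
                length(object@series), object@binMonths,
                if (object@imputed) "imputed" else "raw bins"))
})

setMethod("show", "TaskSpec", function(object) {
    cat(sprintf("Task: observe %dM (k = %d bins) -> predict %dM\n",
                object@xMonths, object@k, object@yMonths))
})

setMethod("show", "WindowedDataset", function(object) {
    cc <- classCounts(object)
    cat(sprintf(
        "WindowedDataset X=%dM Y=%dM: %d instances, %d class 1 (%.2f%%)\n",
        object@task@xMonths, object@task@yMonths, cc["total"], cc["class1"],
        100 * cc["class1"] / max(cc["total"], 1)))
})

setMethod("show", "DesignMatrix", function(object) {
    tags <- table(object@schema$tag)
    cat(sprintf(
        "DesignMatrix: %d x %d (%d demographic, %d raw, %d delta), k = %d\n",
        nrow(object@values), ncol(object@values),
        tags["demographic"], tags["raw"],
        if ("delta" %in% names(tags)) tags[["delta"]] else 0L, object@k))
})

setMethod("show", "SequenceTensor", function(object) {
    d <- dim(object@values)
    cat(sprintf("SequenceTensor: %d x %d x %d, %d class 1\n",
                d[1], d[2], d[3], sum(object@labels)))
})

setMethod("show", "BagSet", function(object) {
    sizes <- lengths(object@bags)
    cat(sprintf(
        "BagSet: %d balanced bags of size %s (%d minority instances)\n",
        length(object@bags),
        if (length(unique(sizes)) == 1) as.character(sizes[1])
        else paste(range(sizes), collapse = "-"),
        length(object@minority)))
})

setMethod("show", "EnsembleSpec", function(object) {
    cat(sprintf("EnsembleSpec: {%s}, %s voting\n",
                paste(object@learners, collapse = ", "), object@voting))
})

setMethod("show", "BaggedModel", function(object) {
    cat(sprintf(
        "BaggedModel: %d bags x %d base learners, %d feature columns\n",
        length(object@fits), length(object@spec@learners),
        length(object@columns)))
})

setMethod("show", "CVPlan", function(object) {
    cat(sprintf(
        "CVPlan: %d outer x %d inner folds, %sstratified%s\n",
        object@outerFolds, object@innerFolds,
        if (object@stratified) "" else "not ",
        if (object@groupByPatient) ", grouped by patient" else ""))
})

setMethod("show", "MetricsGrid", function(object) {
    cat(sprintf("MetricsGrid: %d cells\n", nrow(object@table)))
    print(utils::head(object@table, 12))
})
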