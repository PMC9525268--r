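#' Number of instances in a windowed container
#' @param x a `WindowedDataset`, `DesignMatrix` or `SequenceTensor`.
#' @return integer instance count.
#' @export
setGeneric("nInstances", function(x) standardGeneric("nInstances"))

#' Instance outcome labels
#' @param x a `WindowedDataset`, `DesignMatrix` or `SequenceTensor`.
#' @return integer 0/1 vector.
#' @export
setGeneric("instanceLabels", function(x) standardGeneric("instanceLabels"))

#' Clinical feature annotation
#' @param x an `SLECohort`, `BinnedCohort` or `WindowedDataset`.
#' @return data.frame with columns `name`, `category`, `type`.
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' Class counts of a labeled dataset
#' @param x a labeled container.
#' @return named integer vector `c(total, class1)`.
#' @export
setGeneric("classCounts", function(x) standardGeneric("classCounts"))

#' Bag index lists of a BagSet
#' @param x a `BagSet`.
#' @return list of integer vectors.
#' @export
setGeneric("bagIndices", function(x) standardGeneric("bagIndices"))

#' Mean-over-folds metric table of a MetricsGrid
#' @param x a `MetricsGrid`.
#' @return data.frame of per-cell mean metrics.
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))
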