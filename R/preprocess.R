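#' Aggregate a patient's irregular visits onto the 6-month grid
#'
#' Bin `b` covers months `[6b, 6(b+1))` (left-closed, right-open). All
#' visits falling in a bin are aggregated per feature category:
#' laboratory values are averaged (multiple lab draws in a half-year
#' are averaged to one equivalent visit, which also damps measurement
#' noise), binary manifestation/medication flags take the maximum (a
#' manifestation observed at any visit in the half-year was present),
#' and utilization counts are summed (utilization is additive). A cell
#' with no observation in its bin is left `NA` for [imputeSeries()].
#'
#' @param record a [PatientRecord-class].
#' @param features feature annotation (`name`, `category`, `type`).
#' @param binMonths bin width in months (default 6).
#' @param nBins number of bins; defaults to the record's span.
#' @return a [RegularSeries-class] (possibly with `NA` cells).
#' @export
binVisits <- function(record, features, binMonths = 6,
                      nBins = record@nObsBins) {
    if (length(record@visitTimes) &&
        (min(record@visitTimes) < 0 ||
         max(record@visitTimes) >= binMonths * nBins))
        stop("visit time outside the patient timeline")
    p <- nrow(features)
    vals <- matrix(NA_real_, nBins, p,
                   dimnames = list(NULL, features$name))
    binOf <- floor(record@visitTimes / binMonths) + 1L
    for (b in seq_len(nBins)) {
        rows <- record@visitValues[binOf == b, , drop = FALSE]
        if (!nrow(rows)) next
        for (j in seq_len(p)) {
            obs <- rows[, j]
            obs <- obs[!is.na(obs)]
            if (!length(obs)) next
            vals[b, j] <- switch(features$type[j],
                continuous = mean(obs),
                binary = max(obs),
                count = sum(obs))
        }
    }
    new("RegularSeries", patientId = record@patientId,
        binMonths = binMonths, values = vals, observedMask = !is.na(vals),
        demographics = record@demographics, events = record@events)
}

#' Fill the missing cells of a binned series
#'
#' Missing-cell estimation per feature, fitted to that feature's
#' observed bins only: interior gaps are filled by piecewise-linear
#' interpolation between the nearest observed bins (observed points are
#' reproduced exactly); leading/trailing gaps are filled by
#' extrapolating the least-squares line through the observed points
#' (robust to a noisy first or last observation); a feature observed in
#' a single bin is held constant. Binary features are clipped to
#' \[0, 1\] and counts floored at 0 after imputation. Observed cells
#' are never altered, so the operation is idempotent.
#'
#' `lsEverywhere = TRUE` switches to the single least-squares line for
#' every missing cell (interior gaps included).
#'
#' @param series a [RegularSeries-class] from [binVisits()].
#' @param features feature annotation.
#' @param cohortMeans optional named vector of cohort-level feature
#'   means, used (with a warning) for a feature this patient never has
#'   observed; without it such a feature is filled with 0.
#' @param lsEverywhere use the least-squares line for interior gaps
#'   too.
#' @return a fully imputed [RegularSeries-class].
#' @export
imputeSeries <- function(series, features, cohortMeans = NULL,
                         lsEverywhere = FALSE) {
    vals <- series@values
    nb <- nrow(vals)
    for (j in seq_len(ncol(vals))) {
        miss <- is.na(vals[, j])
        if (!any(miss)) next
        obs <- which(!miss)
        if (!length(obs)) {
            fill <- if (!is.null(cohortMeans)) cohortMeans[[features$name[j]]]
                    else 0
            warning(sprintf(
                "feature '%s' never observed for patient %s; using %s",
                features$name[j], series@patientId,
                if (is.null(cohortMeans)) "0" else "cohort mean"))
            vals[miss, j] <- fill
            next
        }
        vals[miss, j] <- linearImputeAt(obs, vals[obs, j], which(miss),
                                        lsEverywhere = lsEverywhere)
        if (features$type[j] == "binary")
            vals[miss, j] <- pmin(pmax(vals[miss, j], 0), 1)
        if (features$type[j] == "count")
            vals[miss, j] <- pmax(vals[miss, j], 0)
    }
    new("RegularSeries", patientId = series@patientId,
        binMonths = series@binMonths, values = vals,
        observedMask = series@observedMask,
        demographics = series@demographics, events = series@events)
}

#' Bin and impute a whole cohort
#'
#' Runs [binVisits()] then [imputeSeries()] over every patient,
#' producing the regular, fully imputed series the windowing stage
#' consumes. Cohort-level feature means (over observed binned cells)
#' back the never-observed-feature fallback. With
#' `order = "impute_first"` the missing visit-level cells are filled by
#' the same linear interpolation/extrapolation along each patient's
#' visit times before binning.
#'
#' @param cohort an [SLECohort-class].
#' @param impute if `FALSE`, stop after binning (cells may be `NA`).
#' @param order `"bin_first"` (default) or `"impute_first"`.
#' @param lsEverywhere passed to [imputeSeries()].
#' @return a [BinnedCohort-class].
#' @export
binCohort <- function(cohort, impute = TRUE,
                      order = c("bin_first", "impute_first"),
                      lsEverywhere = FALSE) {
    order <- match.arg(order)
    feats <- cohort@features
    patients <- cohort@patients
    if (order == "impute_first" && impute)
        patients <- lapply(patients, imputeVisits, features = feats,
                           lsEverywhere = lsEverywhere)
    series <- lapply(patients, binVisits, features = feats)
    if (impute) {
        allVals <- do.call(rbind, lapply(series, slot, "values"))
        cohortMeans <- colMeans(allVals, na.rm = TRUE)
        cohortMeans[is.nan(cohortMeans)] <- 0
        names(cohortMeans) <- feats$name
        series <- lapply(series, imputeSeries, features = feats,
                         cohortMeans = cohortMeans,
                         lsEverywhere = lsEverywhere)
    }
    new("BinnedCohort", series = series, features = feats,
        imputed = impute, binMonths = 6)
}

# Fill missing cells at the visit level (impute_first order): per
# feature, linear interpolation/extrapolation along the patient's own
# visit times.
imputeVisits <- function(record, features, lsEverywhere = FALSE) {
    vals <- record@visitValues
    if (!nrow(vals)) return(record)
    for (j in seq_len(ncol(vals))) {
        miss <- is.na(vals[, j])
        if (!any(miss) || all(miss)) next
        obs <- which(!miss)
        vals[miss, j] <- linearImputeAt(record@visitTimes[obs], vals[obs, j],
                                        record@visitTimes[miss],
                                        lsEverywhere = lsEverywhere)
        if (features$type[j] == "binary")
            vals[miss, j] <- pmin(pmax(vals[miss, j], 0), 1)
        if (features$type[j] == "count")
            vals[miss, j] <- pmax(vals[miss, j], 0)
    }
    initialize(record, visitValues = vals)
}

#' Write / read a binned cohort as wide-format CSV
#'
#' One row per patient-bin with the 52 feature columns, plus a
#' companion mask file marking which cells were actually observed (vs
#' imputed), a demographics/events file pair, and the feature
#' annotation.
#'
#' @param binned a [BinnedCohort-class].
#' @param dir target directory.
#' @return `writeBinnedCohort()` returns `dir` invisibly;
#'   `readBinnedCohort()` the reconstructed [BinnedCohort-class].
#' @export
writeBinnedCohort <- function(binned, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    rows <- do.call(rbind, lapply(binned@series, function(s)
        data.frame(patient_id = s@patientId,
                   bin = seq_len(nrow(s@values)) - 1L, s@values,
                   check.names = FALSE, stringsAsFactors = FALSE)))
    utils::write.csv(rows, file.path(dir, "series.csv"), row.names = FALSE)
    mask <- do.call(rbind, lapply(binned@series, function(s)
        data.frame(patient_id = s@patientId,
                   bin = seq_len(nrow(s@values)) - 1L,
                   s@observedMask * 1L, check.names = FALSE,
                   stringsAsFactors = FALSE)))
    utils::write.csv(mask, file.path(dir, "observed_mask.csv"),
                     row.names = FALSE)
    demo <- do.call(rbind, lapply(binned@series, function(s)
        data.frame(patient_id = s@patientId, t(s@demographics),
                   stringsAsFactors = FALSE)))
    utils::write.csv(demo, file.path(dir, "demographics.csv"),
                     row.names = FALSE)
    events <- do.call(rbind, lapply(binned@series, function(s) {
        if (!length(s@events)) return(NULL)
        data.frame(patient_id = s@patientId, time_months = s@events)
    }))
    if (is.null(events))
        events <- data.frame(patient_id = character(), time_months = numeric())
    utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
    utils::write.csv(binned@features, file.path(dir, "features.csv"),
                     row.names = FALSE)
    invisible(dir)
}

#' @rdname writeBinnedCohort
#' @export
readBinnedCohort <- function(dir) {
    rows <- utils::read.csv(file.path(dir, "series.csv"), check.names = FALSE,
                            stringsAsFactors = FALSE)
    mask <- utils::read.csv(file.path(dir, "observed_mask.csv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
    demo <- utils::read.csv(file.path(dir, "demographics.csv"),
                            stringsAsFactors = FALSE)
    events <- utils::read.csv(file.path(dir, "events.csv"),
                              stringsAsFactors = FALSE)
    feats <- utils::read.csv(file.path(dir, "features.csv"),
                             stringsAsFactors = FALSE)
    ids <- unique(rows$patient_id)
    series <- lapply(ids, function(id) {
        vr <- rows[rows$patient_id == id, ]
        vr <- vr[order(vr$bin), ]
        mr <- mask[mask$patient_id == id, ]
        mr <- mr[order(mr$bin), ]
        vals <- as.matrix(vr[, feats$name, drop = FALSE])
        rownames(vals) <- NULL
        msk <- as.matrix(mr[, feats$name, drop = FALSE]) == 1
        rownames(msk) <- NULL
        drow <- demo[demo$patient_id == id, ]
        new("RegularSeries", patientId = id, binMonths = 6, values = vals,
            observedMask = msk,
            demographics = unlist(drow[setdiff(names(drow), "patient_id")]),
            events = as.numeric(events$time_months[events$patient_id == id]))
    })
    new("BinnedCohort", series = series, features = feats,
        imputed = !anyNA(rows[, feats$name]), binMonths = 6)
}
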