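#' Define an observation-window / prediction-horizon task
#'
#' @param xMonths observation window length in months; must be a
#'   multiple of 6 (the study grid uses 6, 12, 18, 24, 30, 36).
#' @param yMonths prediction horizon in months (3, 6, 9 or 12 in the
#'   study grid; any positive value is accepted).
#' @return a [TaskSpec-class] with `k = xMonths / 6`.
#' @export
taskSpec <- function(xMonths, yMonths) {
    new("TaskSpec", xMonths = xMonths, yMonths = yMonths, k = xMonths / 6)
}

#' Extract labeled sliding-window instances for a task
#'
#' Moves a `k`-bin window step-wise (one bin at a time) along each
#' patient's regular series and labels every window by whether an SLE
#' hospitalization occurred within `yMonths` after the window end
#' (half-open interval `(end, end + yMonths]`). Windows from one
#' patient overlap and are kept as separate instances. A patient with
#' `b` usable bins contributes `b - k + 1` windows, so with the default
#' 6-bin timeline each patient contributes `7 - k` instances and totals
#' shrink by the cohort size at each 6-month window increment; totals
#' do not depend on the horizon because every window end retains a full
#' follow-up.
#'
#' @param binned a fully imputed [BinnedCohort-class] (or a list of
#'   [RegularSeries-class] plus `features`).
#' @param task a [TaskSpec-class].
#' @param features feature annotation; defaults to the binned cohort's.
#' @return a [WindowedDataset-class].
#' @examples
#' cohort <- generateCohort(cohortConfig(nPatients = 20, seed = 1))
#' wd <- extractWindows(binCohort(cohort), taskSpec(12, 6))
#' classCounts(wd)
#' @export
extractWindows <- function(binned, task, features = NULL) {
    if (is(binned, "BinnedCohort")) {
        series <- binned@series
        if (is.null(features)) features <- binned@features
    } else series <- binned
    stopifnot(is(task, "TaskSpec"))
    k <- task@k
    p <- nrow(features)
    seqs <- list(); demos <- list(); labels <- integer()
    pids <- character(); starts <- integer()
    for (s in series) {
        nb <- nrow(s@values)
        if (anyNA(s@values))
            stop("series must be fully imputed before windowing")
        if (nb < k) {
            warning(sprintf("patient %s has %d bins < k = %d; skipped",
                            s@patientId, nb, k))
            next
        }
        for (start in 0:(nb - k)) {
            seqs[[length(seqs) + 1L]] <-
                s@values[start + seq_len(k), , drop = FALSE]
            demos[[length(demos) + 1L]] <- s@demographics
            endMonths <- s@binMonths * (start + k)
            labels <- c(labels, eventInInterval(s@events, endMonths,
                                                task@yMonths))
            pids <- c(pids, s@patientId)
            starts <- c(starts, start)
        }
    }
    n <- length(seqs)
    arr <- array(0, dim = c(n, k, p),
                 dimnames = list(NULL, NULL, features$name))
    for (i in seq_len(n)) arr[i, , ] <- seqs[[i]]
    demoM <- do.call(rbind, demos)
    if (is.null(demoM)) demoM <- matrix(0, 0, 0)
    new("WindowedDataset", task = task, sequences = arr,
        demographics = demoM, labels = as.integer(labels),
        patientIds = pids, startBins = as.integer(starts),
        features = features)
}

#' Write a windowed dataset as flat CSV + JSON sidecar
#'
#' The CSV flattens each instance's sequence to columns named
#' `f{feature}_t{step}` plus demographics, provenance and `label`; the
#' sidecar records the task and class counts.
#'
#' @param wd a [WindowedDataset-class].
#' @param path CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
writeWindowedDataset <- function(wd, path) {
    k <- wd@task@k
    p <- dim(wd@sequences)[3]
    flat <- matrix(wd@sequences, nrow = nInstances(wd))
    colnames(flat) <- as.vector(outer(seq_len(k), seq_len(p), function(t, j)
        sprintf("f%d_t%d", j, t - 1)))
    df <- data.frame(patient_id = wd@patientIds, start_bin = wd@startBins,
                     wd@demographics, flat, label = wd@labels,
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    cc <- classCounts(wd)
    jsonlite::write_json(
        list(xMonths = wd@task@xMonths, yMonths = wd@task@yMonths,
             k = k, total = unname(cc["total"]),
             class1 = unname(cc["class1"])),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Table of window counts across the task grid
#'
#' Reproduces the study-design bookkeeping: for each observation
#' window X and horizon Y, the number of extracted instances and the
#' class-1 (hospitalization) count and prevalence.
#'
#' @param binned a fully imputed [BinnedCohort-class].
#' @param xList,yList window lengths and horizons in months.
#' @return data.frame with columns `xMonths`, `yMonths`, `total`,
#'   `class1`, `prevalence`.
#' @export
windowCountTable <- function(binned, xList = c(6, 12, 18, 24, 30, 36),
                             yList = c(3, 6, 9, 12)) {
    rows <- lapply(xList, function(x) {
        do.call(rbind, lapply(yList, function(y) {
            cc <- classCounts(extractWindows(binned, taskSpec(x, y)))
            data.frame(xMonths = x, yMonths = y,
                       total = unname(cc["total"]),
                       class1 = unname(cc["class1"]),
                       prevalence = unname(cc["class1"] / cc["total"]))
        }))
    })
    do.call(rbind, rows)
}
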