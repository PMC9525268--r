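#' Write / read a cohort as plain-text files
#'
#' A cohort is serialized to a directory of CSV/JSON files so that real
#' visit-level data could be substituted for the generator's output:
#' `visits.csv` (long format: `patient_id`, `time_months`,
#' `feature_name`, `value`, with empty `value` for a feature not
#' recorded at that visit), `demographics.csv`, `events.csv`,
#' `features.csv` (the feature annotation) and `config.json`. The
#' round trip is lossless.
#'
#' @param cohort an [SLECohort-class].
#' @param dir directory to create/populate.
#' @return `writeCohort()` returns `dir` invisibly; `readCohort()`
#'   returns the reconstructed [SLECohort-class].
#' @export
writeCohort <- function(cohort, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    feats <- cohort@features
    visits <- do.call(rbind, lapply(cohort@patients, function(p) {
        if (!length(p@visitTimes)) return(NULL)
        data.frame(patient_id = p@patientId,
                   time_months = rep(p@visitTimes, each = ncol(p@visitValues)),
                   feature_name = rep(colnames(p@visitValues),
                                      length(p@visitTimes)),
                   value = as.vector(t(p@visitValues)),
                   stringsAsFactors = FALSE)
    }))
    utils::write.csv(visits, file.path(dir, "visits.csv"), row.names = FALSE)
    demo <- do.call(rbind, lapply(cohort@patients, function(p)
        data.frame(patient_id = p@patientId, n_obs_bins = p@nObsBins,
                   t(p@demographics), stringsAsFactors = FALSE)))
    utils::write.csv(demo, file.path(dir, "demographics.csv"),
                     row.names = FALSE)
    events <- do.call(rbind, lapply(cohort@patients, function(p) {
        if (!length(p@events)) return(NULL)
        data.frame(patient_id = p@patientId, time_months = p@events,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(events))
        events <- data.frame(patient_id = character(),
                             time_months = numeric())
    utils::write.csv(events, file.path(dir, "events.csv"), row.names = FALSE)
    utils::write.csv(feats, file.path(dir, "features.csv"), row.names = FALSE)
    cfg <- cohort@config
    cfgList <- lapply(slotNames(cfg), function(s) slot(cfg, s))
    names(cfgList) <- slotNames(cfg)
    # a named atomic vector loses its names in JSON; keep them via a list
    cfgList$categorySizes <- as.list(cfg@categorySizes)
    jsonlite::write_json(cfgList, file.path(dir, "config.json"),
                         digits = NA, auto_unbox = FALSE)
    invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
    visits <- utils::read.csv(file.path(dir, "visits.csv"),
                              stringsAsFactors = FALSE)
    demo <- utils::read.csv(file.path(dir, "demographics.csv"),
                            stringsAsFactors = FALSE)
    events <- utils::read.csv(file.path(dir, "events.csv"),
                              stringsAsFactors = FALSE)
    feats <- utils::read.csv(file.path(dir, "features.csv"),
                             stringsAsFactors = FALSE)
    cfgList <- jsonlite::read_json(file.path(dir, "config.json"),
                                   simplifyVector = TRUE)
    cfg <- do.call(new, c(list("CohortConfig"),
                          lapply(cfgList, function(x) {
                              if (is.list(x)) unlist(x) else x
                          })))
    patients <- lapply(demo$patient_id, function(id) {
        drow <- demo[demo$patient_id == id, ]
        dvec <- unlist(drow[setdiff(names(drow),
                                    c("patient_id", "n_obs_bins"))])
        pv <- visits[visits$patient_id == id, ]
        times <- sort(unique(pv$time_months))
        vals <- matrix(NA_real_, length(times), nrow(feats),
                       dimnames = list(NULL, feats$name))
        if (nrow(pv)) {
            vals[cbind(match(pv$time_months, times),
                       match(pv$feature_name, feats$name))] <- pv$value
        }
        ev <- events$time_months[events$patient_id == id]
        new("PatientRecord", patientId = id, demographics = dvec,
            visitTimes = times, visitValues = vals,
            events = as.numeric(ev), nObsBins = drow$n_obs_bins)
    })
    new("SLECohort", patients = patients, features = feats, config = cfg)
}
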