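#' Build a synthetic-cohort configuration
#'
#' The generator emulates a longitudinal EHR-based lupus cohort: static
#' demographics, four categories of time-stamped clinical features
#' (clinical manifestations, SLE medications, laboratory values,
#' healthcare utilization) observed at irregular visits with missing
#' values, and dated SLE-hospitalization events. Each patient carries a
#' latent monthly disease-activity trajectory
#' \deqn{a(m) = \mu_i + s_i \, m/6 + u(m),}
#' a patient intercept plus a patient-specific linear drift plus an
#' AR(1) deviation. Observed features are noisy functions of \eqn{a(m)}
#' (labs linear-Gaussian, manifestations/medications thresholded,
#' utilization Poisson), and hospitalizations are drawn month by month
#' with hazard
#' \deqn{h(m) = \mathrm{logistic}(\beta_0 + \beta_L a(m) + \beta_\Delta
#'   [a(m) - a(m-6)]),}
#' so both the activity level and its recent 6-month change drive risk.
#' The drift term makes recent change persist across the
#' window/horizon boundary, which is what gives lagged difference
#' features predictive value.
#'
#' @param nPatients cohort size (default 925).
#' @param nDemographic number of static demographic features (5).
#' @param categorySizes named counts per clinical category, summing to
#'   the clinical feature total (default 14 manifestations, 12
#'   medications, 16 labs, 10 utilization = 52).
#' @param nObsBins 6-month observation bins per patient (default 6,
#'   i.e. a 3-year observation period).
#' @param followupMonths outcome follow-up after the last bin (12).
#' @param visitRate expected visits per bin (2).
#' @param missingProb per-feature per-visit missingness probability.
#' @param hazardBase,betaLevel,betaDelta monthly hazard parameters (see
#'   Details).
#' @param interceptSd,driftSd,arPhi,arSd latent-trajectory parameters.
#' @param labNoiseSd observation noise SD of laboratory features.
#' @param variableLength give patients variable record lengths.
#' @param seed RNG seed.
#' @return a [CohortConfig-class] object.
#' @seealso [generateCohort()], [nullPreset()], [signalPreset()]
#' @export
cohortConfig <- function(nPatients = 925, nDemographic = 5,
                         categorySizes = c(manifestation = 14, medication = 12,
                                           lab = 16, utilization = 10),
                         nObsBins = 6, followupMonths = 12,
                         visitRate = 2, missingProb = 0.15,
                         hazardBase = -7.5, betaLevel = 0.8, betaDelta = 2.5,
                         interceptSd = 0.8, driftSd = 0.35,
                         arPhi = 0.8, arSd = 0.15, labNoiseSd = 0.6,
                         variableLength = FALSE, seed = 1) {
    new("CohortConfig", nPatients = nPatients, nDemographic = nDemographic,
        nClinical = sum(categorySizes), categorySizes = categorySizes,
        nObsBins = nObsBins, followupMonths = followupMonths,
        visitRate = visitRate, missingProb = missingProb,
        hazardBase = hazardBase, betaLevel = betaLevel, betaDelta = betaDelta,
        interceptSd = interceptSd, driftSd = driftSd, arPhi = arPhi,
        arSd = arSd, labNoiseSd = labNoiseSd,
        variableLength = variableLength, seed = seed)
}

#' Signal and null cohort presets
#'
#' `signalPreset()` is the default configuration, in which the
#' 6-month activity *change* dominates the hazard (`betaDelta` large
#' relative to `betaLevel`), so lagged difference features carry real
#' signal. `nullPreset()` removes all dependence of the hazard on the
#' latent activity (`betaLevel = betaDelta = 0`); outcomes are then
#' pure noise with monthly probability `plogis(hazardBase)` and any
#' classifier's true AUC is 0.5.
#'
#' @param ... overrides passed on to [cohortConfig()].
#' @return a [CohortConfig-class].
#' @export
signalPreset <- function(...) cohortConfig(...)

#' @rdname signalPreset
#' @export
nullPreset <- function(...) {
    cohortConfig(betaLevel = 0, betaDelta = 0, hazardBase = -5.27, ...)
}

# Draw per-feature observation parameters for one cohort.
makeFeatureTable <- function(config) {
    sizes <- config@categorySizes[c("manifestation", "medication",
                                    "lab", "utilization")]
    category <- rep(names(sizes), sizes)
    type <- c(manifestation = "binary", medication = "binary",
              lab = "continuous", utilization = "count")[category]
    n <- sum(sizes)
    data.frame(
        name = sprintf("%s_%02d", category, unlist(lapply(sizes, seq_len))),
        category = category, type = unname(type),
        loading = stats::runif(n, 0.4, 1.2),
        offset = ifelse(type == "count", stats::rnorm(n, log(0.8), 0.4),
                        stats::rnorm(n, 0, 1)),
        threshold = stats::rnorm(n, 0.9, 0.3),
        stringsAsFactors = FALSE)
}

# Latent monthly disease activity a(0..T): intercept + drift + AR(1).
simulateActivity <- function(config, totalMonths) {
    mu <- stats::rnorm(1, 0, config@interceptSd)
    slope <- stats::rnorm(1, 0, config@driftSd)
    u <- numeric(totalMonths + 1)
    statSd <- config@arSd / sqrt(1 - config@arPhi^2)
    u[1] <- stats::rnorm(1, 0, statSd)
    innov <- stats::rnorm(totalMonths, 0, config@arSd)
    for (m in seq_len(totalMonths)) u[m + 1] <- config@arPhi * u[m] + innov[m]
    mu + slope * (0:totalMonths) / 6 + u
}

# Monthly hospitalization hazard given the activity path.
monthlyHazard <- function(config, activity) {
    Tm <- length(activity) - 1
    m <- seq_len(Tm)
    delta <- activity[m + 1] - activity[pmax(m - 6, 0) + 1]
    sigmoid(config@hazardBase + config@betaLevel * activity[m + 1] +
            config@betaDelta * delta)
}

observeFeatures <- function(config, features, act) {
    n <- nrow(features)
    raw <- features$offset + features$loading * act
    vals <- numeric(n)
    lab <- features$type == "continuous"
    bin <- features$type == "binary"
    cnt <- features$type == "count"
    vals[lab] <- raw[lab] + stats::rnorm(sum(lab), 0, config@labNoiseSd)
    vals[bin] <- as.numeric(features$loading[bin] * act +
                            stats::rnorm(sum(bin), 0, 0.8) >
                            features$threshold[bin])
    vals[cnt] <- stats::rpois(sum(cnt),
                              exp(features$offset[cnt] +
                                  0.5 * features$loading[cnt] * act))
    vals
}

#' Generate a synthetic longitudinal lupus cohort
#'
#' Draws `nPatients` patient records under the latent-activity model
#' described in [cohortConfig()]. Generation is a pure function of the
#' configuration (including its seed): identical configurations yield
#' byte-identical cohorts, and the caller's RNG state is left
#' untouched.
#'
#' @param config a [CohortConfig-class].
#' @return an [SLECohort-class].
#' @examples
#' cohort <- generateCohort(cohortConfig(nPatients = 10, seed = 7))
#' cohort
#' @export
generateCohort <- function(config) {
    validObject(config)
    withSeed(config@seed, {
        features <- makeFeatureTable(config)
        patients <- lapply(seq_len(config@nPatients), function(i) {
            nb <- config@nObsBins
            if (config@variableLength)
                nb <- sample(seq(ceiling(config@nObsBins / 2),
                                 config@nObsBins), 1)
            totalMonths <- 6 * nb + config@followupMonths
            act <- simulateActivity(config, totalMonths)
            haz <- monthlyHazard(config, act)
            hit <- which(stats::runif(totalMonths) < haz)
            events <- if (length(hit)) hit - stats::runif(length(hit))
                      else numeric()
            nVisits <- stats::rpois(nb, config@visitRate)
            times <- sort(unlist(lapply(seq_len(nb), function(b)
                stats::runif(nVisits[b], 6 * (b - 1), 6 * b))))
            vals <- matrix(NA_real_, length(times), nrow(features),
                           dimnames = list(NULL, features$name))
            for (v in seq_along(times)) {
                row <- observeFeatures(config, features,
                                       act[floor(times[v]) + 1])
                row[stats::runif(nrow(features)) < config@missingProb] <- NA
                vals[v, ] <- row
            }
            demo <- c(age = stats::rnorm(1, 45, 13),
                      female = stats::rbinom(1, 1, 0.9),
                      nonwhite = stats::rbinom(1, 1, 0.35),
                      duration_years = stats::rexp(1, 1 / 8),
                      public_insurance = stats::rbinom(1, 1, 0.4))
            new("PatientRecord", patientId = sprintf("P%04d", i),
                demographics = demo, visitTimes = times, visitValues = vals,
                events = events, nObsBins = nb)
        })
        new("SLECohort", patients = patients, features = features,
            config = config)
    })
}

#' Did a hospitalization occur in a given interval?
#'
#' Uses the half-open convention `(start, start + horizon]`: an event
#' exactly at the interval's start belongs to the previous horizon, one
#' exactly at its end to this one, so consecutive label windows never
#' double-count an event.
#'
#' @param record a [PatientRecord-class], or a numeric vector of event
#'   times in months.
#' @param startMonths interval start (months from the patient origin).
#' @param horizonMonths interval length in months (> 0).
#' @return 1 if any event falls in the interval, else 0.
#' @examples
#' eventInInterval(c(10), 6, 6)   # 1: 6 < 10 <= 12
#' eventInInterval(c(10), 12, 3)  # 0
#' @export
eventInInterval <- function(record, startMonths, horizonMonths) {
    stopifnot(horizonMonths > 0)
    events <- if (is(record, "PatientRecord")) record@events else record
    as.integer(any(events > startMonths &
                   events <= startMonths + horizonMonths))
}

#' Cohort-level event prevalence at a horizon
#'
#' Fraction of patients with at least one hospitalization within
#' `horizonMonths` after `startMonths`.
#'
#' @param cohort an [SLECohort-class].
#' @inheritParams eventInInterval
#' @return numeric fraction in \[0, 1\].
#' @export
eventPrevalence <- function(cohort, startMonths, horizonMonths) {
    mean(vapply(cohort@patients, eventInInterval, integer(1),
                startMonths = startMonths, horizonMonths = horizonMonths))
}
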