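# Shared fixtures, built in code at test time.

tinyConfig <- function(nPatients = 25, seed = 101, ...) {
    cohortConfig(nPatients = nPatients, visitRate = 3, missingProb = 0.1,
                 seed = seed, ...)
}

tinyBinned <- function(...) {
    suppressWarnings(binCohort(generateCohort(tinyConfig(...))))
}

# A minimal feature annotation with one feature of each type.
toyFeatures <- function() {
    data.frame(name = c("lab_a", "flag_b", "count_c"),
               category = c("lab", "manifestation", "utilization"),
               type = c("continuous", "binary", "count"),
               stringsAsFactors = FALSE)
}

toyRecord <- function(times, values, events = numeric(), nObsBins = 2,
                      demographics = c(age = 50, female = 1, nonwhite = 0,
                                       duration_years = 5,
                                       public_insurance = 0)) {
    new("PatientRecord", patientId = "T001", demographics = demographics,
        visitTimes = times, visitValues = values, events = events,
        nObsBins = nObsBins)
}

# A RegularSeries with given value matrix (fully observed mask).
toySeries <- function(values, events = numeric(), id = "T001") {
    new("RegularSeries", patientId = id, binMonths = 6, values = values,
        observedMask = !is.na(values),
        demographics = c(age = 50, female = 1, nonwhite = 0,
                         duration_years = 5, public_insurance = 0),
        events = events)
}

# A WindowedDataset built directly from a list of k x p sequences.
toyWindowed <- function(seqs, labels, xMonths = 6 * nrow(seqs[[1]]),
                        yMonths = 6, demographics = NULL) {
    k <- nrow(seqs[[1]]); p <- ncol(seqs[[1]]); n <- length(seqs)
    arr <- array(0, dim = c(n, k, p),
                 dimnames = list(NULL, NULL, colnames(seqs[[1]])))
    for (i in seq_len(n)) arr[i, , ] <- seqs[[i]]
    if (is.null(demographics))
        demographics <- matrix(rep(c(50, 1, 0, 5, 0), each = n), n, 5,
                               dimnames = list(NULL,
                                   c("age", "female", "nonwhite",
                                     "duration_years", "public_insurance")))
    feats <- data.frame(name = dimnames(arr)[[3]],
                        category = "lab", type = "continuous",
                        stringsAsFactors = FALSE)
    if (is.null(feats$name)) feats$name <- sprintf("f%02d", seq_len(p))
    new("WindowedDataset", task = taskSpec(xMonths, yMonths),
        sequences = arr, demographics = demographics,
        labels = as.integer(labels),
        patientIds = sprintf("P%03d", seq_len(n)),
        startBins = rep(0L, n), features = feats)
}

# Linearly separable toy windows: class-1 sequences rise, class-0 fall.
separableWindowed <- function(n = 60, k = 2, p = 3, seed = 5) {
    set.seed(seed)
    labels <- sample(rep(0:1, length.out = n))
    seqs <- lapply(seq_len(n), function(i) {
        base <- matrix(rnorm(k * p, sd = 0.1), k, p,
                       dimnames = list(NULL, sprintf("f%02d", seq_len(p))))
        shift <- if (labels[i] == 1) seq(0, 3, length.out = k)
                 else seq(3, 0, length.out = k)
        base + shift
    })
    toyWindowed(seqs, labels)
}

# Independent scalar transcription of the LSTM gate equations for
# hidden size 1: weights are w = c(wh, wx) acting on (hPrev, x).
scalarLstmOracle <- function(wi, bi, wf, bf, wo, bo, wc, bc,
                             x, hPrev, cPrev) {
    sig <- function(v) 1 / (1 + exp(-v))
    i <- sig(wi[1] * hPrev + wi[2] * x + bi)
    f <- sig(wf[1] * hPrev + wf[2] * x + bf)
    o <- sig(wo[1] * hPrev + wo[2] * x + bo)
    ctil <- tanh(wc[1] * hPrev + wc[2] * x + bc)
    C <- f * cPrev + i * ctil
    list(h = o * tanh(C), C = C)
}

# Brute-force pairwise AUC: P(score_pos > score_neg) + 0.5 P(tie).
bruteForceAuc <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (sp in pos) for (sn in neg)
        tot <- tot + (sp > sn) + 0.5 * (sp == sn)
    tot / (length(pos) * length(neg))
}
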