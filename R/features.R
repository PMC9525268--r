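#' Build the Differential flat design matrix
#'
#' Lays every window instance out as a single feature vector:
#' demographics, the raw clinical features at each of the `k` steps,
#' and the lagged change (delta) variables between consecutive steps,
#' `delta@t = raw@t - raw@(t-1)`. With the default `"full"` layout the
#' column count is `p = 5 + 52 k + 52 (k - 1)`; the `"compact"` layout
#' keeps only the first step's raw features alongside the deltas
#' (`p = 5 + 52 + 52 (k - 1)`). For `k = 1` there are no delta
#' columns.
#'
#' @param wd a [WindowedDataset-class].
#' @param layout `"full"` (default) or `"compact"`.
#' @return a [DesignMatrix-class].
#' @export
buildDifferential <- function(wd, layout = c("full", "compact")) {
    layout <- match.arg(layout)
    k <- wd@task@k
    p <- dim(wd@sequences)[3]
    n <- nInstances(wd)
    fn <- wd@features$name
    dn <- colnames(wd@demographics)
    if (is.null(dn)) dn <- sprintf("demo_%d", seq_len(ncol(wd@demographics)))
    rawSteps <- if (layout == "full") seq_len(k) - 1L else 0L
    blocks <- list(wd@demographics)
    schema <- data.frame(name = dn, tag = "demographic", step = NA_integer_,
                         feature = dn, stringsAsFactors = FALSE)
    for (t in rawSteps) {
        blocks[[length(blocks) + 1L]] <- wd@sequences[, t + 1L, , drop = TRUE]
        schema <- rbind(schema, data.frame(
            name = sprintf("%s_t%d", fn, t), tag = "raw", step = t,
            feature = fn, stringsAsFactors = FALSE))
    }
    if (k > 1) for (t in seq_len(k - 1)) {
        blocks[[length(blocks) + 1L]] <-
            wd@sequences[, t + 1L, , drop = TRUE] -
            wd@sequences[, t, , drop = TRUE]
        schema <- rbind(schema, data.frame(
            name = sprintf("%s_d%d", fn, t), tag = "delta", step = t,
            feature = fn, stringsAsFactors = FALSE))
    }
    blocks <- lapply(blocks, function(b)
        if (is.null(dim(b))) matrix(b, nrow = n) else b)
    values <- do.call(cbind, blocks)
    colnames(values) <- schema$name
    rownames(values) <- NULL
    new("DesignMatrix", values = values, schema = schema,
        labels = wd@labels, k = k)
}

#' Build the LSTM equal-length sequence tensor
#'
#' `tensor[i, t, ]` is the 52 clinical features of instance `i` at step
#' `t` with the 5 static demographics appended, so every step carries
#' the same demographic tail and all sequences share length `k`. No
#' delta variables are included: the recurrent model is expected to
#' learn temporal dependencies itself.
#'
#' @param wd a [WindowedDataset-class].
#' @return a [SequenceTensor-class] of shape `n x k x 57`.
#' @export
buildLstmTensor <- function(wd) {
    k <- wd@task@k
    p <- dim(wd@sequences)[3]
    n <- nInstances(wd)
    d <- ncol(wd@demographics)
    dn <- colnames(wd@demographics)
    if (is.null(dn)) dn <- sprintf("demo_%d", seq_len(d))
    arr <- array(0, dim = c(n, k, p + d),
                 dimnames = list(NULL, NULL, c(wd@features$name, dn)))
    arr[, , seq_len(p)] <- wd@sequences
    for (t in seq_len(k)) arr[, t, p + seq_len(d)] <- wd@demographics
    new("SequenceTensor", values = arr, labels = wd@labels)
}

#' Fit / apply feature standardization
#'
#' `fitScaler()` learns per-column centering and scaling statistics on
#' training data only; `applyScaler()` applies them unchanged to any
#' other data, so no held-out information leaks into the transform.
#' Columns whose training values all lie in \{0, 1\} are treated as
#' binary and passed through; a zero-variance continuous column is
#' centered by its mean with scale 1. For a [SequenceTensor-class] (or
#' a 3-d array) statistics are per feature across instances and steps.
#'
#' @param x a [DesignMatrix-class], [SequenceTensor-class], matrix or
#'   3-d array (training data only).
#' @return `fitScaler()`: an object of class `"slehorizonScaler"`;
#'   `applyScaler()`: `x` with standardized numeric content (same
#'   class as the input).
#' @export
fitScaler <- function(x) {
    m <- scalerFlatten(x)
    center <- colMeans(m)
    scale <- apply(m, 2, stats::sd)
    binary <- apply(m, 2, function(col) all(col %in% c(0, 1)))
    center[binary] <- 0
    scale[binary] <- 1
    scale[!binary & (is.na(scale) | scale == 0)] <- 1
    structure(list(center = center, scale = scale, binary = binary),
              class = "slehorizonScaler")
}

#' @rdname fitScaler
#' @param scaler a fitted `"slehorizonScaler"`.
#' @export
applyScaler <- function(scaler, x) {
    stopifnot(inherits(scaler, "slehorizonScaler"))
    if (is(x, "DesignMatrix"))
        return(initialize(x, values = applyScaler(scaler, x@values)))
    if (is(x, "SequenceTensor"))
        return(initialize(x, values = applyScaler(scaler, x@values)))
    if (length(dim(x)) == 3) {
        for (j in seq_len(dim(x)[3]))
            x[, , j] <- (x[, , j] - scaler$center[j]) / scaler$scale[j]
        return(x)
    }
    sweep(sweep(x, 2, scaler$center), 2, scaler$scale, "/")
}

scalerFlatten <- function(x) {
    if (is(x, "DesignMatrix")) return(x@values)
    if (is(x, "SequenceTensor")) x <- x@values
    if (length(dim(x)) == 3) {
        m <- matrix(x, nrow = dim(x)[1] * dim(x)[2])
        colnames(m) <- dimnames(x)[[3]]
        return(m)
    }
    x
}

#' Write a design matrix as CSV with its schema
#'
#' The CSV header is the schema's column names with a final `label`
#' column; the schema itself (tags, steps, source features) goes to a
#' companion CSV so the layout round-trips in order.
#'
#' @param dm a [DesignMatrix-class].
#' @param path CSV path; schema goes to `paste0(path, ".schema.csv")`.
#' @return `path`, invisibly.
#' @export
writeDesignMatrix <- function(dm, path) {
    utils::write.csv(data.frame(dm@values, label = dm@labels,
                                check.names = FALSE),
                     path, row.names = FALSE)
    utils::write.csv(dm@schema, paste0(path, ".schema.csv"),
                     row.names = FALSE)
    invisible(path)
}

#' @rdname writeDesignMatrix
#' @export
readDesignMatrix <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE)
    schema <- utils::read.csv(paste0(path, ".schema.csv"),
                              stringsAsFactors = FALSE)
    vals <- as.matrix(df[, schema$name, drop = FALSE])
    rownames(vals) <- NULL
    k <- if (any(schema$tag == "raw"))
        max(schema$step[schema$tag == "raw"], 1) + 1 else 1
    if (any(schema$tag == "delta"))
        k <- max(k, max(schema$step[schema$tag == "delta"]) + 1)
    new("DesignMatrix", values = vals, schema = schema,
        labels = as.integer(df$label), k = k)
}
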