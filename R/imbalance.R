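#' Balanced bootstrap bags (bagging with random undersampling)
#'
#' Builds `nBags` balanced training sets from an imbalanced labeled
#' dataset: every bag contains *all* minority-class indices exactly
#' once, plus an equal number of majority-class indices sampled with
#' replacement from the entire majority population. Each bag is thus
#' exactly 50/50 and of size twice the minority count. Sub-models
#' fitted on the bags are later aggregated by averaging their class-1
#' probabilities ([fitBaggedEnsemble()]).
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param nBags number of bags (default 100).
#' @param seed RNG seed; bags are reproducible given the seed.
#' @return a [BagSet-class].
#' @export
makeBags <- function(labels, nBags = 100, seed = 1) {
    tab <- table(factor(labels, levels = c(0, 1)))
    if (any(tab == 0)) stop("both classes must be present to form bags")
    minorityClass <- if (tab["1"] <= tab["0"]) 1 else 0
    minority <- which(labels == minorityClass)
    majority <- which(labels != minorityClass)
    m <- length(minority)
    bags <- withSeed(seed, lapply(seq_len(nBags), function(i)
        c(minority, sample(majority, m, replace = TRUE))))
    new("BagSet", bags = bags, minority = as.integer(minority), seed = seed)
}

#' Minority oversampling by duplication
#'
#' Balances a labeled dataset by repeating each minority instance
#' `r - 1` extra times, where `r` is the majority-to-minority count
#' ratio rounded to the nearest integer (ties round half to even;
#' `rounding = "floor"` truncates instead). The output index multiset
#' contains every majority index once and every minority index `r`
#' times; no sampling is involved, so the result is deterministic.
#' Apply it to training folds only — never to evaluation data.
#'
#' @param labels 0/1 vector (both classes must be present).
#' @param rounding how to integerize a non-integer ratio.
#' @return integer index multiset into the input.
#' @export
oversampleIndices <- function(labels, rounding = c("even", "floor")) {
    rounding <- match.arg(rounding)
    tab <- table(factor(labels, levels = c(0, 1)))
    if (any(tab == 0)) stop("both classes must be present to oversample")
    minorityClass <- if (tab["1"] <= tab["0"]) 1 else 0
    minority <- which(labels == minorityClass)
    majority <- which(labels != minorityClass)
    ratio <- length(majority) / length(minority)
    r <- if (rounding == "even") round(ratio) else floor(ratio)
    r <- max(1L, as.integer(r))
    sort(c(majority, rep(minority, r)))
}

#' Serialize / restore a BagSet as JSON
#'
#' Exact integer index lists plus the seed, for byte-identical reruns.
#'
#' @param bagset a [BagSet-class].
#' @param path JSON file path.
#' @return `writeBagSet()` returns `path` invisibly; `readBagSet()`
#'   the restored [BagSet-class].
#' @export
writeBagSet <- function(bagset, path) {
    jsonlite::write_json(list(bags = bagset@bags,
                              minority = bagset@minority,
                              seed = bagset@seed),
                         path, digits = NA)
    invisible(path)
}

#' @rdname writeBagSet
#' @export
readBagSet <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    bags <- x$bags
    if (is.matrix(bags)) bags <- lapply(seq_len(nrow(bags)), function(i)
        as.integer(bags[i, ]))
    else bags <- lapply(bags, as.integer)
    new("BagSet", bags = bags, minority = as.integer(x$minority),
        seed = as.numeric(x$seed))
}
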