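#' Acquisition configuration
#'
#' Parameters of the dual-criterion batch selection: per selection event,
#' \code{nExploit} compounds predicted most active among the
#' \code{coveragePool} best-covered (least novel) candidates, plus
#' \code{nInformative} compounds predicted least active among those highly
#' similar to a potent training nearest neighbor.
#'
#' @param nExploit exploit batch size (default 10).
#' @param nInformative informative batch size (default 10).
#' @param coveragePool size of the low-novelty pool the exploit picks are
#'   drawn from (default 200).
#' @param nnTopK candidates ranked within the top \code{nnTopK} by NN
#'   similarity qualify for the informative rule (default 100).
#' @param nnSimThreshold absolute NN-similarity qualification threshold,
#'   inclusive (default 0.85).
#' @param nnActivityThreshold required experimental activity of the NN
#'   training molecule, inclusive, pIC50 (default 8.5).
#' @return A classed list of settings.
#' @export
acquisitionConfig <- function(nExploit = 10L, nInformative = 10L,
                              coveragePool = 200L, nnTopK = 100L,
                              nnSimThreshold = 0.85,
                              nnActivityThreshold = 8.5) {
    for (nm in c("nExploit", "nInformative", "coveragePool", "nnTopK"))
        stopIfNotScalarCount(get(nm), nm)
    if (!is.finite(nnSimThreshold) || nnSimThreshold < 0 ||
        nnSimThreshold > 1)
        stop("nnSimThreshold must be in [0, 1]")
    if (!is.finite(nnActivityThreshold))
        stop("nnActivityThreshold must be finite")
    structure(list(nExploit = as.integer(nExploit),
                   nInformative = as.integer(nInformative),
                   coveragePool = as.integer(coveragePool),
                   nnTopK = as.integer(nnTopK),
                   nnSimThreshold = nnSimThreshold,
                   nnActivityThreshold = nnActivityThreshold),
              class = "AcquisitionConfig")
}

checkPredictions <- function(predictions) {
    need <- c("id", "orderIndex", "predicted", "novelty", "nnId", "nnSim")
    if (!is.data.frame(predictions) || !all(need %in% names(predictions)))
        stop("predictions must be a data.frame with columns ",
             paste(need, collapse = ", "))
    if (nrow(predictions) == 0L) stop("predictions must be non-empty")
    invisible(predictions)
}

#' Exploit selection: predicted-most-active among the best covered
#'
#' Restricts to the \code{coveragePool} least novel (best-covered) candidate
#' predictions, then returns the \code{nExploit} with the highest predicted
#' activity, in descending predicted order. All ties are broken toward the
#' smaller synthesis-order index, making the selection invariant to input
#' permutation.
#'
#' @param predictions a prediction \code{data.frame} from
#'   [scoreCandidates()].
#' @param cfg an [acquisitionConfig()].
#' @return Ordered character vector of selected ids.
#' @export
selectExploit <- function(predictions, cfg = acquisitionConfig()) {
    checkPredictions(predictions)
    pool <- predictions[order(predictions$novelty, predictions$orderIndex), ]
    pool <- pool[seq_len(min(cfg$coveragePool, nrow(pool))), ]
    pick <- pool[order(-pool$predicted, pool$orderIndex), ]
    pick$id[seq_len(min(cfg$nExploit, nrow(pick)))]
}

#' Informative selection: surprisingly weak predictions near potent neighbors
#'
#' A candidate is eligible when (its NN-similarity rank within the full
#' prediction set is at most \code{nnTopK} OR its NN similarity is at least
#' \code{nnSimThreshold}) AND its nearest training neighbor's experimental
#' activity is at least \code{nnActivityThreshold}. From the eligible
#' candidates not in \code{excluded}, the \code{nInformative} with the lowest
#' predicted activity are returned in ascending predicted order (ties toward
#' the smaller order index). The similarity rank is computed on the full
#' candidate set before the exclusion is applied.
#'
#' @inheritParams selectExploit
#' @param train the current training [CompoundSet-class]; every \code{nnId}
#'   must resolve in it.
#' @param excluded ids to exclude (typically the exploit picks).
#' @return Ordered character vector of selected ids (possibly shorter than
#'   \code{nInformative}, or empty, when few candidates qualify).
#' @export
selectInformative <- function(predictions, train,
                              cfg = acquisitionConfig(),
                              excluded = character()) {
    checkPredictions(predictions)
    trainAct <- activities(train)
    if (!all(predictions$nnId %in% names(trainAct)))
        stop("data error: nn train id(s) not found in training set: ",
             paste(unique(setdiff(predictions$nnId, names(trainAct))),
                   collapse = ", "))
    simRank <- integer(nrow(predictions))
    simRank[order(-predictions$nnSim, predictions$orderIndex)] <-
        seq_len(nrow(predictions))
    eligible <- (simRank <= cfg$nnTopK |
                 predictions$nnSim >= cfg$nnSimThreshold) &
        unname(trainAct[predictions$nnId]) >= cfg$nnActivityThreshold &
        !(predictions$id %in% excluded)
    el <- predictions[eligible, ]
    if (nrow(el) == 0L) return(character())
    pick <- el[order(el$predicted, el$orderIndex), ]
    pick$id[seq_len(min(cfg$nInformative, nrow(pick)))]
}

#' One full round of dual-criterion selection
#'
#' Applies [selectExploit()] first, then [selectInformative()] on the
#' remaining candidates, so a compound qualifying for both rules is acquired
#' once, as an exploit pick. The two lists are disjoint by construction.
#'
#' @inheritParams selectInformative
#' @return A list with components \code{exploit} and \code{informative}
#'   (ordered id vectors), of class \code{SelectionResult}.
#' @export
selectRound <- function(predictions, train, cfg = acquisitionConfig()) {
    ex <- selectExploit(predictions, cfg)
    inf <- selectInformative(predictions, train, cfg, excluded = ex)
    structure(list(exploit = ex, informative = inf),
              class = "SelectionResult")
}

#' Random-acquisition baseline selector
#'
#' Uniform sample of candidate ids, used as the comparison arm for
#' benchmarking the dual-criterion strategy. Not part of the modeled
#' selection procedure.
#'
#' @param predictions a prediction \code{data.frame}.
#' @param n batch size (default 20).
#' @param seed RNG seed.
#' @return A \code{SelectionResult} whose \code{exploit} component carries
#'   the sample and whose \code{informative} component is empty.
#' @export
selectRandomBaseline <- function(predictions, n = 20L, seed = 1L) {
    checkPredictions(predictions)
    ids <- withSeed(seed,
        sample(predictions$id, size = min(n, nrow(predictions))))
    structure(list(exploit = ids, informative = character()),
              class = "SelectionResult")
}

#' Pick structurally diverse actives
#'
#' From the compounds within the top \code{window} log units of the maximum
#' experimental activity, greedily picks a maximally 2D-diverse subset under
#' the max-min criterion on distance 1 - Tanimoto: the selection is seeded
#' with the most active eligible compound, then repeatedly extended with the
#' eligible compound whose minimum distance to the chosen set is largest.
#' Ties at every step are broken toward the smaller order index, so the
#' result is invariant to input order. Used to choose the diverse active
#' ligands that anchor an initial alignment hypothesis.
#'
#' @param data a non-empty [CompoundSet-class].
#' @param window activity window below the maximum, log units (default 1.0).
#' @param k number of compounds to pick (default 4).
#' @return Ordered character vector of min(k, number eligible) ids, in
#'   selection order.
#' @export
pickDiverseActives <- function(data, window = 1.0, k = 4L) {
    if (length(data) == 0L) stop("data must be non-empty")
    if (window < 0) stop("window must be >= 0")
    if (k < 1L) stop("k must be >= 1")
    act <- unname(activities(data))
    elig <- which(act >= max(act) - window)
    ids <- compoundIds(data)[elig]
    ord <- orderIndex(data)[elig]
    a <- act[elig]
    D <- 1 - tanimotoMatrix(fingerprints(data)[elig, , drop = FALSE],
                            fingerprints(data)[elig, , drop = FALSE])
    chosen <- integer()
    seedIdx <- order(-a, ord)[1L]
    chosen <- seedIdx
    while (length(chosen) < min(k, length(elig))) {
        rest <- setdiff(seq_along(elig), chosen)
        minD <- apply(D[rest, chosen, drop = FALSE], 1L, min)
        nxt <- rest[order(-minD, ord[rest])[1L]]
        chosen <- c(chosen, nxt)
    }
    ids[chosen]
}
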