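#' CompoundSet: a time-stamped, fingerprinted structure-activity table
#'
#' Container for one lead-optimization dataset. Each record carries a unique
#' compound id, a synthesis-order index (temporal surrogate), a binary
#' structural fingerprint and an experimental activity in pIC50 units.
#' Records are always stored sorted ascending by order index, which makes the
#' temporal train/future split a simple prefix cut.
#'
#' @slot ids character, unique compound identifiers.
#' @slot orderIndex integer, unique synthesis-order indices (>= 1).
#' @slot activity numeric, finite pIC50 values.
#' @slot isGoal logical, flags the campaign goal compound (at most a handful,
#'   typically one).
#' @slot fingerprints 0/1 numeric matrix, one row per compound; all rows share
#'   the same length and every row has at least one set bit.
#'
#' @seealso [CompoundSet()] for the user constructor,
#'   [readCompoundTable()], [readSdf()], [temporalSplit()].
#' @export
setClass("CompoundSet",
    representation(
        ids = "character",
        orderIndex = "integer",
        activity = "numeric",
        isGoal = "logical",
        fingerprints = "matrix"
    )
)

setValidity("CompoundSet", function(object) {
    n <- length(object@ids)
    msg <- character()
    if (length(object@orderIndex) != n || length(object@activity) != n ||
        length(object@isGoal) != n || nrow(object@fingerprints) != n)
        msg <- c(msg, "slot lengths disagree")
    if (anyDuplicated(object@ids))
        msg <- c(msg, sprintf("duplicated compound id '%s'",
                              object@ids[duplicated(object@ids)][1L]))
    if (anyDuplicated(object@orderIndex))
        msg <- c(msg, "duplicated order index")
    if (n > 1L && is.unsorted(object@orderIndex))
        msg <- c(msg, "records must be sorted ascending by order index")
    if (n > 0L) {
        if (any(!is.finite(object@activity)))
            msg <- c(msg, "activities must be finite")
        if (any(object@orderIndex < 1L))
            msg <- c(msg, "order indices must be >= 1")
        if (!all(object@fingerprints %in% c(0, 1)))
            msg <- c(msg, "fingerprints must be 0/1")
        else if (any(rowSums(object@fingerprints) < 1))
            msg <- c(msg, "every fingerprint needs at least one set bit")
    }
    if (length(msg)) msg else TRUE
})

#' SurrogateModel: a fitted baseline affinity predictor
#'
#' Stands in for an engine-specific 3D-QSAR model behind a minimal contract:
#' fit on a training [CompoundSet], then score candidates to get predicted
#' activity plus novelty / nearest-neighbor diagnostics. Two variants are
#' provided: \code{"kernel"} (similarity-weighted k-nearest-neighbor average,
#' convex so never out-of-range) and \code{"additive"} (ridge regression on
#' fingerprint bits, which can extrapolate beyond the training activity
#' range).
#'
#' @slot train the training [CompoundSet].
#' @slot variant \code{"kernel"} or \code{"additive"}.
#' @slot gamma numeric, kernel similarity exponent (> 0).
#' @slot k integer, kernel neighbor count (>= 1).
#' @slot lambda numeric, ridge strength for the additive variant (>= 0).
#' @slot seed integer, fit seed (kept for provenance; both baselines are
#'   deterministic given the training data).
#' @slot coef numeric, additive-variant coefficients (intercept first);
#'   length zero for the kernel variant.
#'
#' @seealso [fitSurrogate()], [scoreCandidates()], [refitMetrics()].
#' @export
setClass("SurrogateModel",
    representation(
        train = "CompoundSet",
        variant = "character",
        gamma = "numeric",
        k = "integer",
        lambda = "numeric",
        seed = "integer",
        coef = "numeric"
    )
)

setValidity("SurrogateModel", function(object) {
    msg <- character()
    if (length(object@train) < 2L)
        msg <- c(msg, "training set must contain at least two compounds")
    if (!object@variant %in% c("kernel", "additive"))
        msg <- c(msg, "variant must be 'kernel' or 'additive'")
    if (object@gamma <= 0) msg <- c(msg, "gamma must be positive")
    if (object@k < 1L) msg <- c(msg, "k must be >= 1")
    if (object@lambda < 0) msg <- c(msg, "lambda must be >= 0")
    if (length(msg)) msg else TRUE
})
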