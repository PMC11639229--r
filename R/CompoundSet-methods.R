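#' Construct a CompoundSet
#'
#' Records are re-sorted ascending by \code{orderIndex}; validity (unique ids
#' and order indices, finite activities, non-empty equal-length fingerprints)
#' is enforced.
#'
#' @param ids character vector of unique compound ids.
#' @param orderIndex integer vector of unique synthesis-order indices.
#' @param activity numeric pIC50 values.
#' @param fingerprints 0/1 matrix, one row per compound.
#' @param isGoal logical goal-compound flags (default all \code{FALSE}).
#' @return A [CompoundSet-class] object.
#' @examples
#' fp <- matrix(c(1, 0, 1, 1, 1, 0), nrow = 2, byrow = TRUE)
#' cs <- CompoundSet(c("a", "b"), c(2L, 1L), c(7.1, 6.4), fp)
#' compoundIds(cs)  # sorted by order index: "b", "a"
#' @export
CompoundSet <- function(ids, orderIndex, activity, fingerprints,
                        isGoal = rep(FALSE, length(ids))) {
    ids <- as.character(ids)
    orderIndex <- as.integer(orderIndex)
    activity <- as.numeric(activity)
    isGoal <- as.logical(isGoal)
    fingerprints <- as.matrix(fingerprints)
    storage.mode(fingerprints) <- "numeric"
    if (length(ids) > 0L) {
        o <- order(orderIndex)
        ids <- ids[o]; orderIndex <- orderIndex[o]
        activity <- activity[o]; isGoal <- isGoal[o]
        fingerprints <- fingerprints[o, , drop = FALSE]
    }
    rownames(fingerprints) <- ids
    methods::new("CompoundSet", ids = ids, orderIndex = orderIndex,
                 activity = activity, isGoal = isGoal,
                 fingerprints = fingerprints)
}

#' Accessors for CompoundSet
#'
#' @param x a [CompoundSet-class].
#' @return \code{compoundIds}: character ids; \code{orderIndex}: integer
#'   order indices; \code{activities}: numeric pIC50; \code{isGoal}: logical
#'   flags; \code{fingerprints}: the 0/1 matrix; \code{descriptorLength}:
#'   number of fingerprint bits; \code{goalId}: id of the flagged goal
#'   compound or \code{NA} if none.
#' @name CompoundSet-accessors
NULL

#' @rdname CompoundSet-accessors
#' @export
setMethod("compoundIds", "CompoundSet", function(x) x@ids)

#' @rdname CompoundSet-accessors
#' @export
setMethod("orderIndex", "CompoundSet", function(x) x@orderIndex)

#' @rdname CompoundSet-accessors
#' @export
setMethod("activities", "CompoundSet", function(x) {
    stats::setNames(x@activity, x@ids)
})

#' @rdname CompoundSet-accessors
#' @export
setMethod("isGoal", "CompoundSet", function(x) x@isGoal)

#' @rdname CompoundSet-accessors
#' @export
setMethod("fingerprints", "CompoundSet", function(x) x@fingerprints)

#' @rdname CompoundSet-accessors
#' @export
setMethod("descriptorLength", "CompoundSet", function(x) ncol(x@fingerprints))

#' @rdname CompoundSet-accessors
#' @export
setMethod("goalId", "CompoundSet", function(x) {
    g <- x@ids[x@isGoal]
    if (length(g)) g[1L] else NA_character_
})

#' @describeIn CompoundSet-accessors number of compounds.
#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' Subset a CompoundSet
#'
#' @param x a [CompoundSet-class].
#' @param i integer, logical or character (compound id) index.
#' @param j,...,drop ignored.
#' @return A [CompoundSet-class] with the selected records (re-sorted by
#'   order index).
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) {
        ii <- match(i, x@ids)
        if (anyNA(ii))
            stop("unknown compound id(s): ",
                 paste(i[is.na(ii)], collapse = ", "))
        i <- ii
    }
    CompoundSet(x@ids[i], x@orderIndex[i], x@activity[i],
                x@fingerprints[i, , drop = FALSE], x@isGoal[i])
})

#' Concatenate CompoundSets
#'
#' @param x a [CompoundSet-class].
#' @param ... further CompoundSets with the same descriptor length.
#' @return The merged, order-sorted [CompoundSet-class].
#' @export
setMethod("c", "CompoundSet", function(x, ...) {
    sets <- c(list(x), list(...))
    CompoundSet(
        unlist(lapply(sets, compoundIds)),
        unlist(lapply(sets, orderIndex)),
        unlist(lapply(sets, function(s) unname(activities(s)))),
        do.call(rbind, lapply(sets, fingerprints)),
        unlist(lapply(sets, isGoal))
    )
})

#' @describeIn CompoundSet-accessors data.frame view (id, orderIndex,
#'   activity, isGoal, bits as a packed "0101..." string).
#' @param row.names,optional,... passed conventions of the generic; ignored.
#' @export
setMethod("as.data.frame", "CompoundSet",
    function(x, row.names = NULL, optional = FALSE, ...) {
        data.frame(
            id = x@ids,
            orderIndex = x@orderIndex,
            activity = x@activity,
            isGoal = x@isGoal,
            bits = apply(x@fingerprints, 1L, paste, collapse = ""),
            stringsAsFactors = FALSE, row.names = NULL
        )
    })

setMethod("show", "CompoundSet", function(object) {
    n <- length(object)
    cat("CompoundSet with", n, "compounds,",
        descriptorLength(object), "fingerprint bits\n")
    if (n > 0L) {
        cat(sprintf("  order index: %d..%d | pIC50: %.2f..%.2f\n",
                    min(object@orderIndex), max(object@orderIndex),
                    min(object@activity), max(object@activity)))
        if (any(object@isGoal))
            cat("  goal compound:", goalId(object), "\n")
    }
})

setMethod("show", "SurrogateModel", function(object) {
    cat(sprintf("SurrogateModel (%s variant), trained on %d compounds\n",
                object@variant, length(object@train)))
    cat(sprintf("  gamma = %g, k = %d, lambda = %g, seed = %d\n",
                object@gamma, object@k, object@lambda, object@seed))
})
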