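#' @rdname CompoundSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("orderIndex", function(x) standardGeneric("orderIndex"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("isGoal", function(x) standardGeneric("isGoal"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("fingerprints", function(x) standardGeneric("fingerprints"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("descriptorLength", function(x) standardGeneric("descriptorLength"))

#' @rdname CompoundSet-accessors
#' @export
setGeneric("goalId", function(x) standardGeneric("goalId"))

#' Score candidate compounds with a fitted surrogate model
#'
#' @param model a fitted [SurrogateModel].
#' @param candidates a non-empty [CompoundSet] whose descriptor length matches
#'   the model's training set.
#' @return A \code{data.frame} of prediction records, one row per candidate in
#'   input order: \code{id}, \code{orderIndex}, \code{predicted} (pIC50),
#'   \code{novelty} (1 - max training similarity), \code{nnId} (nearest
#'   training neighbor, ties broken toward the smallest order index) and
#'   \code{nnSim}.
#' @export
setGeneric("scoreCandidates",
    function(model, candidates) standardGeneric("scoreCandidates"))

#' Training-set refit quality metrics
#'
#' Re-scores the training compounds with the fitted model and summarizes the
#' refit as the triple used for probabilistic model selection: parsimony P,
#' Kendall's tau T and mean unsigned error E (see [probabilityScores()]).
#'
#' Parsimony is a descriptor-space concordance measure: Kendall's tau between
#' pairwise activity differences |y_i - y_j| and pairwise structural distances
#' 1 - Tanimoto(i, j) over training pairs, rescaled to [0, 1] as
#' (tau + 1) / 2. When a training set has more than 10^4 pairs a deterministic
#' evenly-spaced subsample of 10^4 pairs is used.
#'
#' @param model a fitted [SurrogateModel].
#' @return A one-row \code{data.frame} with columns \code{parsimony},
#'   \code{tau}, \code{mue}.
#' @export
setGeneric("refitMetrics", function(model) standardGeneric("refitMetrics"))
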