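#' Probabilistic multi-metric model scores
#'
#' Converts the (parsimony P, refit tau T, refit MUE E) triples of N
#' alternative models into per-metric probability scores and their product.
#' For each metric column a normal distribution is fit across the N models
#' (population standard deviation, N denominator) and each value is mapped
#' through the normal CDF \eqn{\Phi}: \eqn{p = \Phi((x - \mu)/\sigma)} for
#' parsimony and tau (higher is better) and \eqn{p = 1 - \Phi((x -
#' \mu)/\sigma)} for MUE (lower is better). A degenerate column (\eqn{\sigma
#' = 0}) contributes p = 0.5 for every model. The combined score of model i
#' is the product of its three probabilities.
#'
#' Because each column is z-scored, the scores — and hence the selection —
#' are invariant to a positive affine transformation applied uniformly to
#' any one metric column; for the same reason the sample-vs-population
#' \eqn{\sigma} choice cannot change which model is selected.
#'
#' @param metrics a \code{data.frame} with columns \code{parsimony},
#'   \code{tau}, \code{mue}, one row per model (N >= 2), as returned by
#'   [refitMetrics()].
#' @return A \code{data.frame} with columns \code{pParsimony}, \code{pTau},
#'   \code{pMue}, \code{combined}.
#' @examples
#' m <- data.frame(parsimony = c(0.6, 0.5, 0.4),
#'                 tau = c(0.8, 0.7, 0.6), mue = c(0.3, 0.4, 0.5))
#' probabilityScores(m)
#' @export
probabilityScores <- function(metrics) {
    need <- c("parsimony", "tau", "mue")
    if (!is.data.frame(metrics) || !all(need %in% names(metrics)))
        stop("metrics must be a data.frame with columns ",
             paste(need, collapse = ", "))
    n <- nrow(metrics)
    if (n < 2L) stop("at least two alternative models are required")
    pcol <- function(x, higherBetter) {
        mu <- mean(x)
        sigma <- sqrt(mean((x - mu)^2))  # population sd
        if (sigma == 0) return(rep(0.5, n))
        p <- stats::pnorm((x - mu) / sigma)
        if (higherBetter) p else 1 - p
    }
    out <- data.frame(
        pParsimony = pcol(metrics$parsimony, TRUE),
        pTau = pcol(metrics$tau, TRUE),
        pMue = pcol(metrics$mue, FALSE)
    )
    out$combined <- out$pParsimony * out$pTau * out$pMue
    out
}

#' Select the best of N alternative models
#'
#' Argmax of the combined probabilistic score from [probabilityScores()];
#' ties go to the smallest index.
#'
#' @inheritParams probabilityScores
#' @return Integer index (1-based) of the selected model.
#' @export
selectBestModel <- function(metrics) {
    which.max(probabilityScores(metrics)$combined)
}

#' ROC area under the curve (Mann-Whitney formulation)
#'
#' AUC = (number of (positive, negative) score pairs where the positive
#' scores higher + half the tied pairs) / (number of positives x number of
#' negatives), computed via mean ranks so ties are handled exactly.
#'
#' @param scores numeric scores, higher = more active.
#' @param labels binary labels (logical or 0/1); both classes must be
#'   present.
#' @return AUC in [0, 1].
#' @examples
#' rocArea(c(3, 2, 1, 0), c(1, 1, 0, 0))  # 1
#' @export
rocArea <- function(scores, labels) {
    labels <- as.logical(labels)
    if (length(scores) != length(labels))
        stop("scores and labels must have equal length")
    nPos <- sum(labels); nNeg <- sum(!labels)
    if (nPos == 0L || nNeg == 0L)
        stop("both classes must be present")
    r <- rank(scores)  # mean ranks: ties contribute 1/2
    (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Rank alignment hypotheses by active/inactive separation
#'
#' Labels compounds as active (activity >= \code{hi}) or inactive (activity
#' <= \code{lo}), drops the intermediate band, and ranks the supplied
#' per-hypothesis score vectors by their ROC area for separating the two
#' classes. How the scores are produced is up to the caller (e.g. similarity
#' of each compound to the hypothesis's ligand set).
#'
#' @param hypothesisScores a list (or matrix with hypotheses in columns) of
#'   numeric score vectors over the same compounds.
#' @param activity numeric pIC50 per compound.
#' @param hi active threshold, inclusive (default 8.5).
#' @param lo inactive threshold, inclusive (default 7.5).
#' @return A \code{data.frame} with columns \code{hypothesis} (index into
#'   the input), \code{auc}, ordered by decreasing AUC (ties keep input
#'   order).
#' @export
rankHypotheses <- function(hypothesisScores, activity, hi = 8.5, lo = 7.5) {
    if (is.matrix(hypothesisScores))
        hypothesisScores <- asplit(hypothesisScores, 2L)
    keep <- activity >= hi | activity <= lo
    lab <- activity[keep] >= hi
    if (!any(lab) || all(lab))
        stop("need at least one active (>= hi) and one inactive (<= lo) ",
             "compound after excluding the intermediate band")
    auc <- vapply(hypothesisScores, function(s) {
        if (length(s) != length(activity))
            stop("score vector length must match activity length")
        rocArea(s[keep], lab)
    }, numeric(1))
    ord <- order(-auc)  # stable: ties keep input order
    data.frame(hypothesis = ord, auc = auc[ord], row.names = NULL)
}
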