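#' Kendall's tau-b with p-value
#'
#' Tie-corrected rank correlation between predicted and observed activities,
#' computed in O(n log n) (Knight's algorithm). The two-sided p-value uses
#' the exact permutation distribution for small tie-free samples (n <= 33)
#' and the tie-corrected normal approximation otherwise.
#'
#' @param pred,obs numeric vectors of equal length (>= 2).
#' @return A list with elements \code{tau} and \code{p}.
#' @examples
#' kendallTau(1:5, c(1, 2, 3, 5, 4))
#' @export
kendallTau <- function(pred, obs) {
    if (length(pred) != length(obs))
        stop("pred and obs must have equal length")
    if (length(pred) < 2L) stop("need at least two observations")
    tau <- tau_b_knight(as.numeric(pred), as.numeric(obs))
    hasTies <- anyDuplicated(pred) > 0L || anyDuplicated(obs) > 0L
    exact <- length(pred) <= 33L && !hasTies
    ct <- suppressWarnings(
        stats::cor.test(as.numeric(pred), as.numeric(obs),
                        method = "kendall", exact = exact))
    list(tau = tau, p = unname(ct$p.value))
}

#' Mean unsigned error
#'
#' @param pred,obs numeric vectors of equal length (>= 1), pIC50 units.
#' @return Mean of |pred - obs|.
#' @export
mue <- function(pred, obs) {
    if (length(pred) != length(obs))
        stop("pred and obs must have equal length")
    if (length(pred) < 1L) stop("need at least one observation")
    mean(abs(pred - obs))
}

#' Bootstrap percentile confidence interval for tau or MUE
#'
#' Resamples (pred, obs) index pairs with replacement \code{nBoot} times and
#' returns the percentile interval of the statistic. Deterministic given
#' \code{seed}; a degenerate statistic across all resamples collapses the
#' interval to a point.
#'
#' @param statistic \code{"tau"} or \code{"mue"}.
#' @param pred,obs numeric vectors of equal length (>= 2).
#' @param nBoot number of resamples (default 1000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed (default 1).
#' @return Numeric \code{c(lo, hi)}.
#' @export
bootstrapCi <- function(statistic = c("tau", "mue"), pred, obs,
                        nBoot = 1000L, level = 0.95, seed = 1L) {
    statistic <- match.arg(statistic)
    if (length(pred) != length(obs))
        stop("pred and obs must have equal length")
    n <- length(pred)
    if (n < 2L) stop("need at least two observations")
    pred <- as.numeric(pred); obs <- as.numeric(obs)
    fn <- if (statistic == "tau") {
        function(i) {
            t <- tau_b_knight(pred[i], obs[i])
            if (is.nan(t)) 0 else t
        }
    } else {
        function(i) mean(abs(pred[i] - obs[i]))
    }
    stats <- withSeed(seed, {
        vapply(seq_len(nBoot),
               function(b) fn(sample.int(n, n, replace = TRUE)),
               numeric(1))
    })
    alpha <- (1 - level) / 2
    unname(stats::quantile(stats, c(alpha, 1 - alpha)))
}

#' kcal/mol error-bin percentages
#'
#' Converts signed prediction errors (pred - obs, pIC50) to kcal/mol at the
#' project's 4/3 kcal per log-unit equivalence and bins them: within 1
#' kcal/mol (|e| <= 1, inclusive), within 2 kcal/mol (|e| <= 2, inclusive),
#' underpredictions (e < -2, strict) and overpredictions (e > 2, strict).
#' The last three always partition: within-2 + under + over = 100.
#'
#' @param pred,obs numeric vectors of equal length (>= 1), pIC50 units.
#' @return Named numeric vector with \code{pctWithin1}, \code{pctWithin2},
#'   \code{pctUnder}, \code{pctOver} (percentages of n, full precision).
#' @examples
#' errorBins(c(7.5, 6.2, 9.0, 5.4), c(7.0, 7.0, 7.0, 7.0))
#' @export
errorBins <- function(pred, obs) {
    if (length(pred) != length(obs))
        stop("pred and obs must have equal length")
    if (length(pred) < 1L) stop("need at least one observation")
    e <- kcalFromPic50(pred - obs)
    c(pctWithin1 = 100 * mean(abs(e) <= 1),
      pctWithin2 = 100 * mean(abs(e) <= 2),
      pctUnder = 100 * mean(e < -2),
      pctOver = 100 * mean(e > 2))
}

#' Percentile rank of the goal compound's prediction
#'
#' Rank of the goal among all candidate predictions by descending predicted
#' activity (ties broken toward the smaller order index), expressed as a
#' top-percent: 100 * rank / n. 1.0 means the goal is predicted most active
#' of 100 candidates. Kept at full precision; round only for reporting.
#'
#' @param goalId the goal compound id.
#' @param predictions a prediction \code{data.frame} from
#'   [scoreCandidates()].
#' @return A value in (0, 100].
#' @export
rankTopPercent <- function(goalId, predictions) {
    checkPredictions(predictions)
    pos <- order(-predictions$predicted, predictions$orderIndex)
    r <- which(predictions$id[pos] == goalId)
    if (length(r) != 1L)
        stop("goal compound '", goalId, "' not among the predictions")
    100 * r / nrow(predictions)
}

#' Assemble one campaign round report
#'
#' One row of the per-round campaign summary: training refit tau and MUE and
#' future-set tau and MUE with bootstrap 95% confidence intervals, kcal/mol
#' error-bin percentages on the future set, and the goal compound's
#' predicted activity and rank percentile. Training metrics come from
#' re-scoring the training set; future metrics from scoring the
#' not-yet-acquired pool.
#'
#' @param roundIndex round number (0 = initial model).
#' @param model a fitted [SurrogateModel-class].
#' @param train,future the current [CompoundSet-class] partitions.
#' @param goalId goal compound id, or \code{NA}; when absent from
#'   \code{future} the goal fields are \code{NA} (the campaign driver
#'   carries forward the last pre-acquisition values).
#' @param seed RNG seed for the bootstrap.
#' @param nBoot bootstrap resamples (default 1000).
#' @return A one-row \code{data.frame} with columns \code{round},
#'   \code{nTrain}, \code{nFuture}, \code{trainTau/Lo/Hi},
#'   \code{trainMue/Lo/Hi}, \code{futureTau/Lo/Hi}, \code{futureMue/Lo/Hi},
#'   \code{goalPred}, \code{goalRankPct}, \code{pctWithin1},
#'   \code{pctWithin2}, \code{pctUnder}, \code{pctOver}.
#' @export
makeRoundReport <- function(roundIndex, model, train, future, goalId = NA,
                            seed = 1L, nBoot = 1000L) {
    trPred <- scoreCandidates(model, train)
    trObs <- unname(activities(train))
    trTau <- kendallTau(trPred$predicted, trObs)$tau
    trTauCi <- bootstrapCi("tau", trPred$predicted, trObs, nBoot = nBoot,
                           seed = deriveSeed(seed, 1))
    trMue <- mue(trPred$predicted, trObs)
    trMueCi <- bootstrapCi("mue", trPred$predicted, trObs, nBoot = nBoot,
                           seed = deriveSeed(seed, 2))

    if (length(future) > 0L) {
        fuPred <- scoreCandidates(model, future)
        fuObs <- unname(activities(future))
        fuTau <- kendallTau(fuPred$predicted, fuObs)$tau
        fuTauCi <- bootstrapCi("tau", fuPred$predicted, fuObs,
                               nBoot = nBoot, seed = deriveSeed(seed, 3))
        fuMue <- mue(fuPred$predicted, fuObs)
        fuMueCi <- bootstrapCi("mue", fuPred$predicted, fuObs,
                               nBoot = nBoot, seed = deriveSeed(seed, 4))
        bins <- errorBins(fuPred$predicted, fuObs)
        goalHere <- !is.na(goalId) && goalId %in% fuPred$id
        goalPred <- if (goalHere)
            fuPred$predicted[fuPred$id == goalId] else NA_real_
        goalRank <- if (goalHere)
            rankTopPercent(goalId, fuPred) else NA_real_
    } else {
        fuTau <- fuMue <- NA_real_
        fuTauCi <- fuMueCi <- c(NA_real_, NA_real_)
        bins <- c(pctWithin1 = NA_real_, pctWithin2 = NA_real_,
                  pctUnder = NA_real_, pctOver = NA_real_)
        goalPred <- goalRank <- NA_real_
    }
    data.frame(
        round = roundIndex, nTrain = length(train),
        nFuture = length(future),
        trainTau = trTau, trainTauLo = trTauCi[1L],
        trainTauHi = trTauCi[2L],
        trainMue = trMue, trainMueLo = trMueCi[1L],
        trainMueHi = trMueCi[2L],
        futureTau = fuTau, futureTauLo = fuTauCi[1L],
        futureTauHi = fuTauCi[2L],
        futureMue = fuMue, futureMueLo = fuMueCi[1L],
        futureMueHi = fuMueCi[2L],
        goalPred = goalPred, goalRankPct = goalRank,
        pctWithin1 = unname(bins["pctWithin1"]),
        pctWithin2 = unname(bins["pctWithin2"]),
        pctUnder = unname(bins["pctUnder"]),
        pctOver = unname(bins["pctOver"]),
        row.names = NULL
    )
}
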