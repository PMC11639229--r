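#' Campaign configuration
#'
#' Settings for an end-to-end active-learning campaign: the temporal split,
#' the round-00 model multiplicity, the number of refinement rounds, the
#' acquisition rule and the surrogate hyperparameters.
#'
#' @param nTrain initial training prefix (default 100).
#' @param nInitialModels alternative initial models built at round 00 and
#'   compared by [probabilityScores()] (default 5). Multiplicity is realized
#'   by jittering the kernel exponent (or ridge strength) around its
#'   configured value, together with distinct fit seeds.
#' @param nRounds refinement rounds after round 00 (default 5).
#' @param acquisition an [acquisitionConfig()].
#' @param selector \code{"dual"} (the exploit + informative rules) or
#'   \code{"random"} (uniform baseline of the same batch size, for
#'   benchmarking only).
#' @param variant,gamma,k,lambda surrogate settings, see [fitSurrogate()].
#'   The campaign default is the additive variant: it can extrapolate
#'   beyond the training activity range (the behavior emphasized for
#'   physically grounded models) and matches the benchmark landscape's
#'   additive structure.
#' @param nBoot bootstrap resamples per report CI (default 1000).
#' @param goalId goal compound id; defaults to the set's flagged goal.
#' @param seed master seed; every random element (bootstrap, random
#'   baseline, fit seeds) is derived from it.
#' @return A classed list of settings.
#' @export
campaignConfig <- function(nTrain = 100L, nInitialModels = 5L,
                           nRounds = 5L,
                           acquisition = acquisitionConfig(),
                           selector = c("dual", "random"),
                           variant = c("additive", "kernel"),
                           gamma = 2, k = 5L, lambda = 1,
                           nBoot = 1000L, goalId = NULL, seed = 1L) {
    selector <- match.arg(selector)
    variant <- match.arg(variant)
    if (nInitialModels < 1L) stop("nInitialModels must be >= 1")
    if (nRounds < 0L) stop("nRounds must be >= 0")
    structure(list(nTrain = as.integer(nTrain),
                   nInitialModels = as.integer(nInitialModels),
                   nRounds = as.integer(nRounds),
                   acquisition = acquisition, selector = selector,
                   variant = variant, gamma = gamma, k = as.integer(k),
                   lambda = lambda, nBoot = as.integer(nBoot),
                   goalId = goalId, seed = as.integer(seed)),
              class = "CampaignConfig")
}

fitJittered <- function(train, cfg, j) {
    # deterministic hyperparameter jitter spans the configured value
    f <- seq(0.7, 1.3, length.out = max(cfg$nInitialModels, 2L))[j]
    if (cfg$variant == "kernel")
        fitSurrogate(train, "kernel", gamma = cfg$gamma * f, k = cfg$k,
                     lambda = cfg$lambda, seed = deriveSeed(cfg$seed, j))
    else
        fitSurrogate(train, "additive", gamma = cfg$gamma, k = cfg$k,
                     lambda = cfg$lambda * f, seed = deriveSeed(cfg$seed, j))
}

#' Run one campaign round
#'
#' Scores the future pool with the current model, assembles the
#' pre-acquisition round report, selects the round's batch, moves the
#' selected compounds from future to train, and refits the model on the
#' enlarged training set. An empty future pool signals campaign completion
#' (\code{done = TRUE}) rather than an error.
#'
#' @param state a list with elements \code{train}, \code{future}
#'   ([CompoundSet-class]) and \code{model} ([SurrogateModel-class]).
#' @param cfg a [campaignConfig()].
#' @param roundIndex the round number used in the report and derived seeds.
#' @return A list: \code{state} (updated), \code{report} (one-row
#'   data.frame), \code{selection} (\code{SelectionResult}),
#'   \code{predictions} (the pre-acquisition scores), \code{done} (logical).
#' @export
runRound <- function(state, cfg = campaignConfig(), roundIndex = 0L) {
    if (length(state$future) == 0L)
        return(list(state = state, report = NULL, selection = NULL,
                    predictions = NULL, done = TRUE))
    gid <- if (!is.null(cfg$goalId)) cfg$goalId else NA_character_
    report <- makeRoundReport(roundIndex, state$model, state$train,
                              state$future, goalId = gid,
                              seed = deriveSeed(cfg$seed, 100L + roundIndex),
                              nBoot = cfg$nBoot)
    preds <- scoreCandidates(state$model, state$future)
    sel <- if (cfg$selector == "dual")
        selectRound(preds, state$train, cfg$acquisition)
    else
        selectRandomBaseline(preds,
                             n = cfg$acquisition$nExploit +
                                 cfg$acquisition$nInformative,
                             seed = deriveSeed(cfg$seed, 200L + roundIndex))
    ids <- c(sel$exploit, sel$informative)
    state$train <- c(state$train, state$future[ids])
    keep <- !(compoundIds(state$future) %in% ids)
    state$future <- state$future[keep]
    state$model <- fitSurrogate(state$train, cfg$variant, gamma = cfg$gamma,
                                k = cfg$k, lambda = cfg$lambda,
                                seed = deriveSeed(cfg$seed,
                                                  300L + roundIndex))
    list(state = state, report = report, selection = sel,
         predictions = preds, done = FALSE)
}

#' Run a full active-learning campaign
#'
#' Round 00 fits \code{nInitialModels} alternative surrogate models on the
#' initial training prefix, selects one by the combined probabilistic score
#' ([selectBestModel()]), then runs the selection loop: score the future
#' pool, report, acquire a batch (exploit + informative under the
#' \code{"dual"} selector), move it into training, refit, repeat for
#' \code{nRounds} refinement rounds. Each round's report reflects the
#' pre-acquisition state; once the goal compound has been acquired its
#' report fields carry the last pre-acquisition values forward. Fully
#' deterministic given the configuration seed.
#'
#' @param data the full [CompoundSet-class] (training prefix + future).
#' @param cfg a [campaignConfig()].
#' @return A \code{CampaignResult} list: \code{reports} (one row per round),
#'   \code{selections} (long data.frame: round, rule, rank, id, predicted,
#'   novelty, nnId, nnSim), \code{modelSelection} (round-00 model
#'   comparison), \code{goalFoundRound} (first round whose batch contains
#'   the goal, or NA), \code{totalSelected}, \code{config}.
#' @examples
#' \donttest{
#' ls <- generateLandscape(landscapeConfig(seed = 3))
#' res <- runCampaign(ls$compounds, campaignConfig(nBoot = 100, seed = 3))
#' res$reports[, c("round", "nTrain", "futureMue", "goalRankPct")]
#' }
#' @export
runCampaign <- function(data, cfg = campaignConfig()) {
    if (length(data) == 0L) stop("data must be non-empty")
    if (cfg$nTrain > length(data))
        stop("nTrain exceeds the dataset size")
    sp <- temporalSplit(data, cfg$nTrain)
    gid <- if (!is.null(cfg$goalId)) cfg$goalId else goalId(data)
    cfg$goalId <- gid

    # round 00: alternative initial models, probabilistic selection
    models <- lapply(seq_len(cfg$nInitialModels),
                     function(j) fitJittered(sp$train, cfg, j))
    metrics <- do.call(rbind, lapply(models, refitMetrics))
    pscores <- probabilityScores(
        if (nrow(metrics) >= 2L) metrics else rbind(metrics, metrics))
    pscores <- pscores[seq_len(nrow(metrics)), , drop = FALSE]
    best <- which.max(pscores$combined)
    modelSelection <- cbind(model = seq_len(nrow(metrics)), metrics,
                            pscores,
                            selected = seq_len(nrow(metrics)) == best)

    state <- list(train = sp$train, future = sp$future,
                  model = models[[best]])
    reports <- list(); selections <- list()
    goalFoundRound <- NA_integer_
    lastGoalPred <- NA_real_; lastGoalRank <- NA_real_

    for (r in 0:cfg$nRounds) {
        step <- runRound(state, cfg, roundIndex = r)
        if (step$done) break
        rpt <- step$report
        if (!is.na(gid) && is.na(rpt$goalPred)) {
            rpt$goalPred <- lastGoalPred      # goal already acquired
            rpt$goalRankPct <- lastGoalRank
        } else {
            lastGoalPred <- rpt$goalPred
            lastGoalRank <- rpt$goalRankPct
        }
        reports[[length(reports) + 1L]] <- rpt
        sel <- step$selection
        selRows <- lapply(c("exploit", "informative"), function(rule) {
            ids <- sel[[rule]]
            if (!length(ids)) return(NULL)
            p <- step$predictions[match(ids, step$predictions$id), ]
            data.frame(round = r, rule = rule, rank = seq_along(ids),
                       id = ids, predicted = p$predicted,
                       novelty = p$novelty, nnId = p$nnId,
                       nnSim = p$nnSim, row.names = NULL)
        })
        selections[[length(selections) + 1L]] <-
            do.call(rbind, selRows[!vapply(selRows, is.null, logical(1))])
        if (!is.na(gid) && is.na(goalFoundRound) &&
            gid %in% c(sel$exploit, sel$informative))
            goalFoundRound <- r
        state <- step$state
    }
    selections <- do.call(rbind, selections)
    structure(list(
        reports = do.call(rbind, reports),
        selections = selections,
        modelSelection = modelSelection,
        goalFoundRound = goalFoundRound,
        totalSelected = if (is.null(selections)) 0L else nrow(selections),
        config = cfg
    ), class = "CampaignResult")
}

#' @export
print.CampaignResult <- function(x, ...) {
    cat("Active-learning campaign:",
        nrow(x$reports), "rounds,",
        x$totalSelected, "compounds acquired\n")
    if (!is.na(x$goalFoundRound))
        cat("  goal compound acquired in round", x$goalFoundRound, "\n")
    cols <- c("round", "nTrain", "nFuture", "trainTau", "trainMue",
              "futureTau", "futureMue", "goalPred", "goalRankPct")
    print(format(x$reports[, cols], digits = 3), ...)
    invisible(x)
}

#' Export a campaign result to files
#'
#' Writes \code{reports.csv}, \code{selections.csv},
#' \code{model_selection.csv} (rounded, report precision) and
#' \code{campaign.json} (full precision, includes CIs and the goal-found
#' round). Output is byte-deterministic for a given result.
#'
#' @param result a \code{CampaignResult} from [runCampaign()].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCampaignResult <- function(result, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    wcsv <- function(df, f)
        utils::write.table(df, file.path(dir, f), sep = ",",
                           row.names = FALSE, quote = FALSE,
                           fileEncoding = "UTF-8")
    rep <- result$reports
    num <- vapply(rep, is.numeric, logical(1))
    rep[num] <- lapply(rep[num], function(x) round(x, 6))
    wcsv(rep, "reports.csv")
    sel <- result$selections
    num <- vapply(sel, is.numeric, logical(1))
    sel[num] <- lapply(sel[num], function(x) round(x, 6))
    wcsv(sel, "selections.csv")
    ms <- result$modelSelection
    num <- vapply(ms, is.numeric, logical(1))
    ms[num] <- lapply(ms[num], function(x) round(x, 6))
    wcsv(ms, "model_selection.csv")
    jsonlite::write_json(
        list(reports = result$reports, selections = result$selections,
             modelSelection = result$modelSelection,
             goalFoundRound = result$goalFoundRound,
             totalSelected = result$totalSelected),
        file.path(dir, "campaign.json"),
        dataframe = "rows", digits = NA, auto_unbox = TRUE, na = "null")
    invisible(dir)
}
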