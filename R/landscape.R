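#' Synthetic SAR landscape configuration
#'
#' Parameters of the calibrated synthetic lead-optimization benchmark. The
#' generator emulates the statistical shape of a 1109-compound campaign:
#' 100 early (training) compounds with mean/sd activity near 7.6/1.3, a
#' 1009-compound future pool with mean/sd near 8.5/1.0 and activity range
#' exactly 4.3-10.1, a dominant early scaffold family A ("macrocycle-like")
#' and a second family B ("non-macrocycle-like") biased toward late
#' synthesis order, and a family-B goal compound of near-maximal activity
#' placed at the final order index.
#'
#' Descriptor layout (bits): a shared always-on warhead block, one scaffold
#' block per family (no activity weight, so scaffold membership is not
#' itself causal), a block of positively weighted pharmacophore bits shared
#' across families (cross-scaffold generalization is learnable), a block of
#' negatively weighted clash bits, and unweighted random decoy bits.
#'
#' @param nTotal total compounds (default 1109).
#' @param nTrain initial training prefix (default 100).
#' @param descriptorLength fingerprint length (default 512).
#' @param nWarheadBits always-on shared bits (default 8).
#' @param nScaffoldBits scaffold bits per family (default 24).
#' @param nPharmacophoreBits positively weighted activity bits (default 48).
#' @param nClashBits negatively weighted penalty bits (default 16).
#' @param familyBFraction fraction of compounds in family B (default 0.35).
#' @param familyBLateBias shift, in order-score units, pushing family B
#'   toward late synthesis order (default 1.0).
#' @param temporalJitterSd sd of the noise added to noiseless activity when
#'   ranking compounds into synthesis order; larger values decouple order
#'   from activity (default 1.45).
#' @param weakFraction fraction of compounds drawn from the weak (early
#'   analog) activity component (default 0.115).
#' @param weakMean,weakSd weak-component intent activity, pIC50
#'   (defaults 5.6, 0.9).
#' @param potentMean,potentSd potent-component intent activity, pIC50
#'   (defaults 8.75, 0.85).
#' @param assayNoiseSd observation noise sd, pIC50 (default 0.3).
#' @param targets calibration targets: future partition min/max are matched
#'   exactly by an affine map; means and sds are matched by
#'   acceptance-rejection within \code{tolerances}.
#' @param tolerances acceptance tolerances around the mean/sd targets.
#' @param maxRetries generation attempts before giving up (default 40).
#' @param seed RNG seed.
#' @return A classed list of settings.
#' @export
landscapeConfig <- function(nTotal = 1109L, nTrain = 100L,
                            descriptorLength = 512L,
                            nWarheadBits = 8L, nScaffoldBits = 24L,
                            nPharmacophoreBits = 48L, nClashBits = 16L,
                            familyBFraction = 0.35,
                            familyBLateBias = 1.0,
                            temporalJitterSd = 2.6,
                            weakFraction = 0.06,
                            weakMean = 5.8, weakSd = 0.9,
                            potentMean = 9.0, potentSd = 0.9,
                            assayNoiseSd = 0.3,
                            targets = list(trainMean = 7.6, trainSd = 1.3,
                                           futureMean = 8.5, futureSd = 1.0,
                                           minAct = 4.3, maxAct = 10.1),
                            tolerances = list(trainMean = 0.2,
                                              trainSd = 0.25,
                                              futureMean = 0.15,
                                              futureSd = 0.25),
                            maxRetries = 40L, seed = 1L) {
    cfg <- as.list(environment())
    nDecoy <- descriptorLength - nWarheadBits - 2L * nScaffoldBits -
        nPharmacophoreBits - nClashBits
    if (nDecoy < 0L)
        stop("bit blocks exceed descriptorLength")
    if (nTrain >= nTotal) stop("nTrain must be smaller than nTotal")
    if (assayNoiseSd < 0) stop("assayNoiseSd must be >= 0")
    cfg$nDecoyBits <- nDecoy
    structure(cfg, class = "LandscapeConfig")
}

#' Generate a calibrated synthetic SAR landscape
#'
#' Produces a [CompoundSet-class] plus the hidden generative truth. The
#' noiseless activity of every compound is an exact linear function of its
#' fingerprint bits (baseline + positive pharmacophore weights - clash
#' penalties), so the landscape is realizable by an additive model.
#' Synthesis order ranks compounds by noiseless activity plus temporal
#' jitter, with family B shifted late; the goal compound is a family-B
#' compound with (by construction) the maximal family-B noiseless activity,
#' pinned to the final order index. Observed activities add Gaussian assay
#' noise and are affinely rescaled so the future partition's observed min
#' and max equal the configured targets exactly; attempts whose partition
#' means/sds fall outside the configured tolerances are rejected and
#' regenerated from a derived sub-seed, so the output is fully deterministic
#' given the config seed.
#'
#' @param cfg a [landscapeConfig()].
#' @return A list with components \code{compounds} ([CompoundSet-class]) and
#'   \code{truth} (class \code{LandscapeTruth}: per-bit \code{weights},
#'   \code{baseline}, \code{family}, \code{noiseless}, \code{goalId},
#'   \code{attempts}).
#' @examples
#' \donttest{
#' ls <- generateLandscape(landscapeConfig(seed = 7))
#' landscapeSummary(ls$compounds, ls$truth)
#' }
#' @export
generateLandscape <- function(cfg = landscapeConfig()) {
    if (!inherits(cfg, "LandscapeConfig"))
        stop("cfg must come from landscapeConfig()")
    diag <- NULL
    for (attempt in seq_len(cfg$maxRetries)) {
        out <- withSeed(deriveSeed(cfg$seed, attempt - 1L),
                        generateOnce(cfg, attempt))
        if (out$ok) {
            out$truth$attempts <- attempt
            return(list(compounds = out$compounds, truth = out$truth))
        }
        diag <- out$why
    }
    stop("generation error: calibration targets not met after ",
         cfg$maxRetries, " attempts; last failure: ", diag)
}

generateOnce <- function(cfg, attempt) {
    n <- cfg$nTotal
    goal <- n  # generated last, pinned to the final order index
    famB <- stats::runif(n) < cfg$familyBFraction
    famB[goal] <- TRUE

    # intent activity: potent main component + weak early-analog tail
    weak <- stats::runif(n) < cfg$weakFraction
    intent <- ifelse(weak,
                     stats::rnorm(n, cfg$weakMean, cfg$weakSd),
                     stats::rnorm(n, cfg$potentMean, cfg$potentSd))
    tLo <- cfg$targets$minAct - 0.3
    tHi <- cfg$targets$maxAct + 0.1
    intent <- pmin(pmax(intent, tLo), tHi)
    # cap ordinary compounds below a fully realized pharmacophore so the
    # goal retains a noiseless-activity margin over the rest of family B
    theta <- pmin(pmax((intent - tLo) / (tHi - tLo), 0.02), 0.85)
    weak[goal] <- FALSE

    # bit blocks
    nW <- cfg$nWarheadBits; nS <- cfg$nScaffoldBits
    nP <- cfg$nPharmacophoreBits; nC <- cfg$nClashBits
    nD <- cfg$nDecoyBits
    warhead <- matrix(1, n, nW)
    scafA <- matrix(stats::rbinom(n * nS, 1L,
                                  ifelse(rep(famB, nS), 0.03, 0.85)), n, nS)
    scafB <- matrix(stats::rbinom(n * nS, 1L,
                                  ifelse(rep(famB, nS), 0.85, 0.03)), n, nS)
    pos <- matrix(stats::rbinom(n * nP, 1L, rep(theta, nP)), n, nP)
    pos[goal, ] <- 1  # the goal realizes the full pharmacophore
    clashProb <- 0.25 * (1 - theta)
    clash <- matrix(stats::rbinom(n * nC, 1L, rep(clashProb, nC)), n, nC)
    clash[goal, ] <- 0
    decoy <- matrix(stats::rbinom(n * nD, 1L, 0.08), n, nD)

    # weights: positive block scaled so a fully realized pharmacophore
    # reaches tHi; clash block subtracts
    wClash <- stats::runif(nC, 0.2, 0.6)
    baseline <- tLo + 0.25 * sum(wClash)
    wPos <- stats::runif(nP, 0.5, 1.5)
    wPos <- wPos * (tHi - baseline) / sum(wPos)

    fp <- cbind(warhead, scafA, scafB, pos, clash, decoy)
    colnames(fp) <- c(sprintf("wh%02d", seq_len(nW)),
                      sprintf("sa%02d", seq_len(nS)),
                      sprintf("sb%02d", seq_len(nS)),
                      sprintf("ph%02d", seq_len(nP)),
                      sprintf("cl%02d", seq_len(nC)),
                      sprintf("dc%03d", seq_len(nD)))
    weights <- stats::setNames(numeric(ncol(fp)), colnames(fp))
    weights[sprintf("ph%02d", seq_len(nP))] <- wPos
    weights[sprintf("cl%02d", seq_len(nC))] <- -wClash

    z <- as.numeric(baseline + fp %*% weights)

    # goal must carry the maximal family-B noiseless activity
    if (max(z[famB]) > z[goal])
        return(list(ok = FALSE, why = "goal not the family-B maximum"))

    # temporal order: activity trend + jitter, family B biased late
    u <- z + stats::rnorm(n, 0, cfg$temporalJitterSd) +
        cfg$familyBLateBias * famB
    u[goal] <- Inf
    ord <- integer(n)
    ord[order(u)] <- seq_len(n)

    obs <- z + stats::rnorm(n, 0, cfg$assayNoiseSd)

    futureMask <- ord > cfg$nTrain
    a <- (cfg$targets$maxAct - cfg$targets$minAct) /
        (max(obs[futureMask]) - min(obs[futureMask]))
    b <- cfg$targets$minAct - a * min(obs[futureMask])
    obs <- a * obs + b
    z <- a * z + b
    weights <- a * weights
    baseline <- a * baseline + b

    # acceptance-rejection against the calibration targets
    tg <- cfg$targets; tol <- cfg$tolerances
    trainMean <- mean(obs[!futureMask]); trainSd <- stats::sd(obs[!futureMask])
    futMean <- mean(obs[futureMask]); futSd <- stats::sd(obs[futureMask])
    checks <- c(
        trainMean = abs(trainMean - tg$trainMean) <= tol$trainMean,
        trainSd = abs(trainSd - tg$trainSd) <= tol$trainSd,
        futureMean = abs(futMean - tg$futureMean) <= tol$futureMean,
        futureSd = abs(futSd - tg$futureSd) <= tol$futureSd,
        goalNearMax = obs[goal] >= max(obs[futureMask]) - 0.6
    )
    if (!all(checks))
        return(list(ok = FALSE,
                    why = paste(names(checks)[!checks], collapse = ", ")))

    ids <- sprintf("Cpd-%04d", ord)
    compounds <- CompoundSet(ids, ord, obs, fp,
                             isGoal = seq_len(n) == goal)
    truth <- structure(list(
        weights = weights, baseline = baseline,
        family = stats::setNames(ifelse(famB, "B", "A"), ids),
        noiseless = stats::setNames(z, ids),
        goalId = ids[goal], attempts = NA_integer_,
        config = cfg
    ), class = "LandscapeTruth")
    list(ok = TRUE, compounds = compounds, truth = truth)
}

#' Summarize a generated landscape
#'
#' Per-partition activity moments and range, family composition by synthesis
#' order decile, and goal metadata.
#'
#' @param data the generated [CompoundSet-class].
#' @param truth the matching \code{LandscapeTruth}.
#' @param nTrain training prefix size (default from the truth's config).
#' @return A list with \code{partitions} (data.frame of per-partition
#'   n/mean/sd/min/max), \code{familyByDecile} (data.frame of family-B
#'   fraction per order decile), and \code{goal} (list of id, family,
#'   observed, noiseless, order index).
#' @export
landscapeSummary <- function(data, truth,
                             nTrain = truth$config$nTrain) {
    sp <- temporalSplit(data, nTrain)
    pstats <- function(x, name) {
        a <- unname(activities(x))
        data.frame(partition = name, n = length(x), mean = mean(a),
                   sd = stats::sd(a), min = min(a), max = max(a))
    }
    partitions <- rbind(pstats(sp$train, "train"),
                        pstats(sp$future, "future"))
    dec <- ceiling(orderIndex(data) / (length(data) / 10))
    famB <- truth$family[compoundIds(data)] == "B"
    familyByDecile <- data.frame(
        decile = sort(unique(dec)),
        fracFamilyB = as.numeric(tapply(famB, dec, mean))
    )
    gid <- truth$goalId
    goal <- list(id = gid,
                 family = unname(truth$family[gid]),
                 observed = unname(activities(data)[gid]),
                 noiseless = unname(truth$noiseless[gid]),
                 orderIndex = orderIndex(data)[compoundIds(data) == gid])
    list(partitions = partitions, familyByDecile = familyByDecile,
         goal = goal)
}
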