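# shared fixtures and independent brute-force oracles

# CompoundSet from bitstrings
makeSet <- function(ids, order, act, bits, goal = rep(FALSE, length(ids))) {
    fp <- do.call(rbind, lapply(strsplit(bits, ""),
                                function(ch) as.numeric(ch == "1")))
    CompoundSet(ids, order, act, fp, goal)
}

# random prediction table over a random train set; discrete grids induce ties
randomInstance <- function(n, nTrainSet = 6L) {
    trainAct <- round(runif(nTrainSet, 6, 10), 1)
    trainIds <- sprintf("T%02d", seq_len(nTrainSet))
    fp <- matrix(rbinom(nTrainSet * 16, 1, 0.5), nTrainSet)
    fp[rowSums(fp) == 0, 1] <- 1
    train <- CompoundSet(trainIds, seq_len(nTrainSet), trainAct, fp)
    preds <- data.frame(
        id = sprintf("C%03d", seq_len(n)),
        orderIndex = sample(seq_len(n) + 100L),
        predicted = round(runif(n, 4, 11), 1),
        novelty = sample(seq(0, 1, by = 0.05), n, replace = TRUE),
        nnId = sample(trainIds, n, replace = TRUE),
        stringsAsFactors = FALSE)
    preds$nnSim <- 1 - preds$novelty
    list(preds = preds, train = train)
}

# exhaustive exploit rule: scan all candidates, no vectorized shortcuts
bruteExploit <- function(preds, cfg) {
    o <- order(preds$novelty, preds$orderIndex)
    pool <- preds[o[seq_len(min(cfg$coveragePool, nrow(preds)))], ]
    o2 <- order(-pool$predicted, pool$orderIndex)
    pool$id[o2[seq_len(min(cfg$nExploit, nrow(pool)))]]
}

# exhaustive informative rule per the documented semantics
bruteInformative <- function(preds, train, cfg, excluded = character()) {
    act <- activities(train)
    # rank of each candidate by NN similarity over the FULL prediction set
    rnk <- integer(nrow(preds))
    rnk[order(-preds$nnSim, preds$orderIndex)] <- seq_len(nrow(preds))
    keep <- logical(nrow(preds))
    for (i in seq_len(nrow(preds))) {
        simOk <- rnk[i] <= cfg$nnTopK || preds$nnSim[i] >= cfg$nnSimThreshold
        actOk <- act[[preds$nnId[i]]] >= cfg$nnActivityThreshold
        keep[i] <- simOk && actOk && !(preds$id[i] %in% excluded)
    }
    el <- preds[keep, ]
    if (nrow(el) == 0L) return(character())
    o <- order(el$predicted, el$orderIndex)
    el$id[o[seq_len(min(cfg$nInformative, nrow(el)))]]
}

# O(n^2) tau-b by explicit pair counting
bruteTauB <- function(x, y) {
    n <- length(x)
    conc <- disc <- tx <- ty <- 0
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
        if (dx == 0 && dy == 0) next
        if (dx == 0) tx <- tx + 1
        else if (dy == 0) ty <- ty + 1
        else if (dx == dy) conc <- conc + 1
        else disc <- disc + 1
    }
    (conc - disc) / sqrt((conc + disc + tx) * (conc + disc + ty))
}

# O(n^2) ROC AUC by pair enumeration
bruteAuc <- function(scores, labels) {
    pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# greedy maxmin trace on an explicit distance matrix (independent recoding)
bruteMaxmin <- function(D, act, ord, k) {
    n <- nrow(D)
    chosen <- order(-act, ord)[1L]
    while (length(chosen) < min(k, n)) {
        rest <- setdiff(seq_len(n), chosen)
        best <- -Inf; bestIdx <- NA
        for (r in rest) {
            m <- min(D[r, chosen])
            if (m > best || (m == best && ord[r] < ord[bestIdx])) {
                best <- m; bestIdx <- r
            }
        }
        chosen <- c(chosen, bestIdx)
    }
    chosen
}

# tiny landscape config for fast campaign tests
smallLandscape <- function(seed = 1L) {
    landscapeConfig(nTotal = 160L, nTrain = 40L, descriptorLength = 128L,
                    nWarheadBits = 4L, nScaffoldBits = 8L,
                    nPharmacophoreBits = 32L, nClashBits = 8L,
                    tolerances = list(trainMean = Inf, trainSd = Inf,
                                      futureMean = Inf, futureSd = Inf),
                    seed = seed)
}
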