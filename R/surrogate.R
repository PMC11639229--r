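#' Fit a surrogate affinity predictor
#'
#' Fits one of the two baseline predictors on a training [CompoundSet]:
#' \describe{
#'   \item{kernel}{similarity-weighted k-nearest-neighbor regression. The
#'     prediction for a candidate is
#'     \eqn{\sum_{i \in kNN} s_i^\gamma y_i / \sum_{i \in kNN} s_i^\gamma}
#'     over the \code{k} most Tanimoto-similar training molecules. Convex in
#'     the neighbor activities, so predictions never leave the training
#'     activity range.}
#'   \item{additive}{ridge regression of activity on fingerprint bits
#'     (intercept unpenalized). Linear in the bits, so unseen bit
#'     combinations can be predicted beyond the training range, mirroring
#'     the out-of-range overprediction behavior of physically motivated
#'     models.}
#' }
#' Both variants are deterministic given \code{(train, hyperparameters,
#' seed)}; the seed is recorded so that plug-in engines with stochastic fits
#' honor the same contract.
#'
#' @param train a [CompoundSet-class] with at least two compounds.
#' @param variant \code{"kernel"} (default) or \code{"additive"}.
#' @param gamma kernel similarity exponent (default 2).
#' @param k kernel neighbor count (default 5).
#' @param lambda ridge strength for the additive variant (default 1).
#' @param seed fit seed (default 1).
#' @return A [SurrogateModel-class].
#' @examples
#' cs <- exampleCompoundSet(20)
#' m <- fitSurrogate(cs, variant = "kernel")
#' head(scoreCandidates(m, cs))
#' @export
fitSurrogate <- function(train, variant = c("kernel", "additive"),
                         gamma = 2, k = 5L, lambda = 1, seed = 1L) {
    variant <- match.arg(variant)
    if (length(train) < 2L)
        stop("training set must contain at least two compounds")
    coefs <- numeric(0)
    if (variant == "additive") {
        X <- fingerprints(train)
        y <- unname(activities(train))
        xm <- colMeans(X); ym <- mean(y)
        Xc <- sweep(X, 2L, xm)
        p <- ncol(Xc)
        # ridge with a tiny floor so exactly-collinear bit columns stay solvable
        A <- crossprod(Xc) + diag(max(lambda, 1e-8), p)
        beta <- solve(A, crossprod(Xc, y - ym))
        coefs <- c(ym - sum(xm * beta), beta)
    }
    methods::new("SurrogateModel", train = train, variant = variant,
                 gamma = as.numeric(gamma), k = as.integer(k),
                 lambda = as.numeric(lambda), seed = as.integer(seed),
                 coef = as.numeric(coefs))
}

#' @rdname scoreCandidates
#' @export
setMethod("scoreCandidates", signature("SurrogateModel", "CompoundSet"),
    function(model, candidates) {
        if (length(candidates) == 0L)
            stop("candidates must be non-empty")
        train <- model@train
        if (descriptorLength(candidates) != descriptorLength(train))
            stop("descriptor length mismatch: candidates ",
                 descriptorLength(candidates), " vs model ",
                 descriptorLength(train))
        S <- tanimotoMatrix(fingerprints(candidates), fingerprints(train))
        y <- unname(activities(train))

        # NN: max similarity, ties broken toward the smallest train order
        # index (training records are stored in ascending order, so the
        # first maximum wins)
        nnIdx <- apply(S, 1L, which.max)
        nnSim <- S[cbind(seq_len(nrow(S)), nnIdx)]

        pred <- if (model@variant == "kernel") {
            k <- min(model@k, length(train))
            vapply(seq_len(nrow(S)), function(i) {
                s <- S[i, ]
                # k most similar, ties toward the smallest order index
                nb <- order(-s, seq_along(s))[seq_len(k)]
                w <- s[nb]^model@gamma
                if (sum(w) == 0) mean(y) else sum(w * y[nb]) / sum(w)
            }, numeric(1))
        } else {
            as.numeric(model@coef[1L] +
                       fingerprints(candidates) %*% model@coef[-1L])
        }
        data.frame(
            id = compoundIds(candidates),
            orderIndex = orderIndex(candidates),
            predicted = pred,
            novelty = 1 - nnSim,
            nnId = compoundIds(train)[nnIdx],
            nnSim = nnSim,
            stringsAsFactors = FALSE, row.names = NULL
        )
    })

#' @rdname refitMetrics
#' @export
setMethod("refitMetrics", "SurrogateModel", function(model) {
    train <- model@train
    preds <- scoreCandidates(model, train)
    obs <- unname(activities(train))
    tau <- kendallTau(preds$predicted, obs)$tau
    e <- mue(preds$predicted, obs)
    data.frame(parsimony = parsimonyOf(train), tau = tau, mue = e)
})

# Descriptor-space parsimony: concordance between pairwise activity
# differences and pairwise structural distances, rescaled to [0, 1].
# Evenly-spaced deterministic subsample of 1e4 pairs when larger.
parsimonyOf <- function(train, maxPairs = 1e4) {
    n <- length(train)
    m <- n * (n - 1) / 2
    pairIdx <- if (m > maxPairs)
        unique(round(seq(1, m, length.out = maxPairs))) else seq_len(m)
    ij <- pairFromLinear(pairIdx, n)
    S <- tanimotoMatrix(fingerprints(train), fingerprints(train))
    y <- unname(activities(train))
    dAct <- abs(y[ij[, 1L]] - y[ij[, 2L]])
    dDesc <- 1 - S[cbind(ij[, 1L], ij[, 2L])]
    tau <- tau_b_knight(dAct, dDesc)
    if (is.nan(tau)) tau <- 0  # constant column: no concordance signal
    (tau + 1) / 2
}

# map linear indices 1..n(n-1)/2 to (i, j) pairs with i < j, row-major
pairFromLinear <- function(idx, n) {
    # cumulative pairs through row i: i*n - i*(i+1)/2; invert the quadratic
    i <- ceiling(((2 * n - 1) - sqrt((2 * n - 1)^2 - 8 * idx)) / 2)
    offset <- (i - 1) * n - (i - 1) * i / 2
    j <- idx - offset + i
    cbind(as.integer(i), as.integer(j))
}
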