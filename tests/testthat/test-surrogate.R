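test_that("tanimoto matches its set definition and validates input", {
    expect_equal(tanimoto(c(1, 1, 0), c(1, 1, 0)), 1)
    expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
    expect_equal(tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1)), 0.5)  # 2 / 4
    expect_error(tanimoto(c(1, 0), c(1, 0, 1)), "length mismatch")
    expect_error(tanimoto(c(0, 0), c(1, 0)), "set bit")

    set.seed(7)
    A <- matrix(rbinom(40, 1, 0.5), 5); A[rowSums(A) == 0, 1] <- 1
    B <- matrix(rbinom(24, 1, 0.5), 3); B[rowSums(B) == 0, 1] <- 1
    M <- tanimotoMatrix(A, B)
    for (i in 1:5) for (j in 1:3)
        expect_equal(M[i, j], tanimoto(A[i, ], B[j, ]))
})

test_that("structure fingerprints are deterministic and form-invariant", {
    skip_if_not_installed("ChemmineR")
    skip_if_not_installed("ChemmineOB")
    f1 <- fingerprintOf("CCO", nBits = 256)
    f2 <- fingerprintOf("CCO", nBits = 256)
    expect_identical(f1, f2)
    expect_gte(sum(f1), 1)

    methane <- fingerprintOf("C", nBits = 256)
    expect_gte(sum(methane), 1)
    expect_lt(tanimoto(methane, f1), 1)

    benzA <- fingerprintOf("c1ccccc1", nBits = 256)
    benzB <- fingerprintOf("C1=CC=CC=C1", nBits = 256)
    expect_identical(benzA, benzB)

    expect_error(fingerprintOf("not a smiles(", nBits = 256), "data error")
    expect_error(fingerprintOf("CCO", nBits = 32), ">= 64")
})

test_that("fits are deterministic and kernel predictions stay in range", {
    cs <- exampleCompoundSet(15, seed = 2)
    probe <- exampleCompoundSet(8, seed = 3)
    m1 <- fitSurrogate(cs, "kernel", seed = 5)
    m2 <- fitSurrogate(cs, "kernel", seed = 5)
    expect_identical(scoreCandidates(m1, probe), scoreCandidates(m2, probe))

    two <- cs[1:2]
    mk <- fitSurrogate(two, "kernel")
    p <- scoreCandidates(mk, probe)$predicted
    rng <- range(activities(two))
    expect_true(all(p >= rng[1] & p <= rng[2]))

    # bounded by the k-neighborhood activity range on random instances
    set.seed(9)
    for (rep in 1:10) {
        tr <- exampleCompoundSet(12, seed = rep)
        mm <- fitSurrogate(tr, "kernel", k = 4)
        pp <- scoreCandidates(mm, exampleCompoundSet(6, seed = rep + 50))
        expect_true(all(pp$predicted >= min(activities(tr)) - 1e-12))
        expect_true(all(pp$predicted <= max(activities(tr)) + 1e-12))
    }

    expect_error(fitSurrogate(cs[1], "kernel"), "at least two")
})

test_that("kernel prediction reproduces the hand-evaluated formula", {
    # candidate similarity 0.6 to t2 (y = 8) and 0.2 to t1 (y = 6);
    # gamma = 2, k = 2 -> (0.04 * 6 + 0.36 * 8) / 0.40 = 7.8
    train <- makeSet(c("t1", "t2"), 1:2, c(6, 8),
                     c("0010000011", "1111100000"))
    cand <- makeSet("c", 3L, 0, "1110000000")
    m <- fitSurrogate(train, "kernel", gamma = 2, k = 2)
    sc <- scoreCandidates(m, cand)
    expect_equal(sc$nnSim, 0.6)
    expect_equal(sc$nnId, "t2")
    expect_equal(sc$predicted, 7.8)
    expect_equal(sc$novelty, 0.4)
})

test_that("a training molecule scores as its own nearest neighbor", {
    cs <- exampleCompoundSet(10)
    m <- fitSurrogate(cs, "kernel")
    sc <- scoreCandidates(m, cs[3])
    expect_equal(sc$nnSim, 1.0)
    expect_equal(sc$novelty, 0.0)
    expect_identical(sc$nnId, compoundIds(cs)[3])
})

test_that("scoring is permutation-equivariant over candidates", {
    cs <- exampleCompoundSet(12)
    m <- fitSurrogate(cs, "kernel")
    cand <- exampleCompoundSet(9, seed = 4)
    perm <- c(5, 1, 9, 3, 7, 2, 8, 6, 4)
    a <- scoreCandidates(m, cand)
    b <- scoreCandidates(m, cand[perm])
    expect_equal(a[match(b$id, a$id), ], b, ignore_attr = TRUE)
})

test_that("additive variant recovers an exactly linear landscape", {
    set.seed(11)
    nb <- 20L
    X <- matrix(rbinom(40 * nb, 1, 0.5), 40); X[rowSums(X) == 0, 1] <- 1
    w <- runif(nb, -0.3, 0.5)
    y <- 6 + as.numeric(X %*% w)
    cs <- CompoundSet(sprintf("L%02d", 1:40), 1:40, y, X)
    m <- fitSurrogate(cs, "additive", lambda = 1e-8)
    expect_lte(refitMetrics(m)$mue, 0.05)
})

test_that("additive variant can extrapolate above the training range", {
    # two bits each worth +1 seen only separately in training; a candidate
    # carrying both scores above every training activity
    train <- makeSet(c("a", "b", "c", "d"), 1:4, c(7, 8, 8, 7),
                     c("100", "110", "101", "100"))
    cand <- makeSet("x", 9L, 0, "111")
    m <- fitSurrogate(train, "additive", lambda = 1e-6)
    expect_gt(scoreCandidates(m, cand)$predicted, max(activities(train)))
})

test_that("refit metrics match brute-force pairwise recomputation", {
    cs <- makeSet(sprintf("f%d", 1:5), 1:5, c(6.2, 7.9, 7.1, 9.0, 8.4),
                  c("110010", "011010", "111100", "000111", "100101"))
    m <- fitSurrogate(cs, "kernel", k = 3)
    got <- refitMetrics(m)

    preds <- scoreCandidates(m, cs)
    expect_equal(got$mue, mean(abs(preds$predicted - activities(cs))),
                 ignore_attr = TRUE)
    expect_equal(got$tau, bruteTauB(preds$predicted,
                                    unname(activities(cs))))

    # parsimony: tau over all pairwise (|dy|, 1 - tanimoto) pairs
    dAct <- c(); dDesc <- c()
    for (i in 1:4) for (j in (i + 1):5) {
        dAct <- c(dAct, abs(activities(cs)[[i]] - activities(cs)[[j]]))
        dDesc <- c(dDesc, 1 - tanimoto(fingerprints(cs)[i, ],
                                       fingerprints(cs)[j, ]))
    }
    expect_equal(got$parsimony, (bruteTauB(dAct, dDesc) + 1) / 2)
})

test_that("perfectly concordant distances give parsimony 1", {
    # pairwise activity gaps 1 < 2 < 3 map to descriptor distances
    # 0.5 < 0.75 < 1 with no ties: perfect concordance
    cs <- makeSet(sprintf("p%d", 1:3), 1:3, c(6, 7, 9),
                  c("1000", "1100", "0111"))
    m <- fitSurrogate(cs, "kernel")
    expect_equal(refitMetrics(m)$parsimony, 1.0)
})
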