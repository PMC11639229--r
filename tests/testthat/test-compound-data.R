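test_that("delimited tables read sorted, validated, and round-trip", {
    tf <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,bits,order,activity",
                 "m3,0011,3,8.4", "m1,1010,1,7.2", "m2,0110,2,9.1"), tf)
    cs <- readCompoundTable(tf)
    expect_s4_class(cs, "CompoundSet")
    expect_identical(compoundIds(cs), c("m1", "m2", "m3"))
    expect_equal(unname(activities(cs)), c(7.2, 9.1, 8.4))
    expect_equal(descriptorLength(cs), 4L)

    bad <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("id,bits,order,activity",
                 "M1,10,1,7", "M1,01,2,8"), bad)
    expect_error(readCompoundTable(bad), "M1")

    expect_error(readCompoundTable(tf, columns = list(id = "id",
        bits = "nope", order = "order", activity = "activity")),
        "missing column")
})

test_that("a full synthetic export round-trips byte-equal on re-export", {
    ls <- generateLandscape(landscapeConfig(seed = 11))
    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    writeCompoundTable(ls$compounds, f1)
    reread <- readCompoundTable(f1, goalColumn = "isGoal")
    writeCompoundTable(reread, f2)
    expect_identical(readLines(f1), readLines(f2))
    expect_identical(goalId(reread), goalId(ls$compounds))
})

test_that("temporal split is an order-respecting partition", {
    ls <- generateLandscape(landscapeConfig(seed = 11))
    sp <- temporalSplit(ls$compounds, 100)
    expect_length(sp$train, 100L)
    expect_length(sp$future, 1009L)
    expect_length(intersect(compoundIds(sp$train),
                            compoundIds(sp$future)), 0L)
    expect_setequal(c(compoundIds(sp$train), compoundIds(sp$future)),
                    compoundIds(ls$compounds))
    expect_true(max(orderIndex(sp$train)) < min(orderIndex(sp$future)))

    sp0 <- temporalSplit(ls$compounds, 0)
    expect_length(sp0$train, 0L)
    expect_length(sp0$future, 1109L)

    # shuffled construction still splits by order index
    set.seed(4)
    perm <- sample(10)
    cs <- CompoundSet(sprintf("s%d", perm), perm, runif(10, 6, 9),
                      matrix(1, 10, 4))
    sp5 <- temporalSplit(cs, 5)
    expect_identical(orderIndex(sp5$train), 1:5)

    expect_error(temporalSplit(cs, 11), "exceeds")
    expect_error(temporalSplit(cs, -1), "non-negative")
})

test_that("pIC50 <-> kcal/mol conversion uses the 4/3 equivalence", {
    expect_equal(kcalFromPic50(1.5), 2.0)
    expect_equal(kcalFromPic50(0), 0)
    expect_equal(kcalFromPic50(0.75), 1.0)
    expect_equal(pic50FromKcal(2.0), 1.5)
    x <- seq(-3, 3, by = 0.25)
    expect_equal(pic50FromKcal(kcalFromPic50(x)), x)
})

test_that("CompoundSet validity rejects malformed inputs", {
    fp <- matrix(c(1, 0, 0, 1), 2, 2)
    expect_error(CompoundSet(c("a", "a"), 1:2, c(7, 8), fp), "duplicated")
    expect_error(CompoundSet(c("a", "b"), c(1L, 1L), c(7, 8), fp),
                 "order index")
    expect_error(CompoundSet(c("a", "b"), 1:2, c(7, NA), fp), "finite")
    expect_error(CompoundSet(c("a", "b"), 1:2, c(7, 8),
                             matrix(c(1, 0, 0, 0), 2, 2)), "set bit")
})

sdfMol <- function(name, atom2) c(
    name, "  test", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    paste0("    1.5000    0.0000    0.0000 ", atom2,
           "   0  0  0  0  0  0  0  0  0  0  0  0"),
    "  1  2  1  0",
    "M  END")

sdfFixture <- function(path, withOrder = TRUE) {
    orderTag <- function(v) if (withOrder) c("> <ORDER>", v, "") else NULL
    writeLines(c(
        sdfMol("mol-a", "C"),
        "> <pIC50>", "7.0", "", orderTag("2"),
        "$$$$",
        sdfMol("mol-b", "N"),
        "> <pIC50>", "8.0", "", orderTag("1"),
        "$$$$"), path)
}

test_that("SDF reading honors property tags and order fallback", {
    skip_if_not_installed("ChemmineR")
    f <- withr::local_tempfile(fileext = ".sdf")
    sdfFixture(f)
    cs <- readSdf(f)
    expect_length(cs, 2L)
    expect_identical(compoundIds(cs), c("mol-b", "mol-a"))  # by ORDER
    expect_equal(unname(activities(cs)), c(8.0, 7.0))

    expect_error(readSdf(f, activityTag = "missing"), "record")

    # order tag absent -> file order, with warning
    f2 <- withr::local_tempfile(fileext = ".sdf")
    sdfFixture(f2, withOrder = FALSE)
    expect_warning(cs2 <- readSdf(f2), "file order")
    expect_identical(compoundIds(cs2), c("mol-a", "mol-b"))
})

test_that("SDF exporter round-trips ids, order and activities", {
    skip_if_not_installed("ChemmineR")
    cs <- exampleCompoundSet(6)
    f <- withr::local_tempfile(fileext = ".sdf")
    writeSdf(cs, f)
    back <- readSdf(f, bitsTag = "FP_BITS")
    expect_identical(compoundIds(back), compoundIds(cs))
    expect_identical(orderIndex(back), orderIndex(cs))
    expect_equal(activities(back), activities(cs))
    expect_equal(fingerprints(back), fingerprints(cs),
                 ignore_attr = TRUE)
})
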