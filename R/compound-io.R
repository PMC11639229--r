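#' Read a delimited structure-activity table
#'
#' Reads a UTF-8 delimited text file with a header row into a [CompoundSet].
#' Structural descriptors are supplied either as explicit fingerprint
#' bitstrings (\code{"0101..."}, the synthetic-data path) or as structure
#' strings (SMILES, the real-data path) which are converted with
#' [fingerprintOf()]. A dataset may not mix the two.
#'
#' @param path file path.
#' @param columns named list mapping the required roles to column names:
#'   \code{id}, \code{order}, \code{activity}, and exactly one of \code{bits}
#'   or \code{structure}. Defaults to
#'   \code{list(id = "id", bits = "bits", order = "order",
#'   activity = "activity")}.
#' @param sep field delimiter (default comma).
#' @param goalColumn optional name of a logical goal-flag column.
#' @param nBits fingerprint length used when converting structures.
#' @return A [CompoundSet-class], sorted by order index.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("id,bits,order,activity",
#'              "m1,1010,1,7.2", "m2,0110,2,8.1"), tf)
#' readCompoundTable(tf)
#' @export
readCompoundTable <- function(path,
                              columns = list(id = "id", bits = "bits",
                                             order = "order",
                                             activity = "activity"),
                              sep = ",", goalColumn = NULL, nBits = 2048L) {
    if (!file.exists(path)) stop("file not found: ", path)
    # read everything as character: bitstrings like "0011" must not be
    # type-converted
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             colClasses = "character", quote = "\"",
                             comment.char = "")
    hasBits <- !is.null(columns$bits)
    hasStruct <- !is.null(columns$structure)
    if (hasBits && hasStruct)
        stop("configuration error: give either a 'bits' or a 'structure' ",
             "column, not both")
    if (!hasBits && !hasStruct)
        stop("configuration error: one of 'bits' or 'structure' is required")
    need <- c(columns$id, if (hasBits) columns$bits else columns$structure,
              columns$order, columns$activity)
    missing <- setdiff(need, names(tab))
    if (length(missing))
        stop("configuration error: missing column(s): ",
             paste(missing, collapse = ", "))

    ids <- as.character(tab[[columns$id]])
    if (anyDuplicated(ids))
        stop("data error: duplicated compound id '",
             ids[duplicated(ids)][1L], "'")
    ord <- as.integer(tab[[columns$order]])
    act <- as.numeric(tab[[columns$activity]])

    if (hasBits) {
        bs <- as.character(tab[[columns$bits]])
        fp <- do.call(rbind, lapply(seq_along(bs), function(i) {
            parseBits(bs[i], where = paste0("row ", i, " (id ", ids[i], ")"))
        }))
        if (length(unique(nchar(bs))) > 1L)
            stop("data error: fingerprint bitstrings differ in length")
    } else {
        fp <- do.call(rbind, lapply(seq_along(ids), function(i) {
            tryCatch(fingerprintOf(tab[[columns$structure]][i], nBits = nBits),
                     error = function(e)
                         stop("data error: unparseable structure at row ", i,
                              " (id ", ids[i], "): ", conditionMessage(e)))
        }))
    }
    goal <- if (!is.null(goalColumn) && goalColumn %in% names(tab))
        as.logical(tab[[goalColumn]]) else rep(FALSE, length(ids))
    CompoundSet(ids, ord, act, fp, goal)
}

#' Write a CompoundSet as a delimited table
#'
#' Inverse of [readCompoundTable()] for the bitstring dialect; a
#' write-then-read round trip reproduces the set exactly.
#'
#' @param x a [CompoundSet-class].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return \code{path}, invisibly.
#' @export
writeCompoundTable <- function(x, path, sep = ",") {
    df <- as.data.frame(x)
    names(df) <- c("id", "order", "activity", "isGoal", "bits")
    df <- df[, c("id", "bits", "order", "activity", "isGoal")]
    df$activity <- formatC(df$activity, digits = 15, format = "g")
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Read an SDF structure-activity file
#'
#' Reads a V2000 SDF whose data blocks carry the activity (and optionally the
#' synthesis-order) property tags. Structures are fingerprinted with
#' [fingerprintOf()]. When \code{orderTag} is absent from every record, file
#' order is used as the synthesis order, with a warning.
#'
#' @param path SDF file path.
#' @param activityTag property tag holding pIC50 (default \code{"pIC50"}).
#' @param orderTag property tag holding the synthesis-order index (default
#'   \code{"ORDER"}).
#' @param idTag property tag holding the compound id; when absent the
#'   molecule title line is used.
#' @param bitsTag optional property tag holding an explicit fingerprint
#'   bitstring (as written by [writeSdf()]); when given, structures are not
#'   fingerprinted.
#' @param nBits fingerprint length.
#' @return A [CompoundSet-class].
#' @export
readSdf <- function(path, activityTag = "pIC50", orderTag = "ORDER",
                    idTag = NULL, bitsTag = NULL, nBits = 2048L) {
    if (!requireNamespace("ChemmineR", quietly = TRUE))
        stop("readSdf requires the ChemmineR package")
    if (!file.exists(path)) stop("file not found: ", path)
    sdf <- ChemmineR::read.SDFset(path)
    n <- length(sdf)
    if (n == 0L) stop("data error: SDF contains no molecules")
    blocks <- lapply(seq_len(n), function(i)
        ChemmineR::datablock(sdf[[i]]))
    act <- vapply(seq_len(n), function(i) {
        b <- blocks[[i]]
        if (!activityTag %in% names(b)) NA_real_
        else suppressWarnings(as.numeric(b[[activityTag]]))
    }, numeric(1))
    if (anyNA(act))
        stop("data error: activity tag '", activityTag,
             "' missing or non-numeric for record(s) ",
             paste(which(is.na(act)), collapse = ", "))
    ords <- vapply(seq_len(n), function(i) {
        b <- blocks[[i]]
        if (!orderTag %in% names(b)) NA_integer_
        else as.integer(b[[orderTag]])
    }, integer(1))
    if (anyNA(ords)) {
        warning("order tag '", orderTag,
                "' absent; falling back to file order")
        ords <- seq_len(n)
    }
    ids <- if (!is.null(idTag)) {
        vapply(seq_len(n), function(i) {
            b <- blocks[[i]]
            if (!idTag %in% names(b))
                stop("data error: id tag '", idTag,
                     "' missing for record ", i)
            as.character(b[[idTag]])
        }, character(1))
    } else {
        vapply(seq_len(n), function(i)
            ChemmineR::sdfid(sdf[[i]]), character(1))
    }
    fp <- if (!is.null(bitsTag)) {
        do.call(rbind, lapply(seq_len(n), function(i) {
            b <- blocks[[i]]
            if (!bitsTag %in% names(b))
                stop("data error: bits tag '", bitsTag,
                     "' missing for record ", i)
            parseBits(as.character(b[[bitsTag]]),
                      where = paste0("record ", i))
        }))
    } else {
        do.call(rbind, lapply(seq_len(n), function(i) {
            tryCatch(fingerprintOf(sdf[[i]], nBits = nBits),
                     error = function(e)
                         stop("data error: unparseable structure in record ",
                              i, ": ", conditionMessage(e)))
        }))
    }
    CompoundSet(ids, ords, act, fp)
}

#' Write a CompoundSet as an SDF file with property tags
#'
#' Emits a minimal V2000 SDF. When the set carries no real structures (the
#' synthetic path) a placeholder single-carbon connection table is written
#' and the fingerprint is preserved in a \code{FP_BITS} tag so that a
#' write-then-read round trip via \code{readSdf(..., bitsTag = "FP_BITS")}
#' is exact; this is intended for format round-trip testing, not for
#' exchanging chemistry.
#'
#' @param x a [CompoundSet-class].
#' @param path output path.
#' @param activityTag,orderTag property tag names (defaults \code{"pIC50"},
#'   \code{"ORDER"}).
#' @return \code{path}, invisibly.
#' @export
writeSdf <- function(x, path, activityTag = "pIC50", orderTag = "ORDER") {
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    ids <- compoundIds(x); ord <- orderIndex(x)
    act <- unname(activities(x)); fp <- fingerprints(x)
    for (i in seq_along(ids)) {
        writeLines(c(
            ids[i], "  ligandAL", "",
            "  2  1  0  0  0  0  0  0  0  0999 V2000",
            "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
            "    1.5000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
            "  1  2  1  0",
            "M  END",
            paste0("> <", activityTag, ">"),
            formatC(act[i], digits = 15, format = "g"), "",
            paste0("> <", orderTag, ">"), as.character(ord[i]), "",
            "> <FP_BITS>", paste(fp[i, ], collapse = ""), "",
            "$$$$"), con)
    }
    invisible(path)
}

#' Temporal train/future split
#'
#' Splits a dataset at a synthesis-order cut: the first \code{nTrain}
#' compounds by order index become the initial training set, the remainder
#' the "future" pool of synthesizable candidates.
#'
#' @param data a [CompoundSet-class].
#' @param nTrain number of earliest compounds to train on
#'   (\code{0 <= nTrain <= length(data)}).
#' @return A list with elements \code{train} and \code{future}, both
#'   [CompoundSet-class]; they partition \code{data}.
#' @examples
#' cs <- exampleCompoundSet(10)
#' sp <- temporalSplit(cs, 5)
#' length(sp$train); length(sp$future)
#' @export
temporalSplit <- function(data, nTrain) {
    stopIfNotScalarCount(nTrain, "nTrain")
    n <- length(data)
    if (nTrain > n)
        stop("nTrain (", nTrain, ") exceeds dataset size (", n, ")")
    idx <- seq_len(n)
    list(train = data[idx <= nTrain], future = data[idx > nTrain])
}

#' Convert activity differences between pIC50 and kcal/mol
#'
#' Uses the fixed project equivalence of 1.5 pIC50 log units to 2 kcal/mol,
#' i.e. a factor of 4/3 kcal/mol per log unit (not RT ln 10), so that the
#' kcal/mol error-bin semantics of [errorBins()] are reproduced exactly.
#'
#' @param delta activity difference in pIC50 log units (kcal/mol for the
#'   inverse).
#' @return The converted difference; linear and sign-preserving.
#' @examples
#' kcalFromPic50(1.5)  # 2
#' pic50FromKcal(2)    # 1.5
#' @export
kcalFromPic50 <- function(delta) delta * (4 / 3)

#' @rdname kcalFromPic50
#' @export
pic50FromKcal <- function(delta) delta * (3 / 4)

#' Small deterministic example CompoundSet
#'
#' Convenience fixture used in documentation examples: \code{n} compounds
#' with random 32-bit fingerprints and activities increasing with synthesis
#' order.
#'
#' @param n number of compounds.
#' @param seed RNG seed.
#' @return A [CompoundSet-class].
#' @export
exampleCompoundSet <- function(n = 10L, seed = 1L) {
    withSeed(seed, {
        fp <- matrix(rbinom(n * 32L, 1L, 0.4), nrow = n)
        fp[rowSums(fp) == 0, 1L] <- 1
        CompoundSet(sprintf("ex-%03d", seq_len(n)), seq_len(n),
                    round(6 + 0.3 * seq_len(n) + rnorm(n, 0, 0.4), 2), fp)
    })
}
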