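#' Tanimoto similarity between binary fingerprints
#'
#' \code{tanimoto} compares two equal-length 0/1 vectors; the similarity is
#' |intersection| / |union| of the set bits. \code{tanimotoMatrix} computes
#' the full cross-similarity matrix between the rows of two fingerprint
#' matrices using BLAS-level bit counting.
#'
#' @param a,b 0/1 numeric vectors of equal length, each with at least one
#'   set bit.
#' @return \code{tanimoto}: a similarity in [0, 1], 1 iff the bit sets are
#'   identical. \code{tanimotoMatrix}: an \code{nrow(A) x nrow(B)} matrix.
#' @examples
#' tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 0))  # 1/3
#' @export
tanimoto <- function(a, b) {
    if (length(a) != length(b))
        stop("fingerprint length mismatch: ", length(a), " vs ", length(b))
    if (sum(a) < 1 || sum(b) < 1)
        stop("fingerprints must each have at least one set bit")
    inter <- sum(a * b)
    inter / (sum(a) + sum(b) - inter)
}

#' @rdname tanimoto
#' @param A,B 0/1 matrices with the same number of columns.
#' @export
tanimotoMatrix <- function(A, B) {
    if (ncol(A) != ncol(B))
        stop("fingerprint length mismatch: ", ncol(A), " vs ", ncol(B))
    inter <- tcrossprod(A, B)
    u <- outer(rowSums(A), rowSums(B), "+") - inter
    inter / u
}

#' Fingerprint a 2D molecular structure
#'
#' Real-data front end: converts a structure into a fixed-length binary
#' fingerprint by folding ChemmineR atom-pair descriptors into \code{nBits}
#' positions. The result is deterministic and invariant to atom ordering and
#' to equivalent input forms (the descriptors are computed on the parsed
#' molecule, not the input string). Molecules too small to produce any
#' descriptor pair still receive one set bit.
#'
#' Requires the ChemmineR package (and ChemmineOB when \code{x} is a SMILES
#' string).
#'
#' @param x a SMILES string or a ChemmineR \code{SDF} object.
#' @param nBits fingerprint length (>= 64, default 2048).
#' @return A 0/1 numeric vector of length \code{nBits} with at least one set
#'   bit.
#' @export
fingerprintOf <- function(x, nBits = 2048L) {
    if (nBits < 64L) stop("nBits must be >= 64")
    if (!requireNamespace("ChemmineR", quietly = TRUE))
        stop("fingerprintOf requires the ChemmineR package")
    sdf <- if (is.character(x)) {
        if (length(x) != 1L || !nzchar(x))
            stop("data error: empty structure string")
        if (!requireNamespace("ChemmineOB", quietly = TRUE))
            stop("SMILES input requires the ChemmineOB package")
        out <- tryCatch(suppressWarnings(ChemmineR::smiles2sdf(x)),
                        error = function(e)
                            stop("data error: unparseable SMILES '", x, "'"))
        if (length(out) == 0L)
            stop("data error: unparseable SMILES '", x, "'")
        out[[1L]]
    } else x
    nAtoms <- tryCatch(nrow(ChemmineR::atomblock(sdf)),
                       error = function(e) 0L)
    if (is.null(nAtoms) || nAtoms < 1L)
        stop("data error: structure has no atoms")
    # single-heavy-atom molecules carry no atom pair; fall back below
    codes <- tryCatch(ChemmineR::ap(ChemmineR::sdf2ap(sdf)),
                      error = function(e) numeric(0))
    fp <- numeric(nBits)
    if (length(codes)) fp[(as.numeric(codes) %% nBits) + 1L] <- 1
    if (sum(fp) < 1) {
        # degenerate molecule (no atom pair): derive one bit from atom count
        na <- tryCatch(nrow(ChemmineR::atomblock(sdf)), error = function(e) 1L)
        fp[(na %% nBits) + 1L] <- 1
    }
    fp
}
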