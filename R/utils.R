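# internal helpers

# run expr under a local RNG stream; the caller's .Random.seed is untouched
withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

# derived sub-seed, kept inside 32-bit integer range
deriveSeed <- function(seed, offset) {
    as.integer((as.numeric(seed) * 97L + as.numeric(offset) * 7919) %%
               2147483587)
}

# parse a "0101..." bitstring row into a numeric 0/1 vector
parseBits <- function(s, where = "row") {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    if (!all(ch %in% c("0", "1")))
        stop("invalid fingerprint bitstring in ", where)
    as.numeric(ch == "1")
}

stopIfNotScalarCount <- function(x, name) {
    if (length(x) != 1L || !is.finite(x) || x < 0 || x != floor(x))
        stop(name, " must be a single non-negative integer")
}
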