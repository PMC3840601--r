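## Internal helpers shared across modules.

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's .Random.seed afterwards so package functions never perturb the
## user's RNG stream.
withSeed <- function(seed, expr) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
        stop("'seed' must be a single non-missing integer", call. = FALSE)
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed)
        old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
        if (has_seed)
            assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
    expr
}

## Derive a stream-specific seed from a base seed; keeps the result a valid
## 32-bit integer whatever the base seed is.
deriveSeed <- function(seed, stream) {
    as.integer((as.numeric(seed) + 1664525 * stream) %% 2147483647)
}

## FNV-1a hash of a character scalar, returned as 8 hex digits. Used to stamp
## output files with a configuration fingerprint without external deps.
fnv1a <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    bytes <- utf8ToInt(x)
    h <- 2166136261
    for (b in bytes) {
        h <- bitwXor(as.integer(h %% 2147483647), b)
        ## multiply mod 2^32 in double precision
        h <- (h * 16777619) %% 4294967296
    }
    sprintf("%08x", as.integer(h %% 2147483647))
}

.assertCount <- function(x, field, positive = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
        (if (positive) x > 0 else x >= 0)
    if (!ok)
        stop(sprintf("'%s' must be a single %s integer", field,
                     if (positive) "positive" else "non-negative"),
             call. = FALSE)
    invisible(as.integer(x))
}

.assertFraction <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
        stop(sprintf("'%s' must be a single real in (0, 1)", field),
             call. = FALSE)
    invisible(as.numeric(x))
}

KNOWN_ENZYMES <- c("trypsin", "chymotrypsin", "glu-c", "none")

## Residues after which each protease cleaves (C-terminal specificity).
ENZYME_SITES <- list(
    trypsin      = c("R", "K"),
    chymotrypsin = c("F", "L", "W", "Y"),
    `glu-c`      = c("D", "E")
)

.checkEnzyme <- function(enzyme) {
    if (!is.character(enzyme) || length(enzyme) != 1L ||
        !(enzyme %in% KNOWN_ENZYMES))
        stop(sprintf("unknown enzyme '%s'; must be one of %s",
                     paste(enzyme, collapse = ","),
                     paste(KNOWN_ENZYMES, collapse = ", ")),
             call. = FALSE)
    enzyme
}
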