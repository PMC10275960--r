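# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's RNG
## state afterwards so library code never clobbers user-level reproducibility.
withSeed <- function(seed, expr) {
    if (!is.null(seed)) {
        old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            get(".Random.seed", envir = globalenv()) else NULL
        on.exit({
            if (is.null(old)) {
                if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
                    rm(".Random.seed", envir = globalenv())
            } else {
                assign(".Random.seed", old, envir = globalenv())
            }
        })
        set.seed(seed)
    }
    expr
}

## Deterministic named sub-seeds spawned from one master seed. Keeps every
## stage (features, noise, missingness, drift, ...) on its own stream so that
## changing e.g. the missingness draw does not perturb the planted effects.
spawnSeeds <- function(seed, names) {
    withSeed(seed, {
        s <- sample.int(.Machine$integer.max - 1L, length(names))
        names(s) <- names
        s
    })
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## TSV I/O used for every on-disk artifact. Missing values round-trip as "NA";
## zeros are real measurements and are never used to encode missingness.
readTsv <- function(path) {
    if (!file.exists(path)) stopf("file not found: %s", path)
    utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", ""))
}

writeTsv <- function(df, path, header_comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(header_comment))
        writeLines(paste0("# ", header_comment), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    invisible(path)
}
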