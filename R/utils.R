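# internal helpers shared across modules

# alphabetical 20-residue alphabet used for PWM columns and background sampling
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# row variances with NA support; rows with < 2 observations give NA
.rowVars <- function(x) {
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    v <- rowSums((x - m)^2, na.rm = TRUE) / (n - 1)
    v[n < 2] <- NA_real_
    v
}

.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
        stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
             call. = FALSE)
    invisible(x)
}

# membership bit-pattern partition over named sets; returns counts per
# exclusive region keyed by "+"-joined set names ("none" for no membership)
.patternCounts <- function(ids, sets) {
    if (is.null(names(sets)) || any(names(sets) == ""))
        stop("sets must be named", call. = FALSE)
    pat <- vapply(ids, function(id) {
        inn <- names(sets)[vapply(sets, function(s) id %in% s, logical(1))]
        if (length(inn) == 0L) "none" else paste(inn, collapse = "+")
    }, character(1))
    table(factor(pat))
}

.seqAsCharacter <- function(seq) {
    if (methods::is(seq, "AAString") || methods::is(seq, "XString"))
        return(as.character(seq))
    if (!is.character(seq) || length(seq) != 1L)
        stop("'seq' must be a single character string or AAString", call. = FALSE)
    seq
}
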