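#' Triage structure-prediction confidence scores
#'
#' Splits candidate records at the interface-confidence threshold: a candidate
#' passes iff `iptm > threshold` (strictly; a score exactly at the threshold
#' fails). Scores outside \[0, 1\] are an error naming the offending record.
#'
#' @param records `data.frame` with columns `candidate_id` and `iptm` (e.g.,
#'   from [simIptm()] or an ipTM TSV read with [utils::read.delim()]).
#' @param threshold triage threshold (default 0.6).
#' @return A list with `pass` and `fail` subsets of `records`.
#' @examples
#' r <- data.frame(candidate_id = c("a", "b"), iptm = c(0.9, 0.6))
#' triageIptm(r)$pass$candidate_id  # "a"; 0.6 exactly fails
#' @export
triageIptm <- function(records, threshold = 0.6) {
    stopifnot(is.data.frame(records),
              all(c("candidate_id", "iptm") %in% names(records)))
    bad <- which(is.na(records$iptm) | records$iptm < 0 | records$iptm > 1)
    if (length(bad) > 0L)
        stop("ipTM outside [0, 1] for record(s): ",
             paste(records$candidate_id[utils::head(bad, 5)], collapse = ", "))
    sel <- records$iptm > threshold
    list(pass = records[sel, , drop = FALSE],
         fail = records[!sel, , drop = FALSE])
}

#' Select the top- and bottom-ranked predictions
#'
#' Sorts records by ipTM descending (ties broken by `candidate_id`, so the
#' selection is deterministic) and returns the `nTop` best and `nBottom`
#' worst — the peptide sets summarised as top/bottom motif logos.
#'
#' @param records `data.frame` with `candidate_id` and `iptm`.
#' @param nTop,nBottom how many records to take from each extreme.
#' @return A list with `top` and `bottom` subsets (both in descending ipTM
#'   order).
#' @export
selectExtremes <- function(records, nTop, nBottom) {
    stopifnot(is.data.frame(records),
              all(c("candidate_id", "iptm") %in% names(records)))
    if (nrow(records) < nTop + nBottom)
        stop(sprintf("need at least %d records, have %d",
                     nTop + nBottom, nrow(records)))
    ord <- order(-records$iptm, records$candidate_id)
    list(top = records[utils::head(ord, nTop), , drop = FALSE],
         bottom = records[utils::tail(ord, nBottom), , drop = FALSE])
}

#' Build a position weight matrix from aligned peptides
#'
#' Estimates per-position residue probabilities as
#' `(count + pseudocount) / (n + 20 * pseudocount)` over the 20 standard
#' residues and the per-position information content
#' `log2(20) - H(p)` in bits. Peptides must be pre-aligned to equal length:
#' C-terminal motifs right-aligned at the terminus, internal motifs on the
#' core window (label positions accordingly via `positionLabels`).
#'
#' @param peptides character vector of equal-length peptides over the standard
#'   alphabet.
#' @param pseudocount pseudocount per residue (default 0.1; 0 gives maximum-
#'   likelihood frequencies).
#' @param positionLabels optional row labels; `cterm = TRUE` labels positions
#'   as negative offsets from the C-terminus (-L .. -1).
#' @param cterm label positions as C-terminal offsets.
#' @return A [PWM-class] object.
#' @examples
#' pwm <- buildPWM(c("TSL", "SAV", "TGI", "SQL"), pseudocount = 0.1)
#' informationContent(pwm)
#' @export
buildPWM <- function(peptides, pseudocount = 0.1, positionLabels = NULL,
                     cterm = FALSE) {
    if (length(peptides) == 0L) stop("no peptides")
    L <- unique(nchar(peptides))
    if (length(L) != 1L)
        stop("peptides must all have the same length (observed: ",
             paste(sort(L), collapse = ", "), ")")
    .assertScalarNumber(pseudocount, "pseudocount", lower = 0)
    ch <- matrix(unlist(strsplit(peptides, "", fixed = TRUE)),
                 nrow = length(peptides), ncol = L, byrow = TRUE)
    if (any(!ch %in% AA20))
        stop("nonstandard residue(s) in peptides: ",
             paste(unique(ch[!ch %in% AA20]), collapse = ", "))
    n <- length(peptides)
    counts <- t(apply(ch, 2, function(col)
        table(factor(col, levels = AA20))))
    probs <- (counts + pseudocount) / (n + 20 * pseudocount)
    ent <- apply(probs, 1, function(p) {
        nz <- p > 0
        -sum(p[nz] * log2(p[nz]))
    })
    ic <- pmin(pmax(log2(20) - ent, 0), log2(20))
    labels <- if (!is.null(positionLabels)) positionLabels
              else if (cterm) as.character(seq(-L, -1L))
              else as.character(seq_len(L))
    dimnames(probs) <- list(labels, AA20)
    methods::new("PWM", probs = probs, ic = unname(ic),
                 nSeqs = as.integer(n), pseudocount = pseudocount)
}
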