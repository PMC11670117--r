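#' Term over-representation by the hypergeometric upper tail
#'
#' For each term, tests whether the hit set overlaps the term's members more
#' than expected under random draws from the universe:
#' `p = P[X >= overlap]` with `X ~ Hypergeometric(N = |universe|,
#' K = |term in universe|, n = |hits|)`. BH correction is applied within each
#' term category (location and function separately, mirroring sub-ontology
#' reporting).
#'
#' @param hitSet character vector of hit ids; must be a subset of `universe`.
#' @param universe character vector of all tested ids.
#' @param terms long-format term table with columns `term_id`, `term_name`,
#'   `category`, `protein_id` (see [simTerms()] or [readFasta()]-style TSV
#'   input).
#' @return `data.frame`: `term_id`, `term_name`, `category`, `n_term`,
#'   `overlap`, `expected`, `p_value`, `q_value`, `log10_q`, sorted by
#'   category then p value. Terms with no members in the universe are dropped.
#' @examples
#' terms <- data.frame(term_id = "T1", term_name = "toy", category = "location",
#'                     protein_id = c("a", "b", "c"))
#' termEnrichment(c("a", "b"), letters[1:10], terms)
#' @export
termEnrichment <- function(hitSet, universe, terms) {
    hitSet <- unique(hitSet)
    universe <- unique(universe)
    offenders <- setdiff(hitSet, universe)
    if (length(offenders) > 0L)
        stop("hit set contains ids outside the universe: ",
             paste(utils::head(offenders, 5), collapse = ", "),
             if (length(offenders) > 5) sprintf(" (and %d more)",
                                                length(offenders)) else "")
    need <- c("term_id", "term_name", "category", "protein_id")
    if (!all(need %in% names(terms)))
        stop("terms must have columns ", paste(need, collapse = ", "))
    terms <- terms[terms$protein_id %in% universe, , drop = FALSE]
    if (nrow(terms) == 0L)
        return(data.frame(term_id = character(0), term_name = character(0),
                          category = character(0), n_term = integer(0),
                          overlap = integer(0), expected = numeric(0),
                          p_value = numeric(0), q_value = numeric(0),
                          log10_q = numeric(0)))
    N <- length(universe)
    n <- length(hitSet)
    key <- paste(terms$term_id, terms$category, sep = "\r")
    members <- split(terms$protein_id, key)
    info <- terms[!duplicated(key), c("term_id", "term_name", "category")]
    info <- info[match(names(members), paste(info$term_id, info$category,
                                             sep = "\r")), ]
    K <- vapply(members, function(m) length(unique(m)), integer(1))
    ov <- vapply(members, function(m) length(intersect(unique(m), hitSet)),
                 integer(1))
    p <- stats::phyper(ov - 1, K, N - K, n, lower.tail = FALSE)
    out <- data.frame(term_id = info$term_id, term_name = info$term_name,
                      category = info$category, n_term = K, overlap = ov,
                      expected = n * K / N, p_value = p,
                      q_value = NA_real_, row.names = NULL,
                      stringsAsFactors = FALSE)
    for (cat in unique(out$category)) {
        i <- out$category == cat
        out$q_value[i] <- bhAdjust(out$p_value[i])
    }
    out$log10_q <- log10(out$q_value)
    out[order(out$category, out$p_value), ]
}

#' Classify proteins by whole-proteome abundance difference
#'
#' Given whole-cell log2 fold changes (state A over state B), assigns each
#' protein to `higher_a` (log2FC >= `fcThresh`), `higher_b`
#' (log2FC <= -`fcThresh`), `equal` otherwise, or `unknown` when no fold
#' change is available — the categories behind "higher / equal abundance"
#' pie charts for state-selective proteins.
#'
#' @param ids protein ids to classify.
#' @param fc named numeric vector of whole-proteome log2 fold changes (A/B).
#' @param fcThresh absolute log2FC at or beyond which abundance is called
#'   different (boundary inclusive; default 1.0).
#' @return A list with `categories` (named character vector per id) and
#'   `percentages` (integer-rounded percentage per category).
#' @examples
#' abundanceCategory(c("a", "b", "c"), c(a = 1.5, b = 0, c = -2))
#' @export
abundanceCategory <- function(ids, fc, fcThresh = 1.0) {
    .assertScalarNumber(fcThresh, "fcThresh", lower = 0)
    v <- fc[ids]
    cat <- ifelse(is.na(v), "unknown",
           ifelse(v >= fcThresh, "higher_a",
           ifelse(v <= -fcThresh, "higher_b", "equal")))
    cat <- stats::setNames(as.character(cat), ids)
    lev <- c("higher_a", "equal", "higher_b", "unknown")
    frac <- table(factor(cat, levels = lev)) / length(ids)
    list(categories = cat,
         percentages = stats::setNames(as.numeric(round(100 * frac)), lev))
}
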