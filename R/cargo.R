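#' Select candidate endocytic cargo from an enriched set
#'
#' Candidate cargo are the enriched proteins harbouring at least one
#' transmembrane segment that are also annotated as localized in the cell
#' membrane — the operational definition of plasma-membrane proteins captured
#' by the endosomal IP. Enriched ids missing from the catalog are excluded
#' with a warning stating how many were dropped.
#'
#' @param enrichedIds character vector of enriched protein ids.
#' @param catalog annotation catalog with `protein_id`, `tm_count`,
#'   `cell_membrane` (and optionally `synaptic`, `domain`, `family`).
#' @return The catalog rows of the selected cargo (a "CargoSet"
#'   `data.frame`); every member has `tm_count >= 1` and `cell_membrane`.
#' @examples
#' cat6 <- simCatalog(simConfig(nProteins = 100, seed = 1))
#' cargo <- selectCandidateCargo(cat6$protein_id, cat6)
#' all(cargo$tm_count >= 1 & cargo$cell_membrane)
#' @export
selectCandidateCargo <- function(enrichedIds, catalog) {
    enrichedIds <- unique(enrichedIds)
    missing <- setdiff(enrichedIds, catalog$protein_id)
    if (length(missing) > 0L)
        warning(length(missing), " enriched id(s) not in the catalog; excluded")
    sub <- catalog[catalog$protein_id %in% enrichedIds, , drop = FALSE]
    out <- sub[sub$tm_count >= 1 & sub$cell_membrane, , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Fraction of a protein universe captured as cargo
#'
#' The percentage of a reference universe (e.g., all annotated PM proteins, or
#' PM proteins with synaptic localization) that appears in the cargo set,
#' rounded to the nearest integer percent.
#'
#' @param universeIds ids of the reference universe (nonempty).
#' @param cargoIds ids of the cargo set.
#' @return Integer percentage `round(100 * |cargo & universe| / |universe|)`.
#' @examples
#' cargoFraction(paste0("u", 1:504), paste0("u", 1:152)) # 30
#' @export
cargoFraction <- function(universeIds, cargoIds) {
    universeIds <- unique(universeIds)
    if (length(universeIds) == 0L) stop("universe is empty")
    round(100 * length(intersect(unique(cargoIds), universeIds)) /
              length(universeIds))
}

#' Categorize cargo by annotated domains and protein families
#'
#' Builds the binary domain-presence matrix (rows ordered by family, then
#' protein id; columns the domain vocabulary observed in the set) and the
#' three-way partition of the cargo: proteins with both an annotated domain
#' and a family, with only one of the two, and with neither.
#'
#' @param cargo a CargoSet `data.frame` from [selectCandidateCargo()] with
#'   `domain` (";"-joined labels or `NA`) and `family` columns.
#' @return A list: `matrix` (logical proteins x domains), `counts` (named:
#'   `domain_and_family`, `domain_or_family_only`, `neither`).
#' @export
categorizeCargo <- function(cargo) {
    if (nrow(cargo) == 0L)
        return(list(matrix = matrix(logical(0), 0, 0),
                    counts = c(domain_and_family = 0L,
                               domain_or_family_only = 0L,
                               neither = 0L)))
    domList <- strsplit(ifelse(is.na(cargo$domain), "", cargo$domain),
                        ";", fixed = TRUE)
    hasD <- lengths(domList) > 0L
    hasF <- !is.na(cargo$family)
    counts <- c(domain_and_family = sum(hasD & hasF),
                domain_or_family_only = sum(xor(hasD, hasF)),
                neither = sum(!hasD & !hasF))
    vocab <- sort(unique(unlist(domList)))
    ord <- order(is.na(cargo$family), cargo$family, cargo$protein_id)
    m <- matrix(FALSE, nrow(cargo), length(vocab),
                dimnames = list(cargo$protein_id[ord], vocab))
    for (i in seq_len(nrow(cargo))) {
        d <- domList[[ord[i]]]
        if (length(d)) m[i, d] <- TRUE
    }
    list(matrix = m, counts = counts)
}

#' Cross-reference cargo against external cargo lists
#'
#' For each cargo protein, records which of the named external id lists it
#' belongs to (a membership bit pattern such as `"snx17+snx27"` or `"none"`),
#' and counts proteins per pattern — the comparison of newly identified cargo
#' with previously reported sorting-dependent surface proteomes.
#'
#' @param cargoIds cargo protein ids.
#' @param lists named list of external id vectors (may be empty).
#' @return A list: `patterns` (named character vector per id), `counts`
#'   (table per pattern, summing to `length(unique(cargoIds))`) and
#'   `fractionNone` (fraction in no external list).
#' @export
crossrefCargo <- function(cargoIds, lists = list()) {
    cargoIds <- unique(cargoIds)
    if (length(lists) == 0L) {
        pat <- stats::setNames(rep("none", length(cargoIds)), cargoIds)
        return(list(patterns = pat,
                    counts = stats::setNames(length(cargoIds), "none"),
                    fractionNone = if (length(cargoIds)) 1 else NaN))
    }
    counts <- .patternCounts(cargoIds, lists)
    pat <- vapply(cargoIds, function(id) {
        inn <- names(lists)[vapply(lists, function(s) id %in% s, logical(1))]
        if (length(inn) == 0L) "none" else paste(inn, collapse = "+")
    }, character(1))
    nNone <- sum(pat == "none")
    list(patterns = pat,
         counts = stats::setNames(as.integer(counts), names(counts)),
         fractionNone = nNone / length(cargoIds))
}
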