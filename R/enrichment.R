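#' Median-center reporter intensities in log2 space
#'
#' Log2-transforms the intensity assay and subtracts each sample's median so
#' every sample column has grand median 0. This removes multiplicative
#' loading/channel differences (a TMT channel scaled by a constant factor maps
#' onto the unscaled channel exactly). Calling the function on an already
#' normalized object only re-centers the medians, so normalization is
#' idempotent.
#'
#' @param se a [SummarizedExperiment::SummarizedExperiment] with a linear-scale
#'   `"intensity"` assay (e.g., from [simQuant()] or [readQuant()]), or an
#'   already normalized object carrying a `"log2norm"` assay.
#' @return A `SummarizedExperiment` with a single `"log2norm"` assay and
#'   `metadata()$log2normalized = TRUE`.
#' @examples
#' sim <- simExperiment(simConfig(nProteins = 50, seed = 1))
#' nq <- normalizeQuant(sim$quant)
#' round(apply(SummarizedExperiment::assay(nq), 2, median), 12)
#' @export
normalizeQuant <- function(se) {
    if (isTRUE(S4Vectors::metadata(se)$log2normalized)) {
        x <- SummarizedExperiment::assay(se, "log2norm")
    } else {
        x <- SummarizedExperiment::assay(se, "intensity")
        if (any(x <= 0, na.rm = TRUE))
            stop("intensities must be positive for log2 transform")
        x <- log2(x)
    }
    allMissing <- colSums(!is.na(x)) == 0L
    if (any(allMissing))
        stop("sample(s) with no observed values: ",
             paste(colnames(x)[allMissing], collapse = ", "))
    med <- apply(x, 2, stats::median, na.rm = TRUE)
    x <- sweep(x, 2, med)
    out <- SummarizedExperiment::SummarizedExperiment(
        assays = list(log2norm = x),
        colData = SummarizedExperiment::colData(se),
        metadata = S4Vectors::metadata(se))
    S4Vectors::metadata(out)$log2normalized <- TRUE
    out
}

.parseContrast <- function(contrast) {
    if (is.character(contrast) && length(contrast) == 1L &&
        grepl(":", contrast, fixed = TRUE)) {
        fac <- sub(":.*$", "", contrast)
        lv <- strsplit(sub("^.*:", "", contrast), "/", fixed = TRUE)[[1]]
        if (length(lv) != 2L)
            stop("contrast string must look like 'factor:levelA/levelB'")
        contrast <- c(fac, lv)
    }
    if (length(contrast) != 3L)
        stop("contrast must be c(factor, levelA, levelB)")
    contrast
}

#' Per-protein differential enrichment between two sample groups
#'
#' Computes log2 fold change (mean A minus mean B on the normalized log2
#' scale) and a two-sample test per protein, with Benjamini-Hochberg
#' correction across all tested proteins. By default the per-protein pooled
#' variance is shrunk toward the global mean variance with `priorDf` prior
#' degrees of freedom (moderated t, the standard stabilisation at 3-4
#' replicates per arm); `priorDf = 0` gives the plain unequal-variance Welch
#' test. Proteins with fewer than `minReps` observed replicates on either side
#' get `NA` statistics and are excluded from the BH universe.
#'
#' @param se a normalized `SummarizedExperiment` (see [normalizeQuant()]; a
#'   linear-scale object is normalized on the fly).
#' @param contrast `c(factor, levelA, levelB)` naming a `colData` column and
#'   the two levels to contrast (A vs B), or a string
#'   `"genotype:tagged/untagged"`.
#' @param fcCut,qCut thresholds used for the `enriched` flag (log2FC >= fcCut
#'   and q <= qCut).
#' @param priorDf prior degrees of freedom for variance shrinkage (0 = pure
#'   Welch).
#' @param minReps minimum observed replicates per arm for a protein to be
#'   tested.
#' @return A `data.frame` with one row per protein: `protein_id`, `log2fc`,
#'   `t_stat`, `p_value`, `q_value`, `enriched`, `n_a`, `n_b`.
#' @examples
#' sim <- simExperiment(simConfig(nProteins = 100, seed = 1))
#' tab <- differential(sim$quant, c("genotype", "tagged", "untagged"))
#' head(tab)
#' @export
differential <- function(se, contrast = c("genotype", "tagged", "untagged"),
                         fcCut = 1.0, qCut = 0.01, priorDf = 4,
                         minReps = 2) {
    contrast <- .parseContrast(contrast)
    if (!isTRUE(S4Vectors::metadata(se)$log2normalized))
        se <- normalizeQuant(se)
    x <- SummarizedExperiment::assay(se, "log2norm")
    fac <- SummarizedExperiment::colData(se)[[contrast[1]]]
    if (is.null(fac))
        stop("design has no column '", contrast[1], "'")
    selA <- fac == contrast[2]
    selB <- fac == contrast[3]
    if (!any(selA) || !any(selB))
        stop(sprintf("contrast selects %d vs %d samples", sum(selA), sum(selB)))
    A <- x[, selA, drop = FALSE]
    B <- x[, selB, drop = FALSE]

    nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
    tested <- nA >= minReps & nB >= minReps
    mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
    log2fc <- mA - mB
    vA <- .rowVars(A); vB <- .rowVars(B)

    if (priorDf > 0) {
        dfRes <- nA + nB - 2
        vp <- ((nA - 1) * vA + (nB - 1) * vB) / dfRes
        v0 <- mean(vp[tested], na.rm = TRUE)
        vs <- (priorDf * v0 + dfRes * vp) / (priorDf + dfRes)
        se2 <- vs * (1 / nA + 1 / nB)
        df <- priorDf + dfRes
    } else {
        se2 <- vA / nA + vB / nB
        df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
    }
    tstat <- log2fc / sqrt(se2)
    # degenerate zero-variance rows: identical groups give t = 0, a real
    # difference with zero spread gives infinite evidence
    zero <- tested & !is.na(se2) & se2 == 0
    tstat[zero & log2fc == 0] <- 0
    tstat[zero & log2fc != 0] <- sign(log2fc[zero & log2fc != 0]) * Inf
    p <- 2 * stats::pt(-abs(tstat), df)
    p[zero & log2fc == 0] <- 1
    p[zero & log2fc != 0] <- 0

    p[!tested] <- NA_real_
    tstat[!tested] <- NA_real_
    log2fc[!tested] <- NA_real_
    q <- rep(NA_real_, length(p))
    q[tested] <- bhAdjust(p[tested])

    enriched <- tested & !is.na(q) & log2fc >= fcCut & q <= qCut
    data.frame(protein_id = rownames(x),
               log2fc = log2fc,
               t_stat = tstat,
               p_value = p,
               q_value = q,
               enriched = enriched,
               n_a = nA, n_b = nB,
               row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: values must
#' lie in \[0, 1\]; `NA`s are carried through without contributing to the
#' number of tests.
#'
#' @param p numeric vector of p values.
#' @return q values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p)) stop("p values must be numeric")
    ok <- !is.na(p)
    if (any(p[ok] < 0 | p[ok] > 1))
        stop("p values must lie in [0, 1]")
    q <- rep(NA_real_, length(p))
    q[ok] <- stats::p.adjust(p[ok], method = "BH")
    q
}

#' Threshold classification of enriched proteins
#'
#' Returns the protein ids passing both the fold-change gate and the q-value
#' gate (log2FC >= `fcCut` and q <= `qCut`), the volcano-plot selection rule.
#'
#' @param tab an enrichment table from [differential()].
#' @param fcCut log2 fold-change cutoff (default 1.0).
#' @param qCut q-value cutoff (default 0.01).
#' @return Character vector of enriched protein ids.
#' @export
classifyEnriched <- function(tab, fcCut = 1.0, qCut = 0.01) {
    sel <- !is.na(tab$log2fc) & !is.na(tab$q_value) &
        tab$log2fc >= fcCut & tab$q_value <= qCut
    tab$protein_id[sel]
}

#' Exact partition counts of two or three id sets
#'
#' Computes the exclusive-region counts of a Venn partition: for two sets,
#' only-A, only-B and the intersection; for three, all seven regions.
#'
#' @param sets a named list of two or three character vectors.
#' @return Named integer vector of exclusive-region counts; region names join
#'   the set names with `"&"`.
#' @examples
#' overlapSets(list(hesc = as.character(1:611),
#'                  ineuron = as.character(376:941)))
#' @export
overlapSets <- function(sets) {
    if (!is.list(sets) || length(sets) < 2L || length(sets) > 3L)
        stop("sets must be a named list of 2 or 3 id vectors")
    if (is.null(names(sets)) || any(names(sets) == ""))
        stop("sets must be named")
    sets <- lapply(sets, unique)
    ids <- unique(unlist(sets))
    member <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
    if (length(ids) == 1L) member <- matrix(member, nrow = 1L,
                                            dimnames = list(NULL, names(sets)))
    pat <- apply(member, 1, function(m)
        paste(names(sets)[m], collapse = "&"))
    combos <- unlist(lapply(seq_along(sets), function(k)
        utils::combn(names(sets), k, paste, collapse = "&")))
    counts <- stats::setNames(integer(length(combos)), combos)
    tb <- table(pat)
    counts[names(tb)] <- as.integer(tb)
    counts
}

#' Per-compartment fold-change distributions
#'
#' Groups the log2 fold changes of an enrichment table by catalog compartment
#' (proteins absent from the catalog form an `"unannotated"` group) and
#' summarises each group, the numbers behind violin plots of IP selectivity.
#'
#' @param tab enrichment table from [differential()].
#' @param catalog annotation catalog with `protein_id` and `compartment`.
#' @return A list with `values` (named list of per-group log2FC vectors) and
#'   `summary` (`data.frame`: compartment, n, median, q1, q3).
#' @export
compartmentSummary <- function(tab, catalog) {
    comp <- catalog$compartment[match(tab$protein_id, catalog$protein_id)]
    comp[is.na(comp)] <- "unannotated"
    keep <- !is.na(tab$log2fc)
    values <- split(tab$log2fc[keep], comp[keep])
    summary <- do.call(rbind, lapply(names(values), function(g) {
        v <- values[[g]]
        data.frame(compartment = g, n = length(v),
                   median = stats::median(v),
                   q1 = unname(stats::quantile(v, 0.25)),
                   q3 = unname(stats::quantile(v, 0.75)),
                   stringsAsFactors = FALSE)
    }))
    if (is.null(summary))
        summary <- data.frame(compartment = character(0), n = integer(0),
                              median = numeric(0), q1 = numeric(0),
                              q3 = numeric(0))
    list(values = values, summary = summary)
}
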