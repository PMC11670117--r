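#' Row-wise z scoring of abundance profiles
#'
#' Centers and scales each protein's profile to mean 0 and sample (n-1)
#' standard deviation 1; constant rows cannot be scaled and are dropped with a
#' warning stating how many.
#'
#' @param m numeric protein x timepoint matrix.
#' @return The z-scored matrix (possibly with fewer rows).
#' @examples
#' zscoreRows(rbind(a = c(1, 2, 3)))  # (-1, 0, 1)
#' @export
zscoreRows <- function(m) {
    stopifnot(is.matrix(m), ncol(m) >= 3)
    sds <- apply(m, 1, stats::sd)
    keep <- !is.na(sds) & sds > 0
    if (any(!keep))
        warning(sum(!keep), " constant row(s) dropped before z scoring")
    m <- m[keep, , drop = FALSE]
    (m - rowMeans(m)) / sds[keep]
}

#' Cluster z-scored time-course profiles
#'
#' Partitions profiles into `k` clusters by centroid-based (k-means)
#' minimisation of within-cluster squared distance, taking the best of
#' `nRestarts` seeded restarts (ties resolved in favour of the earliest
#' restart) and relabelling clusters by descending size so labels are
#' reproducible. Input rows are z-scored first (constant rows dropped, see
#' [zscoreRows()]).
#'
#' @param m protein x timepoint matrix.
#' @param k number of clusters (2 <= k <= number of rows).
#' @param seed integer seed; the same seed always yields the same result.
#' @param nRestarts number of random restarts.
#' @return A list: `assignment` (named cluster ids, contiguous from 1),
#'   `centroids` (k x timepoint, z units), `withinss` (per cluster),
#'   `totWithinss`, `sizes`, `k`.
#' @examples
#' sim <- simExperiment(simConfig(nProteins = 60, seed = 1))
#' cl <- clusterTimecourse(sim$timecourse$profiles, k = 3, seed = 1)
#' cl$sizes
#' @export
clusterTimecourse <- function(m, k = 6, seed = 1, nRestarts = 10) {
    z <- zscoreRows(m)
    n <- nrow(z)
    if (k < 2 || k > n) stop("k must be in 2..", n)
    uz <- unique(z)
    if (nrow(uz) < k)
        stop("fewer than k distinct profiles; cannot seed ", k, " clusters")
    set.seed(as.integer(seed))
    if (k == n) {
        # one protein per cluster: the partition is forced
        best <- list(cluster = seq_len(n), centers = z,
                     withinss = rep(0, k), tot.withinss = 0,
                     size = rep(1L, k))
    } else {
        best <- NULL
        for (r in seq_len(nRestarts)) {
            centers <- uz[sample.int(nrow(uz), k), , drop = FALSE]
            km <- suppressWarnings(
                stats::kmeans(z, centers = centers, iter.max = 100L))
            if (is.null(best) || km$tot.withinss < best$tot.withinss)
                best <- km
        }
    }
    # relabel by descending size (ties: original label order)
    sizes <- best$size
    relabel <- order(-sizes, seq_along(sizes))
    newId <- integer(k)
    newId[relabel] <- seq_len(k)
    assignment <- stats::setNames(newId[best$cluster], rownames(z))
    centroids <- best$centers[relabel, , drop = FALSE]
    rownames(centroids) <- seq_len(k)
    list(assignment = assignment,
         centroids = centroids,
         withinss = best$withinss[relabel],
         totWithinss = best$tot.withinss,
         sizes = sizes[relabel],
         k = k)
}

#' Adjusted agreement between two partitions
#'
#' The adjusted Rand index: 1 for identical partitions (up to relabelling),
#' approximately 0 for independent ones.
#'
#' @param a,b two cluster assignments over the same items (vectors of equal
#'   length, or named vectors matched by name when both are named).
#' @return The adjusted Rand index.
#' @export
clusterAgreement <- function(a, b) {
    if (!is.null(names(a)) && !is.null(names(b))) {
        common <- intersect(names(a), names(b))
        a <- a[common]; b <- b[common]
    }
    stopifnot(length(a) == length(b), length(a) > 1)
    ct <- table(a, b)
    sij <- sum(choose(ct, 2))
    ai <- sum(choose(rowSums(ct), 2))
    bj <- sum(choose(colSums(ct), 2))
    nn <- choose(sum(ct), 2)
    expected <- ai * bj / nn
    denom <- (ai + bj) / 2 - expected
    if (denom == 0) return(1)
    (sij - expected) / denom
}

#' Within-cluster dispersion across candidate k (elbow diagnostic)
#'
#' Runs [clusterTimecourse()] over a range of `k` and reports total
#' within-cluster dispersion, which is non-increasing in `k`; the elbow guides
#' the user-chosen cluster count.
#'
#' @param m protein x timepoint matrix.
#' @param ks candidate cluster counts.
#' @param seed,nRestarts passed to [clusterTimecourse()].
#' @return `data.frame` with columns `k` and `tot_withinss`.
#' @export
elbowDiagnostic <- function(m, ks = 2:8, seed = 1, nRestarts = 10) {
    tw <- vapply(ks, function(k)
        clusterTimecourse(m, k = k, seed = seed,
                          nRestarts = nRestarts)$totWithinss, numeric(1))
    data.frame(k = ks, tot_withinss = tw)
}
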