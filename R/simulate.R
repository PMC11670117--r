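#' Synthetic data with known ground truth
#'
#' The generator family produces every input the pipeline consumes — an
#' annotation catalog, protein sequences with planted sorting motifs, a
#' tagged-vs-untagged reporter-intensity matrix with planted organelle
#' enrichment, a differentiation time course with cluster structure, and
#' mock structure-prediction (ipTM) scores — together with the ground truth
#' needed to score recovery. Everything is a deterministic function of the
#' [SimConfig-class] seed; each generator draws from its own substream
#' (a fixed offset of the master seed) so that, e.g., regenerating sequences
#' does not perturb the quant matrix.
#'
#' @name synthetic-data
NULL

.seedOffsets <- c(catalog = 0L, sequences = 1L, quant = 2L,
                  timecourse = 3L, iptm = 4L, terms = 5L)

.substream <- function(config, stage) {
    set.seed(config@seed + .seedOffsets[[stage]])
}

.domainVocab <- c("Ig-like C2-type", "Fibronectin type-III", "EGF-like",
                  "Protein kinase", "LDL-receptor class A", "Cadherin",
                  "Leucine-rich repeat", "Sushi")
.familyVocab <- c("Nectin", "LDLR", "Neurexin", "Immunoglobulin",
                  "Tyrosine kinase", "Tetraspanin", "SLC transporter",
                  "Ion channel")

#' Generate a per-protein annotation catalog
#'
#' Assigns each protein a compartment (drawn per `compartmentFractions`, the
#' remainder labelled `"other"`), a transmembrane-segment count, a
#' cell-membrane location flag (always set, with TM count >= 1, for
#' plasma-membrane proteins), synaptic-term membership, and sparse
#' extracellular-domain / protein-family labels.
#'
#' @param config a [SimConfig-class].
#' @return A `data.frame` with columns `protein_id`, `compartment`,
#'   `tm_count`, `cell_membrane`, `synaptic`, `domain` (";"-joined labels or
#'   `NA`) and `family`.
#' @examples
#' cat6 <- simCatalog(simConfig(nProteins = 50, seed = 3))
#' table(cat6$compartment)
#' @export
simCatalog <- function(config) {
    methods::validObject(config)
    .substream(config, "catalog")
    n <- config@nProteins
    cf <- config@compartmentFractions
    levels <- c(names(cf), "other")
    compartment <- sample(levels, n, replace = TRUE, prob = c(cf, 1 - sum(cf)))

    tm <- integer(n)
    isPM <- compartment == "pm"
    # PM proteins: single- or multi-pass, never zero
    tm[isPM] <- sample(c(1L, 2L, 4L, 7L, 12L), sum(isPM), replace = TRUE,
                       prob = c(0.45, 0.15, 0.15, 0.20, 0.05))
    isOrg <- compartment %in% c("lysosome", "endosome")
    tm[isOrg] <- sample(c(0L, 1L, 2L, 6L), sum(isOrg), replace = TRUE,
                        prob = c(0.55, 0.25, 0.10, 0.10))
    isOther <- !isPM & !isOrg
    tm[isOther] <- sample(c(0L, 1L), sum(isOther), replace = TRUE,
                          prob = c(0.90, 0.10))

    cellMembrane <- isPM
    synaptic <- stats::runif(n) < config@synapticFraction

    hasDomain <- stats::runif(n) < 0.45
    hasFamily <- stats::runif(n) < 0.50
    domain <- rep(NA_character_, n)
    nd <- sum(hasDomain)
    if (nd > 0) {
        k <- sample(1:2, nd, replace = TRUE, prob = c(0.7, 0.3))
        domain[hasDomain] <- vapply(k, function(m)
            paste(sample(.domainVocab, m), collapse = ";"), character(1))
    }
    family <- rep(NA_character_, n)
    family[hasFamily] <- sample(.familyVocab, sum(hasFamily), replace = TRUE)

    data.frame(
        protein_id = sprintf("P%05d", seq_len(n)),
        compartment = compartment,
        tm_count = tm,
        cell_membrane = cellMembrane,
        synaptic = synaptic,
        domain = domain,
        family = family,
        stringsAsFactors = FALSE
    )
}

#' Generate a synaptic-term membership table
#'
#' Builds a small SynGO-like ontology (location and function categories) and
#' assigns each synaptic protein in the catalog to one to three location terms
#' and up to two function terms.
#'
#' @param catalog output of [simCatalog()].
#' @param config the same [SimConfig-class] used for the catalog.
#' @return Long-format `data.frame` with columns `term_id`, `term_name`,
#'   `category` and `protein_id`.
#' @export
simTerms <- function(catalog, config) {
    .substream(config, "terms")
    loc <- c("presynapse", "postsynapse", "synaptic vesicle",
             "postsynaptic density", "synaptic membrane")
    fun <- c("synapse organization", "synaptic signaling",
             "transport at the synapse")
    terms <- data.frame(
        term_id = c(sprintf("LOC:%04d", seq_along(loc)),
                    sprintf("FUN:%04d", seq_along(fun))),
        term_name = c(loc, fun),
        category = c(rep("location", length(loc)), rep("function", length(fun))),
        stringsAsFactors = FALSE
    )
    syn <- catalog$protein_id[catalog$synaptic]
    rows <- lapply(syn, function(id) {
        nl <- sample(1:3, 1L)
        picked <- c(sample(which(terms$category == "location"), nl),
                    sample(which(terms$category == "function"),
                           sample(0:2, 1L)))
        cbind(terms[picked, , drop = FALSE], protein_id = id)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    if (is.null(out))
        out <- cbind(terms[0, , drop = FALSE], protein_id = character(0))
    rownames(out) <- NULL
    out
}

.matchesSNX27tail <- function(last3, phi) {
    substr(last3, 1, 1) %in% c("S", "T") && substr(last3, 3, 3) %in% phi
}

# all SNX17-pattern window starts in a character string (overlaps allowed)
.snx17starts <- function(seq, phi) {
    L <- nchar(seq)
    if (L < 6) return(integer(0))
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    starts <- seq_len(L - 5L)
    starts[ch[starts] %in% phi & ch[starts + 2L] == "N" &
           ch[starts + 5L] %in% c("F", "Y")]
}

#' Generate protein sequences with planted sorting motifs
#'
#' Each protein gets a uniform-background amino-acid sequence. A configured
#' fraction is planted with an SNX27 PDZ-binding C-terminus (final triplet
#' \[S/T\]-x-Phi, positions -4..-6 drawn acidic/phospho-rich) and a fraction
#' with an internal SNX17 FERM-binding window (Phi-x-N-x-x-\[F/Y\]).
#' Non-planted proteins are rejection-sampled so their C-terminal triplet
#' never matches the SNX27 pattern; incidental internal SNX17 matches are
#' permitted (and recorded) unless `suppressIncidentalSNX17` is set, in which
#' case the offending windows are neutralised so scan counts equal plant
#' counts exactly.
#'
#' @param catalog output of [simCatalog()].
#' @param config a [SimConfig-class].
#' @param suppressIncidentalSNX17 force the background SNX17 match rate to 0.
#' @return A list with `sequences` (a named [Biostrings::AAStringSet]) and
#'   `truth`: `motifIdsSNX27`, `motifIdsSNX17`, `snx17Planted`
#'   (protein/start), and `incidentalSNX17` (chance matches present in the
#'   emitted sequences).
#' @export
simSequences <- function(catalog, config, suppressIncidentalSNX17 = FALSE) {
    .substream(config, "sequences")
    n <- nrow(catalog)
    ids <- catalog$protein_id
    phi <- c("A", "V", "L", "I", "M", "F", "W", "Y")
    lens <- sample(seq(config@seqLengthRange[1], config@seqLengthRange[2]),
                   n, replace = TRUE)
    nS27 <- round(config@motifPlantRateSNX27 * n)
    nS17 <- round(config@motifPlantRateSNX17 * n)
    ids27 <- sort(sample(ids, nS27))
    ids17 <- sort(sample(ids, nS17))

    acidicPool <- c("D", "E", "S", "T", "A", "G")
    acidicProb <- c(0.25, 0.25, 0.15, 0.15, 0.10, 0.10)

    seqs <- character(n)
    s17start <- stats::setNames(rep(NA_integer_, n), ids)
    for (i in seq_len(n)) {
        L <- lens[i]
        ch <- sample(AA20, L, replace = TRUE)
        id <- ids[i]
        if (id %in% ids27) {
            ch[(L - 2):L] <- c(sample(c("S", "T"), 1L), sample(AA20, 1L),
                               sample(phi, 1L))
            ch[(L - 5):(L - 3)] <- sample(acidicPool, 3L, replace = TRUE,
                                          prob = acidicProb)
        } else {
            # reject C-terminal triplets matching the SNX27 pattern
            while (ch[L - 2] %in% c("S", "T") && ch[L] %in% phi)
                ch[(L - 2):L] <- sample(AA20, 3L, replace = TRUE)
        }
        if (id %in% ids17) {
            st <- sample(4:(L - 9), 1L)
            ch[st:(st + 5L)] <- c(sample(phi, 1L), sample(AA20, 1L), "N",
                                  sample(AA20, 2L, replace = TRUE),
                                  sample(c("F", "Y"), 1L))
            s17start[id] <- st
        }
        seqs[i] <- paste(ch, collapse = "")
    }

    if (suppressIncidentalSNX17) {
        for (i in seq_len(n)) {
            id <- ids[i]
            repeat {
                st <- .snx17starts(seqs[i], phi)
                bad <- setdiff(st, s17start[id])
                if (length(bad) == 0L) break
                ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
                # replacing the obligate N never creates a new match elsewhere;
                # keep positions constrained by a planted window valid
                st0 <- s17start[id]
                for (p in bad + 2L) {
                    pool <- if (!is.na(st0) && p == st0) {
                        phi
                    } else if (!is.na(st0) && p == st0 + 5L) {
                        c("F", "Y")
                    } else {
                        setdiff(AA20, "N")
                    }
                    ch[p] <- sample(pool, 1L)
                }
                seqs[i] <- paste(ch, collapse = "")
            }
        }
    }

    inc <- lapply(seq_len(n), function(i) {
        st <- .snx17starts(seqs[i], phi)
        st <- setdiff(st, s17start[ids[i]])
        if (length(st) == 0L) return(NULL)
        data.frame(protein_id = ids[i], start = st, stringsAsFactors = FALSE)
    })
    inc <- do.call(rbind, inc)
    if (is.null(inc))
        inc <- data.frame(protein_id = character(0), start = integer(0))

    sset <- Biostrings::AAStringSet(stats::setNames(seqs, ids))
    planted <- data.frame(protein_id = ids17,
                          start = unname(s17start[ids17]),
                          stringsAsFactors = FALSE)
    list(sequences = sset,
         truth = list(motifIdsSNX27 = ids27,
                      motifIdsSNX17 = ids17,
                      snx17Planted = planted,
                      incidentalSNX17 = inc))
}

#' Generate a tagged-vs-untagged reporter-intensity matrix
#'
#' Log2 intensity of protein *i* in sample *s* is
#' `baseline_i + effect_i * [tagged & enriched] + offset_s + N(0, noiseSd)`,
#' emitted on the linear scale (`2^x`). The enriched set is every protein
#' whose compartment has a nonzero `enrichmentEffect`. Channel offsets are
#' drawn once per sample to exercise normalization.
#'
#' @param catalog output of [simCatalog()].
#' @param config a [SimConfig-class].
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `"intensity"` (linear scale), the sample design in `colData` and the
#'   ground truth (`enrichedIds`, per-sample offsets) in `metadata`.
#' @export
simQuant <- function(catalog, config) {
    .substream(config, "quant")
    n <- nrow(catalog)
    r <- config@nReplicates
    design <- data.frame(
        sample_id = c(sprintf("tagged_%d", seq_len(r)),
                      sprintf("untagged_%d", seq_len(r))),
        genotype = rep(c("tagged", "untagged"), each = r),
        ip_type = "endo",
        state = "ineuron",
        treatment = "none",
        replicate = rep(seq_len(r), 2L),
        stringsAsFactors = FALSE
    )
    eff <- config@enrichmentEffect[catalog$compartment]
    eff[is.na(eff)] <- 0
    enrichedIds <- catalog$protein_id[eff != 0]

    baseline <- stats::rnorm(n, config@baselineLog2Mean, config@baselineLog2Sd)
    offsets <- stats::rnorm(nrow(design), 0, config@channelOffsetSd)
    tagged <- design$genotype == "tagged"
    log2x <- outer(baseline, offsets, `+`) +
        outer(eff, as.numeric(tagged)) +
        matrix(stats::rnorm(n * nrow(design), 0, config@noiseSd),
               n, nrow(design))
    x <- 2^log2x
    dimnames(x) <- list(catalog$protein_id, design$sample_id)
    if (config@missingQuantile > 0) {
        x[x < stats::quantile(x, config@missingQuantile)] <- NA
    }
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = x),
        colData = S4Vectors::DataFrame(design, row.names = design$sample_id),
        metadata = list(enrichedIds = enrichedIds,
                        channelOffsets = stats::setNames(offsets,
                                                         design$sample_id),
                        effect = config@enrichmentEffect)
    )
}

# z-scored profile templates over nT timepoints; the first k are used
.tcTemplates <- function(nT, k) {
    t01 <- seq(0, 1, length.out = nT)
    raw <- rbind(
        up        = t01,
        down      = -t01,
        transient = sin(pi * t01),
        late_up   = t01^3,
        early_up  = 1 - (1 - t01)^3,
        dip       = -sin(pi * t01)
    )
    z <- t(apply(raw, 1, function(x) (x - mean(x)) / stats::sd(x)))
    z[seq_len(k), , drop = FALSE]
}

#' Generate a differentiation time course with cluster structure
#'
#' Each protein is assigned one of `nClusters` z-scored profile templates
#' (monotone up/down, transient, and variants) and observed with Gaussian
#' noise. Templates are checked to be pairwise separated by at least three
#' times the noise sd in z space so cluster recovery is well posed.
#'
#' @param catalog output of [simCatalog()].
#' @param config a [SimConfig-class].
#' @return A list with `profiles` (protein x timepoint matrix, columns
#'   `day_0 ... day_12`), `clusters` (named ground-truth assignment) and
#'   `templates` (the z-scored template matrix).
#' @export
simTimecourse <- function(catalog, config) {
    .substream(config, "timecourse")
    n <- nrow(catalog)
    k <- config@nClusters
    nT <- config@nTimepoints
    tpl <- .tcTemplates(nT, k)
    if (config@tcNoiseSd > 0) {
        dmin <- min(stats::dist(tpl))
        if (dmin < 3 * config@tcNoiseSd)
            stop(sprintf(
                "templates separated by %.2f < 3 x noise sd (%.2f) in z space",
                dmin, config@tcNoiseSd))
    }
    cl <- sample(seq_len(k), n, replace = TRUE)
    prof <- tpl[cl, , drop = FALSE] +
        matrix(stats::rnorm(n * nT, 0, config@tcNoiseSd), n, nT)
    days <- round(seq(0, 12, length.out = nT))
    dimnames(prof) <- list(catalog$protein_id, paste0("day_", days))
    list(profiles = prof,
         clusters = stats::setNames(cl, catalog$protein_id),
         templates = tpl)
}

#' Generate mock structure-prediction confidence scores
#'
#' Candidates flagged as planted draw their ipTM from the high-confidence
#' Beta mode, all others from the low-confidence mode; all values lie in
#' \[0, 1\].
#'
#' @param candidates `data.frame` with at least `candidate_id` and a logical
#'   `planted` column (e.g., from [motifCandidates()] joined to ground truth).
#' @param config a [SimConfig-class].
#' @return The input with an added numeric `iptm` column.
#' @export
simIptm <- function(candidates, config) {
    stopifnot(is.data.frame(candidates), "planted" %in% names(candidates))
    .substream(config, "iptm")
    nHi <- sum(candidates$planted)
    nLo <- sum(!candidates$planted)
    iptm <- numeric(nrow(candidates))
    iptm[candidates$planted] <- stats::rbeta(nHi, config@iptmHighParams[1],
                                             config@iptmHighParams[2])
    iptm[!candidates$planted] <- stats::rbeta(nLo, config@iptmLowParams[1],
                                              config@iptmLowParams[2])
    candidates$iptm <- iptm
    candidates
}

#' Run every generator and collect ground truth
#'
#' Convenience wrapper producing all synthetic inputs for one experiment:
#' catalog, term table, sequences (+ motif truth), quant matrix (+ enrichment
#' truth) and time course (+ cluster truth). ipTM scores are generated later,
#' once motif candidates have been enumerated (see [motifCandidates()] and
#' [simIptm()]).
#'
#' @param config a [SimConfig-class].
#' @param suppressIncidentalSNX17 passed to [simSequences()].
#' @return A list: `catalog`, `terms`, `sequences`, `quant`, `timecourse`,
#'   `truth` (merged ground-truth list).
#' @examples
#' sim <- simExperiment(simConfig(nProteins = 100, seed = 2))
#' names(sim)
#' @export
simExperiment <- function(config, suppressIncidentalSNX17 = FALSE) {
    catalog <- simCatalog(config)
    terms <- simTerms(catalog, config)
    sq <- simSequences(catalog, config, suppressIncidentalSNX17)
    quant <- simQuant(catalog, config)
    tc <- simTimecourse(catalog, config)
    truth <- c(sq$truth,
               list(enrichedIds = S4Vectors::metadata(quant)$enrichedIds,
                    clusterAssignment = tc$clusters))
    list(catalog = catalog, terms = terms, sequences = sq$sequences,
         quant = quant, timecourse = tc, truth = truth, config = config)
}
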