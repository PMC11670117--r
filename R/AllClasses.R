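#' Simulation configuration for synthetic organelle-IP experiments
#'
#' An S4 container holding every parameter of the synthetic-data generator:
#' catalog composition, planted enrichment effects, reporter-intensity noise,
#' motif plant rates, time-course structure and ipTM score distributions.
#' All generator functions consume a `SimConfig` so that a single seed fully
#' determines every synthetic dataset.
#'
#' @slot nProteins number of proteins in the catalog.
#' @slot compartmentFractions named fractions (must sum to at most 1) of
#'   proteins assigned to the labelled compartments; the remainder is labelled
#'   `"other"` (cytosol/ER/Golgi/mitochondria pool).
#' @slot enrichmentEffect named log2-unit enrichment planted in tagged-IP
#'   channels, per compartment; compartments absent from the vector get 0.
#' @slot noiseSd per-measurement Gaussian noise, log2 units.
#' @slot nReplicates replicates per genotype arm (>= 2).
#' @slot baselineLog2Mean,baselineLog2Sd protein baseline abundance, log2 units.
#' @slot channelOffsetSd per-sample (TMT channel) offset sd, log2 units.
#' @slot motifPlantRateSNX27,motifPlantRateSNX17 fraction of proteins that get
#'   a planted sorting motif of each class.
#' @slot seqLengthRange min/max simulated sequence length (min >= 20 residues).
#' @slot synapticFraction fraction of proteins carrying synaptic-term
#'   membership.
#' @slot nTimepoints,nClusters differentiation time-course shape.
#' @slot tcNoiseSd time-course noise sd in z-score units.
#' @slot iptmHighParams,iptmLowParams Beta(shape1, shape2) parameters of the
#'   high-confidence (planted motif) and low-confidence (control) ipTM modes.
#' @slot missingQuantile intensities below this quantile are masked as missing
#'   (0 disables masking).
#' @slot seed integer seed; all generator substreams derive from it.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @export
setClass("SimConfig", representation(
    nProteins = "numeric",
    compartmentFractions = "numeric",
    enrichmentEffect = "numeric",
    noiseSd = "numeric",
    nReplicates = "numeric",
    baselineLog2Mean = "numeric",
    baselineLog2Sd = "numeric",
    channelOffsetSd = "numeric",
    motifPlantRateSNX27 = "numeric",
    motifPlantRateSNX17 = "numeric",
    seqLengthRange = "numeric",
    synapticFraction = "numeric",
    nTimepoints = "numeric",
    nClusters = "numeric",
    tcNoiseSd = "numeric",
    iptmHighParams = "numeric",
    iptmLowParams = "numeric",
    missingQuantile = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character(0)
    cf <- object@compartmentFractions
    if (length(cf) == 0L || is.null(names(cf)) || any(names(cf) == ""))
        msg <- c(msg, "compartmentFractions must be a named numeric vector")
    if (any(cf < 0) || any(cf > 1))
        msg <- c(msg, "compartment fractions must lie in [0, 1]")
    if (sum(cf) > 1 + 1e-12)
        msg <- c(msg, sprintf("compartment fractions sum to %.3f > 1", sum(cf)))
    if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
    if (object@nReplicates < 2) msg <- c(msg, "nReplicates must be >= 2")
    if (length(object@seqLengthRange) != 2L ||
        object@seqLengthRange[1] < 20 ||
        diff(object@seqLengthRange) < 0)
        msg <- c(msg, "seqLengthRange must be (min, max) with min >= 20")
    for (f in c("motifPlantRateSNX27", "motifPlantRateSNX17",
                "synapticFraction", "missingQuantile")) {
        v <- methods::slot(object, f)
        if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
    }
    if (object@nTimepoints < 3) msg <- c(msg, "nTimepoints must be >= 3")
    if (object@nClusters < 2 || object@nClusters > 6)
        msg <- c(msg, "nClusters must be in 2..6 (that many templates exist)")
    for (f in c("iptmHighParams", "iptmLowParams")) {
        v <- methods::slot(object, f)
        if (length(v) != 2L || any(v <= 0))
            msg <- c(msg, sprintf("%s must be two positive Beta shapes", f))
    }
    if (object@nProteins < 1) msg <- c(msg, "nProteins must be >= 1")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' Construct a simulation configuration
#'
#' Defaults emulate the study design the package targets: a 1000-protein
#' catalog with lysosomal/endosomal/plasma-membrane compartments, a planted
#' 2.0 log2-unit tagged-vs-untagged IP enrichment for organelle-resident
#' proteins, triplicate arms, 0.3 log2 units of measurement noise, TMT-style
#' per-channel offsets, sorting-motif plant rates matching the reported scale
#' of 25 SNX27 and 60 SNX17 candidates among 241 cargo, a 5-timepoint
#' 12-day differentiation course with 3 profile templates, and bimodal ipTM
#' scores separated around the 0.6 triage threshold.
#'
#' @param nProteins catalog size.
#' @param compartmentFractions named fractions per compartment (sum <= 1).
#' @param enrichmentEffect named log2 enrichment per compartment.
#' @param noiseSd measurement noise sd, log2 units.
#' @param nReplicates replicates per genotype arm.
#' @param baselineLog2Mean,baselineLog2Sd baseline abundance distribution.
#' @param channelOffsetSd per-sample offset sd, log2 units.
#' @param motifPlantRateSNX27,motifPlantRateSNX17 motif plant fractions.
#' @param seqLengthRange sequence length range, residues.
#' @param synapticFraction fraction with synaptic-term membership.
#' @param nTimepoints,nClusters time-course dimensions.
#' @param tcNoiseSd time-course noise sd (z units).
#' @param iptmHighParams,iptmLowParams Beta shapes of the two ipTM modes.
#' @param missingQuantile quantile below which intensities are masked (0 = off).
#' @param seed integer master seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nProteins = 200, seed = 7)
#' cfg
#' @export
simConfig <- function(nProteins = 1000,
                      compartmentFractions = c(lysosome = 0.10,
                                               endosome = 0.10,
                                               pm = 0.15),
                      enrichmentEffect = c(lysosome = 2.0,
                                           endosome = 2.0,
                                           pm = 2.0),
                      noiseSd = 0.3,
                      nReplicates = 3,
                      baselineLog2Mean = 18,
                      baselineLog2Sd = 2,
                      channelOffsetSd = 0.2,
                      motifPlantRateSNX27 = 25 / 241,
                      motifPlantRateSNX17 = 60 / 241,
                      seqLengthRange = c(50, 500),
                      synapticFraction = 0.15,
                      nTimepoints = 5,
                      nClusters = 3,
                      tcNoiseSd = 0.2,
                      iptmHighParams = c(16, 4),
                      iptmLowParams = c(4, 8),
                      missingQuantile = 0,
                      seed = 1L) {
    methods::new("SimConfig",
        nProteins = nProteins,
        compartmentFractions = compartmentFractions,
        enrichmentEffect = enrichmentEffect,
        noiseSd = noiseSd,
        nReplicates = nReplicates,
        baselineLog2Mean = baselineLog2Mean,
        baselineLog2Sd = baselineLog2Sd,
        channelOffsetSd = channelOffsetSd,
        motifPlantRateSNX27 = motifPlantRateSNX27,
        motifPlantRateSNX17 = motifPlantRateSNX17,
        seqLengthRange = seqLengthRange,
        synapticFraction = synapticFraction,
        nTimepoints = nTimepoints,
        nClusters = nClusters,
        tcNoiseSd = tcNoiseSd,
        iptmHighParams = iptmHighParams,
        iptmLowParams = iptmLowParams,
        missingQuantile = missingQuantile,
        seed = as.integer(seed))
}

#' @describeIn SimConfig-class compact display of the key parameters
#' @param object a `SimConfig`
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nProteins, "proteins, seed", object@seed, "\n")
    cat("  compartments:",
        paste(sprintf("%s=%.2f", names(object@compartmentFractions),
                      object@compartmentFractions), collapse = ", "), "\n")
    cat("  effect (log2):",
        paste(sprintf("%s=%.2f", names(object@enrichmentEffect),
                      object@enrichmentEffect), collapse = ", "),
        " noise sd:", object@noiseSd, "\n")
    cat("  replicates:", object@nReplicates,
        " motif plant rates:", round(object@motifPlantRateSNX27, 3), "/",
        round(object@motifPlantRateSNX17, 3), "\n")
    invisible(NULL)
})

#' Position weight matrix with per-position information content
#'
#' Rows are motif positions, columns the 20 standard residues (alphabetical);
#' each row is a probability distribution. Information content per position is
#' `log2(20) - H(p)` in bits, so 0 for a uniform position and `log2(20)`
#' (about 4.32) for an invariant one.
#'
#' @slot probs numeric matrix, positions x 20 residues; rows sum to 1.
#' @slot ic numeric vector of per-position information content, bits.
#' @slot nSeqs number of peptides the matrix was built from.
#' @slot pseudocount pseudocount per residue used in estimation.
#' @seealso [buildPWM()], [pwmMatrix()], [informationContent()]
#' @export
setClass("PWM", representation(
    probs = "matrix",
    ic = "numeric",
    nSeqs = "integer",
    pseudocount = "numeric"
))

setValidity("PWM", function(object) {
    msg <- character(0)
    p <- object@probs
    if (ncol(p) != 20L || !identical(colnames(p), AA20))
        msg <- c(msg, "probs must have the 20 standard residues as columns")
    if (any(abs(rowSums(p) - 1) > 1e-9))
        msg <- c(msg, "each PWM row must sum to 1 (tolerance 1e-9)")
    if (any(p < -1e-12))
        msg <- c(msg, "probabilities must be nonnegative")
    if (length(object@ic) != nrow(p))
        msg <- c(msg, "one information-content value per position required")
    if (any(object@ic < -1e-9) || any(object@ic > log2(20) + 1e-9))
        msg <- c(msg, "information content must lie in [0, log2(20)]")
    if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn PWM-class display dimensions, consensus and peak positions
#' @param object a `PWM`
#' @export
setMethod("show", "PWM", function(object) {
    cat(sprintf("PWM: %d positions x 20 residues (from %d peptides, pseudocount %g)\n",
                nrow(object@probs), object@nSeqs, object@pseudocount))
    cat("  consensus:", paste(consensusResidues(object), collapse = ""), "\n")
    cat("  information content (bits):",
        paste(sprintf("%s=%.2f", rownames(object@probs),
                      round(object@ic, 2)), collapse = " "), "\n")
    invisible(NULL)
})

#' @rdname PWM-class
#' @param pwm a `PWM` object
#' @return `pwmMatrix` returns the position x residue probability matrix.
#' @export
pwmMatrix <- function(pwm) pwm@probs

#' @rdname PWM-class
#' @return `informationContent` returns the per-position IC vector in bits.
#' @export
informationContent <- function(pwm) stats::setNames(pwm@ic, rownames(pwm@probs))

#' @rdname PWM-class
#' @return `consensusResidues` returns the highest-probability residue per
#'   position.
#' @export
consensusResidues <- function(pwm) {
    stats::setNames(colnames(pwm@probs)[apply(pwm@probs, 1, which.max)],
                    rownames(pwm@probs))
}
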