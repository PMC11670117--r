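test_that("invalid configurations are rejected", {
    expect_error(simConfig(compartmentFractions = c(lysosome = 0.7, pm = 0.5)),
                 "sum")
    expect_error(simConfig(nReplicates = 1), "nReplicates")
    expect_error(simConfig(seqLengthRange = c(5, 100)), "seqLengthRange")
    expect_error(simConfig(motifPlantRateSNX27 = 1.2), "\\[0, 1\\]")
})

test_that("catalog composition follows the configured fractions", {
    cfg <- simConfig(nProteins = 500, seed = 4)
    cat1 <- simCatalog(cfg)
    expect_identical(cat1, simCatalog(cfg))            # determinism
    pm <- cat1[cat1$compartment == "pm", ]
    expect_true(all(pm$tm_count >= 1))
    expect_true(all(pm$cell_membrane))
    expect_true(all(!cat1$cell_membrane[cat1$compartment != "pm"]))

    # zero PM fraction forces zero PM proteins
    cfg0 <- simConfig(nProteins = 200,
                      compartmentFractions = c(lysosome = 0.2, endosome = 0.1,
                                               pm = 0),
                      seed = 2)
    expect_false(any(simCatalog(cfg0)$compartment == "pm"))

    # lysosome count ~ Binomial(1000, 0.1): stay within the 1e-4 tail bounds
    lo <- qbinom(5e-5, 1000, 0.1); hi <- qbinom(1 - 5e-5, 1000, 0.1)
    for (s in 1:5) {
        k <- sum(simCatalog(simConfig(nProteins = 1000, seed = s))$compartment
                 == "lysosome")
        expect_gte(k, lo); expect_lte(k, hi)
    }
})

test_that("planted motifs are guaranteed and background SNX27 is impossible", {
    cfg <- simConfig(nProteins = 120, motifPlantRateSNX27 = 0.25,
                     motifPlantRateSNX17 = 0.3, seed = 9)
    cat1 <- simCatalog(cfg)
    sq <- simSequences(cat1, cfg)
    seqs <- as.character(sq$sequences)
    expect_identical(as.character(simSequences(cat1, cfg)$sequences), seqs)
    lens <- nchar(seqs)
    expect_true(all(lens >= 50 & lens <= 500))

    planted27 <- sq$truth$motifIdsSNX27
    expect_length(planted27, round(0.25 * 120))
    expect_true(all(snx27OracleHit(seqs[planted27])))
    expect_false(any(snx27OracleHit(seqs[setdiff(names(seqs), planted27)])))

    p17 <- sq$truth$snx17Planted
    expect_length(sq$truth$motifIdsSNX17, round(0.3 * 120))
    for (i in seq_len(nrow(p17)))
        expect_true(p17$start[i] %in% snx17OracleStarts(seqs[[p17$protein_id[i]]]))

    # plant rate 0: no sequence ends in the SNX27 pattern
    cfg0 <- simConfig(nProteins = 80, motifPlantRateSNX27 = 0,
                      motifPlantRateSNX17 = 0, seed = 9)
    sq0 <- simSequences(simCatalog(cfg0), cfg0)
    expect_false(any(snx27OracleHit(as.character(sq0$sequences))))
    expect_length(sq0$truth$motifIdsSNX27, 0)
})

test_that("background SNX17 match rate follows the analytic window probability", {
    # per window: P(phi) * P(N) * P(F/Y) = 0.4 * 0.05 * 0.1 = 0.002
    cfg <- simConfig(nProteins = 250, motifPlantRateSNX27 = 0,
                     motifPlantRateSNX17 = 0, seqLengthRange = c(200, 400),
                     seed = 21)
    sq <- simSequences(simCatalog(cfg), cfg)
    seqs <- as.character(sq$sequences)
    nWindows <- sum(nchar(seqs) - 5)
    nMatches <- sum(vapply(seqs, function(s) length(snx17OracleStarts(s)),
                           integer(1)))
    p0 <- 0.002
    band <- 5 * sqrt(p0 * (1 - p0) / nWindows)
    expect_lt(abs(nMatches / nWindows - p0), band)
    # and the generator recorded exactly these incidental matches
    expect_equal(nrow(sq$truth$incidentalSNX17), nMatches)
})

test_that("suppression forces the background SNX17 rate to zero", {
    cfg <- simConfig(nProteins = 60, seed = 5)
    sq <- simSequences(simCatalog(cfg), cfg, suppressIncidentalSNX17 = TRUE)
    seqs <- as.character(sq$sequences)
    expect_equal(nrow(sq$truth$incidentalSNX17), 0)
    for (id in names(seqs)) {
        st <- snx17OracleStarts(seqs[[id]])
        want <- sq$truth$snx17Planted$start[sq$truth$snx17Planted$protein_id == id]
        expect_identical(st, as.integer(sort(want)))
    }
})

test_that("quant matrix encodes the planted enrichment", {
    base <- simConfig(nProteins = 150,
                      compartmentFractions = c(lysosome = 0.2),
                      enrichmentEffect = c(lysosome = 2.0),
                      noiseSd = 1e-12, channelOffsetSd = 0.2, seed = 3)
    cat1 <- simCatalog(base)
    se <- simQuant(cat1, base)
    x <- log2(SummarizedExperiment::assay(se, "intensity"))
    off <- S4Vectors::metadata(se)$channelOffsets
    x <- sweep(x, 2, off)  # exact channel-offset removal
    gt <- S4Vectors::metadata(se)$enrichedIds
    fc <- rowMeans(x[, 1:3]) - rowMeans(x[, 4:6])
    expect_equal(unname(fc[gt]), rep(2, length(gt)), tolerance = 1e-6)
    expect_equal(unname(fc[setdiff(rownames(x), gt)]),
                 rep(0, 150 - length(gt)), tolerance = 1e-6)

    # null model: effect 0 everywhere, per-protein log2FC averages to ~0
    cfg0 <- simConfig(nProteins = 400,
                      compartmentFractions = c(lysosome = 0.2),
                      enrichmentEffect = c(lysosome = 0), seed = 3)
    se0 <- simQuant(simCatalog(cfg0), cfg0)
    expect_length(S4Vectors::metadata(se0)$enrichedIds, 0)
    x0 <- log2(SummarizedExperiment::assay(se0))
    x0 <- sweep(x0, 2, S4Vectors::metadata(se0)$channelOffsets)
    fc0 <- rowMeans(x0[, 1:3]) - rowMeans(x0[, 4:6])
    expect_lt(abs(mean(fc0)), 4 * 0.3 * sqrt(2 / 3) / sqrt(400))
})

test_that("estimated log2FC has the closed-form sampling distribution", {
    # diff of two 3-replicate means at noise sd 0.3: sd = 0.3 * sqrt(2/3)
    cfg <- simConfig(nProteins = 1000,
                     compartmentFractions = c(lysosome = 0.25),
                     enrichmentEffect = c(lysosome = 2.0),
                     noiseSd = 0.3, seed = 8)
    se <- simQuant(simCatalog(cfg), cfg)
    x <- log2(SummarizedExperiment::assay(se))
    x <- sweep(x, 2, S4Vectors::metadata(se)$channelOffsets)
    gt <- S4Vectors::metadata(se)$enrichedIds
    fc <- rowMeans(x[gt, 1:3]) - rowMeans(x[gt, 4:6])
    sdTheory <- 0.3 * sqrt(2 / 3)
    expect_equal(mean(fc), 2, tolerance = 4 * sdTheory / sqrt(length(gt)))
    expect_equal(sd(fc), sdTheory, tolerance = 0.05)
})

test_that("time-course templates separate and ipTM scores stay in range", {
    cfg <- simConfig(nProteins = 90, tcNoiseSd = 0, seed = 6)
    tc <- simTimecourse(simCatalog(cfg), cfg)
    z <- zscoreRows(tc$profiles)
    for (k in unique(tc$clusters)) {
        rows <- z[names(tc$clusters)[tc$clusters == k], , drop = FALSE]
        expect_lt(max(dist(rows)), 1e-9)  # noise 0: identical z profiles
    }
    # 2 clusters, up vs down: sign of (last - first) separates perfectly
    cfg2 <- simConfig(nProteins = 50, nClusters = 2, tcNoiseSd = 0, seed = 6)
    tc2 <- simTimecourse(simCatalog(cfg2), cfg2)
    sgn <- sign(tc2$profiles[, 5] - tc2$profiles[, 1])
    expect_true(all(tapply(sgn, tc2$clusters, function(v)
        length(unique(v)) == 1)))

    cand <- data.frame(candidate_id = sprintf("c%04d", 1:2000),
                       planted = rep(c(TRUE, FALSE), 1000))
    scored <- simIptm(cand, simConfig(seed = 17))
    expect_true(all(scored$iptm >= 0 & scored$iptm <= 1))
    expect_gt(mean(scored$iptm[scored$planted]),
              mean(scored$iptm[!scored$planted]))
})

test_that("control ipTM pass rate can be calibrated and is hit", {
    # choose the low mode so that P(ipTM > 0.6) = 0.05 exactly
    b <- uniroot(function(b) pbeta(0.6, 2, b, lower.tail = FALSE) - 0.05,
                 c(2, 50))$root
    cfg <- simConfig(iptmLowParams = c(2, b), seed = 12)
    cand <- data.frame(candidate_id = sprintf("c%04d", 1:4000),
                       planted = FALSE)
    scored <- simIptm(cand, cfg)
    rate <- mean(scored$iptm > 0.6)
    expect_lt(abs(rate - 0.05), 5 * sqrt(0.05 * 0.95 / 4000))
})
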