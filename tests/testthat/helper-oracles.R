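# Independent oracles used across the suite. Each deliberately takes a
# different route than the implementation (regex engines, exhaustive
# enumeration, textbook formulas) so agreement is evidence, not tautology.

# step-up BH computed directly from its definition
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    q <- pmin(q, 1)
    out <- numeric(m)
    out[o] <- q
    out
}

# exhaustive hypergeometric upper tail: enumerate every n-subset of 1..N and
# count those overlapping the first K elements by >= ov
hyperOracle <- function(N, K, n, ov) {
    draws <- utils::combn(N, n)
    mean(colSums(draws <= K) >= ov)
}

# regex-based motif checks (PCRE route, independent of the window scanner)
PHI_RE <- "[AVLIMFWY]"
snx27OracleHit <- function(seq) grepl(paste0("[ST].", PHI_RE, "$"), seq)
snx17OracleStarts <- function(seq) {
    m <- gregexpr(paste0("(?=", PHI_RE, ".N..[FY])"), seq, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
}
contextOracle <- function(seq) {
    L <- nchar(seq)
    win <- substr(seq, max(1, L - 7), L - 3)
    sum(strsplit(win, "")[[1]] %in% c("D", "E", "S", "T"))
}

randomSeq <- function(len) {
    paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y"),
                 len, replace = TRUE), collapse = "")
}

# simulate + test one tagged-vs-untagged experiment; returns sensitivity and
# empirical FDR at the given cutoffs
recoveryRun <- function(seed, nProteins = 1000, frac = 0.1, effect = 2,
                        noiseSd = 0.3, nReps = 3, fcCut = 1, qCut = 0.01) {
    cfg <- simConfig(nProteins = nProteins,
                     compartmentFractions = c(lysosome = frac),
                     enrichmentEffect = c(lysosome = effect),
                     noiseSd = noiseSd, nReplicates = nReps, seed = seed)
    sim <- simExperiment(cfg)
    tab <- differential(sim$quant, fcCut = fcCut, qCut = qCut)
    hits <- classifyEnriched(tab, fcCut, qCut)
    truth <- sim$truth$enrichedIds
    c(sensitivity = if (length(truth)) mean(truth %in% hits) else NA_real_,
      fdr = if (length(hits)) mean(!(hits %in% truth)) else 0,
      fpr = mean(tab$q_value[!(tab$protein_id %in% truth)] <= 0.05,
                 na.rm = TRUE))
}
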