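test_that("SNX27 scanner handles the worked sequences", {
    h <- scanSNX27("AAAAAAATSV")
    expect_equal(nrow(h), 1L)
    expect_equal(h$match, "TSV")
    expect_equal(h$context_score, 0L)       # context "AAAAA"
    expect_equal(h$start, 8L)
    expect_equal(h$offset_from_cterm, -3L)

    expect_equal(nrow(scanSNX27("AAAAAAATSD")), 0L)  # D not hydrophobic
    expect_equal(nrow(scanSNX27("AAAAAAAASV")), 0L)  # -3 not S/T

    h2 <- scanSNX27("AADEESGTSL")
    expect_equal(h2$context_score, 4L)      # D,E,E,S in "DEESG"
    expect_equal(h2$match, "TSL")

    # short sequences: context window truncates at the N-terminus
    h3 <- scanSNX27("DTSL")
    expect_equal(h3$context_score, 1L)
    expect_error(scanSNX27(""), "empty")
    expect_warning(expect_equal(nrow(scanSNX27("AAAAATXV")), 0L),
                   "nonstandard")
    # a custom hydrophobic set changes the verdict
    expect_equal(nrow(scanSNX27("AAAAAAATSG", phi = c("G"))), 1L)
})

test_that("SNX17 scanner reports every window, honoring the TM boundary", {
    h <- scanSNX17("AALPNAAYAA")
    expect_equal(h$start, 3L)
    expect_equal(h$match, "LPNAAY")
    expect_equal(h$offset_from_cterm, -8L)
    expect_equal(nrow(scanSNX17("AAAAAAAAAA")), 0L)
    # overlapping hits are all reported
    h2 <- scanSNX17("LLNNAFYAA")
    expect_true(all(c(1L, 2L) %in% h2$start))
    # scan region starts after the TM end
    s <- "LPNAAYAAAALPNAAY"
    expect_equal(scanSNX17(s)$start, c(1L, 11L))
    expect_equal(scanSNX17(s, tmEnd = 5)$start, 11L)
    expect_equal(nrow(scanSNX17(s, tmEnd = 12)), 0L)  # no scannable tail
})

test_that("scanners agree with the regex oracle on random sequences", {
    set.seed(77)
    for (i in 1:300) {
        s <- randomSeq(sample(6:120, 1))
        expect_identical(nrow(scanSNX27(s)) == 1L, snx27OracleHit(s))
        expect_identical(scanSNX17(s)$start, snx17OracleStarts(s))
        if (nrow(scanSNX27(s)) == 1L)
            expect_equal(scanSNX27(s)$context_score, contextOracle(s))
    }
    # one long sequence, full brute-force equivalence
    s <- randomSeq(10000)
    expect_identical(scanSNX17(s)$start, snx17OracleStarts(s))
    # hit windows re-match their pattern when rechecked independently
    h <- scanSNX17(s)
    expect_true(all(grepl("^[AVLIMFWY].N..[FY]$", h$match)))
    expect_identical(h$match,
                     substring(s, h$start, h$start + 5L))
})

test_that("C-terminal peptides are always suffixes of the input", {
    expect_equal(ctermPeptide(strrep("AC", 10)), substr(strrep("AC", 10), 6, 20))
    expect_equal(ctermPeptide("PEPTIDEABC", 15), "PEPTIDEABC")
    expect_error(ctermPeptide(""), "empty")
    set.seed(12)
    for (i in 1:200) {
        s <- randomSeq(sample(5:60, 1))
        p <- ctermPeptide(s, 15)
        expect_true(endsWith(s, p))
        expect_equal(nchar(p), min(15, nchar(s)))
    }
})

test_that("proteome scan summarises protein- and motif-level counts", {
    seqs <- c(a = "AADEESGTSL",          # SNX27 hit
              b = "AALPNAAYAAQQ",        # one SNX17 hit
              c = "LLNNAFYAAKKKLPNAAYK", # several SNX17 hits
              d = "GGGGGGGGGG")          # nothing
    res <- scanProteome(seqs)
    expect_equal(unname(res$summary["n_scanned"]), 4)
    expect_equal(unname(res$summary["n_snx27_proteins"]), 1)
    expect_equal(unname(res$summary["n_snx17_proteins"]), 2)
    expect_equal(unname(res$summary["n_snx17_motifs"]),
                 length(snx17OracleStarts(seqs["b"])) +
                 length(snx17OracleStarts(seqs["c"])))
    expect_equal(nrow(scanProteome(character(0))$hits), 0L)
    expect_error(scanProteome(c(a = "AAA", a = "CCC")), "duplicate")
    # invariant to input ordering
    res2 <- scanProteome(rev(seqs))
    expect_equal(res2$summary, res$summary)
    # AAStringSet input gives identical results
    res3 <- scanProteome(Biostrings::AAStringSet(seqs))
    expect_equal(res3$hits, res$hits)
})

test_that("scan counts equal a brute-force rescan on simulated proteomes", {
    cfg <- simConfig(nProteins = 150, seed = 13)
    sq <- simSequences(simCatalog(cfg), cfg)
    seqs <- as.character(sq$sequences)
    res <- scanProteome(sq$sequences)
    expect_equal(unname(res$summary["n_snx27_proteins"]),
                 sum(snx27OracleHit(seqs)))
    expect_equal(unname(res$summary["n_snx17_motifs"]),
                 sum(vapply(seqs, function(s) length(snx17OracleStarts(s)),
                            integer(1))))
    # planted proteins are always found
    expect_true(all(sq$truth$motifIdsSNX27 %in%
                    res$hits$protein_id[res$hits$motif_class == "SNX27"]))
    expect_true(all(sq$truth$motifIdsSNX17 %in%
                    res$hits$protein_id[res$hits$motif_class == "SNX17"]))
})

test_that("motif candidates carry the right peptides", {
    seqs <- c(a = "AADEESGTSLKKKKKKKKKK", b = "AALPNAAYAAQQ")
    seqs["a"] <- "KKKKKKKKAADEESGTSL"   # 18-mer ending in the motif
    scan <- scanProteome(seqs)
    cand <- motifCandidates(scan, seqs, k = 15)
    c27 <- cand[cand$motif_class == "SNX27", ]
    expect_equal(c27$peptide, ctermPeptide(seqs[["a"]], 15))
    expect_equal(nchar(c27$peptide), 15L)
    c17 <- cand[cand$motif_class == "SNX17", ]
    expect_equal(c17$peptide, "LPNAAY")
    expect_equal(c17$candidate_id, "b_3")
})
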