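makeSE <- function(x, genotype = rep(c("tagged", "untagged"),
                                     each = ncol(x) / 2)) {
    colnames(x) <- paste0(genotype, "_", ave(seq_len(ncol(x)), genotype,
                                             FUN = seq_along))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = x),
        colData = S4Vectors::DataFrame(sample_id = colnames(x),
                                       genotype = genotype,
                                       row.names = colnames(x)))
}

test_that("normalization centers, is idempotent and removes constant scaling", {
    x <- cbind(s1 = 2^c(1, 3, 5), s2 = 2^c(2, 4, 8))
    rownames(x) <- paste0("p", 1:3)
    se <- makeSE(x, genotype = c("tagged", "untagged"))
    nq <- normalizeQuant(se)
    y <- SummarizedExperiment::assay(nq, "log2norm")
    expect_equal(unname(y[, 1]), c(-2, 0, 2))       # hand-computed medians
    expect_equal(unname(y[, 2]), c(-2, 0, 4))
    expect_equal(SummarizedExperiment::assay(normalizeQuant(nq)), y)

    x4 <- x; x4[, 2] <- x[, 1] * 4                   # 4x loading difference
    n4 <- SummarizedExperiment::assay(normalizeQuant(makeSE(
        x4, c("tagged", "untagged"))))
    expect_equal(unname(n4[, 2]), unname(n4[, 1]))
})

test_that("normalization rejects nonpositive and all-missing samples", {
    x <- cbind(s1 = c(1, 2), s2 = c(NA_real_, NA_real_))
    rownames(x) <- c("p1", "p2")
    se <- makeSE(x, c("tagged", "untagged"))
    expect_error(normalizeQuant(se), "untagged_1")
    x2 <- cbind(s1 = c(1, -2), s2 = c(1, 2)); rownames(x2) <- c("p1", "p2")
    expect_error(normalizeQuant(makeSE(x2, c("tagged", "untagged"))),
                 "positive")
})

test_that("Welch statistics match t.test and the worked example", {
    set.seed(42)
    x <- 2^matrix(rnorm(50 * 6, 15, 1), 50, 6,
                  dimnames = list(sprintf("p%02d", 1:50), NULL))
    x[1, ] <- 2^c(5, 6, 7, 1, 2, 3)                  # the worked protein
    se <- makeSE(x)
    # bypass median centering so the worked numbers are exact
    S4Vectors::metadata(se)$log2normalized <- TRUE
    SummarizedExperiment::assays(se) <-
        list(log2norm = log2(SummarizedExperiment::assay(se, "intensity")))
    tab <- differential(se, priorDf = 0)
    expect_equal(tab$log2fc[1], 4)
    expect_equal(tab$t_stat[1], 4 / sqrt(2 / 3), tolerance = 1e-12)
    for (i in c(1, 5, 20, 50)) {
        tt <- t.test(log2(x[i, 1:3]), log2(x[i, 4:6]), var.equal = FALSE)
        expect_equal(tab$t_stat[i], unname(tt$statistic), tolerance = 1e-9)
        expect_equal(tab$p_value[i], tt$p.value, tolerance = 1e-9)
    }
})

test_that("contrast direction and degenerate contrasts behave", {
    set.seed(7)
    x <- 2^matrix(rnorm(30 * 6, 15, 1), 30, 6,
                  dimnames = list(sprintf("p%02d", 1:30), NULL))
    se <- makeSE(x)
    fwd <- differential(se, c("genotype", "tagged", "untagged"))
    rev <- differential(se, c("genotype", "untagged", "tagged"))
    expect_equal(rev$log2fc, -fwd$log2fc)
    expect_equal(rev$p_value, fwd$p_value, tolerance = 1e-12)
    expect_error(differential(se, c("genotype", "tagged", "nosuch")),
                 "0 samples")
    expect_error(differential(se, c("nosuch", "a", "b")), "nosuch")
    # string form parses to the same result
    expect_equal(differential(se, "genotype:tagged/untagged")$t_stat,
                 fwd$t_stat)
    # identical groups: log2FC exactly 0
    xdup <- cbind(x[, 1:3], x[, 1:3])
    same <- differential(makeSE(xdup), priorDf = 0)
    expect_true(all(same$log2fc == 0))
    expect_true(all(same$p_value == 1))
})

test_that("moderated variance agrees with limma's squeezeVar machinery", {
    skip_if_not_installed("limma")
    set.seed(11)
    x <- matrix(rnorm(200 * 6), 200, 6,
                dimnames = list(sprintf("p%03d", 1:200), NULL))
    se <- makeSE(2^x)
    tab <- differential(se, priorDf = 4)
    # limma's posterior variance at the same fixed prior (df0 = 4, s0^2 =
    # mean pooled variance) must equal the variance differential() uses
    xn <- SummarizedExperiment::assay(normalizeQuant(se))
    vp <- (apply(xn[, 1:3], 1, var) + apply(xn[, 4:6], 1, var)) / 2
    vs <- limma:::.squeezeVar(vp, df = 4, var.prior = mean(vp), df.prior = 4)
    tExp <- (rowMeans(xn[, 1:3]) - rowMeans(xn[, 4:6])) / sqrt(vs * (2 / 3))
    expect_equal(tab$t_stat, unname(tExp), tolerance = 1e-9)
})

test_that("BH adjustment matches the step-up oracle and is permutation stable", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhAdjust(0.37), 0.37)
    expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
    expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
    set.seed(3)
    for (i in 1:10) {
        p <- runif(sample(5:200, 1))^sample(1:3, 1)
        expect_equal(bhAdjust(p), bhOracle(p), tolerance = 1e-12)
        perm <- sample(length(p))
        expect_equal(bhAdjust(p[perm]), bhAdjust(p)[perm], tolerance = 1e-15)
    }
    # monotone nondecreasing in sorted-p order
    p <- runif(100); q <- bhAdjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    # NAs carried through without counting as tests
    p2 <- c(0.01, NA, 0.04)
    expect_equal(bhAdjust(p2), c(0.02, NA, 0.04))
})

test_that("threshold classification applies both gates inclusively", {
    tab <- data.frame(protein_id = c("a", "b", "c", "d", "e"),
                      log2fc = c(2.0, 0.99, 1.0, 3.0, NA),
                      q_value = c(0.001, 1e-9, 0.01, 0.2, 0.001))
    expect_identical(classifyEnriched(tab), c("a", "c"))
    expect_identical(classifyEnriched(tab, fcCut = 0.5, qCut = 0.05),
                     c("a", "b", "c"))
})

test_that("set overlaps partition exactly, including the printed worked counts", {
    expect_equal(overlapSets(list(A = "a", B = "b")),
                 c(A = 1L, B = 1L, `A&B` = 0L))
    expect_equal(overlapSets(list(A = letters[1:4], B = letters[1:4])),
                 c(A = 0L, B = 0L, `A&B` = 4L))
    # 611 and 566 enriched with 236 common: 375 and 330 state-selective
    hesc <- sprintf("h%04d", 1:611)
    ineuron <- c(hesc[1:236], sprintf("n%04d", 1:330))
    ov <- overlapSets(list(hesc = hesc, ineuron = ineuron))
    expect_equal(unname(ov), c(375L, 330L, 236L))
    # three sets against a brute-force recount
    set.seed(1)
    s3 <- list(x = sample(letters, 10), y = sample(letters, 12),
               z = sample(letters, 8))
    ov3 <- overlapSets(s3)
    expect_equal(sum(ov3), length(unique(unlist(s3))))
    expect_equal(unname(ov3["x&y&z"]),
                 length(Reduce(intersect, s3)))
})

test_that("compartment summaries recover planted group medians", {
    cfg <- simConfig(nProteins = 600,
                     compartmentFractions = c(lysosome = 0.1),
                     enrichmentEffect = c(lysosome = 2.0), seed = 14)
    sim <- simExperiment(cfg)
    tab <- differential(sim$quant)
    cs <- compartmentSummary(tab, sim$catalog)
    med <- setNames(cs$summary$median, cs$summary$compartment)
    expect_lt(abs(med["lysosome"] - 2), 0.35)
    expect_lt(abs(med["other"]), 0.3)
    # proteins missing from the catalog fall into "unannotated"
    cs2 <- compartmentSummary(tab, sim$catalog[-(1:5), ])
    expect_true("unannotated" %in% cs2$summary$compartment)
    # empty table gives an empty summary
    empty <- compartmentSummary(tab[0, ], sim$catalog)
    expect_equal(nrow(empty$summary), 0)
})
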