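#' Assemble a pipeline configuration
#'
#' Collects every tunable of the end-to-end run: the synthetic-experiment
#' parameters, enrichment cutoffs, the hydrophobic set, ipTM threshold,
#' logo extremes and the output directory. Defaults follow the package-wide
#' conventions (log2FC >= 1, q <= 0.01, ipTM > 0.6, top/bottom 10 logos).
#'
#' @param seed master seed; also seeds the simulator unless `sim` is supplied.
#' @param sim a [SimConfig-class] (default `simConfig(seed = seed)`).
#' @param fcCut,qCut enrichment thresholds.
#' @param iptmThreshold triage threshold.
#' @param phi hydrophobic residue set for motif scanning.
#' @param ctermK C-terminal peptide length for screening.
#' @param nTop,nBottom logo extremes.
#' @param nClustersFit clusters fit to the time course (defaults to the
#'   simulated count).
#' @param outDir optional directory for all output tables and the run report.
#' @return A named list (`PipelineConfig`).
#' @export
pipelineConfig <- function(seed = 1, sim = simConfig(seed = seed),
                           fcCut = 1.0, qCut = 0.01, iptmThreshold = 0.6,
                           phi = hydrophobicResidues(), ctermK = 15,
                           nTop = 10, nBottom = 10,
                           nClustersFit = sim@nClusters, outDir = NULL) {
    list(seed = as.integer(seed), sim = sim, fcCut = fcCut, qCut = qCut,
         iptmThreshold = iptmThreshold, phi = phi, ctermK = ctermK,
         nTop = nTop, nBottom = nBottom, nClustersFit = nClustersFit,
         outDir = outDir)
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> normalize -> differential -> classify -> cargo ->
#' motif scan -> ipTM triage -> logos -> time-course clustering, collecting
#' stage counts and parameters in a run report. With `outDir` set, all tables
#' and a JSON report are written; a re-run with the same configuration
#' reproduces them exactly.
#'
#' @param config a [pipelineConfig()] list.
#' @return A list with `report` (stage counts, parameters, seed, versions) and
#'   `results` (the intermediate objects: sim, enrichment table, enriched ids,
#'   cargo, scan, candidates, triage, pwms, clustering).
#' @examples
#' out <- runPipeline(pipelineConfig(seed = 1, sim = simConfig(
#'     nProteins = 150, seed = 1)))
#' out$report$counts
#' @export
runPipeline <- function(config = pipelineConfig()) {
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop(sprintf("pipeline stage '%s' failed: %s", name,
                         conditionMessage(e)), call. = FALSE))
    }
    sim <- stage("simulate", simExperiment(config$sim))
    nq <- stage("normalize", normalizeQuant(sim$quant))
    tab <- stage("differential",
                 differential(nq, c("genotype", "tagged", "untagged"),
                              fcCut = config$fcCut, qCut = config$qCut))
    enriched <- stage("classify",
                      classifyEnriched(tab, config$fcCut, config$qCut))
    termTab <- stage("terms", termEnrichment(
        enriched, tab$protein_id[!is.na(tab$q_value)], sim$terms))
    cargo <- stage("cargo", selectCandidateCargo(enriched, sim$catalog))
    cargoCat <- stage("categorize", categorizeCargo(cargo))
    scanSeqs <- sim$sequences[cargo$protein_id]
    scan <- stage("motifs", scanProteome(scanSeqs, phi = config$phi))
    cand <- stage("candidates",
                  motifCandidates(scan, scanSeqs, k = config$ctermK))
    if (nrow(cand) > 0L) {
        planted27 <- cand$motif_class == "SNX27" &
            cand$protein_id %in% sim$truth$motifIdsSNX27
        key <- paste(sim$truth$snx17Planted$protein_id,
                     sim$truth$snx17Planted$start)
        planted17 <- cand$motif_class == "SNX17" &
            paste(cand$protein_id,
                  sub("^.*_", "", cand$candidate_id)) %in% key
        cand$planted <- planted27 | planted17
    } else cand$planted <- logical(0)
    iptm <- stage("iptm", simIptm(cand, config$sim))
    triage <- stage("triage", triageIptm(iptm, config$iptmThreshold))
    pwms <- stage("logo", {
        out <- list()
        for (cls in c("SNX27", "SNX17")) {
            r <- iptm[iptm$motif_class == cls, , drop = FALSE]
            nT <- min(config$nTop, floor(nrow(r) / 2))
            nB <- min(config$nBottom, nrow(r) - nT)
            if (nT >= 2 && nB >= 2) {
                ex <- selectExtremes(r, nT, nB)
                out[[cls]] <- list(
                    top = buildPWM(ex$top$peptide, cterm = cls == "SNX27"),
                    bottom = buildPWM(ex$bottom$peptide,
                                      cterm = cls == "SNX27"))
            }
        }
        out
    })
    clustering <- stage("timecourse",
                        clusterTimecourse(sim$timecourse$profiles,
                                          k = config$nClustersFit,
                                          seed = config$seed))
    agreement <- clusterAgreement(clustering$assignment,
                                  sim$truth$clusterAssignment)

    report <- list(
        seed = config$seed,
        parameters = list(fcCut = config$fcCut, qCut = config$qCut,
                          iptmThreshold = config$iptmThreshold,
                          phi = paste(config$phi, collapse = ""),
                          ctermK = config$ctermK,
                          nTop = config$nTop, nBottom = config$nBottom,
                          nClustersFit = config$nClustersFit,
                          simSeed = config$sim@seed,
                          nReplicates = config$sim@nReplicates,
                          noiseSd = config$sim@noiseSd),
        counts = list(
            n_proteins = nrow(sim$catalog),
            n_tested = sum(!is.na(tab$q_value)),
            n_enriched = length(enriched),
            n_cargo = nrow(cargo),
            n_snx27_proteins = unname(scan$summary["n_snx27_proteins"]),
            n_snx17_proteins = unname(scan$summary["n_snx17_proteins"]),
            n_snx17_motifs = unname(scan$summary["n_snx17_motifs"]),
            n_candidates = nrow(cand),
            n_iptm_pass = nrow(triage$pass),
            cluster_sizes = unname(clustering$sizes)),
        metrics = list(cluster_agreement = agreement),
        versions = list(package = as.character(utils::packageVersion("endolyso")),
                        r = as.character(getRversion()))
    )
    results <- list(sim = sim, enrichment = tab, enriched = enriched,
                    terms = termTab, cargo = cargo, cargoCategories = cargoCat,
                    scan = scan, candidates = iptm, triage = triage,
                    pwms = pwms, clustering = clustering)
    if (!is.null(config$outDir)) {
        dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
        writeSimData(sim, file.path(config$outDir, "sim"))
        .writeTsv(tab, file.path(config$outDir, "enrichment.tsv"))
        .writeTsv(termTab, file.path(config$outDir, "term_enrichment.tsv"))
        .writeTsv(cargo, file.path(config$outDir, "cargo.tsv"))
        .writeTsv(scan$hits, file.path(config$outDir, "motifs.tsv"))
        .writeTsv(iptm, file.path(config$outDir, "iptm.tsv"))
        asg <- data.frame(protein_id = names(clustering$assignment),
                          cluster = unname(clustering$assignment))
        .writeTsv(asg, file.path(config$outDir, "clusters.tsv"))
        jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    list(report = report, results = results)
}
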