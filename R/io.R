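#' Read an amino-acid FASTA file
#'
#' Wrapped or unwrapped records are both handled. Sequence names are the first
#' whitespace-delimited token of each header; duplicate ids and empty files
#' are errors.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::AAStringSet], record order preserved.
#' @export
readFasta <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    seqs <- Biostrings::readAAStringSet(path)
    if (length(seqs) == 0L) stop("no FASTA records in ", path)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate sequence ids in ", path, ": ",
             paste(unique(names(seqs)[duplicated(names(seqs))]),
                   collapse = ", "))
    seqs
}

#' Write an amino-acid FASTA file
#'
#' @param sequences a named [Biostrings::AAStringSet] or named character
#'   vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(sequences, path) {
    if (!methods::is(sequences, "AAStringSet"))
        sequences <- Biostrings::AAStringSet(sequences)
    Biostrings::writeXStringSet(sequences, path, width = 60L)
    invisible(path)
}

.readTsv <- function(path) {
    utils::read.delim(path, sep = "\t", header = TRUE, na.strings = c("NA", "."),
                      check.names = FALSE, stringsAsFactors = FALSE)
}

.writeTsv <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    invisible(path)
}

#' Read a quant matrix with its sample design
#'
#' Loads a protein x sample intensity TSV (first column protein id, one
#' column per sample) and a design TSV (one row per sample), checks that the
#' two agree, reorders the intensity columns to the design order and returns a
#' `SummarizedExperiment`. `mapping` renames nonstandard design columns
#' (e.g., `c(genotype = "Genotype")` reads column `Genotype` as `genotype`),
#' so externally exported tables can be adapted in configuration rather than
#' code.
#'
#' @param quantPath path to the intensity TSV (linear scale).
#' @param designPath path to the design TSV; must contain `sample_id` after
#'   mapping.
#' @param mapping optional named character vector `standard_name = file_name`.
#' @return A `SummarizedExperiment` with assay `"intensity"` and the design as
#'   `colData`.
#' @export
readQuant <- function(quantPath, designPath, mapping = NULL) {
    quant <- .readTsv(quantPath)
    design <- .readTsv(designPath)
    if (!is.null(mapping)) {
        for (std in names(mapping)) {
            if (!mapping[[std]] %in% names(design))
                stop("design has no column '", mapping[[std]], "'")
            names(design)[names(design) == mapping[[std]]] <- std
        }
    }
    if (!"sample_id" %in% names(design))
        stop("design must have a 'sample_id' column (use 'mapping' to rename)")
    ids <- quant[[1]]
    if (anyDuplicated(ids))
        stop("duplicate protein ids in ", quantPath)
    x <- as.matrix(quant[, -1, drop = FALSE])
    rownames(x) <- ids
    onlyQuant <- setdiff(colnames(x), design$sample_id)
    onlyDesign <- setdiff(design$sample_id, colnames(x))
    if (length(onlyQuant) || length(onlyDesign))
        stop("sample mismatch between quant and design",
             if (length(onlyQuant)) paste0("; only in quant: ",
                 paste(onlyQuant, collapse = ", ")) else "",
             if (length(onlyDesign)) paste0("; only in design: ",
                 paste(onlyDesign, collapse = ", ")) else "")
    x <- x[, design$sample_id, drop = FALSE]
    SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = x),
        colData = S4Vectors::DataFrame(design, row.names = design$sample_id))
}

#' Write a quant matrix and its design as TSV
#'
#' Inverse of [readQuant()]; numeric values round-trip at full precision
#' (15 significant digits).
#'
#' @param se `SummarizedExperiment` with an `"intensity"` assay.
#' @param quantPath,designPath output paths.
#' @return `quantPath`, invisibly.
#' @export
writeQuant <- function(se, quantPath, designPath) {
    x <- SummarizedExperiment::assay(se, "intensity")
    df <- data.frame(protein_id = rownames(x),
                     signif(x, 15), check.names = FALSE)
    .writeTsv(df, quantPath)
    .writeTsv(as.data.frame(SummarizedExperiment::colData(se)), designPath)
    invisible(quantPath)
}

#' Write all synthetic inputs of one experiment to a directory
#'
#' Emits the quant/design/annotation/term/time-course TSVs, the sequence
#' FASTA and a ground-truth JSON, the on-disk contract shared with
#' [readQuant()] and [readFasta()].
#'
#' @param sim result of [simExperiment()].
#' @param dir output directory (created if needed).
#' @return Named vector of the written paths, invisibly.
#' @export
writeSimData <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(quant = file.path(dir, "quant.tsv"),
               design = file.path(dir, "design.tsv"),
               annotation = file.path(dir, "annotation.tsv"),
               terms = file.path(dir, "terms.tsv"),
               fasta = file.path(dir, "sequences.fasta"),
               timecourse = file.path(dir, "timecourse.tsv"),
               truth = file.path(dir, "truth.json"))
    writeQuant(sim$quant, paths["quant"], paths["design"])
    .writeTsv(sim$catalog, paths["annotation"])
    .writeTsv(sim$terms, paths["terms"])
    writeFasta(sim$sequences, paths["fasta"])
    tc <- data.frame(protein_id = rownames(sim$timecourse$profiles),
                     sim$timecourse$profiles, check.names = FALSE)
    .writeTsv(tc, paths["timecourse"])
    truth <- sim$truth
    truth$clusterAssignment <- as.list(truth$clusterAssignment)
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
    invisible(paths)
}
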