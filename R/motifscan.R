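#' The hydrophobic residue set used for the Phi position
#'
#' The motif patterns leave Phi ("any hydrophobic residue") open to
#' interpretation; this standard hydrophobic alphabet is the package default
#' and every scanner accepts an alternative set, since candidate counts depend
#' on the choice.
#'
#' @return `c("A","V","L","I","M","F","W","Y")`.
#' @export
hydrophobicResidues <- function() c("A", "V", "L", "I", "M", "F", "W", "Y")

.emptyHits <- function() {
    data.frame(motif_class = character(0), start = integer(0),
               offset_from_cterm = integer(0), match = character(0),
               context_score = integer(0), stringsAsFactors = FALSE)
}

#' Scan a sequence for the SNX27 PDZ-binding C-terminal motif
#'
#' A hit requires the C-terminal triplet to match \[S/T\]-x-Phi: residue -3 in
#' \{S, T\} and the final residue hydrophobic (position -2 unrestricted). The
#' motif is strictly C-terminal, so a sequence has at most one hit. The
#' reported `context_score` counts acidic or phospho-acceptor residues
#' \{D, E, S, T\} at positions -4..-8 (binding is often enhanced by acidic or
#' phosphorylated residues just upstream); it is descriptive and never used
#' as a filter. Nonstandard residues (U, X, B, Z, ...) never match; if one
#' occurs in the triplet a warning is raised.
#'
#' @param seq a single character string or `AAString` (length >= 3).
#' @param phi hydrophobic residue set (see [hydrophobicResidues()]).
#' @return A one-row hit `data.frame` (`motif_class`, `start`,
#'   `offset_from_cterm` of the triplet start, `match`, `context_score`) or a
#'   zero-row frame when there is no hit.
#' @examples
#' scanSNX27("AADEESGTSL")   # hit, context score 4 over "DEESG"
#' scanSNX27("AAAAAAATSD")   # D is not hydrophobic: no hit
#' @export
scanSNX27 <- function(seq, phi = hydrophobicResidues()) {
    seq <- .seqAsCharacter(seq)
    if (nchar(seq) == 0L) stop("empty sequence")
    L <- nchar(seq)
    if (L < 3L) return(.emptyHits())
    last3 <- substr(seq, L - 2L, L)
    ch <- strsplit(last3, "", fixed = TRUE)[[1]]
    if (any(!ch %in% AA20)) {
        warning("nonstandard residue in C-terminal triplet; no match")
        return(.emptyHits())
    }
    if (!(ch[1] %in% c("S", "T") && ch[3] %in% phi)) return(.emptyHits())
    ctx <- substr(seq, max(1L, L - 7L), L - 3L)
    score <- sum(strsplit(ctx, "", fixed = TRUE)[[1]] %in%
                     c("D", "E", "S", "T"))
    data.frame(motif_class = "SNX27", start = L - 2L,
               offset_from_cterm = -3L, match = last3,
               context_score = as.integer(score), stringsAsFactors = FALSE)
}

#' Scan a sequence for SNX17 FERM-binding motifs
#'
#' Reports every 6-residue window matching Phi-x-N-x-x-\[F/Y\] (positions 1,
#' 3 and 6 constrained), overlapping windows included. When the end of the
#' last transmembrane segment is known, scanning is restricted to the region
#' C-terminal to it (the cytosolic tail under type-I topology); topology is
#' never inferred.
#'
#' @param seq a single character string or `AAString` (length >= 6 to yield
#'   hits).
#' @param tmEnd 1-based position of the last transmembrane-segment end, or
#'   `NA` to scan the whole sequence. A `tmEnd` leaving no complete window
#'   returns an empty list.
#' @param phi hydrophobic residue set.
#' @return Hit `data.frame` with one row per matching window (`motif_class`,
#'   `start`, `offset_from_cterm` of the window start, `match`,
#'   `context_score = NA`).
#' @examples
#' scanSNX17("AALPNAAYAA")  # one hit, "LPNAAY" at position 3
#' @export
scanSNX17 <- function(seq, tmEnd = NA, phi = hydrophobicResidues()) {
    seq <- .seqAsCharacter(seq)
    if (nchar(seq) == 0L) stop("empty sequence")
    L <- nchar(seq)
    from <- if (is.na(tmEnd)) 1L else as.integer(tmEnd) + 1L
    if (L < 6L || from > L - 5L) return(.emptyHits())
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    starts <- from:(L - 5L)
    hit <- ch[starts] %in% phi & ch[starts + 2L] == "N" &
        ch[starts + 5L] %in% c("F", "Y")
    starts <- starts[hit]
    if (length(starts) == 0L) return(.emptyHits())
    data.frame(motif_class = "SNX17", start = starts,
               offset_from_cterm = starts - L - 1L,
               match = substring(seq, starts, starts + 5L),
               context_score = NA_integer_, stringsAsFactors = FALSE)
}

#' Extract the C-terminal peptide of a sequence
#'
#' The last `min(k, length)` residues, order preserved — the peptides
#' submitted to structure-prediction screening of PDZ-motif candidates.
#'
#' @param seq a single character string or `AAString` (nonempty).
#' @param k peptide length (default 15).
#' @return The C-terminal peptide as a character string.
#' @export
ctermPeptide <- function(seq, k = 15) {
    seq <- .seqAsCharacter(seq)
    L <- nchar(seq)
    if (L == 0L) stop("empty sequence")
    substr(seq, max(1L, L - k + 1L), L)
}

#' Scan a whole sequence set for both motif classes
#'
#' Runs [scanSNX27()] and [scanSNX17()] over every sequence and summarises the
#' result at both the protein level (proteins with a hit per class) and the
#' motif level (total SNX17 windows; one protein may contribute several).
#'
#' @param sequences a named [Biostrings::AAStringSet] or named character
#'   vector; duplicate names are an error.
#' @param tmEnd optional named vector of last-TM-segment end positions, used
#'   to restrict the SNX17 scan region per protein.
#' @param phi hydrophobic residue set.
#' @return A list: `hits` (`data.frame` with `protein_id`, `motif_class`,
#'   `start`, `offset_from_cterm`, `match`, `context_score`) and `summary`
#'   (named counts: `n_scanned`, `n_snx27_proteins`, `n_snx17_proteins`,
#'   `n_snx17_motifs`).
#' @examples
#' scanProteome(c(a = "AADEESGTSL", b = "AALPNAAYAAQQ"))$summary
#' @export
scanProteome <- function(sequences, tmEnd = NULL,
                         phi = hydrophobicResidues()) {
    if (methods::is(sequences, "XStringSet"))
        sequences <- as.character(sequences)
    if (length(sequences) == 0L)
        return(list(hits = cbind(protein_id = character(0), .emptyHits()),
                    summary = c(n_scanned = 0L, n_snx27_proteins = 0L,
                                n_snx17_proteins = 0L, n_snx17_motifs = 0L)))
    ids <- names(sequences)
    if (is.null(ids) || any(ids == ""))
        stop("sequences must be named by protein id")
    if (anyDuplicated(ids))
        stop("duplicate protein ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    hits <- lapply(ids, function(id) {
        h27 <- scanSNX27(sequences[[id]], phi = phi)
        te <- if (!is.null(tmEnd) && id %in% names(tmEnd)) tmEnd[[id]] else NA
        h17 <- scanSNX17(sequences[[id]], tmEnd = te, phi = phi)
        h <- rbind(h27, h17)
        if (nrow(h) == 0L) return(NULL)
        cbind(protein_id = id, h, stringsAsFactors = FALSE)
    })
    hits <- do.call(rbind, hits)
    if (is.null(hits))
        hits <- cbind(protein_id = character(0), .emptyHits())
    rownames(hits) <- NULL
    s27 <- unique(hits$protein_id[hits$motif_class == "SNX27"])
    s17 <- hits$protein_id[hits$motif_class == "SNX17"]
    list(hits = hits,
         summary = c(n_scanned = length(ids),
                     n_snx27_proteins = length(s27),
                     n_snx17_proteins = length(unique(s17)),
                     n_snx17_motifs = length(s17)))
}

#' Build the candidate table for structure-prediction screening
#'
#' Converts motif hits into screening candidates: SNX27 candidates are the
#' protein's C-terminal `k`-mer (one per protein), SNX17 candidates the
#' 6-residue core window of each hit (one per motif, id suffixed with the
#' window start).
#'
#' @param scan result of [scanProteome()].
#' @param sequences the scanned sequence set.
#' @param k C-terminal peptide length for SNX27 candidates.
#' @return `data.frame`: `candidate_id`, `protein_id`, `motif_class`,
#'   `peptide`.
#' @export
motifCandidates <- function(scan, sequences, k = 15) {
    if (methods::is(sequences, "XStringSet"))
        sequences <- as.character(sequences)
    h <- scan$hits
    h27 <- h[h$motif_class == "SNX27", , drop = FALSE]
    h17 <- h[h$motif_class == "SNX17", , drop = FALSE]
    out <- rbind(
        if (nrow(h27)) data.frame(
            candidate_id = h27$protein_id,
            protein_id = h27$protein_id,
            motif_class = "SNX27",
            peptide = vapply(h27$protein_id, function(id)
                ctermPeptide(sequences[[id]], k), character(1)),
            stringsAsFactors = FALSE),
        if (nrow(h17)) data.frame(
            candidate_id = paste0(h17$protein_id, "_", h17$start),
            protein_id = h17$protein_id,
            motif_class = "SNX17",
            peptide = h17$match,
            stringsAsFactors = FALSE)
    )
    if (is.null(out))
        out <- data.frame(candidate_id = character(0),
                          protein_id = character(0),
                          motif_class = character(0),
                          peptide = character(0))
    rownames(out) <- NULL
    out
}
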