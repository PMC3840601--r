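#' @include AllClasses.R
NULL

#' Six-frame translation
#'
#' Translates a nucleotide sequence in the three forward frames and the three
#' frames of its reverse complement under the standard genetic code. Stop
#' codons are emitted as \code{"*"}, codons containing \code{N} as \code{"X"},
#' and trailing partial codons are dropped. This is how the protein search
#' space is built from assembled transcripts whose coding frame is unknown.
#'
#' @param ntSequence a character scalar or \code{DNAString} over A/C/G/T/N.
#' @return Named character vector of six amino-acid strings, frames
#'   \code{"+1" "+2" "+3" "-1" "-2" "-3"}.
#' @examples
#' sixFrameTranslate("ATGAAATAA")[["+1"]]   # "MK*"
#' @export
sixFrameTranslate <- function(ntSequence) {
    if (is(ntSequence, "DNAString"))
        ntSequence <- as.character(ntSequence)
    stopifnot(is.character(ntSequence), length(ntSequence) == 1L)
    s <- toupper(ntSequence)
    bad <- regexpr("[^ACGTN]", s)
    if (bad > 0)
        stop(sprintf("invalid nucleotide '%s' at position %d",
                     substr(s, bad, bad), bad), call. = FALSE)
    if (nchar(s) < 3L)
        stop("sequence must contain at least one full codon", call. = FALSE)
    fwd <- Biostrings::DNAString(s)
    rev <- Biostrings::reverseComplement(fwd)
    oneFrame <- function(x, off) {
        w <- 3L * ((length(x) - off + 1L) %/% 3L)
        if (w < 3L) return("")
        as.character(Biostrings::translate(
            Biostrings::subseq(x, off, off + w - 1L),
            if.fuzzy.codon = "X", no.init.codon = TRUE))
    }
    out <- c(oneFrame(fwd, 1L), oneFrame(fwd, 2L), oneFrame(fwd, 3L),
             oneFrame(rev, 1L), oneFrame(rev, 2L), oneFrame(rev, 3L))
    names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
    out
}

#' Extract stop-free segments from a translated frame
#'
#' Splits a translation on stop codons and returns the maximal stop-free
#' substrings of at least \code{minLength} residues, in sequence order.
#' Search databases must be stop-free, so each retained segment becomes one
#' database entry.
#'
#' @param translated amino-acid string possibly containing \code{"*"}.
#' @param minLength minimum retained segment length (default 1).
#' @return Character vector of segments.
#' @examples
#' splitOrfs("MK*AR", minLength = 2)   # "MK" "AR"
#' @export
splitOrfs <- function(translated, minLength = 1L) {
    stopifnot(is.character(translated), length(translated) == 1L)
    minLength <- .assertCount(minLength, "minLength", positive = TRUE)
    segs <- strsplit(translated, "*", fixed = TRUE)[[1]]
    segs[nchar(segs) >= minLength]
}

.cleavageSites <- function(chars, params) {
    residues <- switch(params@enzyme,
        "glu-c" = if (params@glucEOnly) "E" else ENZYME_SITES[["glu-c"]],
        ENZYME_SITES[[params@enzyme]])
    n <- length(chars)
    if (n < 2L) return(integer())
    sites <- which(chars[-n] %in% residues)
    if (params@prolineRule && length(sites))
        sites <- sites[chars[sites + 1L] != "P"]
    sites
}

#' In-silico proteolytic digestion
#'
#' Enumerates the peptides an enzymatic digest can produce from a protein,
#' allowing missed cleavages. Cleavage occurs immediately C-terminal to the
#' enzyme's recognition residues (trypsin: R, K; chymotrypsin: F, L, W, Y;
#' Glu-C: D, E). A peptide with \eqn{k} missed cleavages spans \eqn{k}
#' internal uncut sites; all peptides with at most
#' \code{params@maxMissedCleavages} are returned, filtered to the configured
#' length range. Enzyme \code{"none"} yields the intact sequence only
#' (subject to the same length filter).
#'
#' @param sequence a non-empty, stop-free amino-acid string.
#' @param params a \linkS4class{DigestionParams}.
#' @return data.frame with columns \code{peptide}, \code{start}, \code{end}
#'   (1-based residue coordinates) and \code{missedCleavages}.
#' @examples
#' digestProtein("MKAR", digestionParams("trypsin", maxMissedCleavages = 1,
#'                                       minPeptideLength = 1))$peptide
#' @export
digestProtein <- function(sequence, params = digestionParams()) {
    stopifnot(is(params, "DigestionParams"))
    validObject(params)
    stopifnot(is.character(sequence), length(sequence) == 1L)
    if (nchar(sequence) == 0L)
        stop("'sequence' must be non-empty", call. = FALSE)
    if (grepl("*", sequence, fixed = TRUE))
        stop("'sequence' must be stop-free; split frames with splitOrfs() first",
             call. = FALSE)
    n <- nchar(sequence)
    lmin <- params@minPeptideLength
    lmax <- params@maxPeptideLength

    if (params@enzyme == "none") {
        out <- data.frame(peptide = sequence, start = 1L, end = n,
                          missedCleavages = 0L, stringsAsFactors = FALSE)
        return(out[n >= lmin & n <= lmax, , drop = FALSE])
    }

    chars <- strsplit(sequence, "")[[1]]
    sites <- .cleavageSites(chars, params)
    b <- c(0L, sites, n)              # peptide boundaries
    nb <- length(b)
    ## all (i, j) boundary pairs spanning <= maxMissedCleavages sites
    mc <- params@maxMissedCleavages
    i <- rep(seq_len(nb - 1L), each = mc + 1L)
    j <- i + rep(seq_len(mc + 1L), times = nb - 1L)
    ok <- j <= nb
    i <- i[ok]; j <- j[ok]
    len <- b[j] - b[i]
    ok <- len >= lmin & len <= lmax
    i <- i[ok]; j <- j[ok]
    if (length(i) == 0L)
        return(data.frame(peptide = character(), start = integer(),
                          end = integer(), missedCleavages = integer(),
                          stringsAsFactors = FALSE))
    data.frame(peptide = substring(sequence, b[i] + 1L, b[j]),
               start = b[i] + 1L, end = b[j],
               missedCleavages = j - i - 1L,
               stringsAsFactors = FALSE)
}

.asProteinSeqs <- function(proteins) {
    if (is(proteins, "VenomeTruth"))
        proteins <- proteins@proteins
    if (is(proteins, "AAStringSet")) {
        s <- as.character(proteins)
        names(s) <- names(proteins)
        return(s)
    }
    if (is.data.frame(proteins)) {
        if (!all(c("id", "sequence") %in% names(proteins)))
            stop("protein data.frame needs 'id' and 'sequence' columns",
                 call. = FALSE)
        return(stats::setNames(as.character(proteins$sequence),
                               as.character(proteins$id)))
    }
    if (is.character(proteins) && !is.null(names(proteins)))
        return(proteins)
    stop("'proteins' must be an AAStringSet, a named character vector, a data.frame, or a VenomeTruth",
         call. = FALSE)
}

#' Map observed peptides to the proteins containing them
#'
#' A peptide matches every protein whose sequence contains it as a substring;
#' the number of matching proteins is the peptide's multiplicity, later used
#' to split its count fractionally. Isoleucine and leucine are isobaric and
#' indistinguishable by mass spectrometry; set \code{ilEquivalent = TRUE} to
#' treat them as identical during matching.
#'
#' @param observations data.frame with at least columns \code{peptide} and
#'   \code{count} (as produced by \code{\link{simulatePeptideObservations}}
#'   or read from a peptide TSV).
#' @param proteins protein sequences: \code{AAStringSet}, named character
#'   vector, data.frame with \code{id}/\code{sequence}, or a
#'   \linkS4class{VenomeTruth}.
#' @param ilEquivalent treat I and L as the same residue (default FALSE).
#' @return The input data.frame with added columns \code{matches} (list of
#'   protein id vectors), \code{multiplicity} (integer) and \code{matched}
#'   (logical; FALSE for peptides found in no protein, which must be dropped
#'   before scoring).
#' @examples
#' obs <- data.frame(peptide = "MK", count = 4)
#' prot <- c(A = "MKAR", B = "GGMKG")
#' matchPeptides(obs, prot)$multiplicity    # 2
#' @export
matchPeptides <- function(observations, proteins, ilEquivalent = FALSE) {
    stopifnot(is.data.frame(observations))
    if (!all(c("peptide", "count") %in% names(observations)))
        stop("'observations' needs 'peptide' and 'count' columns",
             call. = FALSE)
    seqs <- .asProteinSeqs(proteins)
    if (any(!nzchar(observations$peptide)))
        stop("empty peptide sequence in observations", call. = FALSE)

    peps <- unique(observations$peptide)
    qp <- if (ilEquivalent) chartr("I", "L", peps) else peps
    qs <- if (ilEquivalent) chartr("I", "L", seqs) else seqs
    hits <- .substringMatches(qp, qs)       # list of protein index vectors
    matches <- lapply(hits, function(ix) names(seqs)[ix])

    idx <- match(observations$peptide, peps)
    observations$matches <- matches[idx]
    observations$multiplicity <- lengths(observations$matches)
    observations$matched <- observations$multiplicity > 0L
    observations
}

## Find, for each peptide, the indices of the proteins containing it as a
## substring. A prefix k-mer index over the proteins (k = shortest peptide,
## capped at 6) narrows each peptide to candidate (protein, offset) sites,
## which are then verified by direct substring comparison; equivalent to a
## full scan but linear in practice.
.substringMatches <- function(peps, seqs) {
    if (length(peps) == 0L)
        return(list())
    w <- min(nchar(peps))
    if (w == 0L)
        stop("empty peptide sequence", call. = FALSE)
    w <- min(w, 6L)
    ns <- nchar(seqs)
    nk <- pmax(ns - w + 1L, 0L)
    protIdx <- rep(seq_along(seqs), nk)
    pos <- unlist(lapply(nk, seq_len), use.names = FALSE)
    kmer <- substring(seqs[protIdx], pos, pos + w - 1L)
    keyMap <- split(seq_along(kmer), kmer)

    cand <- keyMap[substr(peps, 1L, w)]     # NULL when prefix absent
    nCand <- lengths(cand)
    pepIdx <- rep(seq_along(peps), nCand)
    entry <- unlist(cand, use.names = FALSE)
    out <- rep(list(integer()), length(peps))
    if (length(entry)) {
        pLen <- nchar(peps)[pepIdx]
        okLen <- pos[entry] + pLen - 1L <= ns[protIdx[entry]]
        pepIdx <- pepIdx[okLen]; entry <- entry[okLen]; pLen <- pLen[okLen]
        verified <- substring(seqs[protIdx[entry]], pos[entry],
                              pos[entry] + pLen - 1L) == peps[pepIdx]
        pepIdx <- pepIdx[verified]
        protHit <- protIdx[entry[verified]]
        ## a peptide can occur at several offsets of one protein
        hit <- !duplicated(cbind(pepIdx, protHit))
        found <- split(protHit[hit], factor(pepIdx[hit],
                                            levels = seq_along(peps)))
        out <- unname(lapply(found, function(ix) sort(unique(ix))))
    }
    out
}
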