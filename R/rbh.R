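#' @include AllClasses.R
NULL

.checkResidues <- function(seq, params, what) {
    allowed <- rownames(params@substitutionMatrix)
    chars <- strsplit(seq, "")[[1]]
    bad <- which(!(chars %in% allowed))
    if (length(bad))
        stop(sprintf("%s: residue '%s' at position %d absent from the substitution matrix",
                     what, chars[bad[1]], bad[1]), call. = FALSE)
    invisible(TRUE)
}

#' Optimal local alignment score
#'
#' Smith-Waterman score of the best local alignment between two amino-acid
#' sequences under a substitution matrix and affine gap penalties (a gap of
#' length L costs \code{gapOpen + L * gapExtend}). The score of the empty
#' alignment is 0, so results are never negative.
#'
#' @param seqA,seqB non-empty amino-acid strings (or \code{AAString}s).
#' @param params an \linkS4class{AlignmentParams}.
#' @return Integer-valued numeric alignment score.
#' @examples
#' localAlign("WW", "WW")   # 22 under BLOSUM62 (W:W = 11)
#' @export
localAlign <- function(seqA, seqB, params = alignmentParams()) {
    stopifnot(is(params, "AlignmentParams"))
    if (is(seqA, "AAString")) seqA <- as.character(seqA)
    if (is(seqB, "AAString")) seqB <- as.character(seqB)
    stopifnot(is.character(seqA), length(seqA) == 1L, nzchar(seqA),
              is.character(seqB), length(seqB) == 1L, nzchar(seqB))
    .checkResidues(seqA, params, "seqA")
    .checkResidues(seqB, params, "seqB")
    Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqA), Biostrings::AAString(seqB),
        type = "local",
        substitutionMatrix = params@substitutionMatrix,
        gapOpening = params@gapOpen,
        gapExtension = params@gapExtend,
        scoreOnly = TRUE)
}

.scoreAgainstSet <- function(query, setSeqs, params) {
    Biostrings::pairwiseAlignment(
        Biostrings::AAStringSet(setSeqs), Biostrings::AAString(query),
        type = "local",
        substitutionMatrix = params@substitutionMatrix,
        gapOpening = params@gapOpen,
        gapExtension = params@gapExtend,
        scoreOnly = TRUE)
}

#' Reciprocal best hits between two protein sets
#'
#' Scores every sequence of one set against every sequence of the other by
#' optimal local alignment and reports the pairs (a, b) such that b is a's
#' unique best hit, a is b's unique best hit, and the score reaches
#' \code{params@minScore}. A sequence whose best score is tied between two
#' or more partners yields no pair: ambiguous homology (close isoforms,
#' recent duplicates) is excluded rather than resolved arbitrarily, which is
#' the conservative criterion appropriate when a reference set may contain
#' one representative for several close genes.
#'
#' @param setA,setB named character vectors or \code{AAStringSet}s; ids must
#'   be unique within each set.
#' @param params an \linkS4class{AlignmentParams}; \code{minScore} is the
#'   acceptance floor.
#' @return data.frame with columns \code{id_a}, \code{id_b}, \code{score};
#'   zero rows when no pair qualifies. Each id appears at most once.
#' @examples
#' a <- c(x = "MKWVFFA", y = "GGDDEEG")
#' reciprocalBestHits(a, a, alignmentParams(minScore = 10))
#' @export
reciprocalBestHits <- function(setA, setB, params = alignmentParams()) {
    stopifnot(is(params, "AlignmentParams"))
    sa <- .asProteinSeqs(setA)
    sb <- .asProteinSeqs(setB)
    if (length(sa) == 0L || length(sb) == 0L)
        stop("both sets must be non-empty", call. = FALSE)
    if (anyDuplicated(names(sa)) || anyDuplicated(names(sb)))
        stop("sequence ids must be unique within each set", call. = FALSE)
    for (i in seq_along(sa)) .checkResidues(sa[[i]], params, names(sa)[i])
    for (i in seq_along(sb)) .checkResidues(sb[[i]], params, names(sb)[i])

    S <- matrix(0, nrow = length(sa), ncol = length(sb),
                dimnames = list(names(sa), names(sb)))
    bset <- Biostrings::AAStringSet(sb)
    for (i in seq_along(sa))
        S[i, ] <- .scoreAgainstSet(sa[[i]], bset, params)

    bestB <- apply(S, 1L, function(r) {
        m <- max(r)
        w <- which(r == m)
        if (length(w) == 1L) w else NA_integer_
    })
    bestA <- apply(S, 2L, function(cl) {
        m <- max(cl)
        w <- which(cl == m)
        if (length(w) == 1L) w else NA_integer_
    })

    ia <- which(!is.na(bestB))
    keep <- vapply(ia, function(i) {
        j <- bestB[i]
        !is.na(bestA[j]) && bestA[j] == i && S[i, j] >= params@minScore
    }, logical(1))
    ia <- ia[keep]
    data.frame(id_a = names(sa)[ia],
               id_b = names(sb)[bestB[ia]],
               score = S[cbind(ia, bestB[ia])],
               stringsAsFactors = FALSE)
}
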