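#' @include proteolysis.R
NULL

#' Fractionally attributed peptide counts per protein
#'
#' Sums observed peptide counts onto proteins, dividing each peptide's count
#' by its multiplicity (the number of proteins containing it) so that a
#' shared peptide contributes equally to all of its possible sources and the
#' total count is conserved:
#' \deqn{\tilde{c}_p = \sum_{o:\, p \in \mathrm{matches}(o)}
#'       \frac{\mathrm{count}(o)}{m(o)}}
#'
#' @param observations matched observations from \code{\link{matchPeptides}};
#'   unmatched rows must have been removed.
#' @param proteins optional protein ids (or any object accepted by
#'   \code{\link{matchPeptides}}) defining the scoring universe; proteins
#'   with no observations receive an adjusted count of 0.
#' @param countMode \code{"events"} (default) sums reported identification
#'   events; \code{"species"} counts each distinct peptide once regardless of
#'   its count column.
#' @return data.frame with columns \code{protein_id}, \code{adjusted_count}.
#' @examples
#' obs <- data.frame(peptide = c("MK", "AR"), count = c(4L, 2L))
#' obs <- matchPeptides(obs, c(A = "MKAR", B = "GGMKG"))
#' adjustedCounts(obs)   # A: 4/2 + 2 = 4, B: 4/2 = 2
#' @export
adjustedCounts <- function(observations, proteins = NULL,
                           countMode = c("events", "species")) {
    countMode <- match.arg(countMode)
    stopifnot(is.data.frame(observations))
    if (!all(c("matches", "multiplicity") %in% names(observations)))
        stop("'observations' must first be matched with matchPeptides()",
             call. = FALSE)
    if (nrow(observations) > 0 && any(observations$multiplicity < 1L))
        stop("unmatched observations present; remove rows with matched == FALSE before scoring",
             call. = FALSE)
    universe <- if (!is.null(proteins)) {
        if (is.character(proteins) && is.null(names(proteins))) proteins
        else names(.asProteinSeqs(proteins))
    } else character()

    cnt <- if (countMode == "events") observations$count
           else rep(1L, nrow(observations))
    share <- rep(cnt / observations$multiplicity, observations$multiplicity)
    prot <- unlist(observations$matches, use.names = FALSE)
    adj <- if (length(prot)) {
        v <- rowsum(share, prot)
        stats::setNames(v[, 1L], rownames(v))
    } else stats::setNames(numeric(), character())

    ids <- union(universe, names(adj))
    out <- stats::setNames(numeric(length(ids)), ids)
    out[names(adj)] <- adj
    data.frame(protein_id = ids, adjusted_count = unname(out),
               stringsAsFactors = FALSE)
}

.effectiveLengths <- function(proteins) {
    if (is(proteins, "VenomeTruth"))
        return(stats::setNames(proteins@proteinMeta$effective_length,
                               proteins@proteinMeta$id))
    if (is(proteins, "AAStringSet"))
        return(stats::setNames(Biostrings::width(proteins), names(proteins)))
    if (is.data.frame(proteins)) {
        if (all(c("id", "effective_length") %in% names(proteins)))
            return(stats::setNames(as.numeric(proteins$effective_length),
                                   as.character(proteins$id)))
        if (all(c("id", "sequence") %in% names(proteins))) {
            len <- nchar(as.character(proteins$sequence))
            if ("signal_peptide_length" %in% names(proteins))
                len <- len - proteins$signal_peptide_length
            return(stats::setNames(len, as.character(proteins$id)))
        }
        stop("protein data.frame needs 'effective_length' or 'sequence'",
             call. = FALSE)
    }
    if (is.numeric(proteins) && !is.null(names(proteins)))
        return(proteins)
    stop("cannot derive effective lengths from 'proteins'", call. = FALSE)
}

#' Length-normalized protein abundance scores
#'
#' Divides each protein's fractionally attributed peptide count by its
#' effective length (mature protein, signal peptide excluded), giving
#' peptides per residue. Longer proteins produce more candidate peptides, so
#' without this normalization they would appear more abundant than they are.
#' The score is deliberately \emph{not} divided by the total number of
#' detected peptides: with adequate chromatographic separation peptides are
#' detected independently of one another, unlike sequencing reads competing
#' for flow-cell positions.
#'
#' @param adjusted data.frame from \code{\link{adjustedCounts}}.
#' @param proteins effective lengths: a \linkS4class{VenomeTruth}, an
#'   \code{AAStringSet} (widths used), a data.frame with
#'   \code{id}/\code{effective_length} (or \code{sequence} and optionally
#'   \code{signal_peptide_length}), or a named numeric vector.
#' @return data.frame with columns \code{protein_id}, \code{adjusted_count},
#'   \code{effective_length}, \code{score}.
#' @examples
#' adj <- data.frame(protein_id = "A", adjusted_count = 5)
#' abundanceScores(adj, c(A = 100))$score   # 0.05
#' @export
abundanceScores <- function(adjusted, proteins) {
    stopifnot(is.data.frame(adjusted),
              all(c("protein_id", "adjusted_count") %in% names(adjusted)))
    len <- .effectiveLengths(proteins)
    missing <- setdiff(adjusted$protein_id, names(len))
    if (length(missing))
        stop(sprintf("no effective length for protein(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    el <- len[adjusted$protein_id]
    if (any(el <= 0))
        stop(sprintf("non-positive effective length for protein(s): %s",
                     paste(adjusted$protein_id[el <= 0], collapse = ", ")),
             call. = FALSE)
    data.frame(protein_id = adjusted$protein_id,
               adjusted_count = adjusted$adjusted_count,
               effective_length = unname(el),
               score = adjusted$adjusted_count / unname(el),
               stringsAsFactors = FALSE)
}
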