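#' @include utils.R
NULL

.asNamedNumeric <- function(x, idCol, valCol, what) {
    if (is.data.frame(x)) {
        if (!all(c(idCol, valCol) %in% names(x)))
            stop(sprintf("'%s' must have columns '%s' and '%s'",
                         what, idCol, valCol), call. = FALSE)
        stats::setNames(as.numeric(x[[valCol]]), as.character(x[[idCol]]))
    } else if (is.numeric(x) && !is.null(names(x))) {
        x
    } else {
        stop(sprintf("'%s' must be a named numeric vector or a data.frame",
                     what), call. = FALSE)
    }
}

#' Compute FPKM from fragment counts
#'
#' Fragments per kilobase of transcript per million fragments sequenced:
#' \deqn{\mathrm{FPKM}_i = \frac{c_i \times 10^9}{L_i \times N}}
#' with \eqn{c_i} the fragment count, \eqn{L_i} the transcript length in
#' nucleotides and \eqn{N} the library size (total mapped fragments). Full
#' transcript length is used; no effective-length correction is applied.
#'
#' @param counts named numeric vector of fragment counts, or a data.frame
#'   with columns \code{transcript_id} (or \code{id}) and \code{fragments}.
#' @param lengths named numeric vector of transcript lengths in nt, a
#'   data.frame with \code{id}/\code{length_nt} columns, or a
#'   \code{DNAStringSet} (widths are used).
#' @param librarySize total fragment count, or \code{"auto"} (the default)
#'   for the sum of \code{counts}.
#' @return data.frame with columns \code{id}, \code{fpkm}.
#' @examples
#' computeFPKM(c(tx1 = 1000), c(tx1 = 2000), librarySize = 1e7)  # FPKM 50
#' @export
computeFPKM <- function(counts, lengths, librarySize = "auto") {
    if (is.data.frame(counts) && !"id" %in% names(counts) &&
        "transcript_id" %in% names(counts))
        names(counts)[names(counts) == "transcript_id"] <- "id"
    counts <- .asNamedNumeric(counts, "id", "fragments", "counts")
    if (is(lengths, "DNAStringSet"))
        lengths <- stats::setNames(Biostrings::width(lengths),
                                   names(lengths))
    else
        lengths <- .asNamedNumeric(lengths, "id", "length_nt", "lengths")
    if (any(counts < 0))
        stop("fragment counts must be non-negative", call. = FALSE)
    missing <- setdiff(names(counts), names(lengths))
    if (length(missing))
        stop(sprintf("no length available for transcript(s): %s",
                     paste(missing, collapse = ", ")), call. = FALSE)
    if (any(lengths[names(counts)] <= 0))
        stop("transcript lengths must be positive", call. = FALSE)
    if (identical(librarySize, "auto")) librarySize <- sum(counts)
    if (!is.numeric(librarySize) || length(librarySize) != 1L ||
        librarySize <= 0)
        stop("'librarySize' must be a positive number (or \"auto\" with at least one non-zero count)",
             call. = FALSE)
    fpkm <- counts * 1e9 / (lengths[names(counts)] * librarySize)
    data.frame(id = names(counts), fpkm = unname(fpkm),
               stringsAsFactors = FALSE)
}

#' Retain transcripts at or above an FPKM threshold
#'
#' Low-abundance transcripts with FPKM strictly below the threshold are
#' removed; a transcript at exactly the threshold is retained.
#'
#' @param fpkm data.frame from \code{\link{computeFPKM}} or a named numeric
#'   vector of FPKM values.
#' @param threshold non-negative FPKM cutoff (default 1).
#' @return Character vector of retained transcript ids.
#' @examples
#' filterLowAbundance(c(a = 0.5, b = 1.0, c = 3.2))   # "b" "c"
#' @export
filterLowAbundance <- function(fpkm, threshold = 1.0) {
    if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
        stop("'threshold' must be a single non-negative number",
             call. = FALSE)
    fpkm <- .asNamedNumeric(fpkm, "id", "fpkm", "fpkm")
    if (any(fpkm < 0))
        stop("FPKM values must be non-negative", call. = FALSE)
    names(fpkm)[fpkm >= threshold]
}

#' Percentage of total FPKM contributed by a transcript subset
#'
#' @param fpkm as in \code{\link{filterLowAbundance}}.
#' @param ids transcript ids of the subset; must all be present.
#' @return \code{100 * sum(fpkm[ids]) / sum(fpkm)}; 0 for an empty subset.
#' @examples
#' fpkmPercent(c(a = 2, b = 2), "a")   # 50
#' @export
fpkmPercent <- function(fpkm, ids) {
    fpkm <- .asNamedNumeric(fpkm, "id", "fpkm", "fpkm")
    bad <- setdiff(ids, names(fpkm))
    if (length(bad))
        stop(sprintf("id(s) not in the FPKM table: %s",
                     paste(bad, collapse = ", ")), call. = FALSE)
    if (length(ids) == 0L) return(0)
    total <- sum(fpkm)
    if (total == 0)
        stop("total FPKM is zero; percentage undefined", call. = FALSE)
    100 * sum(fpkm[ids]) / total
}
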