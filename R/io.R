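#' @include utils.R
NULL

#' Read a FASTA file
#'
#' Thin wrapper over the Biostrings readers that enforces unique record ids
#' (the part of each header up to the first whitespace) while preserving the
#' full header as the record name.
#'
#' @param path file path.
#' @param type \code{"AA"} or \code{"DNA"}.
#' @return An \code{AAStringSet} or \code{DNAStringSet}; names hold the full
#'   headers. Use \code{\link{fastaIds}} for the whitespace-trimmed ids.
#' @export
readFasta <- function(path, type = c("AA", "DNA")) {
    type <- match.arg(type)
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    set <- tryCatch(
        if (type == "AA") Biostrings::readAAStringSet(path)
        else Biostrings::readDNAStringSet(path),
        error = function(e)
            stop(sprintf("malformed FASTA '%s': %s", path,
                         conditionMessage(e)), call. = FALSE))
    ids <- fastaIds(set)
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop(sprintf("duplicate record id(s) in '%s': %s", path,
                     paste(dup, collapse = ", ")), call. = FALSE)
    set
}

#' Record ids of a FASTA set
#' @param set an \code{XStringSet} (or anything with names).
#' @return Character vector: each name truncated at the first whitespace.
#' @export
fastaIds <- function(set) {
    sub("\\s.*$", "", names(set))
}

#' Write sequences to FASTA
#'
#' @param set an \code{XStringSet} or a named character vector.
#' @param path output path.
#' @param width line-wrap width (default 60 columns).
#' @return Invisibly, \code{path}.
#' @export
writeFasta <- function(set, path, width = 60L) {
    if (is.character(set))
        set <- Biostrings::BStringSet(set)
    Biostrings::writeXStringSet(set, path, width = as.integer(width))
    invisible(path)
}

.fileHeader <- function(seed = NULL, extra = character()) {
    v <- as.character(utils::packageVersion("venomeCorr"))
    h <- sprintf("# venomeCorr %s", v)
    if (!is.null(seed)) {
        h <- c(h, sprintf("# seed: %d", as.integer(seed)),
               sprintf("# config_hash: %s",
                       fnv1a(paste(v, seed, paste(extra, collapse = "|")))))
    }
    c(h, extra)
}

#' Read a TSV table
#'
#' Tab-separated values with a header row; lines starting with \code{#} are
#' comments. Column presence can be asserted up front so stage errors name
#' the offending file.
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data.frame.
#' @export
readTsvTable <- function(path, required = NULL) {
    if (!file.exists(path))
        stop(sprintf("file not found: %s", path), call. = FALSE)
    df <- tryCatch(
        utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE, check.names = FALSE),
        error = function(e)
            stop(sprintf("malformed TSV '%s': %s", path,
                         conditionMessage(e)), call. = FALSE))
    missing <- setdiff(required, names(df))
    if (length(missing))
        stop(sprintf("'%s' lacks required column(s): %s", path,
                     paste(missing, collapse = ", ")), call. = FALSE)
    df
}

#' Write a TSV table with a provenance header
#'
#' Writes \code{#}-prefixed comment lines (package version, seed,
#' configuration hash) followed by a tab-separated table. List columns (e.g.
#' the \code{matches} column of matched observations) are collapsed with
#' \code{";"}.
#'
#' @param df data.frame.
#' @param path output path.
#' @param seed optional seed recorded in the header.
#' @param extra additional \code{#} comment lines.
#' @return Invisibly, \code{path}.
#' @export
writeTsvTable <- function(df, path, seed = NULL, extra = character()) {
    isList <- vapply(df, is.list, logical(1))
    for (j in which(isList))
        df[[j]] <- vapply(df[[j]], paste, character(1), collapse = ";")
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(.fileHeader(seed, extra), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
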