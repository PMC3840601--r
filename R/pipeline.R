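#' @include correlation.R io.R
NULL

#' Pipeline configuration
#'
#' Paths and parameters for the end-to-end driver \code{\link{runPipeline}}.
#' The transcript FASTA and fragment-count TSV are required. If no protein
#' FASTA is given, the search space is built from the retained transcripts by
#' six-frame translation (stop-free segments of at least
#' \code{minOrfLength} residues, ids \code{<transcript>|<frame>|<k>}).
#' Proteins are linked to transcripts either by sharing the transcript's id
#' or by the id prefix before the first \code{"|"}.
#'
#' @slot transcriptFasta,countsTsv,peptideTsv required input paths.
#' @slot proteinFasta,contaminantFasta optional input paths (\code{""} to
#'   omit).
#' @slot fpkmThreshold FPKM retention cutoff.
#' @slot minOrfLength minimum stop-free segment length when six-frame
#'   building the search space.
#' @slot bootstrap a \linkS4class{BootstrapConfig}.
#' @slot transform correlation transform.
#' @slot ilEquivalent match peptides with I = L.
#' @slot seed seed recorded in every output header and used for the
#'   bootstrap.
#' @slot outputDir directory for all outputs.
#' @name PipelineConfig-class
#' @rdname PipelineConfig-class
#' @exportClass PipelineConfig
setClass("PipelineConfig",
    representation(
        transcriptFasta = "character",
        countsTsv = "character",
        peptideTsv = "character",
        proteinFasta = "character",
        contaminantFasta = "character",
        fpkmThreshold = "numeric",
        minOrfLength = "integer",
        bootstrap = "BootstrapConfig",
        transform = "character",
        ilEquivalent = "logical",
        seed = "integer",
        outputDir = "character"
    )
)

setValidity("PipelineConfig", function(object) {
    msg <- character()
    for (slot in c("transcriptFasta", "countsTsv", "peptideTsv")) {
        p <- methods::slot(object, slot)
        if (!nzchar(p) || !file.exists(p))
            msg <- c(msg, sprintf("%s: file not found: '%s'", slot, p))
    }
    for (slot in c("proteinFasta", "contaminantFasta")) {
        p <- methods::slot(object, slot)
        if (nzchar(p) && !file.exists(p))
            msg <- c(msg, sprintf("%s: file not found: '%s'", slot, p))
    }
    if (object@fpkmThreshold < 0)
        msg <- c(msg, "'fpkmThreshold' must be non-negative")
    if (!(object@transform %in% c("log10", "identity", "rank")))
        msg <- c(msg, "'transform' must be log10, identity or rank")
    if (length(msg)) msg else TRUE
})

#' @param transcriptFasta,countsTsv,peptideTsv,proteinFasta,contaminantFasta
#'   input paths; see \linkS4class{PipelineConfig}.
#' @param fpkmThreshold,minOrfLength,bootstrap,transform,ilEquivalent,seed,outputDir
#'   see \linkS4class{PipelineConfig}.
#' @return A validated \linkS4class{PipelineConfig}.
#' @rdname PipelineConfig-class
#' @export
pipelineConfig <- function(transcriptFasta, countsTsv, peptideTsv,
                           proteinFasta = "", contaminantFasta = "",
                           fpkmThreshold = 1.0, minOrfLength = 30L,
                           bootstrap = NULL,
                           transform = "log10", ilEquivalent = FALSE,
                           seed = 1L, outputDir = ".") {
    if (is.null(bootstrap))
        bootstrap <- bootstrapConfig(seed = deriveSeed(seed, 3L))
    cfg <- new("PipelineConfig",
        transcriptFasta = transcriptFasta,
        countsTsv = countsTsv,
        peptideTsv = peptideTsv,
        proteinFasta = proteinFasta,
        contaminantFasta = contaminantFasta,
        fpkmThreshold = as.numeric(fpkmThreshold),
        minOrfLength = .assertCount(minOrfLength, "minOrfLength",
                                    positive = TRUE),
        bootstrap = bootstrap,
        transform = transform,
        ilEquivalent = isTRUE(ilEquivalent),
        seed = as.integer(seed),
        outputDir = outputDir)
    validObject(cfg)
    cfg
}

.sixFrameDatabase <- function(transcripts, minOrfLength) {
    out <- character()
    ids <- fastaIds(transcripts)
    for (i in seq_along(transcripts)) {
        frames <- sixFrameTranslate(as.character(transcripts[[i]]))
        for (f in names(frames)) {
            segs <- splitOrfs(frames[[f]], minLength = minOrfLength)
            if (length(segs))
                out[sprintf("%s|%s|%d", ids[i], f, seq_along(segs))] <- segs
        }
    }
    out
}

#' Run the full comparison pipeline from files
#'
#' Executes, in order: FPKM computation and the low-abundance retention
#' filter; search-space construction (six-frame translation of the retained
#' transcripts, unless a protein FASTA is supplied); peptide-to-protein
#' matching; fractionally attributed, length-normalized abundance scoring;
#' the bootstrap contaminant threshold; and the transcript-protein abundance
#' correlation. All intermediate tables, a threshold report, the
#' Figure-style scatter table and a stage log are written to
#' \code{outputDir}; every file starts with a comment header recording the
#' package version, seed and configuration hash, and reruns with the same
#' configuration are byte-identical.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @return Invisibly, a list with the \linkS4class{CorrelationResult}, the
#'   \linkS4class{ThresholdResult} (or NULL), stage tallies, and the paths
#'   written.
#' @export
runPipeline <- function(config) {
    stopifnot(is(config, "PipelineConfig"))
    validObject(config)
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    seed <- config@seed
    log <- character()
    say <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))

    tx <- readFasta(config@transcriptFasta, type = "DNA")
    names(tx) <- fastaIds(tx)
    counts <- readTsvTable(config@countsTsv,
                           required = c("transcript_id", "fragments"))
    say("transcripts: %d; fragments: %.0f", length(tx),
        sum(counts$fragments))

    fpkm <- computeFPKM(counts, tx)
    retainedTx <- filterLowAbundance(fpkm, config@fpkmThreshold)
    say("fpkm filter (>= %g): %d of %d transcripts retained",
        config@fpkmThreshold, length(retainedTx), nrow(fpkm))

    if (nzchar(config@proteinFasta)) {
        protSet <- readFasta(config@proteinFasta, type = "AA")
        prot <- stats::setNames(as.character(protSet), fastaIds(protSet))
        say("proteins: %d from %s", length(prot), config@proteinFasta)
    } else {
        prot <- .sixFrameDatabase(tx[names(tx) %in% retainedTx],
                                  config@minOrfLength)
        say("proteins: %d six-frame segments (>= %d aa) from retained transcripts",
            length(prot), config@minOrfLength)
    }

    contIds <- character()
    if (nzchar(config@contaminantFasta)) {
        contSet <- readFasta(config@contaminantFasta, type = "AA")
        cont <- stats::setNames(as.character(contSet), fastaIds(contSet))
        clash <- intersect(names(cont), names(prot))
        if (length(clash))
            stop(sprintf("contaminant id(s) collide with protein ids: %s",
                         paste(clash, collapse = ", ")), call. = FALSE)
        prot <- c(prot, cont)
        contIds <- names(cont)
        say("contaminants: %d from %s", length(contIds),
            config@contaminantFasta)
    }

    obs <- readTsvTable(config@peptideTsv,
                        required = c("peptide", "count"))
    matched <- matchPeptides(obs, prot, ilEquivalent = config@ilEquivalent)
    nUnmatched <- sum(!matched$matched)
    matched <- matched[matched$matched, , drop = FALSE]
    say("peptides: %d observations, %d unmatched (dropped)",
        nrow(obs), nUnmatched)

    adj <- adjustedCounts(matched, proteins = names(prot))
    sc <- abundanceScores(adj, stats::setNames(nchar(prot), names(prot)))

    thr <- NULL
    cutoff <- 0
    if (length(contIds) >= 2L) {
        thr <- bootstrapThreshold(sc$score[sc$protein_id %in% contIds],
                                  config@bootstrap)
        cutoff <- threshold(thr)
        say("contaminant threshold: %g (%g%% CI upper bound, %d contaminants)",
            cutoff, 100 * config@bootstrap@confidence, length(contIds))
    } else {
        say("contaminant threshold: none (fewer than 2 contaminants)")
    }
    parts <- applyThreshold(sc, cutoff, contaminantIds = contIds)
    say("threshold filter: %d retained, %d filtered",
        nrow(parts$retained), nrow(parts$filtered))

    ## link each protein to its source transcript: identical id, or the id
    ## prefix before the first '|' (six-frame segment ids)
    bioIds <- setdiff(sc$protein_id, contIds)
    linkTx <- ifelse(bioIds %in% names(tx), bioIds,
                     sub("\\|.*$", "", bioIds))
    link <- stats::setNames(linkTx, bioIds)
    unknown <- bioIds[!(link %in% names(tx))]
    if (length(unknown))
        stop(sprintf("protein(s) with no linked transcript: %s",
                     paste(utils::head(unknown, 5), collapse = ", ")),
             call. = FALSE)

    keep <- parts$retained[link[parts$retained$protein_id] %in% retainedTx, ,
                           drop = FALSE]
    fpkmVec <- stats::setNames(fpkm$fpkm, fpkm$id)
    pt <- pairAndTransform(fpkmVec, keep, link, transform = config@transform)
    corr <- correlateAbundance(pt)
    say("correlation: r = %.4f, p = %.3g, n = %d (%s scale)",
        corCoef(corr), pValue(corr), nPairs(corr), config@transform)

    ## ---- outputs -----------------------------------------------------
    od <- config@outputDir
    paths <- c(fpkm = file.path(od, "fpkm.tsv"),
               matched = file.path(od, "matched_peptides.tsv"),
               scores = file.path(od, "scores.tsv"),
               thresholdReport = file.path(od, "threshold_report.txt"),
               retained = file.path(od, "retained.tsv"),
               filtered = file.path(od, "filtered.tsv"),
               scatter = file.path(od, "scatter.tsv"),
               summary = file.path(od, "summary.txt"),
               log = file.path(od, "run.log"))

    fpkmOut <- fpkm
    fpkmOut$retained <- fpkmOut$id %in% retainedTx
    writeTsvTable(fpkmOut, paths[["fpkm"]], seed = seed)
    writeTsvTable(matched, paths[["matched"]], seed = seed)
    scOut <- sc
    scOut$is_contaminant <- scOut$protein_id %in% contIds
    writeTsvTable(scOut, paths[["scores"]], seed = seed)

    thrLines <- if (is.null(thr)) {
        c("threshold: 0", "note: fewer than 2 contaminant scores")
    } else {
        c(sprintf("threshold: %.10g", threshold(thr)),
          sprintf("ci_lower: %.10g", thr@ciLower),
          sprintf("ci_upper: %.10g", thr@ciUpper),
          sprintf("n_contaminants: %d", thr@nContaminants),
          sprintf("confidence: %g", thr@config@confidence),
          sprintf("n_boot: %d", thr@config@nBoot),
          sprintf("statistic: %s", thr@config@statistic))
    }
    writeLines(c(.fileHeader(seed), thrLines), paths[["thresholdReport"]])

    writeTsvTable(parts$retained, paths[["retained"]], seed = seed)
    writeTsvTable(parts$filtered, paths[["filtered"]], seed = seed)
    writeTsvTable(pt$pairs, paths[["scatter"]], seed = seed)
    writeLines(c(.fileHeader(seed),
                 sprintf("r: %.10g", corCoef(corr)),
                 sprintf("p_value: %.10g", pValue(corr)),
                 sprintf("n_pairs: %d", nPairs(corr)),
                 sprintf("transform: %s", config@transform),
                 sprintf("excluded_zero_fpkm: %d", pt$excludedZeroFpkm),
                 sprintf("excluded_zero_score: %d", pt$excludedZeroScore)),
               paths[["summary"]])
    writeLines(c(.fileHeader(seed), log), paths[["log"]])

    invisible(list(correlation = corr, threshold = thr,
                   counts = c(transcripts = length(tx),
                              retainedTranscripts = length(retainedTx),
                              proteins = length(prot),
                              contaminants = length(contIds),
                              observations = nrow(obs),
                              unmatched = nUnmatched,
                              retainedProteins = nrow(keep),
                              pairs = nPairs(corr)),
                   paths = paths))
}
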