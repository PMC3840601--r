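#' @include contaminantFilter.R peptideAbundance.R transcriptQuant.R
NULL

#' Pair protein scores with transcript FPKM and transform
#'
#' Joins the retained protein abundance scores to the FPKM of each protein's
#' source transcript and applies the requested transform to both axes. Under
#' \code{log10}, pairs in which either value is zero cannot be transformed
#' and are excluded and tallied (no pseudocount is added by default;
#' \code{pseudocount} adds a constant to both axes before the log instead).
#' The caller is expected to have applied the FPKM retention filter and the
#' contaminant threshold already, mirroring the pipeline order.
#'
#' @param fpkm FPKM values (data.frame or named numeric).
#' @param scores abundance scores (data.frame from
#'   \code{\link{abundanceScores}} or named numeric).
#' @param link named character vector mapping protein id to transcript id;
#'   every scored protein must be present.
#' @param transform \code{"log10"} (default), \code{"identity"} or
#'   \code{"rank"}.
#' @param pseudocount optional constant added to both axes before a log10
#'   transform; \code{NULL} (default) excludes zeros instead.
#' @return List with \code{pairs} (data.frame \code{protein_id}, \code{fpkm},
#'   \code{score}, \code{x}, \code{y}), \code{excludedZeroFpkm} and
#'   \code{excludedZeroScore}.
#' @export
pairAndTransform <- function(fpkm, scores, link,
                             transform = c("log10", "identity", "rank"),
                             pseudocount = NULL) {
    transform <- match.arg(transform)
    fpkm <- .asNamedNumeric(fpkm, "id", "fpkm", "fpkm")
    sc <- .asNamedNumeric(scores, "protein_id", "score", "scores")
    if (is.null(names(link)))
        stop("'link' must be a named character vector (protein -> transcript)",
             call. = FALSE)
    unlinked <- setdiff(names(sc), names(link))
    if (length(unlinked))
        stop(sprintf("protein(s) with no linked transcript: %s",
                     paste(unlinked, collapse = ", ")), call. = FALSE)
    tx <- link[names(sc)]
    missingTx <- setdiff(tx, names(fpkm))
    if (length(missingTx))
        stop(sprintf("linked transcript(s) missing from the FPKM table: %s",
                     paste(missingTx, collapse = ", ")), call. = FALSE)

    df <- data.frame(protein_id = names(sc),
                     fpkm = unname(fpkm[tx]),
                     score = unname(sc),
                     stringsAsFactors = FALSE)
    exF <- exS <- 0L
    if (transform == "log10") {
        if (!is.null(pseudocount)) {
            df$x <- log10(df$fpkm + pseudocount)
            df$y <- log10(df$score + pseudocount)
        } else {
            zf <- df$fpkm == 0
            zs <- df$score == 0
            exF <- sum(zf)
            exS <- sum(zs & !zf)
            df <- df[!zf & !zs, , drop = FALSE]
            df$x <- log10(df$fpkm)
            df$y <- log10(df$score)
        }
    } else if (transform == "rank") {
        df$x <- rank(df$fpkm)
        df$y <- rank(df$score)
    } else {
        df$x <- df$fpkm
        df$y <- df$score
    }
    rownames(df) <- NULL
    list(pairs = df, transform = transform,
         excludedZeroFpkm = as.integer(exF),
         excludedZeroScore = as.integer(exS))
}

#' Pearson correlation of paired abundances
#'
#' Product-moment correlation of the transformed (FPKM, score) pairs with a
#' two-sided p-value from the t distribution on \code{n - 2} degrees of
#' freedom.
#'
#' @param pairs the result of \code{\link{pairAndTransform}}, or a data.frame
#'   with columns \code{x} and \code{y}.
#' @return A \linkS4class{CorrelationResult}.
#' @examples
#' p <- data.frame(x = 1:10, y = 2 * (1:10) + 1)
#' corCoef(correlateAbundance(p))   # exactly 1
#' @export
correlateAbundance <- function(pairs) {
    transform <- "identity"
    exF <- exS <- 0L
    if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs)) {
        transform <- pairs$transform
        exF <- pairs$excludedZeroFpkm
        exS <- pairs$excludedZeroScore
        pairs <- pairs$pairs
    }
    stopifnot(is.data.frame(pairs), all(c("x", "y") %in% names(pairs)))
    n <- nrow(pairs)
    if (n < 3L)
        stop(sprintf("need at least 3 pairs to correlate, got %d", n),
             call. = FALSE)
    if (stats::sd(pairs$x) == 0 || stats::sd(pairs$y) == 0)
        stop("zero variance on one axis; correlation undefined",
             call. = FALSE)
    ct <- stats::cor.test(pairs$x, pairs$y, method = "pearson",
                          alternative = "two.sided")
    new("CorrelationResult",
        r = unname(ct$estimate),
        pValue = max(ct$p.value, .Machine$double.xmin),
        nPairs = as.integer(n),
        transform = transform,
        excludedZeroFpkm = as.integer(exF),
        excludedZeroScore = as.integer(exS))
}

#' End-to-end parameter-recovery experiment on a synthetic venome
#'
#' Runs the whole pipeline on generated data with known ground truth:
#' generate the venome, draw fragment counts, compute FPKM and apply the
#' retention filter, simulate peptide observations, match them to the
#' proteins, score by fractionally attributed counts per residue, derive the
#' contaminant threshold by bootstrap, filter, and correlate protein score
#' against transcript FPKM. Because the truth is known, the experiment also
#' reports how well the estimated quantities track the true abundances.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @param fpkmThreshold FPKM retention cutoff (default 1).
#' @param bootConfig \linkS4class{BootstrapConfig} for the contaminant
#'   threshold; its seed is derived from \code{config@seed} when NULL.
#' @param transform correlation transform (default \code{"log10"}).
#' @param ilEquivalent passed to \code{\link{matchPeptides}}.
#' @return List with elements \code{correlation} (a
#'   \linkS4class{CorrelationResult} for estimated FPKM vs estimated score),
#'   \code{rTrueScore} and \code{rTrueFpkm} (correlations of each estimate
#'   with the true abundance, same transform), \code{threshold} (a
#'   \linkS4class{ThresholdResult} or NULL if no contaminants), \code{counts}
#'   (stage tallies) and \code{truth}.
#' @examples
#' \donttest{
#' rep <- recoveryExperiment(generatorConfig(nTranscripts = 50, seed = 11))
#' rep$correlation
#' }
#' @export
recoveryExperiment <- function(config = generatorConfig(),
                               fpkmThreshold = 1.0,
                               bootConfig = NULL,
                               transform = "log10",
                               ilEquivalent = FALSE) {
    truth <- sampleVenome(config)
    counts <- simulateFragmentCounts(truth)
    fpkm <- computeFPKM(counts, transcripts(truth))
    retainedTx <- filterLowAbundance(fpkm, fpkmThreshold)

    obs <- simulatePeptideObservations(truth)
    matched <- matchPeptides(obs, truth, ilEquivalent = ilEquivalent)
    matched <- matched[matched$matched, , drop = FALSE]
    adj <- adjustedCounts(matched, proteins = truth@proteinMeta$id)
    sc <- abundanceScores(adj, truth)

    contIds <- contaminantIds(truth)
    thr <- NULL
    cutoff <- 0
    if (length(contIds) >= 2L) {
        if (is.null(bootConfig))
            bootConfig <- bootstrapConfig(seed = deriveSeed(config@seed, 3L))
        contScores <- sc$score[sc$protein_id %in% contIds]
        thr <- bootstrapThreshold(contScores, bootConfig)
        cutoff <- threshold(thr)
    }
    parts <- applyThreshold(sc, cutoff, contaminantIds = contIds)

    ## proteins must also pass the transcript-level retention filter
    meta <- truth@proteinMeta
    link <- stats::setNames(meta$source_transcript, meta$id)
    keep <- parts$retained[link[parts$retained$protein_id] %in% retainedTx, ,
                           drop = FALSE]
    fpkmVec <- stats::setNames(fpkm$fpkm, fpkm$id)
    pt <- pairAndTransform(fpkmVec, keep, link, transform = transform)
    corr <- correlateAbundance(pt)

    ## how well each estimated axis tracks the truth, on the same pairs
    truthAb <- truth@proteinAbundance[pt$pairs$protein_id]
    rTrueScore <- stats::cor(log10(truthAb), pt$pairs$y)
    rTrueFpkm <- stats::cor(log10(truthAb), pt$pairs$x)

    list(correlation = corr,
         rTrueScore = rTrueScore,
         rTrueFpkm = rTrueFpkm,
         threshold = thr,
         counts = c(transcripts = length(transcripts(truth)),
                    retainedTranscripts = length(retainedTx),
                    observations = nrow(obs),
                    matchedObservations = nrow(matched),
                    retainedProteins = nrow(keep),
                    filteredProteins = nrow(parts$filtered),
                    pairs = nPairs(corr)),
         truth = truth)
}
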