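#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## GeneratorConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic venome generator
#'
#' Parameters controlling \code{\link{sampleVenome}} and the two downstream
#' simulators. The defaults describe a desk-scale venom-gland study: a few
#' hundred transcripts whose relative abundances span six decades, a
#' paired-end fragment depth of one million, a small set of low-abundance
#' laboratory contaminants, and peptide detection whose expected spectral
#' count grows with protein abundance.
#'
#' @slot nTranscripts number of biological transcripts.
#' @slot abundanceLog10Range lower/upper decade of the log-uniform relative
#'   abundance prior (default \code{c(0, 6)}: six orders of magnitude).
#' @slot lengthRangeNt bounds on coding length in nucleotides; both multiples
#'   of 3.
#' @slot totalFragments total sequenced fragment count distributed across
#'   transcripts.
#' @slot nContaminants number of contaminant proteins (keratin-like spike-ins).
#' @slot contaminantAbundanceQuantile where contaminants sit in the biological
#'   abundance distribution (default 0.05, i.e. well below typical targets).
#' @slot detectionKappa rate constant of the peptide detection model: expected
#'   spectral count of a candidate peptide from a protein of relative
#'   abundance \eqn{a} is \eqn{\kappa a^{\gamma}} before noise.
#' @slot detectionExponent the exponent \eqn{\gamma} (1 = proportional
#'   detection, 0 = abundance-independent null).
#' @slot detectionNoiseSigma standard deviation of log-normal multiplicative
#'   noise on the expected count.
#' @slot enzymes proteases used to generate candidate peptides; subset of
#'   \code{c("trypsin", "chymotrypsin", "glu-c", "none")}.
#' @slot maxMissedCleavages maximum missed cleavages in candidate peptides.
#' @slot paralogPairs number of duplicated (paralog) proteins appended to
#'   induce shared-peptide ambiguity; 0 disables.
#' @slot paralogIdentity approximate residue identity of each paralog copy.
#' @slot seed integer seed; fully determines all generator output.
#'
#' @seealso \code{\link{generatorConfig}}, \code{\link{sampleVenome}}
#' @name GeneratorConfig-class
#' @rdname GeneratorConfig-class
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
    representation(
        nTranscripts = "integer",
        abundanceLog10Range = "numeric",
        lengthRangeNt = "integer",
        totalFragments = "integer",
        nContaminants = "integer",
        contaminantAbundanceQuantile = "numeric",
        detectionKappa = "numeric",
        detectionExponent = "numeric",
        detectionNoiseSigma = "numeric",
        enzymes = "character",
        maxMissedCleavages = "integer",
        paralogPairs = "integer",
        paralogIdentity = "numeric",
        seed = "integer"
    )
)

setValidity("GeneratorConfig", function(object) {
    msg <- character()
    r <- object@abundanceLog10Range
    if (length(r) != 2L || any(!is.finite(r)) || r[2] < r[1])
        msg <- c(msg, "'abundanceLog10Range' must be a finite pair with upper >= lower")
    l <- object@lengthRangeNt
    if (length(l) != 2L || any(l <= 0L) || l[2] < l[1])
        msg <- c(msg, "'lengthRangeNt' must be positive with upper >= lower")
    else if (any(l %% 3L != 0L))
        msg <- c(msg, "'lengthRangeNt' bounds must be multiples of 3")
    if (object@nTranscripts < 0L)
        msg <- c(msg, "'nTranscripts' must be non-negative")
    if (object@totalFragments <= 0L)
        msg <- c(msg, "'totalFragments' must be strictly positive")
    if (object@nContaminants < 0L)
        msg <- c(msg, "'nContaminants' must be non-negative")
    q <- object@contaminantAbundanceQuantile
    if (length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
        msg <- c(msg, "'contaminantAbundanceQuantile' must lie in (0, 1)")
    if (object@detectionKappa < 0)
        msg <- c(msg, "'detectionKappa' must be non-negative")
    if (object@detectionExponent < 0)
        msg <- c(msg, "'detectionExponent' must be non-negative")
    if (object@detectionNoiseSigma < 0)
        msg <- c(msg, "'detectionNoiseSigma' must be non-negative")
    if (!all(object@enzymes %in% KNOWN_ENZYMES))
        msg <- c(msg, sprintf("'enzymes' must be a subset of {%s}",
                              paste(KNOWN_ENZYMES, collapse = ", ")))
    if (object@maxMissedCleavages < 0L)
        msg <- c(msg, "'maxMissedCleavages' must be non-negative")
    if (object@paralogPairs < 0L)
        msg <- c(msg, "'paralogPairs' must be non-negative")
    p <- object@paralogIdentity
    if (length(p) != 1L || is.na(p) || p <= 0 || p > 1)
        msg <- c(msg, "'paralogIdentity' must lie in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Construct a generator configuration
#'
#' @param nTranscripts,abundanceLog10Range,lengthRangeNt,totalFragments
#'   see \linkS4class{GeneratorConfig}.
#' @param nContaminants,contaminantAbundanceQuantile,detectionKappa see
#'   \linkS4class{GeneratorConfig}.
#' @param detectionExponent,detectionNoiseSigma,enzymes,maxMissedCleavages
#'   see \linkS4class{GeneratorConfig}.
#' @param paralogPairs,paralogIdentity,seed see \linkS4class{GeneratorConfig}.
#' @return A validated \linkS4class{GeneratorConfig}.
#' @examples
#' generatorConfig(nTranscripts = 50, seed = 7)
#' @export
generatorConfig <- function(nTranscripts = 300L,
                            abundanceLog10Range = c(0, 6),
                            lengthRangeNt = c(300L, 1500L),
                            totalFragments = 1e6,
                            nContaminants = 20L,
                            contaminantAbundanceQuantile = 0.05,
                            detectionKappa = 500,
                            detectionExponent = 1,
                            detectionNoiseSigma = 0.5,
                            enzymes = c("trypsin", "chymotrypsin",
                                        "glu-c", "none"),
                            maxMissedCleavages = 2L,
                            paralogPairs = 0L,
                            paralogIdentity = 0.9,
                            seed = 1L) {
    cfg <- new("GeneratorConfig",
        nTranscripts = .assertCount(nTranscripts, "nTranscripts"),
        abundanceLog10Range = as.numeric(abundanceLog10Range),
        lengthRangeNt = as.integer(lengthRangeNt),
        totalFragments = .assertCount(totalFragments, "totalFragments",
                                      positive = TRUE),
        nContaminants = .assertCount(nContaminants, "nContaminants"),
        contaminantAbundanceQuantile =
            .assertFraction(contaminantAbundanceQuantile,
                            "contaminantAbundanceQuantile"),
        detectionKappa = as.numeric(detectionKappa),
        detectionExponent = as.numeric(detectionExponent),
        detectionNoiseSigma = as.numeric(detectionNoiseSigma),
        enzymes = as.character(enzymes),
        maxMissedCleavages = .assertCount(maxMissedCleavages,
                                          "maxMissedCleavages"),
        paralogPairs = .assertCount(paralogPairs, "paralogPairs"),
        paralogIdentity = as.numeric(paralogIdentity),
        seed = as.integer(seed)
    )
    validObject(cfg)
    cfg
}

setMethod("show", "GeneratorConfig", function(object) {
    cat("GeneratorConfig\n")
    cat("  transcripts:", object@nTranscripts,
        sprintf("(abundance 10^%g..10^%g, length %d..%d nt)",
                object@abundanceLog10Range[1], object@abundanceLog10Range[2],
                object@lengthRangeNt[1], object@lengthRangeNt[2]), "\n")
    cat("  fragments:", object@totalFragments, "\n")
    cat("  contaminants:", object@nContaminants,
        sprintf("at abundance quantile %.3g",
                object@contaminantAbundanceQuantile), "\n")
    cat(sprintf("  detection: kappa=%g exponent=%g noiseSigma=%g\n",
                object@detectionKappa, object@detectionExponent,
                object@detectionNoiseSigma))
    cat("  enzymes:", paste(object@enzymes, collapse = ", "),
        sprintf("(<=%d missed cleavages)", object@maxMissedCleavages), "\n")
    cat("  seed:", object@seed, "\n")
})

## ---------------------------------------------------------------------------
## VenomeTruth
## ---------------------------------------------------------------------------

#' Synthetic venome with known ground truth
#'
#' Container returned by \code{\link{sampleVenome}}: transcripts as a
#' \code{DNAStringSet}, proteins (biological translations plus contaminants)
#' as an \code{AAStringSet}, the true relative abundances on both levels, and
#' per-protein metadata. Biological proteins carry the id of their source
#' transcript; contaminant proteins have none.
#'
#' @slot transcripts \code{DNAStringSet} of coding sequences.
#' @slot txAbundance named numeric; true relative transcript abundances
#'   summing to 1.
#' @slot proteins \code{AAStringSet} of protein sequences (biological then
#'   contaminant).
#' @slot proteinAbundance named numeric; true protein abundances, proportional
#'   to the source transcript's abundance for biological proteins.
#' @slot proteinMeta data.frame with columns \code{id},
#'   \code{source_transcript}, \code{frame}, \code{is_contaminant},
#'   \code{signal_peptide_length}, \code{effective_length}.
#' @slot config the \linkS4class{GeneratorConfig} used.
#'
#' @seealso \code{\link{sampleVenome}}, \code{\link{simulateFragmentCounts}},
#'   \code{\link{simulatePeptideObservations}}
#' @name VenomeTruth-class
#' @rdname VenomeTruth-class
#' @exportClass VenomeTruth
setClass("VenomeTruth",
    representation(
        transcripts = "DNAStringSet",
        txAbundance = "numeric",
        proteins = "AAStringSet",
        proteinAbundance = "numeric",
        proteinMeta = "data.frame",
        config = "GeneratorConfig"
    )
)

setValidity("VenomeTruth", function(object) {
    msg <- character()
    n <- length(object@transcripts)
    if (length(object@txAbundance) != n)
        msg <- c(msg, "one abundance per transcript required")
    if (n > 0 && abs(sum(object@txAbundance) - 1) > 1e-9)
        msg <- c(msg, "transcript abundances must sum to 1 (tolerance 1e-9)")
    if (length(object@proteins) != nrow(object@proteinMeta))
        msg <- c(msg, "one metadata row per protein required")
    if (length(object@proteins) != length(object@proteinAbundance))
        msg <- c(msg, "one abundance per protein required")
    meta <- object@proteinMeta
    if (nrow(meta) > 0) {
        bio <- !meta$is_contaminant
        if (any(is.na(meta$source_transcript[bio])))
            msg <- c(msg,
                "every non-contaminant protein must map to one transcript")
        if (any(!is.na(meta$source_transcript[!bio])))
            msg <- c(msg, "contaminant proteins must not map to a transcript")
        if (any(duplicated(meta$id)))
            msg <- c(msg, "protein ids must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' @rdname accessors
#' @export
setMethod("transcripts", "VenomeTruth", function(x, ...) x@transcripts)

#' @rdname accessors
#' @export
setMethod("proteins", "VenomeTruth", function(x, ...) x@proteins)

#' @param level \code{"transcript"} or \code{"protein"}.
#' @rdname accessors
#' @export
setMethod("trueAbundance", "VenomeTruth",
    function(x, level = c("transcript", "protein"), ...) {
        level <- match.arg(level)
        if (level == "transcript") x@txAbundance else x@proteinAbundance
    })

#' @rdname accessors
#' @export
setMethod("contaminantIds", "VenomeTruth", function(x, ...)
    x@proteinMeta$id[x@proteinMeta$is_contaminant])

#' Protein metadata of a synthetic venome
#'
#' @param x a \linkS4class{VenomeTruth}.
#' @return data.frame with one row per protein (id, source transcript, frame,
#'   contaminant flag, signal peptide length, effective length).
#' @export
proteinMeta <- function(x) {
    stopifnot(is(x, "VenomeTruth"))
    x@proteinMeta
}

setMethod("show", "VenomeTruth", function(object) {
    nc <- sum(object@proteinMeta$is_contaminant)
    cat("VenomeTruth\n")
    cat(sprintf("  %d transcripts, %d proteins (%d biological + %d contaminant)\n",
                length(object@transcripts), length(object@proteins),
                length(object@proteins) - nc, nc))
    if (length(object@txAbundance) > 1) {
        rng <- range(object@txAbundance)
        cat(sprintf("  abundance span: %.2g decades\n",
                    log10(rng[2] / rng[1])))
    }
    cat("  seed:", object@config@seed, "\n")
})

## ---------------------------------------------------------------------------
## DigestionParams
## ---------------------------------------------------------------------------

#' In-silico digestion parameters
#'
#' Cleavage specificity and peptide filtering for \code{\link{digestProtein}}.
#' Trypsin cleaves C-terminal to R and K, chymotrypsin to F, L, W and Y, and
#' Glu-C to D and E; \code{"none"} leaves the protein intact (undigested
#' samples containing naturally occurring peptides are searched without
#' enzyme). The common "no cleavage before proline" refinement is available
#' but off by default, since the stated specificities are bare residue sets.
#' Glu-C can be restricted to E-only (the dialect observed in some buffers)
#' via \code{glucEOnly}.
#'
#' @slot enzyme one of \code{"trypsin"}, \code{"chymotrypsin"},
#'   \code{"glu-c"}, \code{"none"}.
#' @slot maxMissedCleavages maximum internal uncut sites per peptide.
#' @slot minPeptideLength,maxPeptideLength retained peptide length bounds in
#'   residues (defaults 6..50, the typical LC/MS detectable range).
#' @slot prolineRule suppress cleavage when the next residue is proline.
#' @slot glucEOnly restrict Glu-C to cleavage after E.
#'
#' @name DigestionParams-class
#' @rdname DigestionParams-class
#' @exportClass DigestionParams
setClass("DigestionParams",
    representation(
        enzyme = "character",
        maxMissedCleavages = "integer",
        minPeptideLength = "integer",
        maxPeptideLength = "integer",
        prolineRule = "logical",
        glucEOnly = "logical"
    )
)

setValidity("DigestionParams", function(object) {
    msg <- character()
    if (!(object@enzyme %in% KNOWN_ENZYMES))
        msg <- c(msg, sprintf("unknown enzyme '%s'", object@enzyme))
    if (object@maxMissedCleavages < 0L)
        msg <- c(msg, "'maxMissedCleavages' must be non-negative")
    if (object@minPeptideLength < 1L)
        msg <- c(msg, "'minPeptideLength' must be positive")
    if (object@maxPeptideLength < object@minPeptideLength)
        msg <- c(msg, "'maxPeptideLength' must be >= 'minPeptideLength'")
    if (length(msg)) msg else TRUE
})

#' @param enzyme,maxMissedCleavages,minPeptideLength,maxPeptideLength,prolineRule,glucEOnly
#'   see \linkS4class{DigestionParams}.
#' @return A validated \linkS4class{DigestionParams}.
#' @examples
#' digestionParams("trypsin", maxMissedCleavages = 2)
#' @rdname DigestionParams-class
#' @export
digestionParams <- function(enzyme = "trypsin",
                            maxMissedCleavages = 2L,
                            minPeptideLength = 6L,
                            maxPeptideLength = 50L,
                            prolineRule = FALSE,
                            glucEOnly = FALSE) {
    .checkEnzyme(enzyme)
    p <- new("DigestionParams",
        enzyme = enzyme,
        maxMissedCleavages = .assertCount(maxMissedCleavages,
                                          "maxMissedCleavages"),
        minPeptideLength = .assertCount(minPeptideLength, "minPeptideLength",
                                        positive = TRUE),
        maxPeptideLength = .assertCount(maxPeptideLength, "maxPeptideLength",
                                        positive = TRUE),
        prolineRule = isTRUE(prolineRule),
        glucEOnly = isTRUE(glucEOnly)
    )
    validObject(p)
    p
}

## ---------------------------------------------------------------------------
## BootstrapConfig / ThresholdResult
## ---------------------------------------------------------------------------

#' Bootstrap settings for the contaminant abundance threshold
#'
#' @slot confidence two-sided confidence level of the percentile interval
#'   (default 0.999).
#' @slot nBoot number of bootstrap resamples.
#' @slot statistic resampled statistic, \code{"mean"} or \code{"median"}.
#' @slot seed RNG seed for the resampling.
#' @name BootstrapConfig-class
#' @rdname BootstrapConfig-class
#' @exportClass BootstrapConfig
setClass("BootstrapConfig",
    representation(
        confidence = "numeric",
        nBoot = "integer",
        statistic = "character",
        seed = "integer"
    )
)

setValidity("BootstrapConfig", function(object) {
    msg <- character()
    if (object@confidence <= 0 || object@confidence >= 1)
        msg <- c(msg, "'confidence' must lie in (0, 1)")
    if (object@nBoot < 1L)
        msg <- c(msg, "'nBoot' must be >= 1")
    if (!(object@statistic %in% c("mean", "median")))
        msg <- c(msg, "'statistic' must be 'mean' or 'median'")
    if (length(msg)) msg else TRUE
})

#' @param confidence,nBoot,statistic,seed see
#'   \linkS4class{BootstrapConfig}.
#' @return A validated \linkS4class{BootstrapConfig}.
#' @examples
#' bootstrapConfig(confidence = 0.999, seed = 17)
#' @rdname BootstrapConfig-class
#' @export
bootstrapConfig <- function(confidence = 0.999, nBoot = 10000L,
                            statistic = c("mean", "median"), seed = 1L) {
    statistic <- match.arg(statistic)
    cfg <- new("BootstrapConfig",
        confidence = .assertFraction(confidence, "confidence"),
        nBoot = .assertCount(nBoot, "nBoot", positive = TRUE),
        statistic = statistic,
        seed = as.integer(seed)
    )
    validObject(cfg)
    cfg
}

#' Contaminant-derived abundance threshold
#'
#' Result of \code{\link{bootstrapThreshold}}: the percentile bootstrap
#' confidence interval of the chosen statistic of the contaminant abundance
#' scores, with the upper bound used as the filtering threshold.
#'
#' @slot threshold the abundance cutoff (= \code{ciUpper}).
#' @slot ciLower,ciUpper percentile interval bounds.
#' @slot nContaminants number of contaminant scores used.
#' @slot config the \linkS4class{BootstrapConfig} used.
#' @name ThresholdResult-class
#' @rdname ThresholdResult-class
#' @exportClass ThresholdResult
setClass("ThresholdResult",
    representation(
        threshold = "numeric",
        ciLower = "numeric",
        ciUpper = "numeric",
        nContaminants = "integer",
        config = "BootstrapConfig"
    )
)

setValidity("ThresholdResult", function(object) {
    if (object@ciLower > object@ciUpper)
        return("'ciLower' must not exceed 'ciUpper'")
    if (!isTRUE(all.equal(object@threshold, object@ciUpper)))
        return("'threshold' must equal 'ciUpper'")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("threshold", "ThresholdResult", function(x, ...) x@threshold)

#' Confidence interval of a threshold result
#' @param x a \linkS4class{ThresholdResult}.
#' @return numeric of length 2 (lower, upper).
#' @export
thresholdCI <- function(x) {
    stopifnot(is(x, "ThresholdResult"))
    c(lower = x@ciLower, upper = x@ciUpper)
}

setMethod("show", "ThresholdResult", function(object) {
    cat("ThresholdResult\n")
    cat(sprintf("  threshold: %g (upper bound of %g%% percentile CI of the %s)\n",
                object@threshold, 100 * object@config@confidence,
                object@config@statistic))
    cat(sprintf("  CI: [%g, %g] from %d contaminants, %d resamples\n",
                object@ciLower, object@ciUpper, object@nContaminants,
                object@config@nBoot))
})

## ---------------------------------------------------------------------------
## CorrelationResult
## ---------------------------------------------------------------------------

#' Transcript-protein abundance correlation
#'
#' Pearson product-moment correlation between transformed transcript (FPKM)
#' and protein (peptides per residue) abundances, with a two-sided p-value
#' from the t distribution on \code{nPairs - 2} degrees of freedom.
#'
#' @slot r correlation coefficient in [-1, 1].
#' @slot pValue two-sided p-value.
#' @slot nPairs number of (FPKM, score) pairs used.
#' @slot transform \code{"log10"}, \code{"identity"} or \code{"rank"}.
#' @slot excludedZeroFpkm,excludedZeroScore pairs dropped because a zero
#'   cannot be log-transformed.
#' @name CorrelationResult-class
#' @rdname CorrelationResult-class
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    representation(
        r = "numeric",
        pValue = "numeric",
        nPairs = "integer",
        transform = "character",
        excludedZeroFpkm = "integer",
        excludedZeroScore = "integer"
    )
)

setValidity("CorrelationResult", function(object) {
    if (abs(object@r) > 1 + 1e-12)
        return("|r| must not exceed 1")
    if (object@pValue <= 0 || object@pValue > 1)
        return("'pValue' must lie in (0, 1]")
    TRUE
})

#' @rdname accessors
#' @export
setMethod("corCoef", "CorrelationResult", function(x, ...) x@r)

#' @rdname accessors
#' @export
setMethod("pValue", "CorrelationResult", function(x, ...) x@pValue)

#' @rdname accessors
#' @export
setMethod("nPairs", "CorrelationResult", function(x, ...) x@nPairs)

setMethod("show", "CorrelationResult", function(object) {
    cat("CorrelationResult\n")
    cat(sprintf("  r = %.4f, p = %.3g, n = %d (%s scale)\n",
                object@r, object@pValue, object@nPairs, object@transform))
    if (object@excludedZeroFpkm > 0 || object@excludedZeroScore > 0)
        cat(sprintf("  excluded: %d zero-FPKM, %d zero-score pairs\n",
                    object@excludedZeroFpkm, object@excludedZeroScore))
})

## ---------------------------------------------------------------------------
## AlignmentParams
## ---------------------------------------------------------------------------

#' Local alignment parameters for reciprocal-best-hit homology
#'
#' Smith-Waterman scoring used by \code{\link{localAlign}} and
#' \code{\link{reciprocalBestHits}}. A gap of length L costs
#' \code{gapOpen + L * gapExtend}. \code{minScore} is a raw-score acceptance
#' floor below which no best-hit pair is emitted; it plays the role an
#' E-value cutoff would play in a database search, without the
#' database-size-dependent statistics.
#'
#' @slot substitutionMatrix a symmetric scoring matrix with amino-acid
#'   dimnames (default BLOSUM62 as shipped with Biostrings).
#' @slot gapOpen,gapExtend affine gap penalties (positive costs).
#' @slot minScore minimum alignment score for a reported pair.
#' @name AlignmentParams-class
#' @rdname AlignmentParams-class
#' @exportClass AlignmentParams
setClass("AlignmentParams",
    representation(
        substitutionMatrix = "matrix",
        gapOpen = "numeric",
        gapExtend = "numeric",
        minScore = "numeric"
    )
)

setValidity("AlignmentParams", function(object) {
    m <- object@substitutionMatrix
    msg <- character()
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
        msg <- c(msg, "substitution matrix must have matching dimnames")
    else if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (object@gapOpen <= 0 || object@gapExtend <= 0)
        msg <- c(msg, "gap penalties must be positive")
    if (object@gapExtend > object@gapOpen)
        msg <- c(msg, "'gapExtend' must not exceed 'gapOpen'")
    if (length(msg)) msg else TRUE
})

#' @param substitutionMatrix matrix or the name of a matrix shipped with
#'   Biostrings (e.g. \code{"BLOSUM62"}).
#' @param gapOpen,gapExtend,minScore see \linkS4class{AlignmentParams}.
#' @return A validated \linkS4class{AlignmentParams}.
#' @examples
#' alignmentParams()                     # BLOSUM62, 11/1, floor 50
#' @rdname AlignmentParams-class
#' @export
alignmentParams <- function(substitutionMatrix = "BLOSUM62",
                            gapOpen = 11, gapExtend = 1, minScore = 50) {
    if (is.character(substitutionMatrix)) {
        name <- substitutionMatrix
        e <- new.env()
        utils::data(list = name, package = "Biostrings", envir = e)
        substitutionMatrix <- get(name, envir = e)
    }
    p <- new("AlignmentParams",
        substitutionMatrix = substitutionMatrix,
        gapOpen = as.numeric(gapOpen),
        gapExtend = as.numeric(gapExtend),
        minScore = as.numeric(minScore)
    )
    validObject(p)
    p
}
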