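#' @include AllClasses.R
NULL

## Sense codons of the standard genetic code, and codons per amino acid,
## computed once at load time from Biostrings::GENETIC_CODE.
.codonTables <- local({
    gc <- NULL
    function() {
        if (is.null(gc)) {
            code <- Biostrings::GENETIC_CODE
            sense <- code[code != "*"]
            gc <<- list(
                sense = names(sense),
                stop = names(code)[code == "*"],
                byAA = split(names(code), code),
                ## amino-acid frequencies of random coding sequence
                ## (codon-count weights of the standard code)
                aaFreq = table(sense) / length(sense)
            )
        }
        gc
    }
})

.randomOrf <- function(lengthNt) {
    ct <- .codonTables()
    nCodons <- lengthNt %/% 3L
    internal <- if (nCodons > 2L)
        sample(ct$sense, nCodons - 2L, replace = TRUE) else character()
    paste0("ATG", paste(internal, collapse = ""),
           sample(ct$stop, 1L))
}

.backTranslate <- function(aa) {
    ct <- .codonTables()
    chars <- strsplit(aa, "")[[1]]
    codons <- vapply(chars, function(a) {
        opts <- ct$byAA[[a]]
        if (is.null(opts))
            stop(sprintf("cannot back-translate residue '%s'", a),
                 call. = FALSE)
        opts[sample.int(length(opts), 1L)]
    }, character(1))
    paste0(paste(codons, collapse = ""), sample(ct$stop, 1L))
}

.mutateProtein <- function(aa, identity) {
    chars <- strsplit(aa, "")[[1]]
    n <- length(chars)
    nMut <- round((1 - identity) * n)
    if (nMut > 0) {
        ## never mutate the initiator methionine
        pos <- sample(seq(2L, n), min(nMut, n - 1L))
        alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
        for (p in pos)
            chars[p] <- sample(setdiff(alphabet, chars[p]), 1L)
    }
    paste(chars, collapse = "")
}

#' Generate a synthetic venome with known ground truth
#'
#' Draws a venom-gland "study" from the generative model described in the
#' package vignette: transcript relative abundances log-uniform over the
#' configured decade span (six decades by default, the span venom-gland
#' transcriptomes exhibit), each transcript a random open reading frame
#' (start codon, stop-free body, stop codon), one protein per transcript by
#' frame +1 translation, plus a configurable number of contaminant proteins
#' (random amino-acid sequences) placed at a low quantile of the biological
#' abundance distribution. Optional paralog pairs duplicate existing proteins
#' at a configurable residue identity to induce shared-peptide ambiguity.
#'
#' Output is fully determined by \code{config@seed}.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return A \linkS4class{VenomeTruth}.
#' @examples
#' truth <- sampleVenome(generatorConfig(nTranscripts = 20, seed = 42))
#' truth
#' @seealso \code{\link{simulateFragmentCounts}},
#'   \code{\link{simulatePeptideObservations}}, \code{\link{writeVenomeFiles}}
#' @export
sampleVenome <- function(config) {
    stopifnot(is(config, "GeneratorConfig"))
    validObject(config)
    withSeed(config@seed, {
        n <- config@nTranscripts
        lo <- config@abundanceLog10Range[1]
        hi <- config@abundanceLog10Range[2]

        txSeq <- character(n)
        protSeq <- character(n)
        ab <- if (n > 0) 10^stats::runif(n, lo, hi) else numeric()
        if (n > 0) {
            lens <- 3L * sample(seq(config@lengthRangeNt[1] %/% 3L,
                                    config@lengthRangeNt[2] %/% 3L),
                                n, replace = TRUE)
            for (i in seq_len(n))
                txSeq[i] <- .randomOrf(lens[i])
        }

        ## paralog copies: duplicated proteins at reduced identity, each with
        ## its own back-translated transcript and freshly drawn abundance
        if (config@paralogPairs > 0L && n > 0L) {
            src <- sample(seq_len(n), config@paralogPairs, replace = TRUE)
            for (k in seq_len(config@paralogPairs)) {
                base <- Biostrings::DNAString(txSeq[src[k]])
                aa <- as.character(Biostrings::translate(base))
                aa <- sub("\\*$", "", aa)
                mut <- .mutateProtein(aa, config@paralogIdentity)
                txSeq <- c(txSeq, .backTranslate(mut))
                ab <- c(ab, 10^stats::runif(1, lo, hi))
            }
            n <- length(txSeq)
        }

        txIds <- sprintf("TX%04d", seq_len(n))
        if (n > 0) ab <- ab / sum(ab)
        names(ab) <- txIds

        transcripts <- Biostrings::DNAStringSet(txSeq)
        names(transcripts) <- txIds
        protSeq <- if (n > 0) {
            aa <- as.character(Biostrings::translate(transcripts))
            sub("\\*$", "", aa)
        } else character()

        ## contaminants: random amino-acid sequences at a fixed low quantile
        ## of the biological abundance distribution
        nc <- config@nContaminants
        contSeq <- character(nc)
        if (nc > 0) {
            ## contaminants are ordinary proteins (keratins etc.), so their
            ## residue composition matches coding sequence, not a uniform
            ## draw over the 20 letters -- digestion behaves comparably
            aaFreq <- .codonTables()$aaFreq
            aaLens <- sample(seq(config@lengthRangeNt[1] %/% 3L - 1L,
                                 config@lengthRangeNt[2] %/% 3L - 1L),
                             nc, replace = TRUE)
            for (i in seq_len(nc))
                contSeq[i] <- paste(sample(names(aaFreq), aaLens[i],
                                           replace = TRUE, prob = aaFreq),
                                    collapse = "")
        }
        contIds <- if (nc > 0) sprintf("CONT%03d", seq_len(nc)) else character()
        contAb <- if (nc > 0 && n > 0)
            rep(unname(stats::quantile(ab, config@contaminantAbundanceQuantile)),
                nc)
        else rep(0, nc)

        protIds <- c(txIds, contIds)
        proteins <- Biostrings::AAStringSet(c(protSeq, contSeq))
        names(proteins) <- protIds
        protAb <- c(unname(ab), contAb)
        names(protAb) <- protIds

        meta <- data.frame(
            id = protIds,
            source_transcript = c(txIds, rep(NA_character_, nc)),
            frame = c(rep(1L, n), rep(NA_integer_, nc)),
            is_contaminant = c(rep(FALSE, n), rep(TRUE, nc)),
            signal_peptide_length = rep(0L, n + nc),
            effective_length = nchar(c(protSeq, contSeq)),
            stringsAsFactors = FALSE
        )

        new("VenomeTruth",
            transcripts = transcripts,
            txAbundance = ab,
            proteins = proteins,
            proteinAbundance = protAb,
            proteinMeta = meta,
            config = config)
    })
}

#' Simulate sequenced fragment counts
#'
#' Distributes the configured total fragment count over transcripts with a
#' single multinomial draw whose category probabilities are proportional to
#' (true abundance x transcript length) -- longer transcripts yield more
#' fragments at equal molar abundance, the sampling property FPKM corrects
#' for. Counts always sum exactly to \code{totalFragments}.
#'
#' @param truth a \linkS4class{VenomeTruth} with at least one transcript.
#' @return data.frame with columns \code{transcript_id}, \code{fragments}.
#' @examples
#' truth <- sampleVenome(generatorConfig(nTranscripts = 10, seed = 3))
#' counts <- simulateFragmentCounts(truth)
#' sum(counts$fragments)     # == totalFragments
#' @export
simulateFragmentCounts <- function(truth) {
    stopifnot(is(truth, "VenomeTruth"))
    if (length(truth@transcripts) < 1L)
        stop("'truth' must contain at least one transcript", call. = FALSE)
    prob <- truth@txAbundance * Biostrings::width(truth@transcripts)
    counts <- withSeed(deriveSeed(truth@config@seed, 1L),
        stats::rmultinom(1L, truth@config@totalFragments, prob))
    data.frame(transcript_id = names(truth@txAbundance),
               fragments = as.integer(counts[, 1L]),
               stringsAsFactors = FALSE)
}

#' Simulate identified-peptide observations
#'
#' Emulates LC/MS peptide identification over the synthetic proteins. For
#' each protein and each enabled protease, candidate peptides are enumerated
#' by \code{\link{digestProtein}} (undigested samples contribute the intact
#' sequence under enzyme \code{"none"}). Each candidate's expected
#' observation count is
#' \deqn{\kappa \, a^{\gamma} \, e^{N(0,\sigma)}}
#' with \eqn{a} the true protein abundance, and the realized count is drawn
#' Poisson from that expectation; zero-count candidates are omitted. More
#' abundant proteins are therefore more likely to be detected, with
#' multiplicative noise -- the two qualitative properties of spectral
#' counting this generator reproduces.
#'
#' Counts of identical (peptide, enzyme) candidates arising from different
#' proteins are summed, as a search engine reports peptide-level events
#' without knowing the source protein.
#'
#' @param truth a \linkS4class{VenomeTruth}.
#' @param enzymes proteases to digest with; defaults to the generator
#'   config's enzyme set, and must be a subset of it.
#' @param minPeptideLength,maxPeptideLength candidate peptide length bounds.
#' @param kappa detection rate constant; defaults to
#'   \code{config@detectionKappa}.
#' @param sampleName label written to the \code{sample} column.
#' @return data.frame with columns \code{peptide}, \code{count},
#'   \code{enzyme}, \code{sample}.
#' @examples
#' truth <- sampleVenome(generatorConfig(nTranscripts = 5, seed = 9))
#' obs <- simulatePeptideObservations(truth)
#' head(obs)
#' @export
simulatePeptideObservations <- function(truth, enzymes = NULL,
                                        minPeptideLength = 6L,
                                        maxPeptideLength = 50L,
                                        kappa = NULL,
                                        sampleName = "S1") {
    stopifnot(is(truth, "VenomeTruth"))
    config <- truth@config
    if (is.null(enzymes)) enzymes <- config@enzymes
    for (e in enzymes) .checkEnzyme(e)
    extra <- setdiff(enzymes, config@enzymes)
    if (length(extra))
        stop(sprintf("enzyme(s) %s not enabled in the generator config",
                     paste(sQuote(extra), collapse = ", ")), call. = FALSE)
    if (is.null(kappa)) kappa <- config@detectionKappa

    empty <- data.frame(peptide = character(), count = integer(),
                        enzyme = character(), sample = character(),
                        stringsAsFactors = FALSE)
    if (length(truth@proteins) == 0L || kappa == 0)
        return(empty)

    seqs <- as.character(truth@proteins)
    ab <- truth@proteinAbundance
    gamma <- config@detectionExponent
    sigma <- config@detectionNoiseSigma

    withSeed(deriveSeed(config@seed, 2L), {
        pepL <- list()
        cntL <- list()
        enzL <- list()
        k <- 0L
        for (enz in enzymes) {
            params <- digestionParams(enzyme = enz,
                maxMissedCleavages = config@maxMissedCleavages,
                minPeptideLength = minPeptideLength,
                maxPeptideLength = maxPeptideLength)
            for (i in seq_along(seqs)) {
                if (ab[i] <= 0) next
                peps <- unique(digestProtein(seqs[i], params)$peptide)
                if (!length(peps)) next
                rate <- kappa * ab[i]^gamma *
                    exp(stats::rnorm(length(peps), 0, sigma))
                cnt <- stats::rpois(length(peps), rate)
                keep <- cnt > 0L
                if (!any(keep)) next
                k <- k + 1L
                pepL[[k]] <- peps[keep]
                cntL[[k]] <- cnt[keep]
                enzL[[k]] <- rep(enz, sum(keep))
            }
        }
        if (k == 0L) return(empty)   # unwinds through withSeed, seed restored
        pep <- unlist(pepL, use.names = FALSE)
        cnt <- unlist(cntL, use.names = FALSE)
        enz <- unlist(enzL, use.names = FALSE)
        ## same peptide species generated from several proteins: one pooled
        ## observation per (peptide, enzyme)
        key <- paste(enz, pep, sep = "\r")
        tot <- rowsum(cnt, key)
        parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
        out <- data.frame(
            peptide = vapply(parts, `[`, character(1), 2L),
            count = as.integer(tot[, 1L]),
            enzyme = vapply(parts, `[`, character(1), 1L),
            sample = sampleName,
            stringsAsFactors = FALSE)
        out <- out[order(out$enzyme, out$peptide), , drop = FALSE]
        rownames(out) <- NULL
        out
    })
}

#' Write a synthetic venome to disk
#'
#' Emits the plain-text file bundle the pipeline stages consume: transcript
#' FASTA, biological protein FASTA, contaminant FASTA, fragment-count TSV,
#' peptide-observation TSV, and a ground-truth TSV. Biological proteins share
#' their source transcript's identifier, which is how the pipeline links the
#' two levels.
#'
#' @param truth a \linkS4class{VenomeTruth}.
#' @param counts fragment-count data.frame from
#'   \code{\link{simulateFragmentCounts}}.
#' @param observations peptide data.frame from
#'   \code{\link{simulatePeptideObservations}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, a named character vector of the paths written.
#' @export
writeVenomeFiles <- function(truth, counts, observations, dir) {
    stopifnot(is(truth, "VenomeTruth"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    meta <- truth@proteinMeta
    bio <- !meta$is_contaminant
    seed <- truth@config@seed
    paths <- c(
        transcripts = file.path(dir, "transcripts.fasta"),
        proteins = file.path(dir, "proteins.fasta"),
        contaminants = file.path(dir, "contaminants.fasta"),
        counts = file.path(dir, "counts.tsv"),
        peptides = file.path(dir, "peptides.tsv"),
        truth = file.path(dir, "truth.tsv")
    )
    writeFasta(truth@transcripts, paths[["transcripts"]])
    writeFasta(truth@proteins[bio], paths[["proteins"]])
    writeFasta(truth@proteins[!bio], paths[["contaminants"]])
    writeTsvTable(counts, paths[["counts"]], seed = seed)
    writeTsvTable(observations, paths[["peptides"]], seed = seed)
    truthTab <- data.frame(
        id = meta$id,
        type = ifelse(meta$is_contaminant, "contaminant", "biological"),
        true_abundance = unname(truth@proteinAbundance[meta$id]),
        effective_length = meta$effective_length,
        stringsAsFactors = FALSE)
    writeTsvTable(truthTab, paths[["truth"]], seed = seed)
    invisible(paths)
}
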