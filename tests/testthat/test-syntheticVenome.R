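test_that("empty configuration yields an empty venome", {
    cfg <- generatorConfig(nTranscripts = 0, nContaminants = 0, seed = 1)
    truth <- sampleVenome(cfg)
    expect_length(transcripts(truth), 0)
    expect_length(proteins(truth), 0)
    expect_equal(nrow(proteinMeta(truth)), 0)
})

test_that("the generator is fully determined by its seed", {
    cfg <- generatorConfig(nTranscripts = 15, nContaminants = 3, seed = 77)
    t1 <- sampleVenome(cfg)
    t2 <- sampleVenome(cfg)
    expect_identical(as.character(transcripts(t1)),
                     as.character(transcripts(t2)))
    expect_identical(as.character(proteins(t1)), as.character(proteins(t2)))
    expect_identical(trueAbundance(t1), trueAbundance(t2))
    expect_identical(simulateFragmentCounts(t1), simulateFragmentCounts(t2))
    expect_identical(simulatePeptideObservations(t1),
                     simulatePeptideObservations(t2))
    t3 <- sampleVenome(generatorConfig(nTranscripts = 15, nContaminants = 3,
                                       seed = 78))
    expect_false(identical(as.character(transcripts(t1)),
                           as.character(transcripts(t3))))
})

test_that("generated transcripts are well-formed ORFs and proteins match", {
    truth <- sampleVenome(generatorConfig(nTranscripts = 25, seed = 4))
    for (s in as.character(transcripts(truth))) {
        expect_identical(substr(s, 1, 3), "ATG")
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
        expect_match(aa, "^[^*]+\\*$")   # single terminal stop
    }
    expect_true(abs(sum(trueAbundance(truth)) - 1) < 1e-9)
    meta <- proteinMeta(truth)
    bio <- !meta$is_contaminant
    expect_true(all(!is.na(meta$source_transcript[bio])))
    expect_identical(meta$effective_length,
                     unname(nchar(as.character(proteins(truth)))))
})

test_that("abundance span matches the log-uniform order-statistics oracle", {
    ## Monte-Carlo oracle: P(max/min of 1000 log-uniform draws over 6
    ## decades lies in [1e5, 1e6]) -- ratio of extremes is unaffected by
    ## normalization.
    set.seed(202)
    inRange <- replicate(10000, {
        d <- runif(1000, 0, 6)
        r <- 10^(max(d) - min(d))
        r >= 1e5 && r <= 1e6
    })
    expect_gt(mean(inRange), 0.99)
    ## the generator's own draws behave the same way
    for (seed in 1:5) {
        ab <- trueAbundance(sampleVenome(
            generatorConfig(nTranscripts = 1000, nContaminants = 0,
                            seed = seed)))
        ratio <- max(ab) / min(ab)
        expect_gte(ratio, 1e5)
        expect_lte(ratio, 1e6)
    }
})

test_that("fragment counts are a single conserved multinomial draw", {
    cfg <- generatorConfig(nTranscripts = 1, totalFragments = 100, seed = 2)
    one <- makeTruth(1, 300, cfg)
    expect_equal(simulateFragmentCounts(one)$fragments, 100L)

    ## equal abundance, equal length: binomial symmetry
    cfg2 <- generatorConfig(nTranscripts = 2, totalFragments = 1e6, seed = 3)
    two <- makeTruth(c(1, 1), c(300, 300), cfg2)
    cts <- simulateFragmentCounts(two)$fragments
    expect_equal(sum(cts), 1e6)
    sdev <- sqrt(1e6 * 0.5 * 0.5)
    expect_true(all(abs(cts - 5e5) < 5 * sdev))

    ## 4:1 abundance at equal length: multinomial expectation oracle
    tot <- c(0, 0)
    for (seed in 1:100) {
        cfg3 <- generatorConfig(nTranscripts = 2, totalFragments = 1e6,
                                seed = seed)
        tr <- makeTruth(c(4, 1), c(300, 300), cfg3)
        tot <- tot + simulateFragmentCounts(tr)$fragments
    }
    expect_lt(abs(tot[1] / tot[2] - 4) / 4, 0.01)
})

test_that("fragment counts always sum exactly to the configured total", {
    for (seed in 1:10) {
        cfg <- generatorConfig(nTranscripts = 30, totalFragments = 12345,
                               seed = seed)
        truth <- sampleVenome(cfg)
        expect_identical(sum(simulateFragmentCounts(truth)$fragments), 12345L)
    }
})

test_that("peptide detection follows the Poisson rate model", {
    ## zero rate constant: no observations
    cfg0 <- generatorConfig(nTranscripts = 3, detectionKappa = 0, seed = 5)
    expect_equal(nrow(simulatePeptideObservations(sampleVenome(cfg0))), 0)

    ## single protein, exponent 0, noise 0, kappa 3: every candidate has
    ## expected count 3 (Poisson mean oracle over seeded replicates)
    counts <- numeric()
    nPep <- NULL
    for (seed in 1:200) {
        cfg <- generatorConfig(nTranscripts = 1, detectionKappa = 3,
                               detectionExponent = 0,
                               detectionNoiseSigma = 0, enzymes = "trypsin",
                               seed = seed)
        truth <- makeTruth(1, 600, cfg)
        if (is.null(nPep)) {
            prot <- as.character(proteins(truth))[[1]]
            nPep <- length(unique(digestProtein(prot,
                digestionParams("trypsin", maxMissedCleavages = 2))$peptide))
        }
        obs <- simulatePeptideObservations(truth)
        counts <- c(counts, sum(obs$count))
    }
    mu <- mean(counts) / nPep
    se <- sd(counts / nPep) / sqrt(length(counts))
    expect_lt(abs(mu - 3), 3 * se + 1e-12)

    ## abundance ratio 100, exponent 1, noise 0: Poisson superposition.
    ## Expected total count per protein is kappa * abundance * nCandidates,
    ## so totals are normalized per candidate peptide before comparing.
    tot <- c(0, 0)
    nCand <- NULL
    for (seed in 1:100) {
        cfg <- generatorConfig(nTranscripts = 2, detectionKappa = 2000,
                               detectionExponent = 1,
                               detectionNoiseSigma = 0, seed = seed)
        truth <- makeTruth(c(100, 1), c(300, 300), cfg)
        if (is.null(nCand)) {
            nCand <- vapply(as.character(proteins(truth)), function(s)
                sum(vapply(cfg@enzymes, function(e)
                    length(unique(digestProtein(s,
                        digestionParams(e, maxMissedCleavages = 2))$peptide)),
                    numeric(1))), numeric(1))
        }
        obs <- simulatePeptideObservations(truth)
        m <- matchPeptides(obs, truth)
        adj <- adjustedCounts(m[m$matched, ], proteins = proteinMeta(truth)$id)
        tot <- tot + adj$adjusted_count[match(c("TX0001", "TX0002"),
                                              adj$protein_id)]
    }
    perCand <- tot / nCand
    expect_lt(abs(perCand[1] / perCand[2] - 100) / 100, 0.10)
})

test_that("expected peptide yield is monotone in abundance without noise", {
    cfg <- generatorConfig(nTranscripts = 6, detectionKappa = 800,
                           detectionExponent = 1, detectionNoiseSigma = 0,
                           seed = 10)
    ## identical sequences, geometric abundances: only abundance varies
    truth <- makeTruth(10^(0:5), rep(600, 6), cfg)
    tot <- numeric(6)
    for (seed in 1:30) {
        truth@config@seed <- seed
        obs <- simulatePeptideObservations(truth)
        m <- matchPeptides(obs, truth)
        adj <- adjustedCounts(m[m$matched, ], proteins = proteinMeta(truth)$id)
        tot <- tot + adj$adjusted_count[match(proteinMeta(truth)$id,
                                              adj$protein_id)]
    }
    expect_true(all(diff(tot) > 0))
})

test_that("requesting an enzyme outside the config is rejected", {
    cfg <- generatorConfig(nTranscripts = 2, enzymes = "trypsin", seed = 1)
    truth <- sampleVenome(cfg)
    expect_error(simulatePeptideObservations(truth, enzymes = "glu-c"),
                 "not enabled")
    expect_error(simulatePeptideObservations(truth, enzymes = "pepsin"),
                 "unknown enzyme")
})

test_that("paralog pairs create shared peptides", {
    cfg <- generatorConfig(nTranscripts = 10, paralogPairs = 3,
                           paralogIdentity = 0.95, nContaminants = 0,
                           seed = 21)
    truth <- sampleVenome(cfg)
    expect_length(transcripts(truth), 13)
    obs <- simulatePeptideObservations(truth)
    m <- matchPeptides(obs, truth)
    expect_gt(sum(m$multiplicity > 1), 0)
})

test_that("invalid configurations fail naming the field", {
    expect_error(generatorConfig(lengthRangeNt = c(301, 600)), "multiples of 3")
    expect_error(generatorConfig(abundanceLog10Range = c(6, 0)),
                 "abundanceLog10Range")
    expect_error(generatorConfig(totalFragments = 0), "totalFragments")
    expect_error(generatorConfig(contaminantAbundanceQuantile = 1),
                 "contaminantAbundanceQuantile")
    expect_error(generatorConfig(enzymes = c("trypsin", "papain")), "enzymes")
})
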