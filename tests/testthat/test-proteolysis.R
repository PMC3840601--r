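test_that("six-frame translation follows the standard code", {
    expect_identical(sixFrameTranslate("ATGAAA")[["+1"]], "MK")
    expect_identical(sixFrameTranslate("ATGAAATAA")[["+1"]], "MK*")
    ## N-containing codons become X; partial codons are dropped
    fr <- sixFrameTranslate("ATGANAAAAG")
    expect_identical(fr[["+1"]], "MXK")
    expect_identical(nchar(fr[["+2"]]), 3L)
    expect_error(sixFrameTranslate("ATGU"), "position 4")
    expect_error(sixFrameTranslate("AT"), "codon")
})

test_that("reverse frames equal forward frames of the reverse complement", {
    set.seed(14)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C", "G", "T", "N"), sample(3:60, 1),
                          replace = TRUE, prob = c(1, 1, 1, 1, 0.1)),
                   collapse = "")
        fr <- sixFrameTranslate(s)
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        frc <- sixFrameTranslate(rc)
        expect_identical(fr[["-1"]], frc[["+1"]])
        expect_identical(fr[["-2"]], frc[["+2"]])
        expect_identical(fr[["-3"]], frc[["+3"]])
    }
})

test_that("splitOrfs extracts maximal stop-free segments", {
    expect_identical(splitOrfs("MK*AR", 2), c("MK", "AR"))
    expect_identical(splitOrfs("***"), character(0))
    expect_identical(splitOrfs("MKR"), "MKR")
    ## reconstruction: segments at minLength 1 plus the stops recover the
    ## residue content and order
    set.seed(6)
    for (i in 1:20) {
        s <- paste(sample(c(AA20, "*"), sample(1:40, 1), replace = TRUE),
                   collapse = "")
        segs <- splitOrfs(s, 1)
        expect_identical(paste(segs, collapse = ""), gsub("*", "", s,
                                                          fixed = TRUE))
    }
})

test_that("digestion reproduces the worked examples", {
    p1 <- digestionParams("trypsin", maxMissedCleavages = 0,
                          minPeptideLength = 1, maxPeptideLength = 50)
    expect_identical(digestProtein("MKAR", p1)$peptide, c("MK", "AR"))
    p2 <- digestionParams("trypsin", maxMissedCleavages = 1,
                          minPeptideLength = 1, maxPeptideLength = 50)
    expect_setequal(digestProtein("MKAR", p2)$peptide, c("MK", "MKAR", "AR"))
    p3 <- digestionParams("chymotrypsin", maxMissedCleavages = 0,
                          minPeptideLength = 1, maxPeptideLength = 50)
    expect_identical(digestProtein("GFLWA", p3)$peptide,
                     c("GF", "L", "W", "A"))
    p4 <- digestionParams("glu-c", maxMissedCleavages = 0,
                          minPeptideLength = 1, maxPeptideLength = 50)
    expect_identical(digestProtein("MDAE", p4)$peptide, c("MD", "AE"))
    pn <- digestionParams("none", minPeptideLength = 1)
    expect_identical(digestProtein("MKAR", pn)$peptide, "MKAR")
    expect_error(digestionParams("pepsin"), "unknown enzyme")
    expect_error(digestProtein("MK*AR", p1), "stop-free")
})

test_that("digestion equals the all-substrings oracle and is nested in k", {
    sites <- list(trypsin = c("R", "K"),
                  chymotrypsin = c("F", "L", "W", "Y"),
                  `glu-c` = c("D", "E"))
    set.seed(91)
    for (i in 1:40) {
        prot <- randomProtein(sample(5:60, 1))
        for (enz in names(sites)) {
            prev <- NULL
            for (k in 0:2) {
                par <- digestionParams(enz, maxMissedCleavages = k,
                                       minPeptideLength = 1,
                                       maxPeptideLength = 60)
                got <- digestProtein(prot, par)
                expect_identical(sort(got$peptide),
                                 oracleDigest(prot, sites[[enz]], k, 1, 60))
                ## missed-cleavage monotonicity
                if (!is.null(prev))
                    expect_true(all(prev %in% got$peptide))
                prev <- got$peptide
                ## zero-missed peptides partition the protein
                if (k == 0)
                    expect_identical(paste(got$peptide, collapse = ""), prot)
            }
        }
    }
})

test_that("the proline rule and Glu-C dialect are honored when enabled", {
    pr <- digestionParams("trypsin", maxMissedCleavages = 0,
                          minPeptideLength = 1, prolineRule = TRUE)
    expect_identical(digestProtein("MKPAR", pr)$peptide, "MKPAR")
    ge <- digestionParams("glu-c", maxMissedCleavages = 0,
                          minPeptideLength = 1, glucEOnly = TRUE)
    expect_identical(digestProtein("MDAE", ge)$peptide, "MDAE")
})

test_that("peptide matching equals the exhaustive substring oracle", {
    obs <- data.frame(peptide = c("MK", "ZZZ"), count = c(4L, 1L))
    m <- matchPeptides(obs, c(A = "MKAR", B = "GGMKG"))
    expect_identical(m$matches[[1]], c("A", "B"))
    expect_identical(m$multiplicity, c(2L, 0L))
    expect_identical(m$matched, c(TRUE, FALSE))

    set.seed(55)
    for (i in 1:30) {
        np <- sample(1:25, 1)
        ns <- sample(1:20, 1)
        prots <- setNames(vapply(seq_len(ns),
                                 function(j) randomProtein(sample(1:30, 1)),
                                 character(1)),
                          paste0("P", seq_len(ns)))
        peps <- unique(vapply(seq_len(np), function(j) {
            if (runif(1) < 0.5 && any(nchar(prots) >= 2)) {
                s <- sample(which(nchar(prots) >= 2), 1)
                a <- sample(nchar(prots[s]) - 1, 1)
                substring(prots[s], a, min(nchar(prots[s]), a + sample(1:6, 1)))
            } else randomProtein(sample(1:8, 1))
        }, character(1)))
        m <- matchPeptides(data.frame(peptide = peps, count = 1L), prots)
        oracle <- lapply(peps, function(p)
            names(prots)[grepl(p, prots, fixed = TRUE)])
        expect_identical(lapply(m$matches, as.character), oracle)
    }
})

test_that("I/L equivalence merges isobaric matches when requested", {
    prots <- c(A = "GGILK", B = "GGLLK")
    off <- matchPeptides(data.frame(peptide = "ILK", count = 1L), prots)
    expect_identical(off$matches[[1]], "A")
    on <- matchPeptides(data.frame(peptide = "ILK", count = 1L), prots,
                        ilEquivalent = TRUE)
    expect_identical(on$matches[[1]], c("A", "B"))
})
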