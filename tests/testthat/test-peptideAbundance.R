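test_that("fractional attribution reproduces the worked examples", {
    prots <- c(A = "QQMKQQ", B = "WWMKWWCCDD", C = "CCDDWW", D = "HHCCDD")
    obs <- data.frame(peptide = c("MK", "QQ"), count = c(4L, 2L))
    m <- matchPeptides(obs, prots)
    adj <- adjustedCounts(m)
    expect_equal(adj$adjusted_count[adj$protein_id == "A"], 4)  # 4/2 + 2
    expect_equal(adj$adjusted_count[adj$protein_id == "B"], 2)  # 4/2

    obs2 <- rbind(obs, data.frame(peptide = "CCDD", count = 1L))
    m2 <- matchPeptides(obs2, prots)
    adj2 <- adjustedCounts(m2)
    get <- function(p) adj2$adjusted_count[adj2$protein_id == p]
    expect_equal(get("B"), 2 + 1 / 3)
    expect_equal(get("C"), 1 / 3)
    expect_equal(get("D"), 1 / 3)
})

test_that("adjusted counts conserve the raw total exactly", {
    set.seed(72)
    for (i in 1:50) {
        fix <- randomMatchedObservations(sample(2:8, 1), sample(4:20, 1))
        adj <- adjustedCounts(fix$observations, proteins = fix$proteins)
        expect_equal(sum(adj$adjusted_count), sum(fix$observations$count),
                     tolerance = 1e-9)
    }
})

test_that("scoring divides by effective length and nothing else", {
    adj <- data.frame(protein_id = c("A", "B"), adjusted_count = c(5, 0))
    sc <- abundanceScores(adj, c(A = 100, B = 50))
    expect_equal(sc$score, c(0.05, 0))
    expect_error(abundanceScores(adj, c(A = 100)), "B")
    expect_error(abundanceScores(adj, c(A = 100, B = 0)), "B")

    ## degree-1 homogeneity: doubling every observation count doubles every
    ## score (fails under total-count normalization)
    set.seed(73)
    for (i in 1:20) {
        fix <- randomMatchedObservations()
        lens <- setNames(nchar(fix$proteins), names(fix$proteins))
        s1 <- abundanceScores(adjustedCounts(fix$observations,
                                             proteins = fix$proteins), lens)
        doubled <- fix$observations
        doubled$count <- doubled$count * 2L
        s2 <- abundanceScores(adjustedCounts(doubled,
                                             proteins = fix$proteins), lens)
        expect_equal(s2$score, 2 * s1$score, tolerance = 1e-12)
    }
})

test_that("duplicating a protein halves each copy's score", {
    prot <- c(A = "MMQQKKWWCCHH")
    obs <- matchPeptides(data.frame(peptide = c("QQKK", "WWCC"),
                                    count = c(6L, 2L)), prot)
    s1 <- abundanceScores(adjustedCounts(obs, prot),
                          setNames(nchar(prot), names(prot)))
    both <- c(A = "MMQQKKWWCCHH", A2 = "MMQQKKWWCCHH")
    obs2 <- matchPeptides(data.frame(peptide = c("QQKK", "WWCC"),
                                     count = c(6L, 2L)), both)
    s2 <- abundanceScores(adjustedCounts(obs2, both),
                          setNames(nchar(both), names(both)))
    expect_equal(s2$score[s2$protein_id == "A"],
                 s1$score[s1$protein_id == "A"] / 2)
})

test_that("distinct-species counting ignores the count column", {
    fix <- randomMatchedObservations()
    adjE <- adjustedCounts(fix$observations, fix$proteins)
    adjS <- adjustedCounts(fix$observations, fix$proteins,
                           countMode = "species")
    expect_equal(sum(adjS$adjusted_count), nrow(fix$observations),
                 tolerance = 1e-9)
    expect_equal(sum(adjE$adjusted_count), sum(fix$observations$count),
                 tolerance = 1e-9)
})

test_that("unmatched observations are rejected before scoring", {
    prots <- c(A = "MKAR")
    m <- matchPeptides(data.frame(peptide = c("MK", "ZZZ"),
                                  count = c(1L, 1L)), prots)
    expect_error(adjustedCounts(m), "unmatched")
    expect_error(adjustedCounts(data.frame(peptide = "MK", count = 1L)),
                 "matchPeptides")
})
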