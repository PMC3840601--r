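test_that("local alignment matches the published BLOSUM62 entries", {
    expect_equal(localAlign("WW", "WW"), 22)        # 2 x W:W = 11
    expect_equal(localAlign("W", "W"), 11)
    ## symmetry
    set.seed(81)
    for (i in 1:10) {
        a <- randomProtein(sample(2:15, 1))
        b <- randomProtein(sample(2:15, 1))
        expect_equal(localAlign(a, b), localAlign(b, a))
    }
    expect_error(localAlign("MKB2", "MK"), "position")
})

test_that("local alignment equals the independent Gotoh oracle", {
    par <- alignmentParams()
    mat <- par@substitutionMatrix
    set.seed(82)
    for (i in 1:40) {
        a <- randomProtein(sample(1:12, 1))
        b <- randomProtein(sample(1:12, 1))
        expect_equal(localAlign(a, b, par),
                     oracleLocalAlign(a, b, mat, par@gapOpen, par@gapExtend),
                     info = paste(a, b))
    }
})

test_that("the Gotoh oracle itself agrees with exhaustive enumeration", {
    par <- alignmentParams()
    mat <- par@substitutionMatrix
    set.seed(83)
    for (i in 1:8) {
        a <- randomProtein(sample(1:3, 1))
        b <- randomProtein(sample(1:3, 1))
        expect_equal(oracleLocalAlign(a, b, mat, par@gapOpen, par@gapExtend),
                     oracleEnumAlign(a, b, mat, par@gapOpen, par@gapExtend),
                     info = paste(a, b))
    }
})

test_that("identical sets are their own reciprocal best hits", {
    set.seed(84)
    s <- c(X = randomProtein(15), Y = randomProtein(15))
    pairs <- reciprocalBestHits(s, s, alignmentParams(minScore = 10))
    expect_setequal(pairs$id_a, c("X", "Y"))
    expect_identical(pairs$id_a, pairs$id_b)
})

test_that("tied best hits are excluded, not broken arbitrarily", {
    set.seed(85)
    a <- c(q = randomProtein(12))
    dup <- randomProtein(12)
    b <- c(r1 = dup, r2 = dup)
    pairs <- reciprocalBestHits(a, b, alignmentParams(minScore = 1))
    expect_equal(nrow(pairs), 0)
})

test_that("reciprocal best hits equal the brute-force double-loop oracle", {
    par <- alignmentParams(minScore = 15)
    set.seed(86)
    for (i in 1:25) {
        na <- sample(1:10, 1); nb <- sample(1:10, 1)
        sa <- setNames(vapply(seq_len(na),
                              function(j) randomProtein(sample(4:12, 1)),
                              character(1)), paste0("a", seq_len(na)))
        sb <- setNames(vapply(seq_len(nb),
                              function(j) randomProtein(sample(4:12, 1)),
                              character(1)), paste0("b", seq_len(nb)))
        got <- reciprocalBestHits(sa, sb, par)
        oracle <- oracleRBH(sa, sb, par)
        expect_equal(got[order(got$id_a), , drop = FALSE],
                     oracle[order(oracle$id_a), , drop = FALSE],
                     ignore_attr = TRUE)
        ## one-to-one mapping
        expect_false(any(duplicated(got$id_a)))
        expect_false(any(duplicated(got$id_b)))
    }
})

test_that("RBH output is symmetric and monotone in the score floor", {
    set.seed(87)
    sa <- setNames(vapply(1:6, function(j) randomProtein(10), character(1)),
                   paste0("a", 1:6))
    sb <- setNames(vapply(1:6, function(j) randomProtein(10), character(1)),
                   paste0("b", 1:6))
    lo <- reciprocalBestHits(sa, sb, alignmentParams(minScore = 5))
    swapped <- reciprocalBestHits(sb, sa, alignmentParams(minScore = 5))
    expect_setequal(paste(lo$id_a, lo$id_b),
                    paste(swapped$id_b, swapped$id_a))
    hi <- reciprocalBestHits(sa, sb, alignmentParams(minScore = 25))
    expect_true(all(paste(hi$id_a, hi$id_b) %in% paste(lo$id_a, lo$id_b)))
})
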