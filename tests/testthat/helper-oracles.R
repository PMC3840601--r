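## Independent oracles used across the suite. Each deliberately recomputes
## the quantity by a different route than the implementation (brute force,
## exhaustive enumeration, closed form).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

randomProtein <- function(n, alphabet = AA20) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Manually construct a VenomeTruth with prescribed abundances and coding
## lengths, bypassing the generator, for targeted simulator tests. The
## coding bodies are random sense codons under a fixed helper seed, so the
## same call always builds the same sequences.
makeTruth <- function(abundance, lengthsNt, config) {
    n <- length(abundance)
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    txSeq <- withr::with_seed(424242, vapply(lengthsNt, function(L) {
        body <- paste(sample(sense, L / 3 - 2, replace = TRUE),
                      collapse = "")
        paste0("ATG", body, "TAA")
    }, character(1)))
    ids <- sprintf("TX%04d", seq_len(n))
    tx <- Biostrings::DNAStringSet(setNames(txSeq, ids))
    protSeq <- vapply(txSeq, function(s) {
        aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
        sub("\\*$", "", aa)
    }, character(1))
    prot <- Biostrings::AAStringSet(setNames(unname(protSeq), ids))
    ab <- abundance / sum(abundance)
    new("VenomeTruth",
        transcripts = tx,
        txAbundance = setNames(ab, ids),
        proteins = prot,
        proteinAbundance = setNames(ab, ids),
        proteinMeta = data.frame(
            id = ids, source_transcript = ids, frame = 1L,
            is_contaminant = FALSE, signal_peptide_length = 0L,
            effective_length = nchar(protSeq), stringsAsFactors = FALSE),
        config = config)
}

## Digestion oracle: test every substring of the protein against the
## cleavage-boundary and internal-site conditions.
oracleDigest <- function(sequence, residues, maxMissed, lmin, lmax) {
    chars <- strsplit(sequence, "")[[1]]
    n <- length(chars)
    isSite <- chars %in% residues        # cleavage after these positions
    out <- character()
    for (s in seq_len(n)) for (e in s:n) {
        len <- e - s + 1
        if (len < lmin || len > lmax) next
        startOk <- s == 1 || isSite[s - 1]
        endOk <- e == n || isSite[e]
        if (!startOk || !endOk) next
        internal <- if (e > s) sum(isSite[s:(e - 1)]) else 0
        if (internal > maxMissed) next
        out <- c(out, substring(sequence, s, e))
    }
    sort(out)
}

## Exhaustive bootstrap oracle: quantiles of the full enumeration of all
## n^n equally likely resamples (inverse empirical CDF).
oracleBootCI <- function(scores, confidence, statistic = mean) {
    n <- length(scores)
    grids <- rep(list(seq_len(n)), n)
    idx <- as.matrix(expand.grid(grids))
    stats <- apply(idx, 1L, function(i) statistic(scores[i]))
    alpha <- 1 - confidence
    quantile(stats, c(alpha / 2, 1 - alpha / 2), type = 1, names = FALSE)
}

## Pearson r and two-sided p straight from the covariance formulas.
oracleCorrelation <- function(x, y) {
    n <- length(x)
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    list(r = r, p = 2 * pt(-abs(tstat), df = n - 2))
}

## Pure-R Gotoh dynamic program for local alignment with affine gaps
## (gap of length L costs open + L * extend). Independent of Biostrings.
oracleLocalAlign <- function(a, b, mat, open, extend) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    NEG <- -1e9
    M <- matrix(0, n + 1, m + 1)       # ends in a match/mismatch
    X <- matrix(NEG, n + 1, m + 1)     # ends in a gap in B (A consumed)
    Y <- matrix(NEG, n + 1, m + 1)     # ends in a gap in A
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                                   X[i, j + 1] - extend)
            Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                                   Y[i + 1, j] - extend)
            s <- mat[A[i], B[j]]
            M[i + 1, j + 1] <- max(0,
                                   M[i, j] + s,
                                   X[i, j] + s,
                                   Y[i, j] + s)
            best <- max(best, M[i + 1, j + 1])
        }
    }
    best
}

## Exhaustive local-alignment enumeration for very short sequences: every
## pair of substrings, every monotone gapped alignment between them,
## generated recursively. Confirms the DP oracle on tiny inputs.
oracleEnumAlign <- function(a, b, mat, open, extend) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    best <- 0
    rec <- function(i, j, ni, nj, score, state) {
        ## i/j: next positions to consume; ni/nj: ends (inclusive)
        if (i > ni && j > nj) {
            best <<- max(best, score)
            return(invisible())
        }
        if (i <= ni && j <= nj)
            rec(i + 1, j + 1, ni, nj, score + mat[A[i], B[j]], "M")
        if (i <= ni)
            rec(i + 1, j, ni, nj,
                score - (if (state == "X") extend else open + extend), "X")
        if (j <= nj)
            rec(i, j + 1, ni, nj,
                score - (if (state == "Y") extend else open + extend), "Y")
    }
    for (s1 in seq_along(A)) for (e1 in s1:length(A))
        for (s2 in seq_along(B)) for (e2 in s2:length(B))
            rec(s1, s2, e1, e2, 0, "M")
    best
}

## Brute-force reciprocal-best-hit oracle: double loop over all pairs.
oracleRBH <- function(sa, sb, params) {
    S <- matrix(0, length(sa), length(sb),
                dimnames = list(names(sa), names(sb)))
    for (i in seq_along(sa)) for (j in seq_along(sb))
        S[i, j] <- localAlign(sa[[i]], sb[[j]], params)
    pairs <- list()
    for (i in seq_along(sa)) {
        ri <- S[i, ]
        if (sum(ri == max(ri)) != 1) next
        j <- which.max(ri)
        cj <- S[, j]
        if (sum(cj == max(cj)) != 1) next
        if (which.max(cj) != i) next
        if (S[i, j] < params@minScore) next
        pairs[[length(pairs) + 1L]] <-
            data.frame(id_a = names(sa)[i], id_b = names(sb)[j],
                       score = S[i, j], stringsAsFactors = FALSE)
    }
    if (length(pairs)) do.call(rbind, pairs)
    else data.frame(id_a = character(), id_b = character(),
                    score = numeric(), stringsAsFactors = FALSE)
}

## Random matched observation sets over a small protein database, for the
## conservation and homogeneity properties.
randomMatchedObservations <- function(nProteins = 6, nPeptides = 12) {
    prots <- setNames(
        vapply(seq_len(nProteins), function(i) randomProtein(sample(20:40, 1)),
               character(1)),
        paste0("P", seq_len(nProteins)))
    ## draw peptides as substrings of the proteins so everything matches
    peps <- unique(vapply(seq_len(nPeptides), function(i) {
        p <- sample(nProteins, 1)
        n <- nchar(prots[[p]])
        s <- sample(seq_len(n - 3), 1)
        substring(prots[[p]], s, min(n, s + sample(3:8, 1)))
    }, character(1)))
    obs <- data.frame(peptide = peps,
                      count = sample(1:9, length(peps), replace = TRUE),
                      stringsAsFactors = FALSE)
    list(observations = matchPeptides(obs, prots), proteins = prots)
}
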