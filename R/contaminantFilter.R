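#' @include AllClasses.R
NULL

#' Bootstrap abundance threshold from contaminant proteins
#'
#' Laboratory contaminants (keratins and other cRAP-style proteins) enter
#' during sample preparation and should be far less abundant than genuine
#' venom proteins; their abundance scores therefore define a noise floor.
#' This function resamples the contaminant scores with replacement
#' \code{nBoot} times, computes the configured statistic (mean by default) of
#' each resample, and takes the percentile confidence interval of that
#' resampling distribution at the configured confidence level (99.9\% by
#' default). The upper bound is the filtering threshold. Percentiles use the
#' inverse empirical CDF, so on small score sets the interval coincides with
#' the exact quantiles of the full enumeration of resamples.
#'
#' @param contaminantScores non-negative, finite abundance scores of the
#'   contaminant proteins (at least one; with a single score the interval is
#'   degenerate and a warning is raised).
#' @param config a \linkS4class{BootstrapConfig}.
#' @return A \linkS4class{ThresholdResult}.
#' @examples
#' bootstrapThreshold(c(0.01, 0.02, 0.015), bootstrapConfig(seed = 17))
#' @export
bootstrapThreshold <- function(contaminantScores,
                               config = bootstrapConfig()) {
    stopifnot(is(config, "BootstrapConfig"))
    validObject(config)
    x <- as.numeric(contaminantScores)
    if (length(x) == 0L)
        stop("no contaminant scores supplied", call. = FALSE)
    if (any(!is.finite(x)))
        stop("contaminant scores must be finite", call. = FALSE)
    if (any(x < 0))
        stop("contaminant scores must be non-negative", call. = FALSE)
    n <- length(x)
    if (n == 1L) {
        warning("only one contaminant score; confidence interval is degenerate")
        return(new("ThresholdResult", threshold = x, ciLower = x,
                   ciUpper = x, nContaminants = 1L, config = config))
    }
    statFun <- match.fun(config@statistic)
    stat <- withSeed(config@seed, {
        m <- matrix(sample(x, n * config@nBoot, replace = TRUE),
                    nrow = config@nBoot)
        if (config@statistic == "mean") rowMeans(m)
        else apply(m, 1L, statFun)
    })
    alpha <- 1 - config@confidence
    ci <- stats::quantile(stat, c(alpha / 2, 1 - alpha / 2),
                          type = 1, names = FALSE)
    new("ThresholdResult", threshold = ci[2L], ciLower = ci[1L],
        ciUpper = ci[2L], nContaminants = n, config = config)
}

#' Partition proteins by an abundance threshold
#'
#' Proteins scoring strictly below the threshold are filtered out as
#' indistinguishable from contamination; proteins at or above it are
#' retained. Contaminant proteins themselves are always reported separately
#' and never enter the retained biological set.
#'
#' @param scores data.frame from \code{\link{abundanceScores}} (columns
#'   \code{protein_id}, \code{score}) or a named numeric vector.
#' @param threshold finite, non-negative cutoff, or a
#'   \linkS4class{ThresholdResult}.
#' @param contaminantIds ids to set aside as contaminants (default none).
#' @return List with elements \code{retained}, \code{filtered} and
#'   \code{contaminants}, each a data.frame with \code{protein_id} and
#'   \code{score}.
#' @examples
#' applyThreshold(c(A = 0.5, B = 0.02), threshold = 0.1)
#' @export
applyThreshold <- function(scores, threshold, contaminantIds = character()) {
    if (is(threshold, "ThresholdResult")) threshold <- threshold@threshold
    if (!is.numeric(threshold) || length(threshold) != 1L ||
        !is.finite(threshold) || threshold < 0)
        stop("'threshold' must be a single finite non-negative number",
             call. = FALSE)
    if (!is.data.frame(scores)) {
        v <- .asNamedNumeric(scores, "protein_id", "score", "scores")
        scores <- data.frame(protein_id = names(v), score = unname(v),
                             stringsAsFactors = FALSE)
    }
    stopifnot(all(c("protein_id", "score") %in% names(scores)))
    isCont <- scores$protein_id %in% contaminantIds
    bio <- scores[!isCont, , drop = FALSE]
    keep <- bio$score >= threshold
    list(retained = bio[keep, , drop = FALSE],
         filtered = bio[!keep, , drop = FALSE],
         contaminants = scores[isCont, , drop = FALSE])
}
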