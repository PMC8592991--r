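#' Trimmed mean of M-values (TMM) normalisation factors
#'
#' Between-sample scaling factors for count data.  The reference sample is
#' the one whose upper-quartile (of library-scaled counts) is closest to
#' the mean upper-quartile.  For every sample, log2 ratios (M) and average
#' log2 abundances (A) against the reference are computed over promoters
#' expressed in both; the most extreme 30 percent of M-values and 5 percent
#' of A-values are trimmed on each side, and the factor is the
#' precision-weighted mean of the remaining M-values.  Factors are rescaled
#' so their geometric mean is exactly 1.
#'
#' @param x a [PromoterCounts-class] or count matrix (promoters x samples).
#' @param logratioTrim,sumTrim two-sided trim fractions for M and A.
#' @return named numeric vector of factors, geometric mean 1.
#' @export
tmmFactors <- function(x, logratioTrim = 0.3, sumTrim = 0.05) {
    m <- if (is(x, "PromoterCounts"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    if (ncol(m) < 2L) stop("TMM needs at least 2 samples")
    if (any(colSums(m) <= 0)) stop("every sample needs a nonzero count")
    lib <- colSums(m)
    uq <- apply(m, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
    f <- vapply(seq_len(ncol(m)), function(j) {
        .tmmPair(m[, j], m[, ref], lib[j], lib[ref],
                 logratioTrim, sumTrim)
    }, numeric(1))
    f <- f / exp(mean(log(f)))
    stats::setNames(f, colnames(m))
}

.tmmPair <- function(y, yr, N, Nr, logratioTrim, sumTrim) {
    keep <- y > 0 & yr > 0
    if (!any(keep))
        stop("degenerate sample: no promoter expressed in both sample ",
             "and reference")
    y <- y[keep]; yr <- yr[keep]
    M <- log2((y / N) / (yr / Nr))
    A <- 0.5 * log2((y / N) * (yr / Nr))
    w <- (N - y) / (N * y) + (Nr - yr) / (Nr * yr)
    fin <- is.finite(M) & is.finite(A) & w > 0
    M <- M[fin]; A <- A[fin]; w <- w[fin]
    if (!length(M) || max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loL <- floor(n * logratioTrim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sumTrim) + 1; hiS <- n + 1 - loS
    keep <- rank(M) >= loL & rank(M) <= hiL &
            rank(A) >= loS & rank(A) <= hiS
    if (!any(keep)) return(1)
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Counts equalised to a common effective library size
#'
#' Scales every sample's counts by (geometric mean effective library) /
#' (its own effective library) and rounds, where effective library =
#' raw library size x TMM factor.  The exact conditional NB machinery
#' assumes equal library sizes; this is the scaling step that grants it.
#'
#' @param x a [PromoterCounts-class] (TMM factors used if set).
#' @return integer matrix of equalised counts.
#' @keywords internal
equalizeCounts <- function(x) {
    m <- SummarizedExperiment::assay(x, "counts")
    eff <- libSizes(x) * normFactors(x)
    round(sweep(m, 2, exp(mean(log(eff))) / eff, "*"))
}

#' Common negative-binomial dispersion by conditional maximum likelihood
#'
#' Maximises, over the dispersion phi, the NB conditional log-likelihood of
#' the equalised counts given their group sums, summed over promoters and
#' groups.  Conditioning removes the per-promoter mean so one global phi is
#' estimated.  For n equal-library samples in a group with size parameter
#' r = 1/phi each, the counts given their sum follow a negative
#' hypergeometric law, giving the closed-form conditional likelihood.
#'
#' @param x a [PromoterCounts-class].
#' @param groups grouping of samples (defaults to `conditions(x)`).
#' @param interval search interval for phi.
#' @return estimated common dispersion (>= 0).
#' @export
estimateCommonDispersion <- function(x, groups = conditions(x),
                                     interval = c(1e-6, 10)) {
    if (all(SummarizedExperiment::assay(x, "counts") == 0))
        stop("all-zero count matrix")
    y <- equalizeCounts(x)
    groups <- as.character(groups)
    glist <- split(seq_len(ncol(y)), groups)
    glist <- glist[lengths(glist) >= 2L]
    if (!length(glist)) stop("need at least one group with >= 2 samples")
    negll <- function(logphi) {
        r <- 1 / exp(logphi)
        ll <- 0
        for (idx in glist) {
            n <- length(idx)
            yi <- y[, idx, drop = FALSE]
            z <- rowSums(yi)
            ll <- ll + sum(lgamma(yi + r)) - length(yi) * lgamma(r) -
                sum(lgamma(z + n * r)) + length(z) * lgamma(n * r)
        }
        -ll
    }
    opt <- stats::optimize(negll, log(interval))
    phi <- exp(opt$minimum)
    # boundary: flat likelihood towards 0 means Poisson-like data
    if (negll(log(interval[1])) <= opt$objective) phi <- interval[1]
    phi
}

#' Exact conditional negative-binomial test p-value for one promoter
#' @keywords internal
.exactNBp <- function(sA, z, nA, nB, phi) {
    if (z == 0) return(1)
    s <- 0:z
    if (phi < 1e-10) {
        logp <- stats::dbinom(s, z, nA / (nA + nB), log = TRUE)
    } else {
        rA <- nA / phi; rB <- nB / phi
        logp <- lgamma(s + rA) - lgamma(s + 1) +
                lgamma(z - s + rB) - lgamma(z - s + 1)
        logp <- logp - max(logp)
        logp <- logp - log(sum(exp(logp)))
    }
    pobs <- logp[sA + 1]
    min(1, sum(exp(logp[logp <= pobs + 1e-8])))
}

#' Exact conditional NB test between two sample groups
#'
#' Two-sided exact test on equalised counts: for each promoter, the groups'
#' sums are conditioned on their total, which under the null of equal means
#' follows a negative hypergeometric distribution (binomial in the Poisson
#' limit phi -> 0).  The p-value sums the probability of all splits at most
#' as probable as the observed one.  Log2 fold changes use a prior count
#' of 0.5 on the per-sample group means: `log2((sB/nB + 0.5)/(sA/nA + 0.5))`,
#' positive when expression is higher in group B.
#'
#' @param x a [PromoterCounts-class] with TMM factors set (factor 1 is
#'   accepted).
#' @param groupA,groupB condition labels (matched against `conditions(x)`)
#'   or explicit sample-name vectors; must be disjoint and nonempty.
#' @param dispersion common NB dispersion from
#'   [estimateCommonDispersion()].
#' @return data.frame with columns `promoter_id`, `logFC` (B vs A),
#'   `PValue`, `FDR` (Benjamini-Hochberg).
#' @export
nbExactTest <- function(x, groupA, groupB, dispersion) {
    sel <- function(g) {
        if (all(g %in% colnames(x))) match(g, colnames(x))
        else which(conditions(x) %in% g)
    }
    ia <- sel(groupA); ib <- sel(groupB)
    if (!length(ia) || !length(ib)) stop("empty group")
    if (length(intersect(ia, ib))) stop("groups must be disjoint")
    y <- equalizeCounts(x)
    sA <- rowSums(y[, ia, drop = FALSE])
    sB <- rowSums(y[, ib, drop = FALSE])
    nA <- length(ia); nB <- length(ib)
    p <- vapply(seq_along(sA), function(i)
        .exactNBp(sA[i], sA[i] + sB[i], nA, nB, dispersion), numeric(1))
    logFC <- log2((sB / nB + 0.5) / (sA / nA + 0.5))
    data.frame(promoter_id = rownames(y), logFC = logFC, PValue = p,
               FDR = bhAdjust(p), row.names = rownames(y))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up BH with monotonicity enforcement (via
#' [stats::p.adjust()]), with input validation.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return FDR values, elementwise `>= p` and `<= 1`.
#' @export
bhAdjust <- function(p) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p-values must lie in [0, 1]")
    stats::p.adjust(p, method = "BH")
}

.checkUniverse <- function(de1, de2) {
    if (!identical(sort(de1$promoter_id), sort(de2$promoter_id)))
        stop("DE results cover different promoter universes")
}

#' Reversible promoters: up in torpor entry, reverted on exit
#'
#' Up-regulated reversible promoters rise significantly from Pre to Mid
#' (FDR < threshold, logFC > 0) and fall significantly from Mid to Post;
#' down-regulated ones mirror this.
#'
#' @param dePreMid,deMidPost DE results (B vs A direction: Mid vs Pre and
#'   Post vs Mid) over the same promoter universe.
#' @param fdr significance threshold (default 0.05).
#' @return list with character-vector elements `up` and `down`.
#' @export
classifyReversible <- function(dePreMid, deMidPost, fdr = 0.05) {
    .checkUniverse(dePreMid, deMidPost)
    de2 <- deMidPost[match(dePreMid$promoter_id, deMidPost$promoter_id), ]
    sig1 <- dePreMid$FDR < fdr
    sig2 <- de2$FDR < fdr
    list(up = dePreMid$promoter_id[sig1 & dePreMid$logFC > 0 &
                                   sig2 & de2$logFC < 0],
         down = dePreMid$promoter_id[sig1 & dePreMid$logFC < 0 &
                                     sig2 & de2$logFC > 0])
}

#' Hypometabolic promoters: changed towards torpor under both preventions
#'
#' Up-regulated hypometabolic promoters rise significantly towards the
#' torpid state in both contrasts (Mid vs HiT and Mid vs Fed); the two
#' torpor-prevention conditions remove, respectively, the cold requirement
#' and the fasting requirement, so shared changes track hypometabolism
#' itself rather than either cue.
#'
#' @param deHitMid,deFedMid DE results (Mid vs HiT and Mid vs Fed) over the
#'   same promoter universe.
#' @param fdr significance threshold (default 0.05).
#' @return list with elements `up` and `down`.
#' @export
classifyHypometabolic <- function(deHitMid, deFedMid, fdr = 0.05) {
    .checkUniverse(deHitMid, deFedMid)
    de2 <- deFedMid[match(deHitMid$promoter_id, deFedMid$promoter_id), ]
    sig1 <- deHitMid$FDR < fdr
    sig2 <- de2$FDR < fdr
    list(up = deHitMid$promoter_id[sig1 & deHitMid$logFC > 0 &
                                   sig2 & de2$logFC > 0],
         down = deHitMid$promoter_id[sig1 & deHitMid$logFC < 0 &
                                     sig2 & de2$logFC < 0])
}

#' Torpor-specific promoters: reversible AND hypometabolic
#'
#' Direction-matched set intersection of the reversible and hypometabolic
#' promoter sets.
#'
#' @param reversible,hypometabolic lists with `up`/`down` elements, as
#'   returned by the classify functions.
#' @return list with elements `up` and `down`.
#' @export
torporSpecific <- function(reversible, hypometabolic) {
    list(up = intersect(reversible$up, hypometabolic$up),
         down = intersect(reversible$down, hypometabolic$down))
}

#' Deprivation-specific promoters and their torpor-specific overlap
#'
#' Single-contrast split (Dep vs Mid) at the FDR threshold by logFC sign.
#' If torpor-specific sets are supplied, the overlap (the candidate
#' upstream regulators, e.g. an Atf3-like promoter) is reported as
#' `overlap_up` / `overlap_down`.
#'
#' @param deMidDep DE result, Dep vs Mid.
#' @param fdr significance threshold (default 0.05).
#' @param torporSets optional list with `up`/`down` torpor-specific sets.
#' @return list with `up`, `down`, and (if `torporSets` given)
#'   `overlap_up`, `overlap_down`.
#' @export
deprivationSpecific <- function(deMidDep, fdr = 0.05, torporSets = NULL) {
    sig <- deMidDep$FDR < fdr
    out <- list(up = deMidDep$promoter_id[sig & deMidDep$logFC > 0],
                down = deMidDep$promoter_id[sig & deMidDep$logFC < 0])
    if (!is.null(torporSets)) {
        out$overlap_up <- intersect(out$up, torporSets$up)
        out$overlap_down <- intersect(out$down, torporSets$down)
    }
    out
}

#' Rank promoters by total fold change over two contrasts
#'
#' Score = |logFC contrast 1| + |logFC contrast 2| on the log2 scale;
#' descending order, ties broken by promoter id.
#'
#' @param ids promoter ids to rank (e.g. a torpor-specific set).
#' @param de1,de2 the two defining DE results.
#' @return data.frame `promoter_id, logFC1, logFC2, total_fc`, ordered.
#' @export
rankByTotalFC <- function(ids, de1, de2) {
    i1 <- match(ids, de1$promoter_id)
    i2 <- match(ids, de2$promoter_id)
    if (any(is.na(i1)) || any(is.na(i2)))
        stop("ids missing from a DE result")
    out <- data.frame(promoter_id = ids,
                      logFC1 = de1$logFC[i1], logFC2 = de2$logFC[i2])
    out$total_fc <- abs(out$logFC1) + abs(out$logFC2)
    out[order(-out$total_fc, out$promoter_id), , drop = FALSE]
}

#' Classical MDS of samples on leading log-fold-change distances
#'
#' Pairwise sample distance = root mean square of the `top` largest
#' absolute log2 fold changes (log-CPM differences, prior count 0.5)
#' between the two samples; embedding by classical multidimensional
#' scaling (double-centering + eigendecomposition, [stats::cmdscale()]).
#'
#' @param x a [PromoterCounts-class].
#' @param top number of leading promoters per pair (default 500).
#' @return samples x 2 coordinate matrix.
#' @export
mdsEmbed <- function(x, top = 500L) {
    m <- SummarizedExperiment::assay(x, "counts")
    eff <- libSizes(x) * normFactors(x)
    lcpm <- log2(sweep(m + 0.5, 2, eff + 1, "/") * 1e6)
    n <- ncol(m)
    top <- min(top, nrow(m))
    d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        dif2 <- (lcpm[, i] - lcpm[, j])^2
        d[i, j] <- d[j, i] <-
            sqrt(mean(sort(dif2, decreasing = TRUE)[seq_len(top)]))
    }
    stats::cmdscale(d, k = 2)
}
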