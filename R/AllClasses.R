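#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges granges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames colData
#' @importFrom stats median quantile var sd
NULL

#' CTSS track: single-base CAGE tag counts on a stranded genome
#'
#' A `CTSSTrack` is a [GenomicRanges::GRanges] of width-1 positions, each
#' carrying an integer tag count in the `count` metadata column.  It is the
#' raw CAGE signal for one sample: every row says "this many capped 5' ends
#' mapped to this base on this strand".
#'
#' @slot .Data inherited `GRanges` representation.
#' @export
setClass("CTSSTrack", contains = "GRanges")

setValidity("CTSSTrack", function(object) {
    msg <- NULL
    if (length(object)) {
        if (!all(width(object) == 1L))
            msg <- c(msg, "all CTSS positions must have width 1")
        if (is.null(mcols(object)$count))
            msg <- c(msg, "metadata column 'count' is required")
        else {
            cnt <- mcols(object)$count
            if (!is.numeric(cnt) || any(is.na(cnt)) || any(cnt <= 0))
                msg <- c(msg, "counts must be positive and non-missing")
        }
        if (any(strand(object) == "*"))
            msg <- c(msg, "CTSS positions must be stranded (+/-)")
        key <- paste(seqnames(object), start(object), strand(object))
        if (anyDuplicated(key))
            msg <- c(msg, "(chrom, position, strand) must be unique")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a CTSS track
#'
#' @param chrom character vector of chromosome names.
#' @param pos 0-based base positions of the CTSSs.
#' @param strand `"+"` or `"-"` per position.
#' @param count positive tag counts.
#' @param seqlengths optional named vector of chromosome lengths.
#' @return A [CTSSTrack-class] object.  Internally coordinates are stored
#'   1-based (GRanges convention); `pos` is taken as 0-based, matching CTSS
#'   BED input where `start` is the TSS base.
#' @examples
#' CTSSTrack("chr1", c(99L, 104L), c("+", "+"), c(5L, 3L))
#' @export
CTSSTrack <- function(chrom, pos, strand, count, seqlengths = NULL) {
    gr <- GRanges(chrom, IRanges(as.integer(pos) + 1L, width = 1L),
                  strand = strand)
    mcols(gr)$count <- as.integer(count)
    if (!is.null(seqlengths))
        GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
    new("CTSSTrack", sort(gr, ignore.strand = TRUE))
}

#' Tag clusters: called promoters with architecture statistics
#'
#' `TagClusters` holds the promoters called from pooled CTSS signal.  The
#' ranges are 0-based-half-open spans re-expressed as 1-based GRanges; the
#' metadata columns are:
#' \describe{
#'   \item{promoter_id}{stable identifier, unique.}
#'   \item{peak}{dominant TSS: the 0-based position with the highest pooled
#'     count (ties broken towards the cluster's 5' end).}
#'   \item{score}{total pooled tag count.}
#'   \item{gene_id}{associated gene (within +/- 500 bp of the peak) or `NA`.}
#'   \item{SI}{entropy-based shape index over the +/-50 bp window, `<= 2`.}
#'   \item{gc}{GC fraction of the +/-50 bp window around the peak.}
#' }
#' The `profiles` slot stores, per cluster, the pooled per-position counts
#' (named integer vectors keyed by 0-based position).
#'
#' @slot profiles list of named integer vectors, parallel to the ranges.
#' @export
setClass("TagClusters", contains = "GRanges",
         representation(profiles = "list"))

setValidity("TagClusters", function(object) {
    msg <- NULL
    mc <- mcols(object)
    need <- c("promoter_id", "peak", "score")
    if (!all(need %in% names(mc)))
        return(paste("metadata columns required:", paste(need, collapse = ", ")))
    if (length(object) != length(object@profiles))
        msg <- c(msg, "profiles slot must be parallel to the ranges")
    if (anyDuplicated(mc$promoter_id))
        msg <- c(msg, "promoter_id must be unique")
    pk <- mc$peak + 1L  # to 1-based
    if (any(pk < start(object) | pk > end(object)))
        msg <- c(msg, "peak must lie inside the cluster span")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TagClusters", function(object) {
    cat("TagClusters with", length(object), "promoters\n")
    if (length(object)) {
        si <- mcols(object)$SI
        cat("  pooled tags:", sum(mcols(object)$score), "\n")
        if (!is.null(si) && any(is.finite(si)))
            cat("  SI range: [", round(min(si, na.rm = TRUE), 2), ", ",
                round(max(si, na.rm = TRUE), 2), "]\n", sep = "")
        ann <- mcols(object)$gene_id
        if (!is.null(ann))
            cat("  gene-associated:", sum(!is.na(ann)), "\n")
    }
    invisible(NULL)
})

#' Promoter count matrix
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' the promoters x samples raw tag counts (assay `"counts"`), with `colData`
#' columns `condition`, `lib.size` and `norm.factors` (TMM scaling factors,
#' default 1, geometric mean constrained to 1 after estimation).
#'
#' @export
setClass("PromoterCounts", contains = "SummarizedExperiment")

setValidity("PromoterCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("condition", "lib.size", "norm.factors") %in% names(cd)))
        return("colData must have condition, lib.size, norm.factors")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(cd$norm.factors <= 0)) msg <- c(msg, "norm.factors must be > 0")
    if (is.null(msg)) TRUE else msg
})

#' Construct a promoter count matrix
#'
#' @param counts integer matrix, promoters x samples, with dimnames.
#' @param condition factor/character of sample conditions, one per column.
#' @param lib.size library sizes; defaults to column sums.
#' @param norm.factors TMM factors; default 1.
#' @return A [PromoterCounts-class] object.
#' @export
PromoterCounts <- function(counts, condition,
                           lib.size = colSums(counts),
                           norm.factors = rep(1, ncol(counts))) {
    counts <- as.matrix(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = DataFrame(condition = as.character(condition),
                            lib.size = as.numeric(lib.size),
                            norm.factors = as.numeric(norm.factors),
                            row.names = colnames(counts)))
    new("PromoterCounts", se)
}

#' @describeIn PromoterCounts conditions of the samples.
#' @param x,object a `PromoterCounts`.
#' @export
conditions <- function(x) SummarizedExperiment::colData(x)$condition

#' @describeIn PromoterCounts library sizes.
#' @export
libSizes <- function(x) SummarizedExperiment::colData(x)$lib.size

#' @describeIn PromoterCounts TMM normalisation factors.
#' @export
normFactors <- function(x) SummarizedExperiment::colData(x)$norm.factors

#' @describeIn PromoterCounts replace the TMM normalisation factors.
#' @param value numeric factors, geometric mean 1.
#' @export
`normFactors<-` <- function(x, value) {
    SummarizedExperiment::colData(x)$norm.factors <- value
    validObject(x)
    x
}

setMethod("show", "PromoterCounts", function(object) {
    cat("PromoterCounts:", nrow(object), "promoters x", ncol(object),
        "samples\n")
    cat("  conditions:", paste(unique(conditions(object)), collapse = ", "),
        "\n")
    cat("  TMM factors set:",
        if (all(normFactors(object) == 1)) "no" else "yes", "\n")
    invisible(NULL)
})

#' Posterior draws with chain structure
#'
#' MCMC output: an iterations x chains x parameters array plus sampler
#' metadata.  At least two chains with equal lengths are required so that
#' split-R-hat is defined.
#'
#' @slot draws numeric array `[iteration, chain, parameter]` with parameter
#'   dimnames.
#' @slot warmup number of discarded adaptation iterations per chain.
#' @slot seed integer seed the sampler was run with.
#' @slot accept_rate mean post-warmup Metropolis acceptance rate per chain.
#' @slot diagnostics data.frame of per-parameter split R-hat and ESS
#'   (filled by [mcmcDiagnostics()] at fit time).
#' @export
setClass("PosteriorDraws",
         representation(draws = "array", warmup = "integer", seed = "integer",
                        accept_rate = "numeric", diagnostics = "data.frame"))

setValidity("PosteriorDraws", function(object) {
    d <- object@draws
    if (length(dim(d)) != 3L) return("draws must be a 3-d array")
    if (dim(d)[2] < 2L) return("at least 2 chains are required")
    if (any(!is.finite(d))) return("draws contain non-finite values")
    TRUE
})

setMethod("show", "PosteriorDraws", function(object) {
    d <- dim(object@draws)
    cat("PosteriorDraws:", d[1], "iterations x", d[2], "chains x", d[3],
        "parameters\n")
    if (nrow(object@diagnostics)) {
        mx <- max(object@diagnostics$rhat, na.rm = TRUE)
        cat("  max split R-hat:", round(mx, 3),
            if (mx > 1.05) " (convergence warning)" else "", "\n", sep = "")
    }
    invisible(NULL)
})

#' Parameter names of a posterior
#' @param x a [PosteriorDraws-class].
#' @return character vector of parameter names.
#' @export
parNames <- function(x) dimnames(x@draws)[[3]]

#' Flatten posterior draws for one parameter across chains
#' @param x a [PosteriorDraws-class].
#' @param par parameter name.
#' @return numeric vector of pooled draws.
#' @export
extractPar <- function(x, par) {
    if (!par %in% parNames(x)) stop("unknown parameter: ", par)
    as.vector(x@draws[, , par])
}

#' Bayesian circadian baseline for one physiological signal
#'
#' Posterior of a two-harmonic (24 h period) circadian regression with
#' Normal residuals, fitted to day-1 recordings of one signal, plus the
#' per-time-of-day lower bound of the posterior predictive distribution at
#' the requested credible level.
#'
#' @slot signal `"tb"` or `"vo2"`.
#' @slot posterior the [PosteriorDraws-class] over (mesor, a1, b1, a2, b2,
#'   sigma).
#' @slot ci credible level used for the predictive band (e.g. 0.999).
#' @slot tod time-of-day grid (hours, `[0, 24)`).
#' @slot lower lower predictive bound on the `tod` grid.
#' @slot median posterior median curve on the `tod` grid.
#' @export
setClass("BaselinePosterior",
         representation(signal = "character", posterior = "PosteriorDraws",
                        ci = "numeric", tod = "numeric", lower = "numeric",
                        median = "numeric"))

setValidity("BaselinePosterior", function(object) {
    if (length(object@tod) != length(object@lower))
        return("tod and lower grids must be parallel")
    if (any(object@lower >= object@median))
        return("lower predictive bound must sit below the median curve")
    TRUE
})

setMethod("show", "BaselinePosterior", function(object) {
    cat("BaselinePosterior for", object@signal, "at", object@ci * 100,
        "% credible level\n")
    cat("  median level:", round(stats::median(object@median), 2),
        " band floor:", round(min(object@lower), 2), "\n")
    invisible(NULL)
})
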