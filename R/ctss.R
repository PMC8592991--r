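#' Pool CTSS tracks into one combined track
#'
#' Sums tag counts over samples at identical (chrom, position, strand).
#'
#' @param tracks list of [CTSSTrack-class] objects on one genome.
#' @return a [CTSSTrack-class] of pooled counts.
#' @export
poolCTSS <- function(tracks) {
    stopifnot(length(tracks) >= 1L)
    grl <- lapply(tracks, function(x) as(x, "GRanges"))
    gr <- suppressWarnings(do.call(c, unname(grl)))
    key <- paste(seqnames(gr), start(gr), strand(gr))
    tot <- rowsum(as.numeric(mcols(gr)$count), key)
    first <- gr[!duplicated(key)]
    CTSSTrack(as.character(seqnames(first)), start(first) - 1L,
              as.character(strand(first)),
              tot[match(paste(seqnames(first), start(first), strand(first)),
                        rownames(tot)), 1],
              seqlengths = stats::setNames(GenomeInfoDb::seqlengths(first),
                                           GenomeInfoDb::seqlevels(first)))
}

#' Cluster pooled CTSS signal into tag clusters (promoters)
#'
#' Single-linkage clustering along each strand: consecutive CTSSs at most
#' `maxGap` bp apart join one cluster; clusters whose pooled tag total is
#' below `minTags` are dropped.  The dominant TSS (peak) of a cluster is
#' the position with the highest pooled count, ties broken towards the
#' cluster's 5' end (smallest position on `+`, largest on `-`).
#'
#' @param tracks list of [CTSSTrack-class] (pooled internally), or a single
#'   pooled track.
#' @param maxGap maximum distance (bp) between consecutive CTSSs in one
#'   cluster (default 20).
#' @param minTags minimum pooled tags to retain a cluster (default 10).
#' @return a [TagClusters-class]; empty input gives an empty object.
#' @examples
#' tr <- CTSSTrack("chr1", c(100, 105, 200), rep("+", 3), c(6, 5, 12))
#' clusterCTSS(list(tr), maxGap = 20, minTags = 10)
#' @export
clusterCTSS <- function(tracks, maxGap = 20L, minTags = 10L) {
    emptyClusters <- function() {
        gr <- GRanges()
        mcols(gr) <- DataFrame(promoter_id = character(0),
                               peak = integer(0), score = numeric(0),
                               gene_id = character(0), SI = numeric(0),
                               gc = numeric(0))
        new("TagClusters", gr, profiles = list())
    }
    if (!is(tracks, "CTSSTrack") && length(tracks) == 0L)
        return(emptyClusters())
    pooled <- if (is(tracks, "CTSSTrack")) tracks else poolCTSS(tracks)
    if (length(pooled) == 0L) return(emptyClusters())
    # reduce() merges same-strand ranges whose gap is < min.gapwidth;
    # positions d apart have gap d - 1, so min.gapwidth = maxGap joins
    # positions at most maxGap apart.
    red <- GenomicRanges::reduce(granges(pooled), min.gapwidth = maxGap,
                                 with.revmap = TRUE)
    revmap <- mcols(red)$revmap
    cnt <- mcols(pooled)$count
    pos1 <- start(pooled)
    keep <- logical(length(red))
    peaks <- integer(length(red))
    scores <- numeric(length(red))
    profiles <- vector("list", length(red))
    str <- as.character(strand(red))
    for (i in seq_along(red)) {
        idx <- revmap[[i]]
        k <- cnt[idx]; p <- pos1[idx]
        scores[i] <- sum(k)
        keep[i] <- scores[i] >= minTags
        if (!keep[i]) next
        top <- which(k == max(k))
        peaks[i] <- if (str[i] == "-") max(p[top]) else min(p[top])
        prof <- as.integer(k[order(p)])
        names(prof) <- sort(p) - 1L          # 0-based positions
        profiles[[i]] <- prof
    }
    red <- red[keep]
    mcols(red) <- DataFrame(
        promoter_id = paste0(seqnames(red), ":", start(red) - 1L, "-",
                             end(red), ",", strand(red)),
        peak = peaks[keep] - 1L,
        score = scores[keep],
        gene_id = NA_character_, SI = NA_real_, gc = NA_real_)
    new("TagClusters", red, profiles = profiles[keep])
}

#' Count pooled or per-sample tags within tag clusters
#'
#' Sums each sample's CTSS counts over each cluster span (same strand),
#' producing the promoters x samples count matrix the differential
#' expression stage consumes.  Sample conditions are taken from the track
#' names (`<condition>_<replicate>`) unless given explicitly.
#'
#' @param tracks named list of [CTSSTrack-class].
#' @param clusters a [TagClusters-class].
#' @param condition optional character vector of conditions per track.
#' @return a [PromoterCounts-class].
#' @export
countCTSS <- function(tracks, clusters, condition = NULL) {
    stopifnot(is(clusters, "TagClusters"), length(tracks) >= 1L)
    if (is.null(condition))
        condition <- sub("_[0-9]+$", "", names(tracks))
    m <- matrix(0L, length(clusters), length(tracks),
                dimnames = list(mcols(clusters)$promoter_id, names(tracks)))
    for (s in seq_along(tracks)) {
        hits <- GenomicRanges::findOverlaps(granges(clusters),
                                            granges(tracks[[s]]))
        if (length(hits)) {
            agg <- rowsum(
                as.numeric(mcols(tracks[[s]])$count[S4Vectors::subjectHits(hits)]),
                S4Vectors::queryHits(hits))
            m[as.integer(rownames(agg)), s] <- agg[, 1]
        }
    }
    PromoterCounts(m, condition)
}

#' Tags-per-million normalisation
#'
#' Rescales every sample (column) so that its total is exactly one million
#' tags.  TPM is the reporting scale; differential testing uses raw counts
#' with TMM effective library sizes instead.
#'
#' @param x a [PromoterCounts-class] or a non-negative count matrix.
#' @return numeric matrix of TPM values; columns sum to 1e6.
#' @export
tpmNormalize <- function(x) {
    m <- if (is(x, "PromoterCounts"))
        SummarizedExperiment::assay(x, "counts") else as.matrix(x)
    tot <- colSums(m)
    if (any(tot <= 0)) stop("zero library: cannot TPM-normalise")
    sweep(m, 2, tot, "/") * 1e6
}

#' Associate tag clusters with annotated gene 5' ends
#'
#' A cluster is associated with the same-strand gene whose annotated TSS is
#' nearest to the cluster peak, provided the distance is within
#' `+/- window` bp; otherwise it stays unassociated (`NA`).
#'
#' @param clusters a [TagClusters-class].
#' @param genes `GRanges` of gene bodies with a `gene_id` column; the 5'
#'   end of each range is the annotated TSS.
#' @param window association radius in bp (default 500).
#' @return the clusters with the `gene_id` metadata column filled in.
#' @export
annotateClusters <- function(clusters, genes, window = 500L) {
    if (length(clusters) == 0L) return(clusters)
    tss0 <- geneTSS0(genes)
    gid <- mcols(genes)$gene_id
    gchr <- as.character(seqnames(genes))
    gstr <- as.character(strand(genes))
    pk <- mcols(clusters)$peak
    cchr <- as.character(seqnames(clusters))
    cstr <- as.character(strand(clusters))
    assoc <- rep(NA_character_, length(clusters))
    for (grp in unique(paste(cchr, cstr))) {
        ci <- which(paste(cchr, cstr) == grp)
        gi <- which(paste(gchr, gstr) == grp)
        if (!length(gi)) next
        o <- order(tss0[gi]); gi <- gi[o]
        ts <- tss0[gi]
        iv <- findInterval(pk[ci], ts)
        lo <- pmax(iv, 1L); hi <- pmin(iv + 1L, length(ts))
        d_lo <- abs(pk[ci] - ts[lo]); d_hi <- abs(pk[ci] - ts[hi])
        best <- ifelse(d_hi < d_lo, hi, lo)
        d <- pmin(d_lo, d_hi)
        ok <- d <= window
        assoc[ci[ok]] <- gid[gi][best[ok]]
    }
    mcols(clusters)$gene_id <- assoc
    clusters
}

#' Entropy-based promoter shape index
#'
#' For a positional tag distribution with count shares p_i,
#' `SI = 2 + sum(p_i * log2(p_i))`.  All tags on one base give SI = 2
#' (singleton promoter); a uniform spread over N bases gives
#' `2 - log2(N)`; values below -1 indicate a broad promoter.  Invariant to
#' total-count scaling.
#'
#' @param x a numeric vector of per-position tag counts, or a
#'   [TagClusters-class].
#' @param ... passed to methods.
#' @return for a numeric vector, the SI in bits (`NA` if all counts are
#'   zero); for `TagClusters`, the object with the `SI` column filled using
#'   counts within `+/- window` bp of each peak.
#' @examples
#' shapeIndex(c(100))                   # 2: singleton
#' shapeIndex(rep(5, 16))               # 2 - log2(16) = -2: broad
#' @export
setGeneric("shapeIndex", function(x, ...) standardGeneric("shapeIndex"))

#' @rdname shapeIndex
#' @export
setMethod("shapeIndex", "numeric", function(x, ...) {
    if (any(x < 0)) stop("counts must be non-negative")
    tot <- sum(x)
    if (tot == 0) return(NA_real_)
    p <- x[x > 0] / tot
    2 + sum(p * log2(p))
})

#' @rdname shapeIndex
#' @param window half-width in bp of the window around the dominant peak
#'   over which positional counts are taken (default 50).
#' @export
setMethod("shapeIndex", "TagClusters", function(x, window = 50L, ...) {
    pk <- mcols(x)$peak
    si <- vapply(seq_along(x), function(i) {
        prof <- x@profiles[[i]]
        pos <- as.integer(names(prof))
        inw <- abs(pos - pk[i]) <= window
        if (!any(inw)) return(NA_real_)
        shapeIndex(as.numeric(prof[inw]))
    }, numeric(1))
    mcols(x)$SI <- si
    x
})

#' GC content of promoter windows
#'
#' Fraction (#G + #C) / (window bases excluding ambiguous codes) over the
#' `+/- window` bp region around each cluster peak, case-insensitive,
#' truncated at chromosome ends.
#'
#' @param x a [TagClusters-class], or a character/`DNAString` sequence.
#' @param ... passed to methods.
#' @return for a sequence, a single fraction; for clusters, the object with
#'   the `gc` column filled.
#' @export
setGeneric("gcContent", function(x, ...) standardGeneric("gcContent"))

#' @rdname gcContent
#' @export
setMethod("gcContent", "character", function(x, ...) {
    s <- Biostrings::DNAString(toupper(x))
    f <- Biostrings::letterFrequency(s, c("G", "C", "A", "T"))
    denom <- sum(f)
    if (denom == 0) return(NA_real_)
    unname((f[["G"]] + f[["C"]]) / denom)
})

#' @rdname gcContent
#' @param genome a named [Biostrings::DNAStringSet].
#' @param window half-width of the window around the peak (default 50).
#' @export
setMethod("gcContent", "TagClusters", function(x, genome, window = 50L, ...) {
    pk <- mcols(x)$peak
    chr <- as.character(seqnames(x))
    gc <- vapply(seq_along(x), function(i) {
        L <- length(genome[[chr[i]]])
        if (pk[i] < 0 || pk[i] >= L) stop("peak outside chromosome: ", i)
        lo <- max(pk[i] - window, 0L) + 1L          # 1-based
        hi <- min(pk[i] + window + 1L, L)
        gcContent(as.character(Biostrings::subseq(genome[[chr[i]]], lo, hi)))
    }, numeric(1))
    mcols(x)$gc <- gc
    x
})
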