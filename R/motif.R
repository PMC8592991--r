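#' Position weight matrix
#'
#' Per-position base probabilities (rows A, C, G, T) against a uniform 0.25
#' background.  Scores are log2 odds, so a base matched with probability 1
#' contributes `log2(1/0.25) = 2` bits.
#'
#' @slot id motif identifier.
#' @slot mat 4 x width probability matrix, rows named A, C, G, T; every
#'   column sums to 1.
#' @export
setClass("PWM", representation(id = "character", mat = "matrix"))

setValidity("PWM", function(object) {
    m <- object@mat
    if (!identical(rownames(m), c("A", "C", "G", "T")))
        return("rows must be A, C, G, T")
    if (ncol(m) < 4L) return("motif width must be >= 4")
    if (any(abs(colSums(m) - 1) > 1e-6))
        return("columns must sum to 1")
    if (any(m < 0)) return("probabilities must be non-negative")
    TRUE
})

setMethod("show", "PWM", function(object) {
    cat("PWM", object@id, "width", ncol(object@mat),
        "consensus", pwmConsensus(object), "\n")
    invisible(NULL)
})

#' Build a PWM from a count or probability matrix
#'
#' @param id motif identifier.
#' @param mat 4 x width matrix of counts or probabilities, rows A, C, G, T.
#' @param pseudocount added to every count before normalising (default 0.5;
#'   use 0 for exact deterministic matrices).
#' @return a [PWM-class].
#' @export
pwm <- function(id, mat, pseudocount = 0.5) {
    mat <- as.matrix(mat)
    rownames(mat) <- c("A", "C", "G", "T")
    mat <- sweep(mat + pseudocount, 2, colSums(mat) + 4 * pseudocount, "/")
    new("PWM", id = id, mat = mat)
}

#' Consensus sequence of a PWM
#' @param x a [PWM-class].
#' @return character string of per-column most probable bases.
#' @export
pwmConsensus <- function(x)
    paste(rownames(x@mat)[apply(x@mat, 2, which.max)], collapse = "")

#' Maximum attainable log2-odds score of a PWM
#' @param x a [PWM-class].
#' @return score in bits of the consensus sequence.
#' @export
pwmMaxScore <- function(x) sum(apply(log2(x@mat / 0.25), 2, max))

#' Reverse-complement a PWM
#' @param x a [PWM-class].
#' @return the reverse-complement [PWM-class].
#' @keywords internal
pwmRevComp <- function(x) {
    m <- x@mat[c("T", "G", "C", "A"), rev(seq_len(ncol(x@mat))), drop = FALSE]
    rownames(m) <- c("A", "C", "G", "T")
    new("PWM", id = x@id, mat = m)
}

#' Read motifs in JASPAR format
#'
#' Parses the standard JASPAR text layout: a `>ID name` header followed by
#' four rows `A [ counts... ]` ... `T [ counts... ]` (brackets optional).
#'
#' @param path file path.
#' @param pseudocount passed to [pwm()].
#' @return named list of [PWM-class].
#' @export
readJASPAR <- function(path, pseudocount = 0.5) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    heads <- grep("^>", lines)
    if (!length(heads)) stop("no JASPAR records found in ", path)
    out <- list()
    for (h in seq_along(heads)) {
        i <- heads[h]
        if (i + 4 > length(lines))
            stop("truncated JASPAR record at line ", i)
        id <- strsplit(sub("^>\\s*", "", lines[i]), "\\s+")[[1]][1]
        rows <- lapply(lines[(i + 1):(i + 4)], function(l) {
            l <- gsub("^[ACGTacgt]\\s*\\[?|\\]\\s*$", "", trimws(l))
            as.numeric(strsplit(trimws(l), "\\s+")[[1]])
        })
        if (length(unique(lengths(rows))) != 1L)
            stop("ragged count rows in JASPAR record ", id)
        out[[id]] <- pwm(id, do.call(rbind, rows), pseudocount)
    }
    out
}

#' Extract strand-oriented promoter regions around cluster peaks
#'
#' Returns the `-up/+down` bp window around each dominant TSS, oriented so
#' that upstream is on the left: minus-strand windows are
#' reverse-complemented.  Windows are truncated at chromosome ends.
#'
#' @param clusters a [TagClusters-class].
#' @param genome a named [Biostrings::DNAStringSet].
#' @param up,down bp upstream/downstream of the TSS (defaults 300/100; the
#'   full window is `up + down + 1` bases including the TSS).
#' @return a [Biostrings::DNAStringSet] named by promoter id, with `mcols`
#'   column `tss` giving the 1-based index of the TSS base within each
#'   sequence (so sequence position i is at offset `i - tss` from the TSS).
#' @export
extractRegions <- function(clusters, genome, up = 300L, down = 100L) {
    pk <- mcols(clusters)$peak
    chr <- as.character(seqnames(clusters))
    str <- as.character(strand(clusters))
    seqs <- character(length(clusters))
    tss <- integer(length(clusters))
    for (i in seq_along(clusters)) {
        L <- length(genome[[chr[i]]])
        if (pk[i] < 0 || pk[i] >= L) stop("peak off chromosome: ", i)
        if (str[i] == "+") {
            lo <- max(pk[i] - up, 0L); hi <- min(pk[i] + down, L - 1L)
            s <- Biostrings::subseq(genome[[chr[i]]], lo + 1L, hi + 1L)
            seqs[i] <- as.character(s)
            tss[i] <- pk[i] - lo + 1L
        } else {
            lo <- max(pk[i] - down, 0L); hi <- min(pk[i] + up, L - 1L)
            s <- Biostrings::reverseComplement(
                Biostrings::subseq(genome[[chr[i]]], lo + 1L, hi + 1L))
            seqs[i] <- as.character(s)
            tss[i] <- hi - pk[i] + 1L
        }
    }
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- mcols(clusters)$promoter_id
    mcols(out) <- DataFrame(tss = tss)
    out
}

#' Log2-odds scores at every offset of one strand
#' @return numeric vector of length `L - w + 1` (empty if region shorter
#'   than the motif); ambiguous bases contribute 0.
#' @keywords internal
.scanScores <- function(codes, lo) {
    w <- ncol(lo)
    L <- length(codes)
    if (L < w) return(numeric(0))
    n <- L - w + 1L
    sc <- numeric(n)
    for (k in seq_len(w)) {
        v <- lo[cbind(codes[k:(k + n - 1L)], k)]
        v[is.na(v)] <- 0
        sc <- sc + v
    }
    sc
}

.encode <- function(seq)
    match(strsplit(toupper(as.character(seq)), "")[[1]], c("A", "C", "G", "T"))

#' Best PWM hit in a region, scanning both strands
#'
#' Maximum over both strands and all offsets of the log2-odds score
#' `sum(log2(p_base / 0.25))`; ambiguous bases (N) contribute 0.
#'
#' @param region character or `DNAString` sequence.
#' @param x a [PWM-class].
#' @param tss 1-based index of the TSS within the region (default 1, i.e.
#'   offsets are reported relative to the region start).
#' @return list `score`, `offset` (start of the hit relative to the TSS)
#'   and `strand`; all `NA` if the region is shorter than the motif.
#' @export
bestHit <- function(region, x, tss = 1L) {
    codes <- .encode(region)
    lo <- log2(x@mat / 0.25)
    fwd <- .scanScores(codes, lo)
    if (!length(fwd))
        return(list(score = NA_real_, offset = NA_integer_,
                    strand = NA_character_))
    rev <- .scanScores(codes, log2(pwmRevComp(x)@mat / 0.25))
    bf <- which.max(fwd); br <- which.max(rev)
    if (fwd[bf] >= rev[br])
        list(score = fwd[bf], offset = bf - as.integer(tss), strand = "+")
    else
        list(score = rev[br], offset = br - as.integer(tss), strand = "-")
}

#' All hit start offsets (either strand) at or above a score threshold
#' @keywords internal
.hitOffsets <- function(region, x, threshold, tss) {
    codes <- .encode(region)
    lo <- log2(x@mat / 0.25)
    fwd <- .scanScores(codes, lo)
    if (!length(fwd)) return(integer(0))
    rev <- .scanScores(codes, log2(pwmRevComp(x)@mat / 0.25))
    sort(unique(c(which(fwd >= threshold), which(rev >= threshold)))) -
        as.integer(tss)
}

.regionTSS <- function(regions) {
    tss <- mcols(regions)$tss
    if (is.null(tss)) rep(1L, length(regions)) else tss
}

#' Motif enrichment in a foreground promoter set
#'
#' For each motif, promoters are labelled hit / no-hit by whether their
#' best log2-odds score reaches `relThreshold x` the motif's maximum
#' attainable score, a 2x2 foreground/background table is formed, and a
#' two-sided Fisher exact p-value is computed, Bonferroni-corrected over
#' the motif set.
#'
#' @param foreground,background `DNAStringSet`s of promoter regions (from
#'   [extractRegions()]).  If `backgroundIsUniverse = TRUE` the background
#'   is taken as all promoters (foreground included) and foreground
#'   promoters are removed from it before tabulation.
#' @param pwms list of [PWM-class].
#' @param relThreshold hit threshold as a fraction of the maximum PWM score
#'   (default 0.8).
#' @param backgroundIsUniverse see above (default `FALSE`: disjoint sets).
#' @return data.frame per motif: hit counts, odds ratio, `p`,
#'   `p_bonferroni`.
#' @export
motifEnrichment <- function(foreground, background, pwms,
                            relThreshold = 0.8,
                            backgroundIsUniverse = FALSE) {
    if (length(foreground) == 0L) stop("empty foreground")
    if (backgroundIsUniverse)
        background <- background[!names(background) %in% names(foreground)]
    ft <- .regionTSS(foreground); bt <- .regionTSS(background)
    res <- lapply(pwms, function(m) {
        th <- relThreshold * pwmMaxScore(m)
        fh <- sum(vapply(seq_along(foreground), function(i)
            isTRUE(bestHit(foreground[[i]], m, ft[i])$score >= th),
            logical(1)))
        bh <- sum(vapply(seq_along(background), function(i)
            isTRUE(bestHit(background[[i]], m, bt[i])$score >= th),
            logical(1)))
        tab <- matrix(c(fh, length(foreground) - fh,
                        bh, length(background) - bh), 2)
        or <- (tab[1, 1] * tab[2, 2]) / max(tab[2, 1] * tab[1, 2], 1e-300)
        data.frame(motif = m@id, fg_hits = fh, fg_total = length(foreground),
                   bg_hits = bh, bg_total = length(background),
                   odds_ratio = or,
                   p = stats::fisher.test(tab)$p.value)
    })
    out <- do.call(rbind, res)
    out$p_bonferroni <- pmin(1, out$p * nrow(out))
    rownames(out) <- NULL
    out[order(out$p), , drop = FALSE]
}

#' Positional motif-probability profile around the TSS
#'
#' Fraction of regions carrying a hit (either strand, score at or above
#' `relThreshold x` max score) starting at each offset relative to the TSS,
#' smoothed by a centered moving average.  The reported peak is the raw
#' argmax within the smoothing window around the smoothed curve's maximum,
#' so an isolated planted site is reported at its own offset rather than
#' at the edge of the plateau smoothing produces.
#'
#' @param regions `DNAStringSet` from [extractRegions()].
#' @param x a [PWM-class].
#' @param relThreshold hit threshold fraction (default 0.8).
#' @param smoothWindow moving-average window in bp (default 20; rounded up
#'   to the enclosing odd width so the average is centered).
#' @return list with `profile` (data.frame `offset`, `raw`, `smoothed`) and
#'   `peakOffset`.  The raw curve sums to the mean number of hits per
#'   region.
#' @export
positionalProfile <- function(regions, x, relThreshold = 0.8,
                              smoothWindow = 20L) {
    stopifnot(length(regions) >= 1L)
    tss <- .regionTSS(regions)
    th <- relThreshold * pwmMaxScore(x)
    w <- ncol(x@mat)
    offmin <- min(1L - tss)
    offmax <- max(Biostrings::width(regions) - w + 1L - tss)
    grid <- offmin:offmax
    counts <- numeric(length(grid))
    for (i in seq_along(regions)) {
        hits <- .hitOffsets(regions[[i]], x, th, tss[i])
        if (length(hits))
            counts[match(hits, grid)] <- counts[match(hits, grid)] + 1
    }
    raw <- counts / length(regions)
    h <- floor(smoothWindow / 2)
    kern <- rep(1 / (2 * h + 1), 2 * h + 1)
    sm <- as.numeric(stats::filter(raw, kern, sides = 2))
    sm[is.na(sm)] <- 0
    # the smoothed curve locates the enriched neighbourhood; the reported
    # peak is the raw argmax inside it, so an isolated planted site is
    # reported at its own offset rather than at a smoothing artefact
    ctr <- which.max(sm)
    region <- which(abs(grid - grid[ctr]) <= h)
    peak <- grid[region[which.max(raw[region])]]
    list(profile = data.frame(offset = grid, raw = raw, smoothed = sm),
         peakOffset = peak)
}
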