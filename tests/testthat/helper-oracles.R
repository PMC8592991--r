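# Independent oracles used across test files.  These deliberately avoid the
# package's own code paths.

# shortest contiguous window containing ceiling(prob * n) sorted samples,
# by exhaustive scan
bruteHPDI <- function(v, prob) {
    s <- sort(v)
    n <- length(s)
    k <- ceiling(prob * n)
    if (k >= n) return(c(s[1], s[n]))
    best <- c(s[1], s[k])
    for (i in seq_len(n - k + 1)) {
        if (s[i + k - 1] - s[i] < best[2] - best[1])
            best <- c(s[i], s[i + k - 1])
    }
    best
}

# two-sided Fisher p as the hypergeometric sum of all tables at most as
# probable as the observed one (fixed margins)
fisherOracle <- function(a, b, c, d) {
    m <- a + c; n <- b + d; k <- a + b
    x <- max(0, k - n):min(k, m)
    p <- stats::dhyper(x, m, n, k)
    sum(p[p <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# literal step-up BH
bhOracle <- function(p) {
    m <- length(p)
    o <- order(p, decreasing = TRUE)
    q <- p[o] * m / (m:1)
    cummin(pmin(q, 1))[order(o)]
}

# minimal DE-result table for the classification functions
mkDE <- function(ids, lfc, fdr)
    data.frame(promoter_id = ids, logFC = lfc, PValue = fdr, FDR = fdr)

# deterministic PWM from a consensus string (pseudocount 0)
consensusPWM <- function(seq, id = "DET") {
    b <- strsplit(seq, "")[[1]]
    m <- vapply(b, function(x) {
        v <- numeric(4); v[match(x, c("A", "C", "G", "T"))] <- 1; v
    }, numeric(4))
    pwm(id, m, pseudocount = 0)
}

# random promoter regions with an optional planted site at a fixed offset
# (tss = position up + 1 inside each region)
plantRegions <- function(n, plantSeq = NULL, offset = -79, up = 300,
                         down = 100, seed = 1) {
    set.seed(seed)
    L <- up + down + 1
    seqs <- vapply(seq_len(n), function(i) {
        s <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
        if (!is.null(plantSeq)) {
            b <- strsplit(plantSeq, "")[[1]]
            start <- up + 1 + offset
            s[start:(start + length(b) - 1)] <- b
        }
        paste(s, collapse = "")
    }, character(1))
    out <- Biostrings::DNAStringSet(seqs)
    names(out) <- paste0("r", seq_len(n))
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(tss = rep(up + 1L, n))
    out
}

# one full synthetic CAGE round: simulate -> cluster -> count -> DE -> sets;
# returns recovery and false-discovery proportion against the planted truth
plantedRecoveryRun <- function(seed, nGenes = 500, nUp = 12, nDown = 8,
                               lfc = 2, phi = 0.2) {
    set.seed(seed)
    ids <- sprintf("gene%04d", sample(nGenes, nUp + nDown))
    up <- ids[seq_len(nUp)]; down <- ids[-seq_len(nUp)]
    cfg <- simConfig(seed = seed, nGenes = nGenes, genomeLength = 2e6,
                     librarySize = 2e5, dispersion = phi,
                     effectTable = torporEffectTable(up = up, down = down,
                                                     lfc = lfc))
    gg <- genGenome(cfg)
    tracks <- genCTSS(cfg, gg$genome, gg$genes)
    cl <- annotateClusters(clusterCTSS(tracks), gg$genes)
    cts <- countCTSS(tracks, cl)
    normFactors(cts) <- tmmFactors(cts)
    phiHat <- estimateCommonDispersion(cts)
    ts <- torporSpecific(
        classifyReversible(nbExactTest(cts, "Pre", "Mid", phiHat),
                           nbExactTest(cts, "Mid", "Post", phiHat)),
        classifyHypometabolic(nbExactTest(cts, "HiT", "Mid", phiHat),
                              nbExactTest(cts, "Fed", "Mid", phiHat)))
    gmap <- stats::setNames(S4Vectors::mcols(cl)$gene_id,
                            S4Vectors::mcols(cl)$promoter_id)
    fu <- unique(stats::na.omit(gmap[ts$up]))
    fd <- unique(stats::na.omit(gmap[ts$down]))
    found <- length(fu) + length(fd)
    list(recovery = (sum(up %in% fu) + sum(down %in% fd)) / (nUp + nDown),
         fdp = if (found) (sum(!fu %in% up) + sum(!fd %in% down)) / found
               else 0,
         phiHat = phiHat)
}
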