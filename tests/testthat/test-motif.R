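test_that("JASPAR parsing yields valid probability matrices", {
    path <- system.file("extdata", "synthetic_motifs.jaspar",
                        package = "torporCAGE")
    pwms <- readJASPAR(path)
    expect_named(pwms, c("SYN_CRE", "SYN_TATA"))
    for (m in pwms) {
        expect_equal(colSums(m@mat), rep(1, ncol(m@mat)))
        expect_gte(ncol(m@mat), 4)
    }
    expect_equal(pwmConsensus(pwms$SYN_CRE), "TGACGTCA")

    # hand-built record parses to the hand-computed probabilities
    f <- tempfile()
    writeLines(c(">M1 test", "A [ 8 0 ]", "C [ 0 8 ]", "G [ 0 0 ]",
                 "T [ 0 0 ]"), f)
    expect_error(readJASPAR(f, pseudocount = 0), "width")  # width 2 < 4
    f2 <- tempfile()
    writeLines(c(">M2", "A  1 0 0 1", "C  0 1 0 0", "G  0 0 1 0",
                 "T  0 0 0 0"), f2)
    p2 <- readJASPAR(f2, pseudocount = 0)
    expect_equal(p2$M2@mat[, 1], c(A = 1, C = 0, G = 0, T = 0))
    expect_error(suppressWarnings(readJASPAR(tempfile())),
                 "cannot open|No such", ignore.case = TRUE)
})

test_that("region extraction is strand-aware and edge-truncated", {
    genome <- Biostrings::DNAStringSet(c(chr1 = paste(
        sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")))
    mkCl <- function(pos, strand)
        clusterCTSS(list(CTSSTrack("chr1", pos, strand, 20)), 20, 1)
    # plus strand: peak at 1000 covers bases 700..1100 (0-based)
    rp <- extractRegions(mkCl(1000, "+"), genome)
    expect_equal(Biostrings::width(rp), 401)
    expect_equal(as.character(rp[[1]]),
                 as.character(Biostrings::subseq(genome[[1]], 701, 1101)))
    expect_equal(S4Vectors::mcols(rp)$tss, 301L)
    # minus strand: reverse complement of the mirrored window
    rm <- extractRegions(mkCl(1000, "-"), genome)
    expect_equal(as.character(rm[[1]]),
                 as.character(Biostrings::reverseComplement(
                     Biostrings::subseq(genome[[1]], 901, 1301))))
    # the TSS base itself must agree between strands and genome
    expect_equal(substr(as.character(rm[[1]]),
                        S4Vectors::mcols(rm)$tss,
                        S4Vectors::mcols(rm)$tss),
                 as.character(Biostrings::complement(
                     Biostrings::subseq(genome[[1]], 1001, 1001))))
    # truncation: peak at position 50 keeps 151 bases
    rt <- extractRegions(mkCl(50, "+"), genome)
    expect_equal(Biostrings::width(rt), 151)
    expect_equal(S4Vectors::mcols(rt)$tss, 51L)
})

test_that("best-hit scanning matches the closed form and a brute oracle", {
    det <- consensusPWM("TGACGTCA")
    # consensus scores 2 bits per base
    hit <- bestHit("TGACGTCA", det)
    expect_equal(hit$score, 16)
    expect_equal(hit$offset, 0)
    # all-N region scores 0
    expect_equal(bestHit(strrep("N", 30), det)$score, 0)
    # region shorter than the motif: absent marker
    expect_true(is.na(bestHit("ACG", det)$score))

    # double-strand scan is invariant to reverse complement
    set.seed(41)
    reg <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(reg)))
    pwms <- readJASPAR(system.file("extdata", "synthetic_motifs.jaspar",
                                   package = "torporCAGE"))
    expect_equal(bestHit(reg, pwms$SYN_CRE)$score,
                 bestHit(rc, pwms$SYN_CRE)$score)

    # brute-force oracle over every offset and strand
    bruteBest <- function(region, m) {
        sc <- function(s, mat) {
            b <- strsplit(s, "")[[1]]
            sum(vapply(seq_along(b), function(k) {
                i <- match(b[k], c("A", "C", "G", "T"))
                if (is.na(i)) 0 else log2(mat[i, k] / 0.25)
            }, numeric(1)))
        }
        w <- ncol(m@mat)
        best <- -Inf
        rcm <- chartr("ACGT", "TGCA", region)
        rcm <- paste(rev(strsplit(rcm, "")[[1]]), collapse = "")
        for (o in 1:(nchar(region) - w + 1)) {
            best <- max(best, sc(substr(region, o, o + w - 1), m@mat),
                        sc(substr(rcm, o, o + w - 1), m@mat))
        }
        best
    }
    for (s in 1:5) {
        set.seed(s)
        r <- paste(sample(c("A", "C", "G", "T", "N"), 60, TRUE,
                          prob = c(rep(0.24, 4), 0.04)), collapse = "")
        expect_equal(bestHit(r, pwms$SYN_CRE)$score,
                     bruteBest(r, pwms$SYN_CRE), tolerance = 1e-10)
    }
})

test_that("motif enrichment reproduces the hypergeometric closed form", {
    det <- consensusPWM("TGACGTCA")
    fore <- plantRegions(10, "TGACGTCA", offset = -50, seed = 1)
    back <- plantRegions(10, NULL, seed = 2)
    # drop chance hits in the background for an exact (10,0/0,10) table
    keep <- vapply(seq_along(back), function(i)
        bestHit(back[[i]], det)$score < 0.99 * 16, logical(1))
    n <- min(10L, sum(keep))
    fore <- fore[seq_len(n)]
    back <- back[keep][seq_len(n)]
    enr <- motifEnrichment(fore, back, list(det), relThreshold = 0.99)
    expect_equal(enr$fg_hits, n)
    expect_equal(enr$bg_hits, 0)
    expect_equal(enr$p, 2 / choose(2 * n, n), tolerance = 1e-9)
    expect_equal(enr$p_bonferroni, pmin(1, enr$p))

    # Fisher p equals the dhyper tail-sum oracle on random tables
    set.seed(44)
    for (i in 1:100) {
        a <- sample(0:15, 1); b <- sample(0:15, 1)
        c_ <- sample(0:15, 1); d <- sample(0:15, 1)
        if ((a + b) * (c_ + d) == 0 || (a + c_) * (b + d) == 0) next
        expect_equal(stats::fisher.test(matrix(c(a, b, c_, d), 2))$p.value,
                     fisherOracle(a, c_, b, d), tolerance = 1e-7)
    }

    # null: foreground drawn from the background population
    nullF <- plantRegions(15, NULL, seed = 5)
    nullB <- plantRegions(60, NULL, seed = 6)
    e0 <- motifEnrichment(nullF, nullB, list(det), relThreshold = 0.9)
    expect_gt(e0$p_bonferroni, 0.2)
    expect_error(motifEnrichment(nullF[0], nullB, list(det)),
                 "empty foreground")
})

test_that("planted motifs are detected against a sparse background", {
    det <- consensusPWM("TGACGTCA")
    hits <- vapply(1:3, function(s) {
        withPlant <- plantRegions(60, "TGACGTCA", offset = -60,
                                  seed = 100 + s)
        noPlant <- plantRegions(140, NULL, seed = 200 + s)
        fore <- c(withPlant[1:18], noPlant[1:42])       # 30% carry the site
        back <- c(plantRegions(10, "TGACGTCA", -60, seed = 300 + s),
                  plantRegions(190, NULL, seed = 400 + s))  # 5% background
        motifEnrichment(fore, back, list(det),
                        relThreshold = 0.95)$p_bonferroni
    }, numeric(1))
    expect_true(all(hits < 0.05))
})

test_that("positional profiles localise planted sites and count hits", {
    det <- consensusPWM("TGACGTCA")
    planted <- plantRegions(25, "TGACGTCA", offset = -79, seed = 7)
    pp <- positionalProfile(planted, det, relThreshold = 0.99)
    expect_equal(pp$peakOffset, -79)
    # raw curve integrates to the mean number of hits per region
    nh <- vapply(seq_along(planted), function(i)
        length(torporCAGE:::.hitOffsets(planted[[i]], det, 0.99 * 16,
                                        301L)), numeric(1))
    expect_equal(sum(pp$profile$raw), mean(nh))

    empty <- plantRegions(10, NULL, seed = 8)
    p0 <- positionalProfile(empty, det, relThreshold = 1)
    expect_true(all(p0$profile$raw == 0))
})
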