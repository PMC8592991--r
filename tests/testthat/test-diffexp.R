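test_that("TMM factors behave on pure depth differences and match edgeR", {
    set.seed(31)
    base <- rnbinom(500, size = 5, mu = 200)
    m <- cbind(a = base, b = base)
    rownames(m) <- paste0("p", 1:500)
    expect_equal(unname(tmmFactors(m)), c(1, 1))
    # doubling depth is absorbed by the library size, not the factor
    m2 <- cbind(a = base, b = 2L * base)
    expect_equal(unname(tmmFactors(m2)), c(1, 1), tolerance = 1e-8)

    # geometric mean is 1 on arbitrary matrices
    m3 <- matrix(rnbinom(500 * 6, size = 3, mu = 150), 500, 6,
                 dimnames = list(paste0("p", 1:500), paste0("s", 1:6)))
    f <- tmmFactors(m3)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)

    skip_if_not_installed("edgeR")
    dg <- edgeR::calcNormFactors(edgeR::DGEList(m3))
    expect_equal(unname(f), dg$samples$norm.factors, tolerance = 1e-10)

    expect_error(tmmFactors(m3[, 1, drop = FALSE]), "2 samples")
    m4 <- m3; m4[, 2] <- 0L
    expect_error(tmmFactors(m4), "nonzero")
})

test_that("common dispersion is recovered by conditional likelihood", {
    set.seed(32)
    mkCounts <- function(phi, n = 500) {
        m <- if (phi == 0) matrix(rpois(n * 8, 300), n, 8)
             else matrix(rnbinom(n * 8, size = 1 / phi, mu = 300), n, 8)
        dimnames(m) <- list(paste0("p", 1:n), paste0("s", 1:8))
        PromoterCounts(m, rep(c("A", "B"), each = 4))
    }
    expect_lt(estimateCommonDispersion(mkCounts(0)), 0.05)
    phiHat <- estimateCommonDispersion(mkCounts(0.4))
    expect_gt(phiHat, 0.25); expect_lt(phiHat, 0.6)

    skip_if_not_installed("edgeR")
    x <- mkCounts(0.2)
    dg <- edgeR::estimateCommonDisp(edgeR::DGEList(
        SummarizedExperiment::assay(x, "counts"),
        group = conditions(x)))
    expect_equal(estimateCommonDispersion(x), dg$common.dispersion,
                 tolerance = 0.02)

    # single-promoter matrix still yields a finite estimate
    one <- PromoterCounts(matrix(c(10L, 14L, 9L, 30L), 1, 4,
                                 dimnames = list("p1", paste0("s", 1:4))),
                          rep(c("A", "B"), each = 2))
    expect_true(is.finite(estimateCommonDispersion(one)))
    z <- PromoterCounts(matrix(0L, 2, 4,
                               dimnames = list(c("p1", "p2"),
                                               paste0("s", 1:4))),
                        rep(c("A", "B"), each = 2))
    expect_error(estimateCommonDispersion(z), "all-zero")
})

test_that("the exact NB test is calibrated, symmetric, and Poisson-limited", {
    set.seed(33)
    n <- 1500
    m <- matrix(rpois(n * 12, 500), n, 12,
                dimnames = list(paste0("g", 1:n), paste0("s", 1:12)))
    cts <- PromoterCounts(m, rep(c("A", "B"), each = 6))
    de <- nbExactTest(cts, "A", "B", 0)
    # null calibration: p approximately uniform
    ks <- suppressWarnings(stats::ks.test(de$PValue, "punif"))
    expect_gt(ks$p.value, 0.01)

    # swapping groups preserves p and negates logFC
    sw <- nbExactTest(cts, "B", "A", 0)
    expect_equal(sw$PValue, de$PValue)
    expect_equal(sw$logFC, -de$logFC)

    # phi -> 0 limit equals the exact binomial split oracle
    oracle <- function(sA, z, nA, nB) {
        p <- stats::dbinom(0:z, z, nA / (nA + nB))
        sum(p[p <= p[sA + 1] * (1 + 1e-7)])
    }
    y <- round(sweep(m, 2, exp(mean(log(colSums(m)))) / colSums(m), "*"))
    idx <- sample(n, 40)
    po <- vapply(idx, function(g) {
        sA <- sum(y[g, 1:6]); oracle(sA, sA + sum(y[g, 7:12]), 6, 6)
    }, numeric(1))
    expect_equal(de$PValue[idx], po, tolerance = 1e-10)

    # edgeR's exact test is an independent route to the same answer
    skip_if_not_installed("edgeR")
    set.seed(34)
    m2 <- matrix(rnbinom(400 * 8, size = 5, mu = 300), 400, 8,
                 dimnames = list(paste0("g", 1:400), paste0("s", 1:8)))
    c2 <- PromoterCounts(m2, rep(c("A", "B"), each = 4))
    normFactors(c2) <- tmmFactors(c2)
    mine <- nbExactTest(c2, "A", "B", 0.2)
    dg <- edgeR::DGEList(m2, group = rep(c("A", "B"), each = 4))
    dg <- edgeR::calcNormFactors(dg)
    dg$common.dispersion <- 0.2
    et <- edgeR::exactTest(dg)
    expect_gt(cor(mine$PValue, et$table$PValue), 0.999)
    expect_gt(cor(mine$logFC, et$table$logFC), 0.999)

    expect_error(nbExactTest(cts, "A", "C", 0), "empty group")
    expect_error(nbExactTest(cts, "A", "A", 0), "disjoint")
})

test_that("BH adjustment matches the step-up recursion", {
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
    expect_equal(bhAdjust(0.2), 0.2)
    set.seed(35)
    for (i in 1:20) {
        p <- runif(sample(3:40, 1))^sample(1:3, 1)
        q <- bhAdjust(p)
        expect_equal(q, bhOracle(p))
        expect_true(all(q >= p - 1e-12) && all(q <= 1))
    }
    expect_error(bhAdjust(c(0.1, 1.2)), "\\[0, 1\\]")
    expect_error(bhAdjust(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("promoter-set classification matches exhaustive truth tables", {
    states <- expand.grid(sig1 = c(TRUE, FALSE), sgn1 = c(-1, 0, 1),
                          sig2 = c(TRUE, FALSE), sgn2 = c(-1, 0, 1))
    ids <- sprintf("p%02d", seq_len(nrow(states)))
    de1 <- mkDE(ids, states$sgn1 * 1.5, ifelse(states$sig1, 0.01, 0.5))
    de2 <- mkDE(ids, states$sgn2 * 1.5, ifelse(states$sig2, 0.01, 0.5))

    rev <- classifyReversible(de1, de2)
    hyp <- classifyHypometabolic(de1, de2)
    for (i in seq_along(ids)) {
        s <- states[i, ]
        expect_equal(ids[i] %in% rev$up,
                     s$sig1 && s$sgn1 > 0 && s$sig2 && s$sgn2 < 0)
        expect_equal(ids[i] %in% rev$down,
                     s$sig1 && s$sgn1 < 0 && s$sig2 && s$sgn2 > 0)
        expect_equal(ids[i] %in% hyp$up,
                     s$sig1 && s$sgn1 > 0 && s$sig2 && s$sgn2 > 0)
        expect_equal(ids[i] %in% hyp$down,
                     s$sig1 && s$sgn1 < 0 && s$sig2 && s$sgn2 < 0)
    }

    # intersection equals a brute-force membership scan, and is contained
    # in both inputs
    ts <- torporSpecific(rev, hyp)
    expect_setequal(ts$up, ids[ids %in% rev$up & ids %in% hyp$up])
    expect_true(all(ts$up %in% rev$up) && all(ts$up %in% hyp$up))
    expect_length(torporSpecific(list(up = "a", down = "b"),
                                 list(up = "c", down = "d"))$up, 0)

    dep <- deprivationSpecific(de1, torporSets = ts)
    expect_setequal(dep$up, ids[states$sig1 & states$sgn1 > 0])
    expect_setequal(dep$overlap_up, intersect(dep$up, ts$up))

    expect_error(classifyReversible(de1, de2[-1, ]), "universes")
})

test_that("total fold-change ranking orders by |logFC| sum with id ties", {
    de1 <- mkDE(c("a", "b", "c"), c(2, -1, 1), rep(0.01, 3))
    de2 <- mkDE(c("a", "b", "c"), c(-1, -3, -1), rep(0.01, 3))
    r <- rankByTotalFC(c("a", "b", "c"), de1, de2)
    expect_equal(r$promoter_id, c("b", "a", "c"))
    expect_equal(r$total_fc, c(4, 3, 2))
    # tie broken by id
    de3 <- mkDE(c("z", "a"), c(1, 1), c(0.01, 0.01))
    expect_equal(rankByTotalFC(c("z", "a"), de3, de3)$promoter_id,
                 c("a", "z"))
    expect_equal(rankByTotalFC("a", de1, de2)$promoter_id, "a")
    expect_error(rankByTotalFC("missing", de1, de2), "missing")
})

test_that("MDS embedding preserves leading-logFC distances", {
    set.seed(36)
    m <- matrix(rnbinom(300 * 3, size = 5, mu = 200), 300, 3,
                dimnames = list(paste0("p", 1:300), c("x", "y", "z")))
    m <- cbind(m, w = m[, "x"])                     # w duplicates x
    cts <- PromoterCounts(m, c("A", "B", "C", "A"))
    xy <- mdsEmbed(cts, top = 100)
    expect_equal(dim(xy), c(4, 2))
    # identical samples land on the same point
    expect_equal(xy["x", ], xy["w", ], tolerance = 1e-8)
    # three distinct points embed exactly in 2-D: pairwise distances match
    eff <- libSizes(cts) * normFactors(cts)
    lcpm <- log2(sweep(SummarizedExperiment::assay(cts, "counts") + 0.5,
                       2, eff + 1, "/") * 1e6)
    dOracle <- function(i, j)
        sqrt(mean(sort((lcpm[, i] - lcpm[, j])^2, decreasing = TRUE)[1:100]))
    for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
        emb <- sqrt(sum((xy[pair[1], ] - xy[pair[2], ])^2))
        expect_equal(emb, dOracle(pair[1], pair[2]), tolerance = 1e-6)
    }
})
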