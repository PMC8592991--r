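test_that("genome generation is deterministic, bounded, and size-checked", {
    cfg <- simConfig(seed = 1, nGenes = 50, genomeLength = 1e6)
    gg <- genGenome(cfg)
    expect_length(gg$genes, 50)
    expect_equal(length(gg$genome[[1]]), 1e6)
    expect_true(all(GenomicRanges::start(gg$genes) >= 1))
    expect_true(all(GenomicRanges::end(gg$genes) <= 1e6))
    expect_false(any(duplicated(S4Vectors::mcols(gg$genes)$gene_id)))

    # byte-identical FASTA/GTF for the same seed
    f1 <- tempfile(); f2 <- tempfile(); g1 <- tempfile(); g2 <- tempfile()
    gg2 <- genGenome(cfg)
    Biostrings::writeXStringSet(gg$genome, f1)
    Biostrings::writeXStringSet(gg2$genome, f2)
    writeGTF(gg$genes, g1); writeGTF(gg2$genes, g2)
    expect_identical(readBin(f1, "raw", 2e6), readBin(f2, "raw", 2e6))
    expect_identical(readLines(g1), readLines(g2))

    expect_error(genGenome(simConfig(seed = 1, nGenes = 500,
                                     genomeLength = 1e5)),
                 "too short")
})

test_that("CTSS generation respects limits, effects, and the seed", {
    # Poisson singleton limit: phi = 0, infinite concentration
    cfg0 <- simConfig(seed = 3, nGenes = 30, genomeLength = 1e5,
                      design = c(Pre = 2L, Mid = 2L), dispersion = 0,
                      shapeConcentration = Inf, librarySize = 3e4)
    gg <- genGenome(cfg0)
    tr <- genCTSS(cfg0, gg$genome, gg$genes)
    # every promoter's tags fall on exactly one base (the annotated TSS)
    expect_true(all(vapply(tr, length, integer(1)) <= 30))
    tss <- sort(ifelse(as.character(GenomicRanges::strand(gg$genes)) == "+",
                       GenomicRanges::start(gg$genes) - 1L,
                       GenomicRanges::end(gg$genes) - 1L))
    expect_true(all(GenomicRanges::start(tr[[1]]) - 1L %in% tss))

    # determinism
    tr2 <- genCTSS(cfg0, gg$genome, gg$genes)
    expect_identical(tr, tr2)

    # a +2 log2 effect in Mid quadruples the Mid/Pre mean ratio; averaging
    # over 150 planted promoters stands in for repeated simulation
    n <- 150
    cfgE <- simConfig(seed = 5, nGenes = n, genomeLength = 4e5,
                      design = c(Pre = 4L, Mid = 4L), dispersion = 0.05,
                      shapeConcentration = Inf, librarySize = 2e5,
                      effectTable = torporEffectTable(
                          up = sprintf("gene%04d", seq_len(n)), lfc = 2))
    ggE <- genGenome(cfgE)
    trE <- genCTSS(cfgE, ggE$genome, ggE$genes)
    cl <- clusterCTSS(trE, minTags = 1)
    m <- SummarizedExperiment::assay(countCTSS(trE, cl), "counts")
    pre <- rowMeans(m[, 1:4]); mid <- rowMeans(m[, 5:8])
    ratio <- mid[pre > 20] / pre[pre > 20]
    expect_gt(median(ratio), 3.2)
    expect_lt(median(ratio), 4.8)

    # unknown condition label is a design error
    expect_error(simConfig(design = c(Pre = 4L, Torpid = 4L)), "conditions")
})

test_that("generated counts are NB-calibrated and SI tracks concentration", {
    # marginal variance ~ mu + phi mu^2 across promoters
    phi <- 0.3
    cfg <- simConfig(seed = 11, nGenes = 250, genomeLength = 6e5,
                     dispersion = phi, shapeConcentration = Inf,
                     librarySize = 1e5)
    gg <- genGenome(cfg)
    tr <- genCTSS(cfg, gg$genome, gg$genes)
    cl <- clusterCTSS(tr, minTags = 1)
    m <- SummarizedExperiment::assay(countCTSS(tr, cl), "counts")
    mu <- rowMeans(m); v <- apply(m, 1, var)
    sel <- mu > 50
    ratio <- v[sel] / (mu[sel] + phi * mu[sel]^2)
    expect_gt(median(ratio), 0.7)
    expect_lt(median(ratio), 1.4)

    # median realized SI increases monotonically with concentration
    med_si <- vapply(c(0.5, 5, 50, Inf), function(conc) {
        cfgS <- simConfig(seed = 7, nGenes = 80, genomeLength = 2e5,
                          design = c(Mid = 2L), shapeConcentration = conc,
                          librarySize = 1e5)
        ggS <- genGenome(cfgS)
        clS <- shapeIndex(clusterCTSS(genCTSS(cfgS, ggS$genome, ggS$genes),
                                      minTags = 5))
        median(S4Vectors::mcols(clS)$SI, na.rm = TRUE)
    }, numeric(1))
    expect_true(all(diff(med_si) > 0))
    expect_equal(med_si[4], 2)      # singleton limit
    expect_lt(med_si[1], -1)        # broad-shape regime
})

test_that("physiological traces have the stated grid, bouts, and errors", {
    tr <- genPhysio(seed = 2)
    expect_equal(nrow(tr), 2160)                     # 3 x 24 x 10
    expect_equal(diff(tr$time_h[1:2]), 0.1)

    # without bouts, day 2 is statistically indistinguishable from day 1
    ks <- vapply(1:5, function(s) {
        x <- genPhysio(seed = s)
        suppressWarnings(stats::ks.test(x$vo2_ml_min[x$time_h < 24],
                 x$vo2_ml_min[x$time_h >= 24 & x$time_h < 48])$p.value)
    }, numeric(1))
    expect_gt(median(ks), 0.01)

    # a depth-0.3 bout at ZT-16 halves the day-2 minimum VO2
    trb <- genPhysio(seed = 2, bouts = data.frame(start = 40, end = 42,
                                                  depth = 0.3))
    d1 <- trb$vo2_ml_min[trb$time_h < 24]
    d2 <- trb$vo2_ml_min[trb$time_h >= 24 & trb$time_h < 48]
    expect_lt(min(d2), 0.5 * median(d1))
    # T_B relaxes towards ambient inside the bout
    expect_lt(min(trb$tb_c[trb$time_h >= 40 & trb$time_h < 42]), 30)

    expect_error(genPhysio(seed = 1, noiseTb = 0), "positive")
    expect_error(genPhysio(seed = 1,
                           bouts = data.frame(start = 10, end = 12,
                                              depth = 0.3)),
                 "days 2")
    expect_error(genPhysio(seed = 1,
                           bouts = data.frame(start = c(30, 31),
                                              end = c(32, 33),
                                              depth = 0.3)),
                 "overlap")
})

test_that("KO phenotype tables follow the two-state generative model", {
    dn <- list("021a", c("wt", "hom"))
    beta <- matrix(c(0, 1), 1, 2, dimnames = dn)
    gamma <- matrix(c(-10, -6), 1, 2, dimnames = dn)

    # noiseless limit: observations equal alpha + beta (+ gamma)
    t0 <- genKOPhenotypes(37, beta, gamma, 0, 0, nPerCell = 3, seed = 1)
    expect_equal(t0$y[t0$state == "NORMAL" & t0$allele == "hom"],
                 rep(38, 3))
    expect_equal(t0$y[t0$state == "TORPOR" & t0$allele == "wt"],
                 rep(27, 3))

    # CLT bound: torpor - normal differences estimate gamma within 0.4
    # at n = 20, sigma = 0.5
    t1 <- genKOPhenotypes(37, beta, gamma, 0.5, 0.5, nPerCell = 20,
                          seed = 4)
    wt <- t1[t1$allele == "wt", ]
    d <- tapply(wt$y, wt$state, mean)
    expect_lt(abs((d[["TORPOR"]] - d[["NORMAL"]]) - (-10)), 0.4)

    expect_identical(genKOPhenotypes(37, beta, gamma, 1, 1, 5, seed = 9),
                     genKOPhenotypes(37, beta, gamma, 1, 1, 5, seed = 9))
    expect_error(genKOPhenotypes(37, beta, gamma, -1, 1, 5, 1), "sigma")
    expect_error(genKOPhenotypes(37, beta, gamma, 1, 1, 0, 1), "n >= 1")
})
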