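#' Simulation configuration for the synthetic study design
#'
#' Bundles every knob of the synthetic-data generators.  The defaults mirror
#' the study design the pipeline targets: six metabolic conditions with
#' group sizes Pre = 4, Mid = 8, Post = 4, HiT = 4, Fed = 4, Dep = 4
#' (Mid = torpid animals; HiT/Fed = torpor-prevented; Dep = torpor-deprived).
#'
#' @slot seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @slot nGenes number of gene models / promoters.
#' @slot genomeLength chromosome length in bp (must be >= 2000 x nGenes).
#' @slot design named integer vector: samples per condition.  Names must be
#'   drawn from `Pre, Mid, Post, HiT, Fed, Dep`.
#' @slot effectTable data.frame with columns `promoter_id`, `condition`,
#'   `log2fc`: per-condition log2 fold effects on promoter expression
#'   relative to baseline.  Conditions absent from the table have effect 0.
#' @slot dispersion negative-binomial dispersion phi (>= 0; 0 = Poisson).
#' @slot shapeConcentration positive real controlling tag-profile sharpness:
#'   large values give singleton-like promoters (shape index near 2), small
#'   values broad promoters (`Inf` = all tags on one base).
#' @slot librarySize expected tags per sample.
#' @export
setClass("SimConfig",
         representation(seed = "integer", nGenes = "integer",
                        genomeLength = "integer", design = "integer",
                        effectTable = "data.frame", dispersion = "numeric",
                        shapeConcentration = "numeric",
                        librarySize = "numeric"))

.CONDITIONS <- c("Pre", "Mid", "Post", "HiT", "Fed", "Dep")

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@genomeLength < 1L) msg <- c(msg, "genomeLength must be >= 1")
    if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
    if (object@shapeConcentration <= 0)
        msg <- c(msg, "shapeConcentration must be > 0")
    if (object@librarySize < 1) msg <- c(msg, "librarySize must be >= 1")
    if (is.null(names(object@design)) ||
        !all(names(object@design) %in% .CONDITIONS))
        msg <- c(msg, paste("design conditions must be among:",
                            paste(.CONDITIONS, collapse = ", ")))
    if (any(object@design < 1L)) msg <- c(msg, "all group sizes must be >= 1")
    et <- object@effectTable
    if (nrow(et)) {
        if (!all(c("promoter_id", "condition", "log2fc") %in% names(et)))
            msg <- c(msg, "effectTable needs promoter_id, condition, log2fc")
        else if (!all(et$condition %in% .CONDITIONS))
            msg <- c(msg, "effectTable conditions outside the vocabulary")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes on",
        round(object@genomeLength / 1e6, 2), "Mbp; seed", object@seed, "\n")
    cat("  design:", paste(names(object@design), object@design,
                           sep = "=", collapse = " "), "\n")
    cat("  phi =", object@dispersion,
        " library =", format(object@librarySize, big.mark = ","),
        " planted effects:", nrow(object@effectTable), "\n")
    invisible(NULL)
})

#' @rdname SimConfig-class
#' @param seed,nGenes,genomeLength,design,effectTable,dispersion
#'   see the class slots.
#' @param shapeConcentration,librarySize see the class slots.
#' @return A validated `SimConfig`.
#' @examples
#' cfg <- simConfig(seed = 1, nGenes = 50, genomeLength = 1e6)
#' @export
simConfig <- function(seed = 1L, nGenes = 500L, genomeLength = 2e6,
                      design = c(Pre = 4L, Mid = 8L, Post = 4L,
                                 HiT = 4L, Fed = 4L, Dep = 4L),
                      effectTable = data.frame(promoter_id = character(),
                                               condition = character(),
                                               log2fc = numeric()),
                      dispersion = 0.2, shapeConcentration = 5,
                      librarySize = 2e5) {
    new("SimConfig", seed = as.integer(seed), nGenes = as.integer(nGenes),
        genomeLength = as.integer(genomeLength),
        design = structure(as.integer(design), names = names(design)),
        effectTable = effectTable, dispersion = dispersion,
        shapeConcentration = shapeConcentration, librarySize = librarySize)
}

#' Effect table planting torpor-specific promoters
#'
#' Convenience builder for the commonest simulation scenario: promoters
#' whose expression changes in the torpid (Mid) state only, which downstream
#' classification should recover as torpor-specific.  A promoter with a
#' +2 effect is 4-fold up in Mid relative to every non-torpid condition,
#' hence reversible (Pre->Mid up, Mid->Post down) and hypometabolic
#' (HiT->Mid and Fed->Mid up).
#'
#' @param up,down promoter ids planted up-/down-regulated in Mid.
#' @param lfc absolute log2 fold change of the planted effect.
#' @return data.frame usable as `effectTable` of [simConfig()].
#' @export
torporEffectTable <- function(up = character(), down = character(), lfc = 2) {
    data.frame(
        promoter_id = c(up, down),
        condition = rep("Mid", length(up) + length(down)),
        log2fc = c(rep(lfc, length(up)), rep(-lfc, length(down))))
}

#' Generate a synthetic genome and gene annotation
#'
#' Produces one random-base chromosome and `nGenes` non-overlapping gene
#' models with defined 5' ends, alternating between strands.  Gene bodies
#' are 1 kb and each gene sits in its own `genomeLength / nGenes` slot, so
#' promoter regions never collide.
#'
#' @param config a [simConfig()].
#' @return list with `genome` (a [Biostrings::DNAStringSet], one
#'   chromosome `chr1`) and `genes` (a `GRanges` with `gene_id` metadata;
#'   the 5' end of each range is the annotated TSS).
#' @examples
#' gg <- genGenome(simConfig(seed = 1, nGenes = 20, genomeLength = 1e5))
#' @export
genGenome <- function(config) {
    stopifnot(is(config, "SimConfig"))
    n <- config@nGenes
    L <- config@genomeLength
    if (L < n * 2000L)
        stop("genome too short: need >= ", n * 2000L, " bp for ", n, " genes")
    set.seed(config@seed)
    chrom <- Biostrings::DNAStringSet(paste(
        sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))
    names(chrom) <- "chr1"
    slot_w <- L %/% n
    slot0 <- (seq_len(n) - 1L) * slot_w          # 0-based slot starts
    body_w <- 1000L
    # gene body placed away from slot edges so -300/+100 windows fit
    offset <- sample(400L:(slot_w - body_w - 400L), n, replace = TRUE)
    gstart <- slot0 + offset                      # 0-based body start
    strand <- sample(c("+", "-"), n, replace = TRUE)
    gr <- GRanges("chr1", IRanges(gstart + 1L, gstart + body_w),
                  strand = strand)
    GenomeInfoDb::seqlengths(gr) <- c(chr1 = L)
    mcols(gr)$gene_id <- sprintf("gene%04d", seq_len(n))
    list(genome = chrom, genes = gr)
}

#' Annotated TSS (5' end) of gene models, 0-based
#' @param genes `GRanges` of gene bodies with strand.
#' @return integer vector of 0-based TSS positions.
#' @keywords internal
geneTSS0 <- function(genes) {
    ifelse(as.character(strand(genes)) == "+",
           start(genes) - 1L, end(genes) - 1L)
}

#' Generate per-sample CTSS tracks
#'
#' Draws CAGE tag counts per promoter and sample from a negative binomial
#' with mean `baseline x 2^effect(condition)` and dispersion
#' `config@dispersion`, then spreads each promoter's tags over positions
#' within +/-50 bp of the annotated 5' end by a Dirichlet-multinomial.
#' The per-gene positional weights are drawn once (promoter architecture is
#' a property of the promoter, not of the sample) from a symmetric Dirichlet
#' with parameter `1 / shapeConcentration`: large concentration values give
#' near-singleton profiles, small ones broad profiles.
#' `shapeConcentration = Inf` puts every tag on the annotated TSS base.
#'
#' Baseline promoter expression levels are drawn from a log-normal
#' (sdlog 1) and scaled so the expected total per sample is
#' `config@librarySize`.
#'
#' @param config a [simConfig()].
#' @param genome,genes output of [genGenome()].
#' @return named list of [CTSSTrack-class], one per sample, named
#'   `<condition>_<replicate>`.
#' @export
genCTSS <- function(config, genome, genes) {
    stopifnot(is(config, "SimConfig"))
    et <- config@effectTable
    if (nrow(et) && !all(et$promoter_id %in% mcols(genes)$gene_id))
        stop("effectTable promoter ids must be a subset of gene ids")
    n <- length(genes)
    set.seed(config@seed + 1L)
    w <- stats::rlnorm(n, 0, 1)
    base_mu <- config@librarySize * w / sum(w)    # baseline mean per promoter

    # fixed per-gene positional profiles over offsets -50..50
    K <- 101L
    conc <- config@shapeConcentration
    profiles <- lapply(seq_len(n), function(i) {
        if (is.infinite(conc)) { p <- numeric(K); p[51L] <- 1; p }
        else {
            g <- stats::rgamma(K, shape = 1 / conc, rate = 1)
            if (all(g == 0)) g[51L] <- 1
            g / sum(g)
        }
    })

    tss0 <- geneTSS0(genes)
    gstrand <- as.character(strand(genes))
    gid <- mcols(genes)$gene_id
    L <- config@genomeLength
    phi <- config@dispersion

    samples <- unlist(lapply(names(config@design), function(cond)
        paste0(cond, "_", seq_len(config@design[[cond]]))))
    condition_of <- sub("_[0-9]+$", "", samples)

    eff <- matrix(0, n, length(.CONDITIONS),
                  dimnames = list(gid, .CONDITIONS))
    if (nrow(et))
        eff[cbind(match(et$promoter_id, gid),
                  match(et$condition, .CONDITIONS))] <- et$log2fc

    offsets <- -50L:50L
    tracks <- vector("list", length(samples))
    names(tracks) <- samples
    for (s in seq_along(samples)) {
        mu <- base_mu * 2^eff[, condition_of[s]]
        tot <- if (phi == 0) stats::rpois(n, mu)
               else stats::rnbinom(n, size = 1 / phi, mu = mu)
        pos_l <- vector("list", n); cnt_l <- vector("list", n)
        for (i in which(tot > 0L)) {
            k <- stats::rmultinom(1, tot[i], profiles[[i]])[, 1]
            nz <- which(k > 0L)
            p0 <- if (gstrand[i] == "+") tss0[i] + offsets[nz]
                  else tss0[i] - offsets[nz]
            keep <- p0 >= 0L & p0 < L
            pos_l[[i]] <- p0[keep]; cnt_l[[i]] <- k[nz][keep]
        }
        pos <- unlist(pos_l); cnt <- unlist(cnt_l)
        str <- rep(gstrand, lengths(pos_l))
        # collapse duplicates (adjacent genes could in principle collide)
        key <- paste(pos, str)
        agg <- rowsum(cnt, key)
        first <- !duplicated(key)
        tracks[[s]] <- CTSSTrack("chr1", pos[first], str[first],
                                 agg[match(key[first], rownames(agg)), 1],
                                 seqlengths = c(chr1 = L))
    }
    tracks
}

#' Generate a synthetic physiological trace
#'
#' Emulates three days of telemetry at 6-min resolution (720 points/day):
#' body temperature and oxygen consumption follow a circadian sinusoid
#' (peak in the dark phase) plus Gaussian noise; within torpor bouts, VO2 is
#' multiplied by `depth` instantaneously while T_B relaxes towards the
#' ambient temperature with first-order kinetics (time constant `tauMin`
#' minutes), recovering the same way after the bout.
#'
#' @param seed integer seed.
#' @param days recording length in days (default 3).
#' @param bouts data.frame with columns `start`, `end` (hours since
#'   recording start; must lie in days 2-3, i.e. >= 24 h) and `depth`
#'   (VO2 multiplier, default column value 0.3: the torpid metabolic rate
#'   is below 30 percent of normal).
#' @param mesorTb,ampTb mesor and circadian amplitude of T_B (deg C).
#' @param mesorVo2,ampVo2 mesor and amplitude of VO2 (mL/min).
#' @param noiseTb,noiseVo2 Gaussian noise SDs (must be > 0).
#' @param ta ambient temperature (deg C).
#' @param tauMin T_B relaxation time constant in minutes.
#' @return data.frame (`time_h`, `tb_c`, `vo2_ml_min`, `ta_c`) with the
#'   bout table attached as attribute `"bouts"`; `720 * days` rows.
#' @examples
#' tr <- genPhysio(seed = 1, bouts = data.frame(start = 40, end = 42,
#'                                              depth = 0.3))
#' @export
genPhysio <- function(seed = 1L, days = 3, bouts = NULL,
                      mesorTb = 37, ampTb = 1.2, mesorVo2 = 1.5,
                      ampVo2 = 0.4, noiseTb = 0.25, noiseVo2 = 0.08,
                      ta = 21, tauMin = 30) {
    if (noiseTb <= 0 || noiseVo2 <= 0) stop("noise scales must be positive")
    if (is.null(bouts))
        bouts <- data.frame(start = numeric(), end = numeric(),
                            depth = numeric())
    if (nrow(bouts)) {
        if (any(bouts$start < 24) || any(bouts$end > days * 24))
            stop("bout windows must lie within days 2-", days)
        if (any(bouts$end <= bouts$start)) stop("bout end must exceed start")
        o <- order(bouts$start)
        if (any(bouts$start[o][-1] < bouts$end[o][-nrow(bouts)]))
            stop("bout windows must not overlap")
    }
    set.seed(seed)
    t <- seq(0, by = 0.1, length.out = as.integer(720 * days))
    zt <- t %% 24
    # nocturnal animal: circadian peak in the dark phase (around ZT 18)
    circ <- cos(2 * pi * (zt - 18) / 24)
    tb_base <- mesorTb + ampTb * circ
    vo2_base <- mesorVo2 + ampVo2 * circ

    in_bout <- rep(FALSE, length(t))
    depth <- rep(1, length(t))
    for (b in seq_len(nrow(bouts))) {
        idx <- t >= bouts$start[b] & t < bouts$end[b]
        in_bout[idx] <- TRUE
        depth[idx] <- bouts$depth[b]
    }
    vo2 <- vo2_base * depth
    # first-order relaxation of T_B: towards T_A inside bouts, back to the
    # circadian baseline outside
    tb <- tb_base
    if (any(in_bout)) {
        tau_h <- tauMin / 60
        decay <- exp(-0.1 / tau_h)
        tb[1] <- if (in_bout[1]) ta else tb_base[1]
        for (k in 2:length(t)) {
            target <- if (in_bout[k]) ta else tb_base[k]
            tb[k] <- target + (tb[k - 1] - target) * decay
        }
    }
    data.frame(time_h = t,
               tb_c = tb + stats::rnorm(length(t), 0, noiseTb),
               vo2_ml_min = pmax(vo2 + stats::rnorm(length(t), 0, noiseVo2),
                                 0.01),
               ta_c = ta) |>
        structure(bouts = bouts)
}

#' Generate a knockout phenotype table
#'
#' Generative twin of the hierarchical phenotype model: for animal i in
#' line g with allele a,
#' `Y_NORMAL ~ Normal(alpha + beta[g,a], sigmaNormal)` and
#' `Y_TORPOR ~ Normal(alpha + beta[g,a] + gamma[g,a], sigmaTorpor)`.
#' Each animal contributes one row per state (long format).
#'
#' @param alpha global mean of the normal-state minimum phenotype.
#' @param beta,gamma numeric matrices (lines x alleles, dimnames required)
#'   of baseline offsets and torpor effects.
#' @param sigmaNormal,sigmaTorpor residual SDs (>= 0; 0 gives the noiseless
#'   limit).
#' @param nPerCell animals per (line, allele) cell (>= 1).
#' @param seed integer seed.
#' @return data.frame `animal_id, line, allele, state, y`.
#' @examples
#' b <- matrix(0, 1, 2, dimnames = list("021a", c("wt", "hom")))
#' g <- matrix(c(-10, -7), 1, 2, dimnames = dimnames(b))
#' genKOPhenotypes(37, b, g, 0.5, 1, nPerCell = 5, seed = 1)
#' @export
genKOPhenotypes <- function(alpha, beta, gamma, sigmaNormal, sigmaTorpor,
                            nPerCell = 10L, seed = 1L) {
    if (sigmaNormal < 0 || sigmaTorpor < 0) stop("sigma must be >= 0")
    if (nPerCell < 1L) stop("need n >= 1 per (line, allele) cell")
    stopifnot(identical(dimnames(beta), dimnames(gamma)))
    set.seed(seed)
    lines <- rownames(beta); alleles <- colnames(beta)
    rows <- expand.grid(line = lines, allele = alleles,
                        rep = seq_len(nPerCell), stringsAsFactors = FALSE)
    mu_n <- alpha + beta[cbind(rows$line, rows$allele)]
    mu_t <- mu_n + gamma[cbind(rows$line, rows$allele)]
    id <- sprintf("%s_%s_%02d", rows$line, rows$allele, rows$rep)
    data.frame(
        animal_id = rep(id, 2L),
        line = rep(rows$line, 2L),
        allele = rep(rows$allele, 2L),
        state = rep(c("NORMAL", "TORPOR"), each = nrow(rows)),
        y = c(stats::rnorm(nrow(rows), mu_n, sigmaNormal),
              stats::rnorm(nrow(rows), mu_t, sigmaTorpor)))
}
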