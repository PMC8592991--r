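#' Run the end-to-end torpor promoter pipeline on synthetic data
#'
#' Orchestrates the full study flow: simulate inputs, call and annotate
#' promoters, differential expression over the five study contrasts,
#' promoter-set classification, motif enrichment, torpor detection from a
#' physiological trace, and the knockout phenotype model.  Every stage
#' writes TSV/BED/FASTA outputs into `outdir` with provenance headers
#' (stage, parameters, seed), and reruns with the same configuration are
#' bit-identical for the deterministic stages.
#'
#' @param outdir output directory (created if absent).
#' @param config a [simConfig()]; its seed drives every stage.
#' @param stages character subset of
#'   `c("ctss", "de", "sets", "motif", "physio", "phen")`; the simulate
#'   stage always runs (it feeds everything else).  Toggling a stage off
#'   skips its outputs only.
#' @param maxGap,minTags clustering parameters (see [clusterCTSS()]).
#' @param fdr significance threshold for the promoter sets.
#' @param ci credible level for torpor detection.
#' @param mcmcDraws,mcmcWarmup sampler sizes for the Bayesian stages
#'   (reduced defaults keep the run light; raise for production use).
#' @param pwms named list of [PWM-class] for the motif stage; defaults to
#'   the synthetic demo motifs shipped with the package.
#' @return (invisibly) a list with the in-memory stage results
#'   (`clusters`, `counts`, `de`, `sets`, `enrichment`, `torporCalls`,
#'   `koSummary`, paths of written files).  A stage failure writes a
#'   machine-readable `error.json` record into `outdir` (stage + message),
#'   keeps earlier outputs, and rethrows the error.
#' @export
runPipeline <- function(outdir, config = simConfig(),
                        stages = c("ctss", "de", "sets", "motif",
                                   "physio", "phen"),
                        maxGap = 20L, minTags = 10L, fdr = 0.05,
                        ci = 0.999, mcmcDraws = 400L, mcmcWarmup = 400L,
                        pwms = NULL) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    seed <- config@seed
    res <- list()
    stage <- "simulate"
    tryCatch({
        gg <- genGenome(config)
        tracks <- genCTSS(config, gg$genome, gg$genes)
        Biostrings::writeXStringSet(gg$genome, file.path(outdir, "genome.fa"))
        writeGTF(gg$genes, file.path(outdir, "genes.gtf"))
        ctssdir <- file.path(outdir, "ctss")
        dir.create(ctssdir, showWarnings = FALSE)
        for (s in names(tracks))
            writeCTSS(tracks[[s]], file.path(ctssdir, paste0(s, ".ctss.bed")))
        sheet <- data.frame(sample_id = names(tracks),
                            condition = sub("_[0-9]+$", "", names(tracks)))
        writeStageTSV(sheet, file.path(outdir, "sample_sheet.tsv"),
                      "simulate", list(n_genes = config@nGenes), seed)
        res$tracks <- tracks; res$genome <- gg$genome; res$genes <- gg$genes

        if ("ctss" %in% stages) {
            stage <- "ctss"
            cl <- clusterCTSS(tracks, maxGap = maxGap, minTags = minTags)
            cl <- annotateClusters(cl, gg$genes)
            cl <- shapeIndex(cl)
            cl <- gcContent(cl, gg$genome)
            writePromoterBED(cl, file.path(outdir, "promoters.bed"))
            writeStageTSV(
                data.frame(promoter_id = mcols(cl)$promoter_id,
                           gene_id = mcols(cl)$gene_id,
                           SI = mcols(cl)$SI, gc = mcols(cl)$gc),
                file.path(outdir, "promoter_features.tsv"), "ctss",
                list(max_gap = maxGap, min_tags = minTags), seed)
            res$clusters <- cl
        }

        if ("de" %in% stages) {
            stage <- "de"
            if (is.null(res$clusters))
                stop("de stage needs the ctss stage")
            counts <- countCTSS(tracks, res$clusters)
            normFactors(counts) <- tmmFactors(counts)
            phi <- estimateCommonDispersion(counts)
            contrasts <- list(Mid_vs_Pre = c("Pre", "Mid"),
                              Post_vs_Mid = c("Mid", "Post"),
                              Mid_vs_HiT = c("HiT", "Mid"),
                              Mid_vs_Fed = c("Fed", "Mid"),
                              Dep_vs_Mid = c("Mid", "Dep"))
            contrasts <- contrasts[vapply(contrasts, function(ab)
                all(ab %in% conditions(counts)), logical(1))]
            de <- lapply(contrasts, function(ab)
                nbExactTest(counts, ab[1], ab[2], phi))
            for (nm in names(de))
                writeStageTSV(de[[nm]],
                              file.path(outdir, paste0("de_", nm, ".tsv")),
                              "de", list(dispersion = signif(phi, 4)), seed)
            res$counts <- counts; res$de <- de; res$dispersion <- phi
        }

        if ("sets" %in% stages) {
            stage <- "sets"
            de <- res$de
            if (is.null(de)) stop("sets stage needs the de stage")
            rev <- classifyReversible(de$Mid_vs_Pre, de$Post_vs_Mid, fdr)
            hyp <- classifyHypometabolic(de$Mid_vs_HiT, de$Mid_vs_Fed, fdr)
            tor <- torporSpecific(rev, hyp)
            dep <- if (!is.null(de$Dep_vs_Mid))
                deprivationSpecific(de$Dep_vs_Mid, fdr, tor) else NULL
            sets <- list(reversible = rev, hypometabolic = hyp,
                         torpor_specific = tor, deprivation = dep)
            memb <- do.call(rbind, lapply(names(sets), function(nm) {
                s <- sets[[nm]]
                if (is.null(s)) return(NULL)
                data.frame(set = nm,
                           direction = rep(c("up", "down"),
                                           c(length(s$up), length(s$down))),
                           promoter_id = c(s$up, s$down))
            }))
            if (is.null(memb))
                memb <- data.frame(set = character(),
                                   direction = character(),
                                   promoter_id = character())
            writeStageTSV(memb, file.path(outdir, "promoter_sets.tsv"),
                          "sets", list(fdr = fdr), seed)
            res$sets <- sets
        }

        if ("motif" %in% stages) {
            stage <- "motif"
            if (is.null(res$clusters)) stop("motif stage needs ctss")
            if (is.null(pwms))
                pwms <- readJASPAR(system.file("extdata",
                                               "synthetic_motifs.jaspar",
                                               package = "torporCAGE"))
            regions <- extractRegions(res$clusters, res$genome)
            fg_ids <- if (!is.null(res$sets))
                unique(unlist(res$sets$torpor_specific)) else character()
            if (length(fg_ids) >= 2L) {
                enr <- motifEnrichment(regions[names(regions) %in% fg_ids],
                                       regions, pwms,
                                       backgroundIsUniverse = TRUE)
                writeStageTSV(enr, file.path(outdir, "motif_enrichment.tsv"),
                              "motif", list(n_motifs = length(pwms)), seed)
                res$enrichment <- enr
            }
            prof <- positionalProfile(regions, pwms[[1]])
            writeStageTSV(prof$profile,
                          file.path(outdir, "motif_profile.tsv"), "motif",
                          list(motif = pwms[[1]]@id,
                               peak_offset = prof$peakOffset), seed)
            res$profile <- prof
        }

        if ("physio" %in% stages) {
            stage <- "physio"
            trace <- genPhysio(seed = seed,
                               bouts = data.frame(start = 38, end = 44,
                                                  depth = 0.3))
            fits <- list(tb = fitBaseline(trace, "tb", ci = ci,
                                          draws = mcmcDraws,
                                          warmup = mcmcWarmup, seed = seed),
                         vo2 = fitBaseline(trace, "vo2", ci = ci,
                                           draws = mcmcDraws,
                                           warmup = mcmcWarmup, seed = seed))
            calls <- detectTorpor(trace, fits)
            writeStageTSV(cbind(trace[c("time_h", "tb_c", "vo2_ml_min")],
                                calls[c("eligible", "torpor")]),
                          file.path(outdir, "torpor_calls.tsv"), "physio",
                          list(ci = ci), seed)
            res$trace <- trace; res$torporCalls <- calls
            res$minPhenotype <- minPhenotype(trace, calls)
        }

        if ("phen" %in% stages) {
            stage <- "phen"
            dn <- list("021a", c("wt", "het", "hom"))
            beta <- matrix(0, 1, 3, dimnames = dn)
            gamma <- matrix(c(-10, -8, -6), 1, 3, dimnames = dn)
            tab <- genKOPhenotypes(37, beta, gamma, 0.5, 1,
                                   nPerCell = 8, seed = seed)
            fit <- fitKOModel(tab, chains = 2L, draws = mcmcDraws,
                              warmup = mcmcWarmup, seed = seed)
            summ <- posteriorSummary(fit)
            writeStageTSV(summ, file.path(outdir, "ko_posterior.tsv"),
                          "phen", list(chains = 2, draws = mcmcDraws), seed)
            res$koFit <- fit; res$koSummary <- summ
        }
    }, error = function(e) {
        jsonlite::write_json(list(stage = stage,
                                  message = conditionMessage(e)),
                             file.path(outdir, "error.json"),
                             auto_unbox = TRUE)
        stop(e)
    })
    invisible(res)
}
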