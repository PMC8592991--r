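#' Write a CTSS track as CTSS BED
#'
#' Format: `chrom  start  end  name  count  strand`, 0-based half-open,
#' `end = start + 1`; `start` is the TSS base.
#'
#' @param track a [CTSSTrack-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCTSS <- function(track, path) {
    df <- data.frame(chrom = as.character(seqnames(track)),
                     start = start(track) - 1L,
                     end = start(track),
                     name = paste0("ctss_", seq_along(track)),
                     count = mcols(track)$count,
                     strand = as.character(strand(track)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read a CTSS BED file
#'
#' Strict parser with line-numbered errors: six tab-separated fields,
#' `end == start + 1`, strand `+`/`-`, positive integer counts.
#'
#' @param path input file.
#' @param seqlengths optional named chromosome lengths.
#' @return a [CTSSTrack-class].
#' @export
readCTSS <- function(path, seqlengths = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 6L)
    if (length(bad))
        stop(path, " line ", bad[1], ": expected 6 tab-separated fields")
    m <- do.call(rbind, parts)
    start <- suppressWarnings(as.integer(m[, 2]))
    end <- suppressWarnings(as.integer(m[, 3]))
    count <- suppressWarnings(as.numeric(m[, 5]))
    bad <- which(is.na(start) | is.na(end) | end != start + 1L)
    if (length(bad))
        stop(path, " line ", bad[1], ": start/end must be integers with ",
             "end == start + 1")
    bad <- which(!m[, 6] %in% c("+", "-"))
    if (length(bad))
        stop(path, " line ", bad[1], ": malformed strand field '",
             m[bad[1], 6], "'")
    bad <- which(is.na(count) | count <= 0)
    if (length(bad))
        stop(path, " line ", bad[1], ": counts must be positive")
    CTSSTrack(m[, 1], start, m[, 6], count, seqlengths = seqlengths)
}

#' Write gene models as GTF
#'
#' One `gene` feature line per range with a `gene_id` attribute.
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGTF <- function(genes, path) {
    lines <- sprintf('%s\ttorporCAGE\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                     as.character(seqnames(genes)), start(genes),
                     end(genes), as.character(strand(genes)),
                     mcols(genes)$gene_id)
    writeLines(lines, path)
    invisible(path)
}

#' Read gene models from GTF
#'
#' Parses `gene` (or, failing that, `transcript`) features and their
#' `gene_id` attributes.
#'
#' @param path input file.
#' @return `GRanges` with `gene_id` metadata.
#' @export
readGTF <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 9L)
    if (length(bad))
        stop(path, " line ", bad[1], ": expected 9 tab-separated fields")
    m <- do.call(rbind, lapply(parts, function(p) p[1:9]))
    feat <- m[, 3]
    use <- feat == "gene"
    if (!any(use)) use <- feat == "transcript"
    if (!any(use)) stop("no gene/transcript features in ", path)
    m <- m[use, , drop = FALSE]
    gid <- sub('.*gene_id[ ="]+([^";]+)[";].*', "\\1", m[, 9])
    gr <- GRanges(m[, 1], IRanges(as.integer(m[, 4]), as.integer(m[, 5])),
                  strand = m[, 7])
    mcols(gr)$gene_id <- gid
    gr
}

#' Write a stage output table with a provenance header
#'
#' The header comments name the producing stage, its parameters and the
#' seed, so every output file is reconstructible from the logged
#' configuration.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param stage producing stage name.
#' @param params named list of parameters to log.
#' @param seed integer seed to log.
#' @return `path`, invisibly.
#' @export
writeStageTSV <- function(df, path, stage, params = list(), seed = NA) {
    hdr <- c(paste0("# stage: ", stage),
             paste0("# params: ",
                    paste(names(params), unlist(params), sep = "=",
                          collapse = " ")),
             paste0("# seed: ", seed))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a stage output table, skipping provenance comments
#' @param path input file.
#' @return data.frame.
#' @export
readStageTSV <- function(path)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)

#' Write promoters as BED6
#'
#' `name` = promoter id, `score` = pooled tag count, thick columns absent.
#'
#' @param clusters a [TagClusters-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePromoterBED <- function(clusters, path) {
    df <- data.frame(chrom = as.character(seqnames(clusters)),
                     start = start(clusters) - 1L,
                     end = end(clusters),
                     name = mcols(clusters)$promoter_id,
                     score = mcols(clusters)$score,
                     strand = as.character(strand(clusters)))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}
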