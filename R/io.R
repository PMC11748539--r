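## Readers and writers for the package's tab-separated dialects.

.readTsv <- function(path, ...) {
    if (!file.exists(path)) stop("file not found: ", path)
    utils::read.delim(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Write a report table as TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(x, path) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read MAG annotation tables
#'
#' Expects a tab-separated file with header columns \code{mag_id},
#' \code{gene_id}, \code{label}, \code{length_bp}, \code{transcribed_low},
#' \code{transcribed_high}, \code{completeness_pct},
#' \code{contamination_pct}, \code{taxonomy} (semicolon-separated seven
#' ranks); one row per gene, MAG-level fields repeated.
#'
#' @param path input TSV path.
#' @return list of [MAGProfile-class] objects.
#' @export
readMagTable <- function(path) {
    df <- .readTsv(path)
    need <- c("mag_id", "gene_id", "label", "length_bp")
    miss <- setdiff(need, names(df))
    if (length(miss))
        stop("MAG table lacks column(s): ", paste(miss, collapse = ", "))
    lapply(split(df, df$mag_id)[unique(df$mag_id)], function(d) {
        tax <- strsplit(as.character(d$taxonomy[1L] %||% ""), ";",
                        fixed = TRUE)[[1L]]
        MAGProfile(
            d$mag_id[1L],
            data.frame(gene_id = d$gene_id,
                       label = ifelse(is.na(d$label) | d$label == "",
                                      NA_character_, d$label),
                       length_bp = d$length_bp,
                       transcribed_low = as.logical(
                           d$transcribed_low %||% FALSE),
                       transcribed_high = as.logical(
                           d$transcribed_high %||% FALSE)),
            taxonomy = tax,
            completeness = as.numeric(d$completeness_pct[1L] %||% 100),
            contamination = as.numeric(d$contamination_pct[1L] %||% 0))
    })
}

#' Write MAG profiles as an annotation table
#'
#' @param profiles list of [MAGProfile-class] objects.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeMagTable <- function(profiles, path) {
    rows <- lapply(profiles, function(p) {
        g <- p@genes
        data.frame(mag_id = p@magId, gene_id = g$gene_id,
                   label = ifelse(is.na(g$label), "", g$label),
                   length_bp = g$length_bp,
                   transcribed_low = g$transcribed_low,
                   transcribed_high = g$transcribed_high,
                   completeness_pct = p@completeness,
                   contamination_pct = p@contamination,
                   taxonomy = paste(p@taxonomy, collapse = ";"))
    })
    writeReport(do.call(rbind, rows), path)
}

#' Read an amplicon count table and its sample metadata
#'
#' The counts file has taxa as rows (first column taxon ids), one column
#' per sample, and a \code{taxonomy} column with semicolon-separated seven
#' ranks (the common biom-style TSV export). The metadata sheet maps
#' \code{sample_id} to \code{day} and \code{series}.
#'
#' @param counts_path counts TSV path.
#' @param metadata_path sample metadata TSV path.
#' @return an [AmpliconExperiment-class].
#' @export
readAmpliconTable <- function(counts_path, metadata_path) {
    df <- .readTsv(counts_path)
    if (!"taxonomy" %in% names(df))
        stop("amplicon counts file lacks a 'taxonomy' column")
    meta <- .readTsv(metadata_path)
    miss <- setdiff(c("sample_id", "day", "series"), names(meta))
    if (length(miss))
        stop("sample metadata lacks column(s): ",
             paste(miss, collapse = ", "))
    taxon_id <- df[[1L]]
    sample_cols <- intersect(names(df), meta$sample_id)
    if (!length(sample_cols))
        stop("no counts column matches a metadata sample_id")
    counts <- as.matrix(df[, sample_cols, drop = FALSE])
    rownames(counts) <- taxon_id
    ranks <- do.call(rbind, lapply(strsplit(df$taxonomy, ";", fixed = TRUE),
                                   function(v) c(v, rep("", 7L))[1:7]))
    taxonomy <- as.data.frame(ranks)
    names(taxonomy) <- TAXONOMY_RANKS
    m <- meta[match(sample_cols, meta$sample_id), ]
    AmpliconExperiment(counts, taxonomy,
                       data.frame(day = m$day, series = m$series,
                                  row.names = sample_cols))
}

#' Write an AmpliconExperiment as counts + metadata TSVs
#'
#' @param x an [AmpliconExperiment-class].
#' @param counts_path,metadata_path output paths.
#' @return \code{counts_path}, invisibly.
#' @export
writeAmpliconTable <- function(x, counts_path, metadata_path) {
    tax <- apply(as.data.frame(rowData(x))[, TAXONOMY_RANKS], 1L,
                 paste, collapse = ";")
    df <- data.frame(taxon_id = rownames(x), assay(x, "counts"),
                     taxonomy = tax, check.names = FALSE)
    writeReport(df, counts_path)
    meta <- data.frame(sample_id = colnames(x),
                       day = colData(x)$day, series = colData(x)$series)
    writeReport(meta, metadata_path)
    invisible(counts_path)
}

#' Read a transcript count matrix and its sample sheet
#'
#' Dense input: a TSV with columns \code{gene_id}, \code{mag_id},
#' \code{label}, \code{length_bp} followed by one column per sample.
#' Sparse input: a matrix-market \code{.mtx} file plus a sidecar gene table
#' with the same four columns (rows in matrix order). The sample sheet maps
#' \code{sample_id} to \code{condition} and \code{day}.
#'
#' @param counts_path counts TSV or \code{.mtx} path.
#' @param samples_path sample sheet TSV path.
#' @param genes_path sidecar gene table (required for \code{.mtx} input).
#' @return a [TranscriptCounts-class].
#' @export
readCountMatrix <- function(counts_path, samples_path, genes_path = NULL) {
    meta <- .readTsv(samples_path)
    miss <- setdiff(c("sample_id", "condition", "day"), names(meta))
    if (length(miss))
        stop("sample sheet lacks column(s): ", paste(miss, collapse = ", "))
    if (grepl("\\.mtx$", counts_path)) {
        if (is.null(genes_path))
            stop("matrix-market input needs a sidecar gene table")
        m <- as.matrix(Matrix::readMM(counts_path))
        genes <- .readTsv(genes_path)
        if (nrow(genes) != nrow(m))
            stop("gene table rows do not match matrix rows")
        colnames(m) <- meta$sample_id[seq_len(ncol(m))]
        rownames(m) <- genes$gene_id
    } else {
        df <- .readTsv(counts_path)
        need <- c("gene_id", "mag_id", "label", "length_bp")
        miss <- setdiff(need, names(df))
        if (length(miss))
            stop("counts file lacks column(s): ",
                 paste(miss, collapse = ", "))
        genes <- df[, need]
        sample_cols <- intersect(names(df), meta$sample_id)
        m <- as.matrix(df[, sample_cols, drop = FALSE])
        rownames(m) <- df$gene_id
    }
    genes$label[is.na(genes$label) | genes$label == ""] <- NA_character_
    meta <- meta[match(colnames(m), meta$sample_id), ]
    tc <- TranscriptCounts(
        m, genes[, c("mag_id", "label", "length_bp")],
        data.frame(condition = meta$condition, day = meta$day,
                   row.names = colnames(m)))
    rownames(tc) <- genes$gene_id
    tc
}

#' Write a transcript count matrix and its sample sheet
#'
#' @param x a [TranscriptCounts-class].
#' @param counts_path,samples_path output paths.
#' @return \code{counts_path}, invisibly.
#' @export
writeCountMatrix <- function(x, counts_path, samples_path) {
    rd <- as.data.frame(rowData(x))
    df <- data.frame(gene_id = rownames(x), mag_id = rd$mag_id,
                     label = ifelse(is.na(rd$label), "", rd$label),
                     length_bp = rd$length_bp, assay(x, "counts"),
                     check.names = FALSE)
    writeReport(df, counts_path)
    meta <- data.frame(sample_id = colnames(x),
                       condition = colData(x)$condition,
                       day = colData(x)$day)
    writeReport(meta, samples_path)
    invisible(counts_path)
}
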