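## Expression layer: RPKM quantification, median-of-ratios normalization, a
## simplified negative-binomial Wald test of HIGH vs LOW cable-bacteria
## abundance, and per-MAG aggregation of EET/shuttle expression.

#' Construct a TranscriptCounts container
#'
#' @param counts integer matrix, genes x samples; row names gene ids,
#'   column names sample ids.
#' @param genes data.frame with columns \code{mag_id}, \code{label}
#'   (ortholog label or \code{NA}) and \code{length_bp}, one row per count
#'   row.
#' @param samples data.frame with columns \code{condition} (\code{"LOW"} =
#'   day-3 samples, \code{"HIGH"} = day-26/33 samples) and \code{day}.
#' @return a [TranscriptCounts-class].
#' @export
TranscriptCounts <- function(counts, genes, samples) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("gene%04d", seq_len(nrow(counts)))
    rownames(counts) <- make.unique(rownames(counts))
    genes <- as.data.frame(genes)
    rownames(genes) <- rownames(counts)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(genes),
        colData = DataFrame(as.data.frame(samples)))
    as(se, "TranscriptCounts")
}

#' Reads per kilobase per million mapped reads
#'
#' \code{counts * 1e9 / (length_bp * library_size)}, computed per gene and
#' sample.
#'
#' @param x a [TranscriptCounts-class].
#' @return numeric matrix of RPKM values.
#' @export
rpkm <- function(x) {
    stopifnot(is(x, "TranscriptCounts"))
    cts <- assay(x, "counts")
    lib <- colSums(cts)
    if (any(lib <= 0))
        stop("sample(s) with zero library size: ",
             paste(colnames(cts)[lib <= 0], collapse = ", "))
    len <- rowData(x)$length_bp
    sweep(cts / len, 2L, lib, "/") * 1e9
}

#' @describeIn nbDiffTest median-of-ratios size factors. Each sample's
#'   factor is the median, over genes with positive counts in every sample,
#'   of the ratio of its count to the gene's geometric mean; factors are
#'   rescaled to geometric mean one. When no gene is positive everywhere the
#'   method falls back to upper-quartile normalization with a warning.
#' @importFrom BiocGenerics sizeFactors
#' @exportMethod sizeFactors
#' @aliases sizeFactors,TranscriptCounts-method
setMethod("sizeFactors", "TranscriptCounts", function(object) {
    cts <- assay(object, "counts")
    pos <- rowSums(cts > 0) == ncol(cts)
    if (any(pos)) {
        m <- cts[pos, , drop = FALSE]
        ref <- exp(rowMeans(log(m)))
        sf <- apply(m / ref, 2L, stats::median)
    } else {
        warning("no gene with positive counts in all samples; ",
                "falling back to upper-quartile normalization")
        sf <- apply(cts, 2L, function(v) stats::quantile(v[v > 0], 0.75))
    }
    sf <- sf / exp(mean(log(sf)))
    names(sf) <- colnames(cts)
    sf
})

## Per-gene NB dispersion: method-of-moments on normalized counts (pooled
## within-condition variance), shrunk 50/50 toward a trend given by the mean
## raw dispersion of the 50 genes nearest in mean normalized count.
.dispersionEstimates <- function(norm, condition, n_neighbors = 50L,
                                 floor = 1e-8) {
    mu <- rowMeans(norm)
    groups <- split(seq_len(ncol(norm)), condition)
    ## method of moments around each condition's own mean, pooled by
    ## degrees of freedom; the denominator correction m^2 - s2/n removes
    ## most of the small-sample bias from the mean-variance correlation
    num <- matrix(0, nrow(norm), length(groups))
    for (k in seq_along(groups)) {
        j <- groups[[k]]
        n_c <- length(j)
        m <- rowMeans(norm[, j, drop = FALSE])
        s2 <- rowSums((norm[, j, drop = FALSE] - m)^2) / (n_c - 1L)
        den <- m^2 - s2 / n_c
        num[, k] <- ifelse(m > 0 & den > 0, (s2 - m) / den, NA_real_) *
            (n_c - 1L)
    }
    df <- matrix(rep(vapply(groups, length, 1L) - 1L, each = nrow(norm)),
                 nrow(norm))
    df[is.na(num)] <- 0
    num[is.na(num)] <- 0
    raw <- rowSums(num) / pmax(rowSums(df), 1L)
    raw <- pmax(raw, floor)
    ord <- order(mu)
    k <- min(n_neighbors, length(raw))
    trend <- numeric(length(raw))
    half <- k %/% 2L
    for (r in seq_along(ord)) {
        lo <- max(1L, min(r - half, length(ord) - k + 1L))
        trend[ord[r]] <- mean(raw[ord[lo:(lo + k - 1L)]])
    }
    pmax(0.5 * raw + 0.5 * trend, floor)
}

## Wald test for one gene at fixed dispersion; offsets are log size factors.
## Falls back to a delta-method Wald on continuity-corrected group means when
## the GLM cannot be fit (e.g. a group of all-zero counts).
.nbWaldGene <- function(y, cond, sf, disp) {
    fit <- tryCatch(
        suppressWarnings(stats::glm(y ~ cond, offset = log(sf),
                                    family = MASS::negative.binomial(
                                        theta = 1 / disp))),
        error = function(e) NULL)
    ok <- !is.null(fit) && fit$converged &&
        all(is.finite(stats::coef(fit)))
    beta <- se <- NA_real_
    if (ok) {
        sm <- summary(fit, dispersion = 1)$coefficients
        beta <- sm["condHIGH", "Estimate"]
        se <- sm["condHIGH", "Std. Error"]
    }
    if (!ok || !is.finite(se) || se <= 0) {
        yn <- y / sf
        m <- tapply(yn, cond, mean)
        n <- tapply(yn, cond, length)
        eps <- 0.5 / mean(sf)
        beta <- log((m["HIGH"] + eps) / (m["LOW"] + eps))
        se <- sqrt(sum(1 / n * (1 / (m + eps) + disp)))
    }
    z <- beta / se
    c(lfc = beta / log(2), p = 2 * stats::pnorm(-abs(z)))
}

#' Negative-binomial differential-expression test, HIGH vs LOW
#'
#' A deliberately simple, fully specified test of per-gene transcript
#' abundance between high (days 26, 33) and low (day 3) cable-bacteria
#' abundance: median-of-ratios size factors, method-of-moments dispersions
#' shrunk 50/50 toward a 50-nearest-gene mean-count trend, a Wald test on
#' the NB GLM log fold change (log link, size-factor offsets), and
#' Benjamini-Hochberg adjustment across the tested genes. Genes with
#' all-zero counts are excluded from the family. This is not a
#' re-implementation of any published differential-expression package; it
#' captures the same inferential structure (NB counts, shared dispersion
#' information, Wald + FDR) with desk-checkable arithmetic.
#'
#' @param x a [TranscriptCounts-class] with at least two samples per
#'   condition.
#' @param alpha adjusted-p significance level for \code{significant_high}.
#' @return data.frame with one row per tested gene: \code{gene_id},
#'   \code{mag_id}, \code{label}, \code{base_mean},
#'   \code{log2_fold_change} (HIGH over LOW), \code{p_value},
#'   \code{p_adjusted}, \code{significant_high}.
#' @export
nbDiffTest <- function(x, alpha = 0.05) {
    stopifnot(is(x, "TranscriptCounts"))
    cond <- factor(colData(x)$condition, levels = c("LOW", "HIGH"))
    if (any(table(cond) < 2L))
        stop("need at least 2 samples per condition")
    cts <- assay(x, "counts")
    tested <- rowSums(cts) > 0
    cts <- cts[tested, , drop = FALSE]
    sf <- sizeFactors(x)
    norm <- sweep(cts, 2L, sf, "/")
    disp <- .dispersionEstimates(norm, cond)
    stats_m <- vapply(seq_len(nrow(cts)), function(i)
        .nbWaldGene(cts[i, ], cond, sf, disp[i]), c(lfc = 0, p = 0))
    rd <- rowData(x)[tested, , drop = FALSE]
    out <- data.frame(gene_id = rownames(cts),
                      mag_id = rd$mag_id, label = rd$label,
                      base_mean = rowMeans(norm),
                      log2_fold_change = stats_m["lfc", ],
                      p_value = stats_m["p", ])
    out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
    out$significant_high <- out$p_adjusted < alpha &
        out$log2_fold_change > 0
    rownames(out) <- NULL
    out
}

#' Per-MAG summed RPKM of pcc or shuttle genes, with top-k ranking
#'
#' Sums RPKM over the catalog's pcc (or electron-shuttle) genes per MAG,
#' averages within each cable-bacteria abundance condition, and ranks MAGs
#' by their summed expression across conditions. The top \code{k} MAGs are
#' reported individually and the remainder pooled as \code{"Other MAGs"};
#' ties break deterministically by MAG id.
#'
#' @param x a [TranscriptCounts-class].
#' @param catalog an [EETCatalog-class].
#' @param gene_class \code{"PCC"} or \code{"SHUTTLE"}.
#' @param k number of MAGs reported individually (default 5).
#' @return data.frame with columns \code{mag_id}, \code{gene_class},
#'   \code{rpkm_low}, \code{rpkm_high}, \code{total} and \code{rank}
#'   (\code{NA} for the pooled remainder row).
#' @export
aggregateMagExpression <- function(x, catalog,
                                   gene_class = c("PCC", "SHUTTLE"),
                                   k = 5L) {
    gene_class <- match.arg(gene_class)
    class_labels <- if (gene_class == "PCC") pccLabels(catalog) else
        shuttleLabels(catalog)
    canon <- canonicalLabel(catalog, rowData(x)$label)
    keep <- !is.na(canon) & canon %in% class_labels
    cond <- colData(x)$condition
    mags <- sort(unique(as.character(rowData(x)$mag_id)))
    r <- rpkm(x)[keep, , drop = FALSE]
    mag_of <- as.character(rowData(x)$mag_id)[keep]
    per_mag <- function(m, cnd) {
        rows <- mag_of == m; cols <- cond == cnd
        if (!any(rows)) 0 else mean(colSums(r[rows, cols, drop = FALSE]))
    }
    out <- data.frame(
        mag_id = mags, gene_class = gene_class,
        rpkm_low = vapply(mags, per_mag, 0, cnd = "LOW"),
        rpkm_high = vapply(mags, per_mag, 0, cnd = "HIGH"))
    out$total <- out$rpkm_low + out$rpkm_high
    out <- out[order(-out$total, out$mag_id), , drop = FALSE]
    out$rank <- seq_len(nrow(out))
    if (nrow(out) > k) {
        top <- out[seq_len(k), , drop = FALSE]
        rest <- out[-seq_len(k), , drop = FALSE]
        pooled <- data.frame(mag_id = "Other MAGs", gene_class = gene_class,
                             rpkm_low = sum(rest$rpkm_low),
                             rpkm_high = sum(rest$rpkm_high),
                             total = sum(rest$total), rank = NA_integer_)
        out <- rbind(top, pooled)
    }
    rownames(out) <- NULL
    out
}
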