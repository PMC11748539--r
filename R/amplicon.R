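## Genus-level abundance-correlation screen against the focal cable-bacteria
## genus: fractional abundance, pruning, agglomeration, prevalence filter,
## day-window restriction, Spearman correlation and multiple-testing
## adjustment.

#' Construct an AmpliconExperiment
#'
#' @param counts integer matrix, taxa x samples. Row names are taxon ids,
#'   column names sample ids.
#' @param taxonomy data.frame with the seven rank columns
#'   \code{domain, phylum, class, order, family, genus, species}; empty
#'   strings mark unclassified ranks. One row per count row.
#' @param samples data.frame with columns \code{day} and \code{series}, one
#'   row per count column.
#' @return an [AmpliconExperiment-class].
#' @export
AmpliconExperiment <- function(counts, taxonomy, samples) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("taxon%03d", seq_len(nrow(counts)))
    rownames(counts) <- make.unique(rownames(counts))
    taxonomy <- as.data.frame(taxonomy)
    for (r in setdiff(TAXONOMY_RANKS, names(taxonomy))) taxonomy[[r]] <- ""
    taxonomy[is.na(taxonomy)] <- ""
    rownames(taxonomy) <- rownames(counts)
    se <- SummarizedExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(taxonomy[, TAXONOMY_RANKS, drop = FALSE]),
        colData = DataFrame(samples))
    as(se, "AmpliconExperiment")
}

#' Per-sample fractional abundances
#'
#' Divides each sample's counts by its library size so every column sums to
#' one.
#'
#' @param x an [AmpliconExperiment-class] or a count matrix.
#' @return numeric matrix of fractions, same dimensions as the counts.
#' @export
fractionalAbundance <- function(x) {
    cts <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else
        as.matrix(x)
    tot <- colSums(cts)
    zero <- tot <= 0
    if (any(zero))
        stop("sample(s) with zero total counts: ",
             paste(colnames(cts)[zero], collapse = ", "))
    sweep(cts, 2L, tot, "/")
}

#' Prune unclassified taxa and agglomerate to genus level
#'
#' Taxa with an empty genus rank are removed first; the remaining taxa are
#' then summed per genus (so unclassified reads never inflate any genus).
#' The lineage above genus is taken from the first member taxon of each
#' genus and the species rank is cleared.
#'
#' @param x an [AmpliconExperiment-class] at any taxon resolution.
#' @return an [AmpliconExperiment-class] with one row per genus; a warning
#'   is emitted (and an empty table returned) when no taxon is classified to
#'   genus.
#' @export
pruneAndAgglomerate <- function(x) {
    stopifnot(is(x, "AmpliconExperiment"))
    genus <- rowData(x)$genus
    keep <- !is.na(genus) & genus != ""
    if (!any(keep)) {
        warning("no taxa classified to genus level; returning empty table")
        empty <- x[0L, ]
        rownames(empty) <- character(0)
        return(empty)
    }
    x <- x[keep, ]
    genus <- rowData(x)$genus
    cts <- rowsum(assay(x, "counts"), group = genus, reorder = TRUE)
    first <- !duplicated(genus)
    tax <- as.data.frame(rowData(x))[first, , drop = FALSE]
    tax <- tax[match(rownames(cts), tax$genus), , drop = FALSE]
    tax$species <- ""
    AmpliconExperiment(cts, tax, as.data.frame(colData(x)))
}

#' Screen configuration
#'
#' @param min_fraction fractional-abundance threshold a genus must exceed
#'   (strictly) to count as present in a sample; default 0.0009 (0.09\%).
#' @param min_samples_exceeding number of samples the threshold must be
#'   exceeded in, strictly more than; default 3, i.e. at least 4 samples.
#' @param rho_threshold minimum Spearman rho for a positive pass; default
#'   0.6.
#' @param alpha_adjusted adjusted-p significance level; default 0.05.
#' @param adjust multiple-testing adjustment, \code{"BH"} (default) or
#'   \code{"holm"}.
#' @param window optional length-2 day interval (inclusive) restricting the
#'   samples, e.g. \code{c(3, 33)} for a growth phase.
#' @param series optional series label restricting the samples before
#'   windowing.
#' @param prevalence_on_window logical; evaluate the prevalence filter on
#'   the windowed samples (default) rather than the whole series.
#' @return a list of class \code{screen_config}.
#' @export
screenConfig <- function(min_fraction = 0.0009, min_samples_exceeding = 3L,
                         rho_threshold = 0.6, alpha_adjusted = 0.05,
                         adjust = c("BH", "holm"), window = NULL,
                         series = NULL, prevalence_on_window = TRUE) {
    stopifnot(min_fraction > 0, min_fraction < 1,
              alpha_adjusted > 0, alpha_adjusted < 1)
    structure(list(min_fraction = min_fraction,
                   min_samples_exceeding = as.integer(min_samples_exceeding),
                   rho_threshold = rho_threshold,
                   alpha_adjusted = alpha_adjusted,
                   adjust = match.arg(adjust), window = window,
                   series = series,
                   prevalence_on_window = isTRUE(prevalence_on_window)),
              class = "screen_config")
}

#' Prevalence filter
#'
#' Keeps genera whose fractional abundance exceeds
#' \code{config$min_fraction} in strictly more than
#' \code{config$min_samples_exceeding} samples. The focal genus is always
#' retained (with a warning if it fails the filter).
#'
#' @param x a genus-level [AmpliconExperiment-class].
#' @param config a [screenConfig()] list.
#' @param focal optional focal genus name to retain unconditionally.
#' @return the filtered [AmpliconExperiment-class].
#' @export
prevalenceFilter <- function(x, config = screenConfig(), focal = NULL) {
    frac <- fractionalAbundance(x)
    n_exceed <- rowSums(frac > config$min_fraction)
    keep <- n_exceed > config$min_samples_exceeding
    if (!is.null(focal)) {
        is_focal <- .matchGenus(rowData(x)$genus, focal)
        if (any(is_focal & !keep))
            warning(sprintf("focal genus '%s' fails the prevalence filter; ",
                            focal), "retained anyway")
        keep <- keep | is_focal
    }
    x[keep, ]
}

.matchGenus <- function(genera, target) {
    tolower(trimws(genera)) == tolower(trimws(target))
}

## all permutations of 1..n as an n! x n index matrix (n <= 9)
.allPerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- .allPerms(n - 1L)
    out <- matrix(0L, nrow(sub) * n, n)
    for (k in seq_len(n)) {
        rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
        out[rows, 1L] <- k
        body <- sub
        body[body >= k] <- body[body >= k] + 1L
        out[rows, -1L] <- body
    }
    out
}

## Spearman rho (average ranks) plus two-sided p: exact permutation null for
## n <= 9, t approximation otherwise
.spearman <- function(x, y, exact_max_n = 9L, perms = NULL) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
        return(list(rho = NA_real_, p = NA_real_))
    rho <- stats::cor(rx, ry)
    if (n <= exact_max_n) {
        if (is.null(perms)) perms <- .allPerms(n)
        rxs <- (rx - mean(rx)) / stats::sd(rx)
        rys <- (ry - mean(ry)) / stats::sd(ry)
        rho_null <- as.vector(matrix(rxs[perms], nrow = nrow(perms)) %*%
                                  rys) / (n - 1)
        p <- mean(abs(rho_null) >= abs(rho) - 1e-12)
    } else {
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    list(rho = rho, p = p)
}

#' Genus-level Spearman correlation screen against a focal genus
#'
#' Restricts samples to the configured series/day window, applies the
#' prevalence filter, and tests every remaining non-focal genus for
#' monotone association with the focal genus's fractional abundance
#' (Spearman correlation, average-rank ties; exact permutation p-values for
#' nine or fewer samples, t approximation otherwise). P-values are adjusted
#' across all tested genera; a genus passes when its adjusted p is below
#' \code{alpha_adjusted} and rho is positive and at least
#' \code{rho_threshold}. Genera with zero rank variance in the window are
#' skipped with a diagnostic and excluded from the adjustment family.
#'
#' @param x a genus-level [AmpliconExperiment-class] (see
#'   [pruneAndAgglomerate()]).
#' @param focal focal genus name (case-insensitive exact match).
#' @param config a [screenConfig()] list.
#' @return data.frame with one row per tested genus: \code{genus},
#'   \code{rho}, \code{p_value}, \code{p_adjusted}, \code{n_samples},
#'   \code{passes}, \code{window}. Skipped zero-variance genera are listed
#'   in \code{attr(, "skipped")}.
#' @export
correlationScreen <- function(x, focal, config = screenConfig()) {
    stopifnot(is(x, "AmpliconExperiment"))
    if (!is.null(config$series))
        x <- x[, colData(x)$series %in% config$series]
    if (!is.null(config$window)) {
        stopifnot(length(config$window) == 2L)
        d <- colData(x)$day
        x <- x[, d >= config$window[1L] & d <= config$window[2L]]
    }
    if (ncol(x) < 4L)
        stop("fewer than 4 samples in the screening window")
    if (!any(.matchGenus(rowData(x)$genus, focal)))
        stop(sprintf("focal genus '%s' not present in the table", focal))
    x <- prevalenceFilter(x, config, focal = focal)

    frac <- fractionalAbundance(x)
    genera <- rowData(x)$genus
    is_focal <- .matchGenus(genera, focal)
    fx <- colSums(frac[is_focal, , drop = FALSE])
    others <- which(!is_focal)
    n <- ncol(frac)
    perms <- if (n <= 9L) .allPerms(n) else NULL

    res <- lapply(others, function(i) {
        s <- .spearman(fx, frac[i, ], perms = perms)
        data.frame(genus = genera[i], rho = s$rho, p_value = s$p,
                   n_samples = n)
    })
    out <- do.call(rbind, res)
    if (is.null(out))
        out <- data.frame(genus = character(0), rho = numeric(0),
                          p_value = numeric(0), n_samples = integer(0))
    skipped <- out$genus[is.na(out$rho)]
    out <- out[!is.na(out$rho), , drop = FALSE]
    out$p_adjusted <- stats::p.adjust(out$p_value, method = config$adjust)
    out$passes <- out$rho >= config$rho_threshold & out$rho > 0 &
        out$p_adjusted < config$alpha_adjusted
    out$window <- if (is.null(config$window)) "full" else
        paste(config$window, collapse = ":")
    out <- out[order(out$p_adjusted, -out$rho, out$genus),
               c("genus", "rho", "p_value", "p_adjusted", "n_samples",
                 "passes", "window")]
    rownames(out) <- NULL
    attr(out, "skipped") <- as.character(skipped)
    out
}
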