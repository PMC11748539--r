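#' @import methods
#' @importFrom BiocGenerics sizeFactors
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData
NULL

#' Recognised functional role tags for catalog labels
#'
#' Structural and functional roles a catalog label can carry: the three
#' structural slots of a porin-cytochrome complex (\code{PORIN},
#' \code{PERIPLASMIC_ANCHOR}, \code{OMC}), inner-membrane/periplasmic
#' conduits, electron-shuttle synthesis/export groups, flagellar-assembly
#' genes, and \code{ACCESSORY} for declared labels that fill no structural
#' slot (e.g. periplasmic carriers excluded from complexes).
#'
#' @export
ROLE_TAGS <- c("PORIN", "OMC", "PERIPLASMIC_ANCHOR", "IM_P_CONDUIT",
               "SHUTTLE_SYNTH_FLAVIN", "SHUTTLE_SYNTH_PHENAZINE",
               "SHUTTLE_EXPORT", "MOTILITY_FLAGELLAR", "ACCESSORY")

#' Candidate-flocker evidence tiers, weakest to strongest
#'
#' Tiers are nested: every \code{SUPPORTED_CANDIDATE} satisfies the
#' \code{ACTIVE_CANDIDATE} predicate, and every \code{ACTIVE_CANDIDATE}
#' satisfies the \code{CANDIDATE} predicate.
#'
#' @export
FLOCKER_TIERS <- c("NOT_CANDIDATE", "CANDIDATE", "ACTIVE_CANDIDATE",
                   "SUPPORTED_CANDIDATE")

## ---------------------------------------------------------------------------
## ComplexDefinition

#' A named porin-cytochrome complex definition
#'
#' @slot name complex name, e.g. \code{"MtrCAB"}.
#' @slot origin model organism the complex is described from.
#' @slot required canonical ortholog labels that must all be present for the
#'   complex to be complete.
#' @slot slotRoles named character vector mapping each required label to the
#'   structural slot it fills.
#' @slot completeAlone \code{TRUE} only for single-gene membrane/cell-wall
#'   spanning complexes.
#' @exportClass ComplexDefinition
setClass("ComplexDefinition",
    representation(name = "character", origin = "character",
                   required = "character", slotRoles = "character",
                   completeAlone = "logical"))

setValidity("ComplexDefinition", function(object) {
    msg <- NULL
    if (length(object@name) != 1L || !nzchar(object@name))
        msg <- c(msg, "complex must have a single non-empty name")
    if (length(object@required) == 0L)
        msg <- c(msg, sprintf("complex '%s': required gene set is empty",
                              object@name))
    if (anyDuplicated(object@required))
        msg <- c(msg, sprintf("complex '%s': duplicated required genes",
                              object@name))
    if (isTRUE(object@completeAlone) && length(object@required) != 1L)
        msg <- c(msg, sprintf(
            "complex '%s': complete_alone requires exactly one gene",
            object@name))
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## EETCatalog

#' Controlled vocabulary of EET-relevant genes and complex definitions
#'
#' Holds the ortholog labels the rule engine understands, their functional
#' roles, synonym resolution, the canonical complex definitions, the hybrid
#' slot assignments, the flagellar-assembly gene set used for motility
#' scoring, and the electron-shuttle gene groups.
#'
#' Construct with [loadCatalog()] or [defaultCatalog()]; never fill slots by
#' hand.
#'
#' @slot labels canonical label spellings.
#' @slot roles named list, canonical label -> character vector of role tags.
#' @slot synonyms named character vector, normalized alias -> canonical label.
#' @slot complexes list of [ComplexDefinition-class] objects.
#' @slot hybridSlots list with character elements \code{porin}, \code{anchor},
#'   \code{omc}: the labels allowed to fill each hybrid slot.
#' @slot flagellarSet flagellar-assembly labels (55 in the default catalog).
#' @slot shuttleRules named list of shuttle gene groups.
#' @slot excluded labels barred from complexes and hybrid slots.
#' @exportClass EETCatalog
setClass("EETCatalog",
    representation(labels = "character", roles = "list",
                   synonyms = "character", complexes = "list",
                   hybridSlots = "list", flagellarSet = "character",
                   shuttleRules = "list", excluded = "character"))

setValidity("EETCatalog", function(object) {
    msg <- NULL
    if (anyDuplicated(object@labels))
        msg <- c(msg, "duplicated canonical labels")
    bad <- setdiff(unique(unlist(object@roles)), ROLE_TAGS)
    if (length(bad))
        msg <- c(msg, paste0("unknown role tag(s): ",
                             paste(bad, collapse = ", ")))
    untagged <- setdiff(object@labels, names(object@roles))
    no_role <- names(object@roles)[lengths(object@roles) == 0L]
    if (length(untagged) || length(no_role))
        msg <- c(msg, paste0("labels without a role tag: ",
                             paste(c(untagged, no_role), collapse = ", ")))
    for (cx in object@complexes) {
        undeclared <- setdiff(cx@required, object@labels)
        if (length(undeclared))
            msg <- c(msg, sprintf(
                "complex '%s' references undeclared label(s): %s",
                cx@name, paste(undeclared, collapse = ", ")))
        barred <- intersect(cx@required, object@excluded)
        if (length(barred))
            msg <- c(msg, sprintf(
                "complex '%s' uses excluded label(s): %s",
                cx@name, paste(barred, collapse = ", ")))
    }
    if (length(object@complexes) &&
        anyDuplicated(vapply(object@complexes, slot, "", "name")))
        msg <- c(msg, "duplicated complex names")
    for (s in c("porin", "anchor", "omc")) {
        undeclared <- setdiff(object@hybridSlots[[s]], object@labels)
        if (length(undeclared))
            msg <- c(msg, sprintf("hybrid slot '%s' has undeclared label(s): %s",
                                  s, paste(undeclared, collapse = ", ")))
        barred <- intersect(object@hybridSlots[[s]], object@excluded)
        if (length(barred))
            msg <- c(msg, sprintf("hybrid slot '%s' uses excluded label(s): %s",
                                  s, paste(barred, collapse = ", ")))
    }
    if (anyDuplicated(object@flagellarSet))
        msg <- c(msg, "duplicated flagellar labels")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "EETCatalog", function(object) {
    cat("EETCatalog with", length(object@labels), "labels,",
        length(object@complexes), "complex definitions\n")
    cat("  pcc labels:      ", length(pccLabels(object)), "\n")
    cat("  conduit labels:  ",
        sum(vapply(object@roles, function(r) "IM_P_CONDUIT" %in% r, NA)), "\n")
    cat("  shuttle labels:  ", length(shuttleLabels(object)), "\n")
    cat("  flagellar set:   ", length(object@flagellarSet), "genes\n")
    cat("  excluded labels: ", paste(object@excluded, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## MAGProfile

#' One metagenome-assembled genome's identity, quality and gene inventory
#'
#' @slot magId unique MAG identifier.
#' @slot taxonomy seven-rank lineage (domain to species); ranks may be empty.
#' @slot completeness genome completeness, percent in [0, 100].
#' @slot contamination genome contamination, percent in [0, 100].
#' @slot genes data.frame with columns \code{gene_id}, \code{label}
#'   (ortholog label or \code{NA}), \code{length_bp},
#'   \code{transcribed_low}, \code{transcribed_high}.
#' @exportClass MAGProfile
setClass("MAGProfile",
    representation(magId = "character", taxonomy = "character",
                   completeness = "numeric", contamination = "numeric",
                   genes = "data.frame"))

setValidity("MAGProfile", function(object) {
    msg <- NULL
    if (length(object@magId) != 1L || !nzchar(object@magId))
        msg <- c(msg, "magId must be a single non-empty string")
    if (length(object@taxonomy) != 7L)
        msg <- c(msg, "taxonomy must have exactly seven ranks")
    if (object@completeness < 0 || object@completeness > 100)
        msg <- c(msg, "completeness must lie in [0, 100]")
    if (object@contamination < 0 || object@contamination > 100)
        msg <- c(msg, "contamination must lie in [0, 100]")
    need <- c("gene_id", "label", "length_bp", "transcribed_low",
              "transcribed_high")
    miss <- setdiff(need, names(object@genes))
    if (length(miss)) {
        msg <- c(msg, paste0("genes table lacks column(s): ",
                             paste(miss, collapse = ", ")))
    } else {
        if (anyDuplicated(object@genes$gene_id))
            msg <- c(msg, sprintf("MAG '%s': duplicated gene_id", object@magId))
        if (nrow(object@genes) && any(object@genes$length_bp < 1))
            msg <- c(msg, "gene lengths must be >= 1 bp")
    }
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "MAGProfile", function(object) {
    lab <- object@genes$label
    cat(sprintf("MAGProfile %s (%s)\n", object@magId,
                paste(object@taxonomy[object@taxonomy != ""],
                      collapse = ";")))
    cat(sprintf("  completeness %.1f%%, contamination %.1f%%\n",
                object@completeness, object@contamination))
    cat(sprintf("  %d genes (%d labelled)\n", nrow(object@genes),
                sum(!is.na(lab) & lab != "")))
})

## ---------------------------------------------------------------------------
## SummarizedExperiment-backed containers

#' Amplicon count table with seven-rank taxonomy and day/series metadata
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a \code{counts}
#' assay (taxa x samples), rowData carrying the seven taxonomy ranks, and
#' colData with \code{day} and \code{series}. Build with
#' [AmpliconExperiment()].
#'
#' @exportClass AmpliconExperiment
setClass("AmpliconExperiment", contains = "SummarizedExperiment")

setValidity("AmpliconExperiment", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        return("must contain a 'counts' assay")
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    miss <- setdiff(TAXONOMY_RANKS, colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks taxonomy rank(s): ",
                             paste(miss, collapse = ", ")))
    miss <- setdiff(c("day", "series"), colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else if (any(colData(object)$day < 0))
        msg <- c(msg, "days must be non-negative")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicated sample ids")
    if (ncol(cts) && any(colSums(cts) < 1))
        msg <- c(msg, paste0("sample(s) with zero total counts: ",
                             paste(colnames(cts)[colSums(cts) < 1],
                                   collapse = ", ")))
    if (is.null(msg)) TRUE else msg
})

#' Per-gene transcript counts with gene metadata and condition labels
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a \code{counts}
#' assay (genes x samples), rowData columns \code{mag_id}, \code{label},
#' \code{length_bp}, and colData columns \code{condition} (\code{"LOW"} or
#' \code{"HIGH"} cable-bacteria abundance) and \code{day}. Build with
#' [TranscriptCounts()].
#'
#' @exportClass TranscriptCounts
setClass("TranscriptCounts", contains = "SummarizedExperiment")

setValidity("TranscriptCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% names(assays(object)))
        return("must contain a 'counts' assay")
    cts <- assay(object, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    miss <- setdiff(c("mag_id", "label", "length_bp"),
                    colnames(rowData(object)))
    if (length(miss))
        msg <- c(msg, paste0("rowData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else if (nrow(object) && any(rowData(object)$length_bp < 1))
        msg <- c(msg, "gene lengths must be >= 1 bp")
    miss <- setdiff(c("condition", "day"), colnames(colData(object)))
    if (length(miss))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(miss, collapse = ", ")))
    else {
        cond <- colData(object)$condition
        if (!all(cond %in% c("LOW", "HIGH")))
            msg <- c(msg, "condition must be 'LOW' or 'HIGH'")
        if (length(unique(cond)) < 2L)
            msg <- c(msg, "both LOW and HIGH conditions must be represented")
    }
    if (is.null(msg)) TRUE else msg
})

#' Seven taxonomy rank names used throughout the package
#' @export
TAXONOMY_RANKS <- c("domain", "phylum", "class", "order", "family",
                    "genus", "species")
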