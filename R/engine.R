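## Rule engine: canonical complex completeness, hybrid assembly, motility
## scoring and conduit/shuttle capability flags for one MAG.

#' Construct a MAGProfile
#'
#' @param mag_id unique MAG identifier.
#' @param genes data.frame with columns \code{gene_id}, \code{label}
#'   (ortholog label or \code{NA} for unannotated genes), \code{length_bp},
#'   \code{transcribed_low}, \code{transcribed_high}. Missing transcription
#'   columns default to \code{FALSE}.
#' @param taxonomy seven-rank lineage; shorter vectors are right-padded with
#'   empty ranks.
#' @param completeness,contamination genome quality percentages in [0, 100].
#' @return a [MAGProfile-class].
#' @export
MAGProfile <- function(mag_id, genes, taxonomy = character(7),
                       completeness = 100, contamination = 0) {
    if (length(taxonomy) < 7L)
        taxonomy <- c(taxonomy, rep("", 7L - length(taxonomy)))
    genes <- as.data.frame(genes)
    if (is.null(genes$label)) genes$label <- NA_character_
    if (is.null(genes$length_bp)) genes$length_bp <- 1000L
    if (is.null(genes$transcribed_low)) genes$transcribed_low <- FALSE
    if (is.null(genes$transcribed_high)) genes$transcribed_high <- FALSE
    genes$label[!is.na(genes$label) & genes$label == ""] <- NA_character_
    new("MAGProfile", magId = as.character(mag_id),
        taxonomy = as.character(taxonomy),
        completeness = as.numeric(completeness),
        contamination = as.numeric(contamination),
        genes = genes[, c("gene_id", "label", "length_bp",
                          "transcribed_low", "transcribed_high")])
}

#' @describeIn MAGProfile genus of the MAG (rank 6 of the lineage).
#' @param profile a [MAGProfile-class].
#' @export
magGenus <- function(profile) profile@taxonomy[6L]

## canonical labelled inventory of a profile: data.frame(label, low, high, n)
.inventory <- function(profile, catalog) {
    g <- profile@genes
    canon <- canonicalLabel(catalog, g$label)
    keep <- !is.na(canon)
    if (!any(keep))
        return(data.frame(label = character(0), low = logical(0),
                          high = logical(0), copies = integer(0)))
    df <- data.frame(label = canon[keep], low = g$transcribed_low[keep],
                     high = g$transcribed_high[keep])
    agg <- do.call(rbind, lapply(split(df, df$label), function(d)
        data.frame(label = d$label[1L], low = any(d$low), high = any(d$high),
                   copies = nrow(d))))
    rownames(agg) <- NULL
    agg[order(agg$label), , drop = FALSE]
}

#' Evaluate canonical complex completeness for one MAG
#'
#' For every complex definition in the catalog, reports whether the MAG's
#' labelled gene inventory makes it \code{COMPLETE} (every required gene
#' present), \code{PARTIAL}, or \code{ABSENT}. Duplicate gene copies count
#' once for completeness (copy number is reported separately); a complex is
#' considered transcribed in a condition when at least one member gene is.
#' Unlabelled genes are invisible to the engine.
#'
#' @param profile a [MAGProfile-class].
#' @param catalog an [EETCatalog-class].
#' @return data.frame, one row per catalog complex ordered by complex name:
#'   \code{complex}, \code{state}, \code{present}, \code{missing}
#'   (comma-separated label lists), \code{n_copies},
#'   \code{transcribed_low}, \code{transcribed_high}.
#' @export
evaluateComplexes <- function(profile, catalog) {
    inv <- .inventory(profile, catalog)
    rows <- lapply(catalog@complexes, function(cx) {
        hit <- inv[inv$label %in% cx@required, , drop = FALSE]
        present <- hit$label
        missing <- setdiff(cx@required, present)
        state <- if (length(missing) == 0L) "COMPLETE"
                 else if (length(present) == 0L) "ABSENT" else "PARTIAL"
        data.frame(complex = cx@name, state = state,
                   present = paste(sort(present), collapse = ","),
                   missing = paste(sort(missing), collapse = ","),
                   n_copies = sum(hit$copies),
                   transcribed_low = any(hit$low),
                   transcribed_high = any(hit$high))
    })
    out <- do.call(rbind, rows)
    out[order(out$complex), , drop = FALSE]
}

## required-gene sets of all canonical complexes, as sorted comma keys
.canonicalSetKeys <- function(catalog) {
    vapply(catalog@complexes,
           function(cx) paste(sort(cx@required), collapse = ","), "")
}

## complex names a label belongs to ("" if standalone)
.provenance <- function(catalog, labels) {
    vapply(labels, function(l) {
        hits <- vapply(catalog@complexes,
                       function(cx) l %in% cx@required, NA)
        if (any(hits))
            paste(vapply(catalog@complexes[hits], slot, "", "name"),
                  collapse = "+")
        else "standalone"
    }, "")
}

#' Assemble functional cross-pathway hybrid complexes
#'
#' Enumerates every (porin, periplasmic anchor, outer-surface cytochrome)
#' combination present in the MAG's inventory and permitted by the catalog's
#' hybrid slot assignments -- the rule being that a hybrid pcc is functional
#' if a complete outer-membrane-crossing complex can be formed from parts of
#' different pathways. Combinations whose gene set equals a canonical
#' complete complex are excluded (those are reported by
#' [evaluateComplexes()] instead).
#'
#' @inheritParams evaluateComplexes
#' @return data.frame with columns \code{porin}, \code{anchor}, \code{omc},
#'   \code{provenance}, \code{transcribed_low}, \code{transcribed_high},
#'   deduplicated and deterministically ordered.
#' @export
assembleHybrids <- function(profile, catalog) {
    inv <- .inventory(profile, catalog)
    hs <- catalog@hybridSlots
    porins <- intersect(hs$porin, inv$label)
    anchors <- intersect(hs$anchor, inv$label)
    omcs <- intersect(hs$omc, inv$label)
    empty <- data.frame(porin = character(0), anchor = character(0),
                        omc = character(0), provenance = character(0),
                        transcribed_low = logical(0),
                        transcribed_high = logical(0))
    if (!length(porins) || !length(anchors) || !length(omcs))
        return(empty)
    combos <- expand.grid(porin = sort(porins), anchor = sort(anchors),
                          omc = sort(omcs), stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
    keys <- apply(combos, 1L, function(r) paste(sort(r), collapse = ","))
    combos <- combos[!keys %in% .canonicalSetKeys(catalog) &
                     !duplicated(keys), , drop = FALSE]
    if (!nrow(combos)) return(empty)
    triples <- combos[, c("porin", "anchor", "omc"), drop = FALSE]
    combos$provenance <- apply(triples, 1L, function(r)
        paste(unique(.provenance(catalog, unname(r))), collapse = "|"))
    trx <- function(col) apply(triples, 1L, function(r)
        any(inv[[col]][inv$label %in% r]))
    combos$transcribed_low <- trx("low")
    combos$transcribed_high <- trx("high")
    combos <- combos[order(combos$porin, combos$anchor, combos$omc), ,
                     drop = FALSE]
    rownames(combos) <- NULL
    combos
}

#' Score flagellar motility
#'
#' Counts the inventory's overlap with the catalog's flagellar-assembly gene
#' set; a MAG is called motile when it carries more than 30 of the 55 genes.
#' An explicit \code{override} wins over the count (used when an incomplete
#' genome is assumed motile on external grounds) and is recorded.
#'
#' @inheritParams evaluateComplexes
#' @param override optional logical; if supplied, the motility call is forced
#'   to this value.
#' @param threshold count strictly above which motility is called (default
#'   30).
#' @return list with \code{count}, \code{n_set} (flagellar set size),
#'   \code{motile}, and \code{override} (\code{NA} when not used).
#' @export
scoreMotility <- function(profile, catalog, override = NULL,
                          threshold = 30L) {
    stopifnot(length(catalog@flagellarSet) >= 1L)
    inv <- .inventory(profile, catalog)
    count <- length(intersect(inv$label, catalog@flagellarSet))
    motile <- count > threshold
    ov <- NA
    if (!is.null(override) && !is.na(override)) {
        ov <- isTRUE(override)
        motile <- ov
    }
    list(count = count, n_set = length(catalog@flagellarSet),
         motile = motile, override = ov)
}

## presence + per-condition transcription of a label group; `all_of` demands
## the full group present (transcription still counts any member)
.groupFlag <- function(inv, group, all_of = FALSE) {
    hit <- inv[inv$label %in% group, , drop = FALSE]
    present <- if (all_of) all(group %in% inv$label) else nrow(hit) > 0L
    c(present = present,
      transcribed_low = present && any(hit$low),
      transcribed_high = present && any(hit$high))
}

#' Conduit and electron-shuttle capability flags
#'
#' Derives presence and per-condition transcription booleans for: any
#' inner-membrane/periplasmic conduit; flavin synthesis (marker genes
#' \code{ribBA} or \code{ribBX}); flavin export (\code{bfe} or \code{yeeO});
#' phenazine synthesis (marker \code{phzE}); phenazine regulation
#' (\code{ipdG}); and the MexGHI-OpmD pump, which requires all four genes
#' (the pump is reported as a flag only and never counts toward candidacy,
#' as it is not exclusively used for shuttle excretion).
#'
#' @inheritParams evaluateComplexes
#' @return data.frame with one row per capability and columns
#'   \code{capability}, \code{present}, \code{transcribed_low},
#'   \code{transcribed_high}.
#' @export
conduitShuttleFlags <- function(profile, catalog) {
    inv <- .inventory(profile, catalog)
    groups <- list(
        conduit = list(conduitLabels(catalog), FALSE),
        flavin_synthesis = list(c("ribBA", "ribBX"), FALSE),
        flavin_export = list(c("bfe", "yeeO"), FALSE),
        phenazine_synthesis = list("phzE", FALSE),
        phenazine_regulation = list("ipdG", FALSE),
        pump = list(catalog@shuttleRules$pump %||%
                        c("mexG", "mexH", "mexI", "opmD"), TRUE))
    rows <- lapply(names(groups), function(nm) {
        fl <- .groupFlag(inv, groups[[nm]][[1L]], groups[[nm]][[2L]])
        data.frame(capability = nm, present = unname(fl["present"]),
                   transcribed_low = unname(fl["transcribed_low"]),
                   transcribed_high = unname(fl["transcribed_high"]))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Per-MAG complex report across a collection of profiles
#'
#' One row per MAG x (canonical complex or assembled hybrid), suitable for
#' writing with [writeReport()].
#'
#' @param profiles list of [MAGProfile-class] objects.
#' @param catalog an [EETCatalog-class].
#' @return data.frame with columns \code{mag_id}, \code{unit} (complex name
#'   or \code{hybrid:porin+anchor+omc}), \code{state}, \code{present},
#'   \code{missing}, \code{transcribed_low}, \code{transcribed_high}.
#' @export
complexReport <- function(profiles, catalog) {
    rows <- lapply(profiles, function(p) {
        cs <- evaluateComplexes(p, catalog)
        a <- data.frame(mag_id = p@magId, unit = cs$complex,
                        state = cs$state, present = cs$present,
                        missing = cs$missing,
                        transcribed_low = cs$transcribed_low,
                        transcribed_high = cs$transcribed_high)
        hy <- assembleHybrids(p, catalog)
        if (nrow(hy)) {
            b <- data.frame(
                mag_id = p@magId,
                unit = paste0("hybrid:", hy$porin, "+", hy$anchor, "+",
                              hy$omc),
                state = "COMPLETE",
                present = paste(hy$porin, hy$anchor, hy$omc, sep = ","),
                missing = "",
                transcribed_low = hy$transcribed_low,
                transcribed_high = hy$transcribed_high)
            a <- rbind(a, b)
        }
        a
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
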