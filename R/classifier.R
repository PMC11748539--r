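## Evidence integration: join engine, screen and differential-expression
## outputs per MAG, then assign nested candidate-flocker tiers with a full
## rationale trace.

#' Default classification policy
#'
#' The three criteria for a candidate flocker are (i) motility, (ii) EET
#' genes and transcription thereof, and (iii) a positive genus-level
#' abundance correlation with the cable bacteria or EET genes significantly
#' more expressed during high cable-bacteria abundance. The default policy
#' encodes them as nested tiers:
#' \describe{
#'   \item{CANDIDATE}{motile AND (at least one complete canonical complex OR
#'     at least one assembled hybrid).}
#'   \item{ACTIVE_CANDIDATE}{CANDIDATE AND at least one member gene of a
#'     complete complex or hybrid transcribed in either condition.}
#'   \item{SUPPORTED_CANDIDATE}{ACTIVE_CANDIDATE AND (correlation pass OR
#'     differential-expression evidence).}
#' }
#'
#' @return a named list of policy settings.
#' @export
defaultPolicy <- function() {
    list(motility_threshold = 30L, de_alpha_applied = TRUE)
}

#' Build per-MAG evidence bundles
#'
#' Joins the rule-engine outputs with the correlation screen and the
#' differential-expression results. Missing screen or DE inputs yield
#' \code{correlation_pass}/\code{de_evidence} of \code{FALSE} with a
#' "no data" rationale rather than an error; a DE table whose MAG ids do
#' not belong to the supplied profiles is an error (inconsistent run).
#'
#' Correlation evidence requires an exact case-insensitive genus match
#' between the MAG lineage and a passing screen genus, optionally through a
#' user-supplied synonym map (genome-taxonomy and amplicon-database genus
#' names differ in practice; no silent fuzzy matching is attempted).
#' DE evidence requires at least one catalog EET gene (pcc member, conduit
#' or shuttle gene) of the MAG called significantly higher during high
#' cable-bacteria abundance.
#'
#' @param profiles list of [MAGProfile-class] objects.
#' @param catalog an [EETCatalog-class].
#' @param screen optional [correlationScreen()] result.
#' @param de optional [nbDiffTest()] result.
#' @param overrides optional named logical vector of motility overrides,
#'   keyed by MAG id.
#' @param genus_synonyms optional named character vector mapping MAG genus
#'   spellings to amplicon genus spellings.
#' @return data.frame, one row per MAG, with the evidence fields and a
#'   \code{notes} column.
#' @export
buildEvidence <- function(profiles, catalog, screen = NULL, de = NULL,
                          overrides = NULL, genus_synonyms = NULL) {
    mag_ids <- vapply(profiles, slot, "", "magId")
    if (anyDuplicated(mag_ids))
        stop("duplicated MAG ids across profiles")
    if (!is.null(de) && nrow(de)) {
        stray <- setdiff(unique(de$mag_id), mag_ids)
        if (length(stray))
            stop("DE results reference unknown MAG id(s): ",
                 paste(stray, collapse = ", "))
    }
    passing <- if (is.null(screen)) character(0) else
        tolower(trimws(screen$genus[screen$passes]))
    eet <- eetLabels(catalog)

    rows <- lapply(profiles, function(p) {
        notes <- character(0)
        ov <- if (!is.null(overrides) && p@magId %in% names(overrides))
            overrides[[p@magId]] else NULL
        mot <- scoreMotility(p, catalog, override = ov)
        cs <- evaluateComplexes(p, catalog)
        hy <- assembleHybrids(p, catalog)
        complete <- cs[cs$state == "COMPLETE", , drop = FALSE]
        flags <- conduitShuttleFlags(p, catalog)
        pcc_low <- any(complete$transcribed_low) || any(hy$transcribed_low)
        pcc_high <- any(complete$transcribed_high) ||
            any(hy$transcribed_high)

        genus <- magGenus(p)
        if (!is.null(genus_synonyms) && genus %in% names(genus_synonyms))
            genus <- genus_synonyms[[genus]]
        if (is.null(screen))
            notes <- c(notes, "no correlation screen data")
        if (genus == "")
            notes <- c(notes, "no genus classification")
        corr_pass <- nzchar(genus) && tolower(trimws(genus)) %in% passing

        if (is.null(de)) {
            notes <- c(notes, "no differential-expression data")
            de_ev <- FALSE
        } else {
            d <- de[de$mag_id == p@magId & !is.na(de$label), , drop = FALSE]
            canon <- canonicalLabel(catalog, d$label)
            de_ev <- any(d$significant_high & !is.na(canon) & canon %in% eet)
        }
        cflag <- function(cap, col) flags[[col]][flags$capability == cap]
        data.frame(
            mag_id = p@magId, genus = magGenus(p),
            motile = mot$motile, flagellar_count = mot$count,
            flagellar_set_size = mot$n_set,
            motility_override = mot$override,
            n_complete = nrow(complete),
            complete_complexes = paste(complete$complex, collapse = ","),
            n_hybrid = nrow(hy),
            hybrids = if (nrow(hy)) paste(
                paste0(hy$porin, "+", hy$anchor, "+", hy$omc),
                collapse = ",") else "",
            pcc_transcribed_low = pcc_low,
            pcc_transcribed_high = pcc_high,
            conduit_present = cflag("conduit", "present"),
            conduit_transcribed = cflag("conduit", "transcribed_low") ||
                cflag("conduit", "transcribed_high"),
            flavin_synthesis = cflag("flavin_synthesis", "present"),
            flavin_export = cflag("flavin_export", "present"),
            phenazine_synthesis = cflag("phenazine_synthesis", "present"),
            phenazine_regulation = cflag("phenazine_regulation", "present"),
            pump = cflag("pump", "present"),
            correlation_pass = corr_pass,
            de_evidence = de_ev,
            notes = paste(notes, collapse = "; "))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(mag_id = character(0), genus = character(0),
                          motile = logical(0), flagellar_count = integer(0),
                          flagellar_set_size = integer(0),
                          motility_override = logical(0),
                          n_complete = integer(0),
                          complete_complexes = character(0),
                          n_hybrid = integer(0), hybrids = character(0),
                          pcc_transcribed_low = logical(0),
                          pcc_transcribed_high = logical(0),
                          correlation_pass = logical(0),
                          de_evidence = logical(0), notes = character(0))
    rownames(out) <- NULL
    out
}

.classifyRow <- function(ev) {
    r1 <- isTRUE(ev$motile)
    r2 <- ev$n_complete > 0 || ev$n_hybrid > 0
    r3 <- isTRUE(ev$pcc_transcribed_low) || isTRUE(ev$pcc_transcribed_high)
    r4 <- isTRUE(ev$correlation_pass) || isTRUE(ev$de_evidence)
    tier <- if (r1 && r2 && r3 && r4) "SUPPORTED_CANDIDATE"
        else if (r1 && r2 && r3) "ACTIVE_CANDIDATE"
        else if (r1 && r2) "CANDIDATE"
        else "NOT_CANDIDATE"
    mot_txt <- sprintf("motility %d/%d (>30 required): %s%s",
                       ev$flagellar_count, ev$flagellar_set_size,
                       if (r1) "pass" else "fail",
                       if (!is.na(ev$motility_override))
                           sprintf(" [override=%s]", ev$motility_override)
                       else "")
    rationale <- c(
        paste0("[R1] ", mot_txt),
        sprintf("[R2] EET complex (complete: %s; hybrid: %s): %s",
                if (nzchar(ev$complete_complexes)) ev$complete_complexes
                else "none",
                if (nzchar(ev$hybrids)) ev$hybrids else "none",
                if (r2) "pass" else "fail"),
        sprintf("[R3] pcc transcription (low=%s, high=%s): %s",
                ev$pcc_transcribed_low, ev$pcc_transcribed_high,
                if (r3) "pass" else "fail"),
        sprintf(paste0("[R4] support (correlation_pass=%s, ",
                       "de_evidence=%s): %s"),
                ev$correlation_pass, ev$de_evidence,
                if (r4) "pass" else "fail"))
    if (nzchar(ev$notes))
        rationale <- c(rationale, paste0("[note] ", ev$notes))
    list(tier = tier, rationale = paste(rationale, collapse = " | "))
}

#' Assign candidate-flocker tiers
#'
#' Applies the (monotone, nested) classification policy to each MAG's
#' evidence bundle. Every call carries a rationale listing all fired and
#' failed rules.
#'
#' @param evidence result of [buildEvidence()].
#' @param policy a policy list, see [defaultPolicy()] (reserved for
#'   alternative rule sets; the tier predicates themselves are fixed).
#' @return data.frame with columns \code{mag_id}, \code{genus}, \code{tier}
#'   (ordered factor over [FLOCKER_TIERS]), the per-rule booleans
#'   \code{r1_motile}, \code{r2_complex}, \code{r3_transcribed},
#'   \code{r4_support}, and \code{rationale}.
#' @export
classifyFlockers <- function(evidence, policy = defaultPolicy()) {
    rows <- lapply(seq_len(nrow(evidence)), function(i) {
        ev <- evidence[i, , drop = FALSE]
        cl <- .classifyRow(ev)
        data.frame(mag_id = ev$mag_id, genus = ev$genus, tier = cl$tier,
                   r1_motile = isTRUE(ev$motile),
                   r2_complex = ev$n_complete > 0 || ev$n_hybrid > 0,
                   r3_transcribed = isTRUE(ev$pcc_transcribed_low) ||
                       isTRUE(ev$pcc_transcribed_high),
                   r4_support = isTRUE(ev$correlation_pass) ||
                       isTRUE(ev$de_evidence),
                   rationale = cl$rationale)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(mag_id = character(0), genus = character(0),
                          tier = character(0), r1_motile = logical(0),
                          r2_complex = logical(0),
                          r3_transcribed = logical(0),
                          r4_support = logical(0), rationale = character(0))
    out$tier <- factor(out$tier, levels = FLOCKER_TIERS, ordered = TRUE)
    rownames(out) <- NULL
    out
}

#' Percentage of MAGs called candidates
#'
#' @param n_candidate number of candidate MAGs (any tier above
#'   \code{NOT_CANDIDATE}, or an externally reported count).
#' @param n_total total number of MAGs.
#' @param digits decimal places to round to (default 1).
#' @return percentage of \code{n_total}.
#' @export
candidatePercentage <- function(n_candidate, n_total, digits = 1L) {
    stopifnot(n_total > 0)
    round(100 * n_candidate / n_total, digits)
}

#' Compare calls against a known ground truth
#'
#' Per-tier precision, recall and F1 of tier assignments against the truth
#' tiers of a synthetic run. Tier membership is evaluated cumulatively
#' (a SUPPORTED_CANDIDATE counts as reaching CANDIDATE too), matching the
#' nested tier semantics.
#'
#' @param calls result of [classifyFlockers()].
#' @param truth data.frame with columns \code{mag_id} and \code{tier}.
#' @return data.frame with columns \code{tier}, \code{tp}, \code{fp},
#'   \code{fn}, \code{precision}, \code{recall}, \code{f1}.
#' @export
evaluateCalls <- function(calls, truth) {
    truth_tier <- factor(truth$tier[match(calls$mag_id, truth$mag_id)],
                         levels = FLOCKER_TIERS, ordered = TRUE)
    if (anyNA(truth_tier))
        stop("truth lacks tier(s) for MAG id(s): ",
             paste(calls$mag_id[is.na(truth_tier)], collapse = ", "))
    rows <- lapply(FLOCKER_TIERS[-1L], function(t) {
        called <- calls$tier >= t
        truthy <- truth_tier >= t
        tp <- sum(called & truthy); fp <- sum(called & !truthy)
        fn <- sum(!called & truthy)
        prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
        rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
        f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec)
              else NA_real_
        data.frame(tier = t, tp = tp, fp = fp, fn = fn, precision = prec,
                   recall = rec, f1 = f1)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
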