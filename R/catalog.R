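## Catalog loading, validation and lookup.

#' Normalize an ortholog label
#'
#' Lower-cases and strips punctuation except \code{"/"} (kept so
#' \code{fccA/3} survives), making matching robust against gene-name dialects
#' such as \code{TherJR_2595} vs \code{therJR2595}.
#'
#' @param x character vector of labels.
#' @return normalized character vector.
#' @export
normalizeLabel <- function(x) {
    x <- tolower(trimws(as.character(x)))
    gsub("[^a-z0-9/]", "", x)
}

.newComplex <- function(name, origin = "", required, slots = NULL,
                        complete_alone = FALSE) {
    slotRoles <- character(0)
    if (!is.null(slots)) {
        slotRoles <- vapply(slots, as.character, "")
        names(slotRoles) <- names(slots)
    }
    new("ComplexDefinition", name = as.character(name),
        origin = as.character(origin), required = as.character(required),
        slotRoles = slotRoles, completeAlone = isTRUE(complete_alone))
}

#' Load and validate an EET gene catalog
#'
#' Reads a structured YAML catalog (sections \code{labels},
#' \code{complexes}, \code{hybrid_slots}, \code{flagellar_set},
#' \code{shuttle_rules}, \code{excluded}) and returns a validated
#' [EETCatalog-class]. Labels named in the \code{flagellar_set} are declared
#' automatically with the \code{MOTILITY_FLAGELLAR} role. Complexes that
#' reference undeclared labels, unknown role tags, or labels listed under
#' \code{excluded} (periplasmic carriers that are not part of the
#' membrane-bound porin complex) are configuration errors.
#'
#' @param config path to a YAML file, or a single YAML string.
#' @return an [EETCatalog-class] object.
#' @seealso [defaultCatalog()], [writeCatalog()]
#' @export
loadCatalog <- function(config) {
    stopifnot(is.character(config), length(config) == 1L)
    doc <- if (file.exists(config)) yaml::read_yaml(config)
           else yaml::yaml.load(config)
    if (!is.list(doc))
        stop("catalog config did not parse to a document")

    roles <- list(); synonyms <- character(0); labels <- character(0)
    for (i in seq_along(doc$labels)) {
        entry <- doc$labels[[i]]
        if (is.null(entry$name))
            stop(sprintf("catalog config: labels entry %d has no name", i))
        nm <- as.character(entry$name)
        rl <- as.character(unlist(entry$roles))
        bad <- setdiff(rl, ROLE_TAGS)
        if (length(bad))
            stop(sprintf(
                "catalog config: label '%s' carries unknown role tag(s): %s",
                nm, paste(bad, collapse = ", ")))
        labels <- c(labels, nm)
        roles[[nm]] <- rl
        syn <- as.character(unlist(entry$synonyms))
        if (length(syn)) {
            s <- rep(nm, length(syn)); names(s) <- normalizeLabel(syn)
            synonyms <- c(synonyms, s)
        }
    }
    flag <- as.character(unlist(doc$flagellar_set))
    for (f in setdiff(flag, labels)) {
        labels <- c(labels, f)
        roles[[f]] <- "MOTILITY_FLAGELLAR"
    }
    for (f in intersect(flag, names(roles)))
        roles[[f]] <- union(roles[[f]], "MOTILITY_FLAGELLAR")

    complexes <- lapply(doc$complexes, function(cx) {
        if (is.null(cx$name) || is.null(cx$required))
            stop("catalog config: complex entries need 'name' and 'required'")
        bad_roles <- setdiff(as.character(unlist(cx$slots)), ROLE_TAGS)
        if (length(bad_roles))
            stop(sprintf(
                "catalog config: complex '%s' has unknown slot role(s): %s",
                cx$name, paste(bad_roles, collapse = ", ")))
        .newComplex(cx$name, cx$origin %||% "", unlist(cx$required),
                    cx$slots, isTRUE(cx$complete_alone))
    })

    hs <- doc$hybrid_slots %||% list()
    hybridSlots <- list(porin = as.character(unlist(hs$porin)),
                        anchor = as.character(unlist(hs$anchor)),
                        omc = as.character(unlist(hs$omc)))
    shuttleRules <- lapply(doc$shuttle_rules %||% list(),
                           function(x) as.character(unlist(x)))

    # canonical spellings are their own synonyms
    self <- labels; names(self) <- normalizeLabel(labels)
    if (anyDuplicated(names(self)))
        stop("catalog config: labels collide after normalization: ",
             paste(labels[duplicated(names(self))], collapse = ", "))
    synonyms <- c(self, synonyms[!names(synonyms) %in% names(self)])

    cat_obj <- new("EETCatalog", labels = labels, roles = roles,
                   synonyms = synonyms, complexes = complexes,
                   hybridSlots = hybridSlots,
                   flagellarSet = flag,
                   shuttleRules = shuttleRules,
                   excluded = as.character(unlist(doc$excluded)))
    validObject(cat_obj)
    cat_obj
}

#' The shipped default catalog
#'
#' Loads the package's default catalog: 32 pcc labels across 12 complex
#' definitions (including the single-gene complexes \code{Cyc2} and
#' \code{CwcA} and the three-gene Gram-positive \code{EetB-system}), 10
#' inner-membrane/periplasmic conduit labels, 16 electron-shuttle labels,
#' and a 55-gene flagellar-assembly set.
#'
#' @return an [EETCatalog-class] object.
#' @export
defaultCatalog <- function() {
    loadCatalog(system.file("extdata", "eet_catalog.yaml",
                            package = "flockerscan", mustWork = TRUE))
}

#' Serialize a catalog back to YAML
#'
#' Inverse of [loadCatalog()]: \code{loadCatalog(writeCatalog(x, f))} is
#' equivalent to \code{x} (set-equality on labels, roles, complexes and
#' gene groups).
#'
#' @param catalog an [EETCatalog-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCatalog <- function(catalog, path) {
    stopifnot(is(catalog, "EETCatalog"))
    syn_by_label <- split(names(catalog@synonyms), catalog@synonyms)
    labels <- lapply(setdiff(catalog@labels, catalog@flagellarSet),
        function(nm) {
            entry <- list(name = nm, roles = as.list(catalog@roles[[nm]]))
            syn <- setdiff(syn_by_label[[nm]], normalizeLabel(nm))
            if (length(syn)) entry$synonyms <- as.list(syn)
            entry
        })
    complexes <- lapply(catalog@complexes, function(cx) {
        entry <- list(name = cx@name, origin = cx@origin,
                      required = as.list(cx@required))
        if (length(cx@slotRoles))
            entry$slots <- as.list(cx@slotRoles)
        if (cx@completeAlone) entry$complete_alone <- TRUE
        entry
    })
    doc <- list(labels = labels, complexes = complexes,
                hybrid_slots = lapply(catalog@hybridSlots, as.list),
                flagellar_set = as.list(catalog@flagellarSet),
                shuttle_rules = lapply(catalog@shuttleRules, as.list),
                excluded = as.list(catalog@excluded))
    yaml::write_yaml(doc, path)
    invisible(path)
}

#' Resolve labels to their canonical catalog spelling
#'
#' @param catalog an [EETCatalog-class].
#' @param labels character vector of labels in any dialect.
#' @return character vector of canonical labels; \code{NA} where unknown.
#' @export
canonicalLabel <- function(catalog, labels) {
    out <- unname(catalog@synonyms[normalizeLabel(labels)])
    out[is.na(labels) | labels == ""] <- NA_character_
    out
}

#' Look up the functional roles of a label
#'
#' Synonym- and case-insensitive; an unknown label returns an empty set
#' rather than an error.
#'
#' @param catalog an [EETCatalog-class].
#' @param label a single ortholog label.
#' @return character vector of role tags (possibly empty).
#' @export
lookupRoles <- function(catalog, label) {
    canon <- canonicalLabel(catalog, label)
    if (is.na(canon)) return(character(0))
    catalog@roles[[canon]]
}

#' @describeIn catalogAccessors labels belonging to porin-cytochrome
#'   complexes: the union of all complex required genes and the standalone
#'   outer-surface cytochromes eligible for the hybrid omc slot.
#' @export
pccLabels <- function(catalog) {
    sort(union(unlist(lapply(catalog@complexes, slot, "required")),
               catalog@hybridSlots$omc))
}

#' Catalog accessors
#'
#' @param catalog an [EETCatalog-class].
#' @return character vectors of canonical labels, or the list of
#'   [ComplexDefinition-class] objects.
#' @name catalogAccessors
NULL

#' @describeIn catalogAccessors electron-shuttle labels (union of all
#'   shuttle gene groups).
#' @export
shuttleLabels <- function(catalog) {
    sort(unique(unlist(catalog@shuttleRules)))
}

#' @describeIn catalogAccessors inner-membrane/periplasmic conduit labels.
#' @export
conduitLabels <- function(catalog) {
    sort(names(catalog@roles)[vapply(catalog@roles,
                                     function(r) "IM_P_CONDUIT" %in% r, NA)])
}

#' @describeIn catalogAccessors flagellar-assembly gene set.
#' @export
flagellarSet <- function(catalog) catalog@flagellarSet

#' @describeIn catalogAccessors named list of hybrid slot assignments
#'   (\code{porin}, \code{anchor}, \code{omc}).
#' @export
hybridSlots <- function(catalog) catalog@hybridSlots

#' @describeIn catalogAccessors complex definitions.
#' @export
catalogComplexes <- function(catalog) catalog@complexes

#' @describeIn catalogAccessors all canonical labels.
#' @export
catalogLabels <- function(catalog) catalog@labels

#' @describeIn catalogAccessors labels counting as EET evidence for the
#'   differential-expression arm: pcc members, conduits and shuttle genes
#'   (flagellar and purely accessory labels excluded).
#' @export
eetLabels <- function(catalog) {
    sort(unique(c(pccLabels(catalog), conduitLabels(catalog),
                  shuttleLabels(catalog))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
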