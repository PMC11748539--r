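# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (nested loops, direct recomputation) so they cannot
# share a defect with the implementation they check.

# profile from a plain label vector
mkProfile <- function(labels, mag_id = "M1", low = FALSE, high = TRUE,
                      genus = "", length_bp = 1000) {
    tax <- c("Bacteria", "", "", "", "", genus, "")
    if (length(labels) == 0L)
        return(MAGProfile(mag_id, data.frame(
            gene_id = character(0), label = character(0),
            length_bp = numeric(0), transcribed_low = logical(0),
            transcribed_high = logical(0)), tax))
    MAGProfile(mag_id, data.frame(
        gene_id = paste0(mag_id, "_g", seq_along(labels)),
        label = labels, length_bp = length_bp,
        transcribed_low = rep_len(low, length(labels)),
        transcribed_high = rep_len(high, length(labels))), tax)
}

# brute-force hybrid enumeration: every ordered triple of distinct canonical
# labels, slot membership checked one by one, canonical gene sets excluded
oracleHybrids <- function(labels, catalog) {
    canon <- unique(stats::na.omit(canonicalLabel(catalog, labels)))
    hs <- hybridSlots(catalog)
    req_keys <- vapply(catalogComplexes(catalog), function(cx)
        paste(sort(cx@required), collapse = ","), "")
    out <- character(0)
    for (a in canon) for (b in canon) for (c in canon) {
        if (a == b || a == c || b == c) next
        if (!(a %in% hs$porin)) next
        if (!(b %in% hs$anchor)) next
        if (!(c %in% hs$omc)) next
        if (paste(sort(c(a, b, c)), collapse = ",") %in% req_keys) next
        out <- c(out, paste(a, b, c, sep = "|"))
    }
    sort(unique(out))
}

# brute-force completeness: subset check per complex
oracleCompleteness <- function(labels, catalog) {
    canon <- unique(stats::na.omit(canonicalLabel(catalog, labels)))
    states <- vapply(catalogComplexes(catalog), function(cx) {
        n_present <- sum(cx@required %in% canon)
        if (n_present == length(cx@required)) "COMPLETE"
        else if (n_present == 0L) "ABSENT" else "PARTIAL"
    }, "")
    names(states) <- vapply(catalogComplexes(catalog), slot, "", "name")
    states[order(names(states))]
}

# Monte-Carlo permutation p-value for Spearman rho (average ranks)
oracleSpearmanP <- function(x, y, n_perm = 5000L) {
    rx <- rank(x); ry <- rank(y)
    obs <- stats::cor(rx, ry)
    hits <- vapply(seq_len(n_perm), function(i)
        abs(stats::cor(sample(rx), ry)) >= abs(obs) - 1e-12, NA)
    list(rho = obs, p = mean(hits))
}

randomInventory <- function(catalog, max_genes = 12L) {
    n <- sample.int(max_genes, 1L)
    sample(catalogLabels(catalog), n)
}
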