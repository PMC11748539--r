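# fixture: ASV table with classified and unclassified taxa
mkAmplicon <- function(counts, genus, day = NULL, series = "TS1") {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("S%02d", seq_len(ncol(counts)))
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("ASV%02d", seq_len(nrow(counts)))
    if (is.null(day)) day <- seq_len(ncol(counts))
    AmpliconExperiment(
        counts,
        data.frame(domain = "Bacteria", phylum = "", class = "",
                   order = "", family = "", genus = genus, species = ""),
        data.frame(day = day, series = series,
                   row.names = colnames(counts)))
}

test_that("fractional abundances are counts over library size", {
    a <- mkAmplicon(matrix(c(50, 50), ncol = 1), c("A", "B"))
    expect_equal(unname(fractionalAbundance(a)[, 1]), c(0.5, 0.5))
    a <- mkAmplicon(matrix(c(1, 0, 0), ncol = 1), c("A", "B", "C"))
    expect_equal(unname(fractionalAbundance(a)[, 1]), c(1, 0, 0))
    set.seed(1)
    m <- matrix(rpois(40, 30) + 1L, nrow = 5)
    a <- mkAmplicon(m, letters[1:5])
    f <- fractionalAbundance(a)
    expect_equal(f, sweep(m, 2, colSums(m), "/"), ignore_attr = TRUE)
    expect_true(all(abs(colSums(f) - 1) < 1e-9))
    # zero-total sample named in the error
    expect_error(fractionalAbundance(cbind(m[, 1], 0L)), "zero total")
})

test_that("pruning removes unclassified ASVs before agglomeration", {
    m <- matrix(c(10, 20, 30, 40,
                  1, 2, 3, 4,
                  100, 100, 100, 100), nrow = 3, byrow = TRUE)
    a <- mkAmplicon(rbind(m, m[1, , drop = FALSE] * 0L + 7L),
                    c("G", "G", "", "H"))
    g <- pruneAndAgglomerate(a)
    expect_setequal(rownames(g), c("G", "H"))
    counts <- SummarizedExperiment::assay(g, "counts")
    expect_equal(unname(counts["G", ]), c(11, 22, 33, 44))
    expect_equal(unname(counts["H", ]), rep(7, 4))
    # classified totals conserved
    expect_equal(sum(counts), sum(m[1:2, ]) + 28)
    # nothing classified: empty table with a warning
    a0 <- mkAmplicon(m[1:2, ], c("", ""))
    expect_warning(g0 <- pruneAndAgglomerate(a0), "no taxa classified")
    expect_identical(nrow(g0), 0L)
})

test_that("prevalence filter reads 'more than three samples' strictly", {
    # 10 samples of 10,000 reads; filler genus makes up the rest
    filler <- rep(10000L, 10)
    mk <- function(v) {
        a <- mkAmplicon(rbind(v, filler - v), c("G", "Filler"))
        rownames(a) <- c("G", "Filler"); a
    }
    cfg <- screenConfig()
    # 0.10% in four samples: kept
    kept <- prevalenceFilter(mk(c(rep(10L, 4), rep(0L, 6))), cfg)
    expect_true("G" %in% rownames(kept))
    # 0.10% in exactly three samples: removed
    kept <- prevalenceFilter(mk(c(rep(10L, 3), rep(0L, 7))), cfg)
    expect_false("G" %in% rownames(kept))
    # 0.05% everywhere: removed
    kept <- prevalenceFilter(mk(rep(5L, 10)), cfg)
    expect_false("G" %in% rownames(kept))
    # focal genus retained with a warning even when it fails
    expect_warning(
        kept <- prevalenceFilter(mk(rep(5L, 10)), cfg, focal = "G"),
        "prevalence")
    expect_true("G" %in% rownames(kept))
})

test_that("screen recovers identity and rejects anti-correlation", {
    set.seed(3)
    n <- 12
    focal <- sort(rpois(n, 5000) + 100L)
    x <- mkAmplicon(rbind(focal, focal, rev(focal),
                          rep(1000L, n), rpois(n, 800)),
                    c("Focal", "Twin", "Mirror", "Flat", "Noise"))
    res <- correlationScreen(x, "Focal")
    expect_equal(res$rho[res$genus == "Twin"], 1)
    expect_true(res$passes[res$genus == "Twin"])
    expect_equal(res$rho[res$genus == "Mirror"], -1)
    expect_false(res$passes[res$genus == "Mirror"])
})

test_that("exact permutation p-values agree with a Monte-Carlo oracle", {
    set.seed(11)
    n <- 8
    focal <- rpois(n, 2000)
    other <- rpois(n, 500) + round(0.3 * focal)
    noise <- rpois(n, 700)
    x <- mkAmplicon(rbind(focal, other, noise, rep(5000L, n) - 0L),
                    c("Focal", "Tracker", "Noise", "Rest"))
    res <- correlationScreen(x, "Focal")
    frac <- fractionalAbundance(x)
    genus_of <- SummarizedExperiment::rowData(x)$genus
    for (g in c("Tracker", "Noise")) {
        row <- res[res$genus == g, ]
        orc <- oracleSpearmanP(frac[match("Focal", genus_of), ],
                               frac[match(g, genus_of), ])
        expect_equal(row$rho, orc$rho, tolerance = 1e-12)
        # Monte-Carlo oracle: 5,000 draws, 4 sigma band
        mc_sd <- sqrt(orc$p * (1 - orc$p) / 5000) + 1e-4
        expect_lt(abs(row$p_value - orc$p), 4 * mc_sd + 0.01)
    }
})

test_that("screen is invariant to per-sample count scaling", {
    set.seed(5)
    m <- matrix(rpois(60, 500) + 1L, nrow = 5)
    genus <- c("Focal", letters[1:4])
    a <- correlationScreen(mkAmplicon(m, genus), "Focal")
    m2 <- m; m2[, 3] <- m2[, 3] * 10L
    b <- correlationScreen(mkAmplicon(m2, genus), "Focal")
    expect_equal(a$rho[order(a$genus)], b$rho[order(b$genus)])
})

test_that("window restriction behaves and degenerate inputs error", {
    set.seed(8)
    m <- matrix(rpois(40, 600) + 1L, nrow = 5)
    genus <- c("Focal", letters[1:4])
    days <- c(3, 6, 13, 19, 26, 33, 47, 61)
    full <- correlationScreen(mkAmplicon(m, genus, day = days), "Focal")
    windowed <- correlationScreen(mkAmplicon(m, genus, day = days),
                                  "Focal",
                                  screenConfig(window = c(3, 61)))
    expect_equal(full$rho[order(full$genus)],
                 windowed$rho[order(windowed$genus)])
    sub <- correlationScreen(mkAmplicon(m, genus, day = days), "Focal",
                             screenConfig(window = c(3, 19)))
    expect_true(all(sub$n_samples == 4))
    expect_error(correlationScreen(mkAmplicon(m, genus, day = days),
                                   "Focal", screenConfig(window = c(3, 6))),
                 "fewer than 4")
    expect_error(correlationScreen(mkAmplicon(m, genus, day = days),
                                   "Nope"), "focal genus")
})

test_that("zero-variance genera are skipped, not tested", {
    n <- 10
    set.seed(2)
    focal <- rpois(n, 3000) + 1L
    # constant fraction needs constant count AND constant library size, so
    # a filler row pins every library to the same total
    lib <- 10000L
    m2 <- rbind(focal, rep(50L, n), rpois(n, 500) + 1L)
    m2 <- rbind(m2, lib - colSums(m2))
    a2 <- mkAmplicon(m2, c("Focal", "Constant", "A", "Rest"))
    res <- correlationScreen(a2, "Focal")
    expect_true("Constant" %in% attr(res, "skipped"))
    expect_false("Constant" %in% res$genus)
})
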