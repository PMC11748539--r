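cat_default <- defaultCatalog()

test_that("canonical complex completeness matches the described cases", {
    cs <- evaluateComplexes(mkProfile(c("mtrA", "mtrB", "mtrC")),
                            cat_default)
    expect_identical(cs$state[cs$complex == "MtrCAB"], "COMPLETE")
    expect_false(any(cs$state[cs$complex != "MtrCAB"] == "COMPLETE"))

    cs <- evaluateComplexes(mkProfile("cwcA"), cat_default)
    expect_identical(cs$state[cs$complex == "CwcA"], "COMPLETE")

    cs <- evaluateComplexes(mkProfile(character(0)), cat_default)
    expect_true(all(cs$state == "ABSENT"))

    # an inventory of anchors alone completes nothing
    cs <- evaluateComplexes(mkProfile(c("pioA", "mtoA", "dmsA", "dmsE")),
                            cat_default)
    expect_false(any(cs$state == "COMPLETE"))
    expect_true(any(cs$state == "PARTIAL"))
})

test_that("hybrid assembly reproduces the cross-pathway cases", {
    hy <- assembleHybrids(mkProfile(c("dmsA", "mtrB", "mtrA", "mtrF")),
                          cat_default)
    expect_true(any(hy$porin == "mtrB" & hy$anchor == "mtrA" &
                        hy$omc == "mtrF"))
    # the canonical MtrCAB set itself must never appear as a hybrid
    expect_false(any(hy$porin == "mtrB" & hy$anchor == "mtrA" &
                         hy$omc == "mtrC"))

    hy <- assembleHybrids(mkProfile(c("mtoA", "therJR_2595", "dmsF")),
                          cat_default)
    expect_identical(nrow(hy), 1L)
    expect_identical(hy$porin, "dmsF")
    expect_identical(hy$anchor, "mtoA")
    expect_identical(hy$omc, "therJR_2595")

    # a lone periplasmic carrier can form nothing
    expect_identical(nrow(assembleHybrids(mkProfile("mtoD"), cat_default)),
                     0L)
    # anchors without a porin cannot form a hybrid
    expect_identical(nrow(assembleHybrids(
        mkProfile(c("pioA", "mtoA", "dmsA", "dmsE")), cat_default)), 0L)
})

test_that("hybrids and completeness agree with brute force on random inventories", {
    set.seed(42)
    for (i in 1:100) {
        inv <- randomInventory(cat_default)
        p <- mkProfile(inv)
        hy <- assembleHybrids(p, cat_default)
        got <- sort(paste(hy$porin, hy$anchor, hy$omc, sep = "|"))
        expect_identical(got, oracleHybrids(inv, cat_default))
        cs <- evaluateComplexes(p, cat_default)
        expect_identical(stats::setNames(cs$state, cs$complex),
                         oracleCompleteness(inv, cat_default))
    }
})

test_that("the engine ignores gene order and duplicate copies", {
    set.seed(7)
    inv <- c("mtrA", "mtrB", "mtrC", "cwcA", "dmsF", "mtoA", "omcS")
    a <- evaluateComplexes(mkProfile(inv), cat_default)
    b <- evaluateComplexes(mkProfile(rev(c(inv, inv))), cat_default)
    expect_identical(a$state, b$state)
    expect_identical(a$present, b$present)
    ha <- assembleHybrids(mkProfile(inv), cat_default)
    hb <- assembleHybrids(mkProfile(sample(c(inv, inv))), cat_default)
    expect_identical(ha[, c("porin", "anchor", "omc")],
                     hb[, c("porin", "anchor", "omc")])
    # four copies of the single-gene complex still count once, reported
    cs <- evaluateComplexes(mkProfile(rep("cwcA", 4L)), cat_default)
    expect_identical(cs$state[cs$complex == "CwcA"], "COMPLETE")
    expect_equal(cs$n_copies[cs$complex == "CwcA"], 4L,
                 ignore_attr = TRUE)
})

test_that("adding a gene never removes evidence (monotonicity)", {
    set.seed(99)
    for (i in 1:30) {
        inv <- randomInventory(cat_default, max_genes = 8L)
        extra <- sample(setdiff(catalogLabels(cat_default), inv), 1L)
        p0 <- mkProfile(inv); p1 <- mkProfile(c(inv, extra))
        c0 <- evaluateComplexes(p0, cat_default)
        c1 <- evaluateComplexes(p1, cat_default)
        expect_true(all(c0$complex[c0$state == "COMPLETE"] %in%
                            c1$complex[c1$state == "COMPLETE"]))
        h0 <- assembleHybrids(p0, cat_default)
        h1 <- assembleHybrids(p1, cat_default)
        k <- function(h) paste(h$porin, h$anchor, h$omc, sep = "|")
        dropped <- setdiff(k(h0), k(h1))
        # a hybrid may only disappear by becoming a canonical complete set
        if (length(dropped)) {
            req <- vapply(catalogComplexes(cat_default), function(cx)
                paste(sort(cx@required), collapse = ","), "")
            for (d in dropped)
                expect_true(paste(sort(strsplit(d, "|", fixed = TRUE)[[1L]]),
                                  collapse = ",") %in% req)
        }
        m0 <- scoreMotility(p0, cat_default)$count
        m1 <- scoreMotility(p1, cat_default)$count
        expect_gte(m1, m0)
    }
})

test_that("motility scoring applies the >30-of-55 rule and overrides", {
    flag <- flagellarSet(cat_default)
    m <- scoreMotility(mkProfile(flag[1:31]), cat_default)
    expect_true(m$motile); expect_identical(m$count, 31L)
    m <- scoreMotility(mkProfile(flag[1:30]), cat_default)
    expect_false(m$motile)
    # an incomplete genome assumed motile on external grounds
    m <- scoreMotility(mkProfile(flag[1:23]), cat_default, override = TRUE)
    expect_true(m$motile); expect_identical(m$count, 23L)
    expect_true(m$override)
    m <- scoreMotility(mkProfile(character(0)), cat_default)
    expect_false(m$motile); expect_identical(m$count, 0L)
})

test_that("conduit and shuttle flags split presence from transcription", {
    p <- mkProfile(c("ribBA", "yeeO"), low = FALSE, high = TRUE)
    fl <- conduitShuttleFlags(p, cat_default)
    for (capname in c("flavin_synthesis", "flavin_export")) {
        row <- fl[fl$capability == capname, ]
        expect_true(row$present)
        expect_true(row$transcribed_high)
        expect_false(row$transcribed_low)
    }
    # incomplete pump is not a pump
    fl <- conduitShuttleFlags(mkProfile(c("mexG", "mexH")), cat_default)
    expect_false(fl$present[fl$capability == "pump"])
    fl <- conduitShuttleFlags(
        mkProfile(c("mexG", "mexH", "mexI", "opmD")), cat_default)
    expect_true(fl$present[fl$capability == "pump"])
    # present but silent
    fl <- conduitShuttleFlags(mkProfile("phzE", low = FALSE, high = FALSE),
                              cat_default)
    row <- fl[fl$capability == "phenazine_synthesis", ]
    expect_true(row$present)
    expect_false(row$transcribed_low || row$transcribed_high)
    # conduits
    fl <- conduitShuttleFlags(mkProfile(c("macA", "cbcL"), low = TRUE),
                              cat_default)
    expect_true(fl$present[fl$capability == "conduit"])
    expect_true(fl$transcribed_low[fl$capability == "conduit"])
})

test_that("complex transcription needs only one member gene", {
    p <- MAGProfile("M1", data.frame(
        gene_id = c("g1", "g2", "g3"),
        label = c("mtrA", "mtrB", "mtrC"), length_bp = 1000,
        transcribed_low = c(FALSE, FALSE, TRUE),
        transcribed_high = FALSE))
    cs <- evaluateComplexes(p, cat_default)
    row <- cs[cs$complex == "MtrCAB", ]
    expect_true(row$transcribed_low)
    expect_false(row$transcribed_high)
})
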