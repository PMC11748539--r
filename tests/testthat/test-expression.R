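mkCounts <- function(m, labels = NA_character_, mags = "MAGX",
                     length_bp = 1000,
                     condition = rep(c("LOW", "HIGH"), each = ncol(m) / 2)) {
    m <- as.matrix(m)
    if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
    tc <- TranscriptCounts(
        m,
        data.frame(mag_id = rep_len(mags, nrow(m)),
                   label = rep_len(labels, nrow(m)),
                   length_bp = rep_len(length_bp, nrow(m))),
        data.frame(condition = condition,
                   day = ifelse(condition == "LOW", 3L, 26L),
                   row.names = colnames(m)))
    rownames(tc) <- rownames(m)
    tc
}

test_that("rpkm matches its defining formula", {
    # gene of 1,000 bp with 10 reads in a 1,000,000-read library -> 10.0
    m <- rbind(c(10, 0), c(999990, 1000000))
    tc <- mkCounts(m, length_bp = c(1000, 50000),
                   condition = c("LOW", "HIGH"))
    r <- rpkm(tc)
    expect_equal(r[1, 1], 10.0)
    expect_equal(r[1, 2], 0.0)
    set.seed(4)
    m <- matrix(rpois(24, 200), nrow = 6)
    len <- sample(300:3000, 6)
    tc <- mkCounts(m, length_bp = len,
                   condition = rep(c("LOW", "HIGH"), each = 2))
    r <- rpkm(tc)
    for (i in 1:6) for (j in 1:4)
        expect_equal(r[i, j], m[i, j] * 1e9 / (len[i] * sum(m[, j])))
    # a zero-count gene row does not perturb other genes' RPKM
    m2 <- rbind(m, 0L)
    tc2 <- mkCounts(m2, length_bp = c(len, 500),
                    condition = rep(c("LOW", "HIGH"), each = 2))
    expect_equal(rpkm(tc2)[1:6, ], r, ignore_attr = TRUE)
})

test_that("size factors follow median-of-ratios", {
    m <- matrix(rpois(200, 100) + 1L, ncol = 2)
    m <- cbind(m[, 1], m[, 1])  # identical samples
    tc <- mkCounts(m, condition = c("LOW", "HIGH"))
    expect_equal(unname(sizeFactors(tc)), c(1, 1))
    # exact doubling
    tc <- mkCounts(cbind(m[, 1], 2L * m[, 1]), condition = c("LOW", "HIGH"))
    sf <- sizeFactors(tc)
    expect_equal(unname(sf[2] / sf[1]), 2)
    # random matrix against a direct recomputation
    set.seed(9)
    m <- matrix(rnbinom(600, mu = 150, size = 5) + 1L, ncol = 6)
    tc <- mkCounts(m, condition = rep(c("LOW", "HIGH"), each = 3))
    sf <- sizeFactors(tc)
    ref <- exp(rowMeans(log(m)))
    raw <- apply(m / ref, 2, median)
    expect_equal(unname(sf), unname(raw / exp(mean(log(raw)))))
    # no gene positive everywhere -> upper-quartile fallback with warning
    m0 <- rbind(c(5L, 0L), c(0L, 9L), c(3L, 0L), c(0L, 7L))
    expect_warning(sf0 <- sizeFactors(mkCounts(m0,
        condition = c("LOW", "HIGH"))), "upper-quartile")
    expect_true(all(sf0 > 0))
})

test_that("the NB Wald test is symmetric and handles flat genes", {
    set.seed(21)
    sim <- simulateTranscripts(n_genes = 300L, base_sd_log = 0.5,
                               fold = 4, de_fraction = 0.1, seed = 22)
    de <- nbDiffTest(sim$counts)
    # swapping condition labels negates every log2 fold change
    sw <- sim$counts
    cd <- SummarizedExperiment::colData(sw)
    cd$condition <- ifelse(cd$condition == "LOW", "HIGH", "LOW")
    sw <- TranscriptCounts(SummarizedExperiment::assay(sw, "counts"),
                           as.data.frame(SummarizedExperiment::rowData(sw)),
                           as.data.frame(cd))
    rownames(sw) <- rownames(sim$counts)
    de_sw <- nbDiffTest(sw)
    expect_equal(de_sw$log2_fold_change, -de$log2_fold_change,
                 tolerance = 1e-6)
    # identical counts in every sample: fold change 0, not significant
    m <- matrix(rep(c(50L, 80L, 120L, 10L, 600L), 6), ncol = 6)
    de_flat <- nbDiffTest(mkCounts(m))
    expect_equal(de_flat$log2_fold_change, rep(0, 5), tolerance = 1e-6)
    expect_false(any(de_flat$significant_high))
    # all-zero genes are excluded from the family
    m0 <- rbind(matrix(rpois(60, 80), nrow = 10), 0L)
    expect_identical(nrow(nbDiffTest(mkCounts(m0))), 10L)
    # a single-condition design is refused
    expect_error(nbDiffTest(mkCounts(matrix(rpois(12, 50), nrow = 2),
                                     condition = rep("HIGH", 6))),
                 "condition|LOW")
})

test_that("planted fold changes are recovered in agreement with DESeq2", {
    suppressMessages(library(DESeq2))
    sim <- simulateTranscripts(n_genes = 400L, base_sd_log = 0.5,
                               fold = 8, de_fraction = 0.08, seed = 31)
    de <- nbDiffTest(sim$counts)
    cts <- SummarizedExperiment::assay(sim$counts, "counts")
    keep <- rowSums(cts) > 0
    dds <- DESeqDataSetFromMatrix(
        cts[keep, ],
        data.frame(condition = factor(
            SummarizedExperiment::colData(sim$counts)$condition,
            levels = c("LOW", "HIGH"))),
        ~condition)
    dds <- suppressMessages(DESeq(dds, quiet = TRUE))
    rr <- results(dds)
    common <- intersect(de$gene_id, rownames(rr))
    lfc_a <- de$log2_fold_change[match(common, de$gene_id)]
    lfc_b <- rr$log2FoldChange[match(common, rownames(rr))]
    expect_gt(cor(lfc_a, lfc_b, use = "complete.obs"), 0.9)
    hits_a <- de$gene_id[de$significant_high]
    hits_b <- rownames(rr)[!is.na(rr$padj) & rr$padj < 0.05 &
                               rr$log2FoldChange > 0]
    planted <- sim$truth$de_genes
    expect_gt(mean(planted %in% hits_a), 0.85)
    jacc <- length(intersect(hits_a, hits_b)) /
        length(union(hits_a, hits_b))
    expect_gt(jacc, 0.5)
})

test_that("per-MAG RPKM aggregation ranks expressers deterministically", {
    cat_default <- defaultCatalog()
    # MAG A: pcc expression only in HIGH; MAG B: smaller in both;
    # MAG C: no catalog-class genes at all
    m <- rbind(A1 = c(0, 0, 4000, 4000),
               B1 = c(500, 500, 500, 500),
               C1 = c(900, 900, 900, 900),
               fill = c(98600, 98600, 94600, 94600))
    tc <- mkCounts(m, labels = c("mtrC", "cwcA", NA, NA),
                   mags = c("A", "B", "C", "C"),
                   condition = c("LOW", "LOW", "HIGH", "HIGH"))
    agg <- aggregateMagExpression(tc, cat_default, "PCC", k = 5)
    expect_identical(agg$mag_id[1], "A")
    expect_equal(agg$rpkm_low[agg$mag_id == "A"], 0)
    expect_gt(agg$rpkm_high[agg$mag_id == "A"],
              agg$rpkm_high[agg$mag_id == "B"])
    expect_equal(agg$rpkm_low[agg$mag_id == "C"], 0)
    expect_equal(agg$rpkm_high[agg$mag_id == "C"], 0)
    # equal totals break ties by MAG id
    m2 <- rbind(x = c(100, 100, 100, 100), y = c(100, 100, 100, 100),
                fill = c(9800, 9800, 9800, 9800))
    tc2 <- mkCounts(m2, labels = c("mtrC", "omcS", NA),
                    mags = c("Zeta", "Alpha", "Q"),
                    condition = c("LOW", "LOW", "HIGH", "HIGH"))
    agg2 <- aggregateMagExpression(tc2, cat_default, "PCC")
    expect_identical(agg2$mag_id[1:2], c("Alpha", "Zeta"))
    # shuttle class selects shuttle genes only
    agg3 <- aggregateMagExpression(tc, cat_default, "SHUTTLE")
    expect_true(all(agg3$total == 0))
})
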