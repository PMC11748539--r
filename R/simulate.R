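## Seeded synthetic-data generators with known ground truth: a community
## time series with a focal bloom and planted correlated genera, MAG gene
## inventories drawn from archetypes, and negative-binomial transcript
## counts with planted upregulation of designated flocker EET genes.

#' Community simulation parameters
#'
#' Defaults emulate a 76-day enrichment time series: nine time points,
#' sixteen samples (duplicates at most time points), a focal genus that
#' blooms logistically to about 55\% of the community around days 26-33 and
#' then declines slowly, per-sample library sizes log-uniform over the
#' 3,909-132,888 read range, and Dirichlet-multinomial count noise.
#' Correlated genera track the focal genus through a multiplicative
#' association on their expected fractions, imposed before compositional
#' closure; background genera fluctuate independently.
#'
#' @param days day of each sample.
#' @param series series label of each sample.
#' @param peak_fraction peak focal fractional abundance, in (0, 1).
#' @param rise_midpoint,rise_rate logistic bloom midpoint (day) and rate
#'   (per day).
#' @param decline_day,decline_rate day the slow exponential decline starts,
#'   and its rate (per day).
#' @param n_correlated,strength number of planted correlated genera and
#'   their association strength in [0, 1].
#' @param n_background number of independent background genera.
#' @param concentration Dirichlet concentration; \code{Inf} disables all
#'   count noise (deterministic expected counts).
#' @param background_sd log-scale sd of independent background fluctuation.
#' @param lib_range per-sample library-size range (log-uniform draw).
#' @param unclassified_fraction community share of genus-unclassified ASVs.
#' @param focal_genus focal genus name.
#' @param seed RNG seed (set via \code{set.seed}).
#' @return a list of class \code{community_sim_params}.
#' @export
communitySimParams <- function(
        days = c(3, 3, 6, 6, 13, 13, 19, 19, 26, 26, 33, 33, 47, 47, 61, 76),
        series = "TS1", peak_fraction = 0.55, rise_midpoint = 15,
        rise_rate = 0.25, decline_day = 33, decline_rate = 0.004,
        n_correlated = 5L, strength = 0.8, n_background = 45L,
        concentration = 5000, background_sd = 0.3,
        lib_range = c(3909, 132888), unclassified_fraction = 0.02,
        focal_genus = "Ca. Electronema", seed = 1L) {
    stopifnot(peak_fraction > 0, peak_fraction < 1,
              strength >= 0, strength <= 1, all(lib_range > 0),
              n_correlated >= 0, n_background >= 1, length(days) >= 4L)
    structure(as.list(environment()), class = "community_sim_params")
}

.focalTrajectory <- function(day, p) {
    f <- p$peak_fraction * stats::plogis(p$rise_rate * (day - p$rise_midpoint))
    decl <- ifelse(day > p$decline_day,
                   exp(-p$decline_rate * (day - p$decline_day)), 1)
    f * decl
}

#' Simulate an amplicon community time series with known ground truth
#'
#' See [communitySimParams()] for the generative model. Each genus is
#' emitted as one or two ASV rows (the focal genus as two) plus a few
#' genus-unclassified ASVs, so the pruning and agglomeration steps are
#' exercised.
#'
#' @param params a [communitySimParams()] list.
#' @return list with \code{table} (an [AmpliconExperiment-class]) and
#'   \code{truth} (focal genus, correlated genus names, baselines).
#' @export
simulateCommunity <- function(params = communitySimParams()) {
    p <- params
    set.seed(p$seed)
    n <- length(p$days)
    f <- .focalTrajectory(p$days, p)

    base_corr <- exp(stats::runif(p$n_correlated, log(0.02), log(0.05)))
    base_bg <- exp(stats::runif(p$n_background, log(1e-4), log(0.02)))
    corr_names <- sprintf("CorrGenus%02d", seq_len(p$n_correlated))
    bg_names <- sprintf("BgGenus%02d", seq_len(p$n_background))

    noiseless <- is.infinite(p$concentration)
    ## correlated genera receive their expected fraction directly, so the
    ## planted multiplicative association survives compositional closure;
    ## only the background pool absorbs the remainder
    p_corr <- outer(base_corr, 1 + p$strength * f)
    rest <- 1 - f - (if (p$n_correlated) colSums(p_corr) else 0)
    if (any(rest <= 0.05))
        stop("degenerate params: focal bloom plus correlated genera ",
             "exceed 95% of the community")
    bg_fluct <- if (noiseless) 1 else
        exp(matrix(stats::rnorm(p$n_background * n, 0, p$background_sd),
                   ncol = n))
    w_bg <- outer(base_bg, rep(1, n)) * bg_fluct
    w_un <- matrix(rep(p$unclassified_fraction / 3, 3L * n), ncol = n)
    w <- rbind(w_bg, w_un)
    w <- sweep(w, 2L, rest / colSums(w), "*")
    w <- rbind(p_corr, w)

    ## split each genus into ASVs: focal 2, others 1 each
    asv_w <- rbind(f * 0.6, f * 0.4, w)
    genus <- c(p$focal_genus, p$focal_genus, corr_names, bg_names,
               rep("", 3L))
    taxon_id <- sprintf("ASV%03d", seq_along(genus))
    rownames(asv_w) <- taxon_id

    lib <- if (noiseless)
        rep(round(exp(mean(log(p$lib_range)))), n)
    else round(exp(stats::runif(n, log(p$lib_range[1]),
                                log(p$lib_range[2]))))
    counts <- matrix(0L, nrow(asv_w), n, dimnames = list(
        taxon_id, sprintf("S%02d_d%03d", seq_len(n), p$days)))
    for (j in seq_len(n)) {
        pr <- asv_w[, j]
        if (noiseless) {
            counts[, j] <- as.integer(round(pr * lib[j]))
        } else {
            g <- stats::rgamma(length(pr), shape = p$concentration * pr)
            if (sum(g) <= 0) g <- pr
            counts[, j] <- as.integer(stats::rmultinom(1L, lib[j],
                                                       g / sum(g)))
        }
    }
    taxonomy <- data.frame(
        domain = "Bacteria", phylum = "SimPhylum", class = "SimClass",
        order = "SimOrder", family = "SimFamily", genus = genus,
        species = "")
    taxonomy$family[genus == p$focal_genus] <- "Desulfobulbaceae"
    samples <- data.frame(day = p$days, series = p$series,
                          row.names = colnames(counts))
    tab <- AmpliconExperiment(counts, taxonomy, samples)
    list(table = tab,
         truth = list(focal_genus = p$focal_genus,
                      correlated_genera = corr_names,
                      background_genera = bg_names,
                      baselines = c(base_corr, base_bg),
                      focal_trajectory = f))
}

#' Genome simulation parameters
#'
#' Archetypes plant one evidence pattern each: \code{COMPLETE_PCC_TRANSCRIBER}
#' (a complete canonical complex, transcribed in both conditions),
#' \code{HYBRID_ONLY} (a functional cross-pathway hybrid, untranscribed),
#' \code{PARTIAL_PCC} (a complex lacking exactly one required gene),
#' \code{SHUTTLE_ONLY}, \code{CONDUIT_ONLY} and \code{EMPTY}, each in motile
#' and non-motile flavours. Among the motile complete transcribers,
#' \code{n_supported_de} receive planted differential expression of their
#' EET genes and \code{n_supported_corr} receive a genus from the correlated
#' pool; these are the ground-truth \code{SUPPORTED_CANDIDATE}s.
#'
#' @param archetype_counts data.frame with columns \code{archetype},
#'   \code{motile}, \code{n}.
#' @param genes_per_genome total genes per MAG (filler genes unlabelled).
#' @param flagellar_motile,flagellar_nonmotile flagellar genes given to
#'   motile (> 30) and non-motile genomes.
#' @param n_supported_de,n_supported_corr numbers of motile complete
#'   transcribers designated as DE-supported / correlation-supported true
#'   flockers.
#' @param correlated_genus_pool genus names matching the community
#'   simulation's correlated genera.
#' @param seed RNG seed.
#' @return a list of class \code{genome_sim_params}.
#' @export
genomeSimParams <- function(
        archetype_counts = data.frame(
            archetype = rep(c("COMPLETE_PCC_TRANSCRIBER", "HYBRID_ONLY",
                              "PARTIAL_PCC", "SHUTTLE_ONLY", "CONDUIT_ONLY",
                              "EMPTY"), each = 2L),
            motile = rep(c(TRUE, FALSE), 6L),
            n = c(4L, 2L, 3L, 1L, 4L, 2L, 3L, 2L, 3L, 2L, 2L, 2L)),
        genes_per_genome = 100L, flagellar_motile = 40L,
        flagellar_nonmotile = 10L, n_supported_de = 2L,
        n_supported_corr = 1L,
        correlated_genus_pool = sprintf("CorrGenus%02d", 1:5),
        seed = 1L) {
    stopifnot(all(archetype_counts$n >= 0), flagellar_motile > 30,
              flagellar_nonmotile <= 30)
    structure(as.list(environment()), class = "genome_sim_params")
}

## a hybrid triple that neither equals nor contains any canonical complex
.sampleHybridTriple <- function(catalog) {
    hs <- hybridSlots(catalog)
    req_sets <- lapply(catalogComplexes(catalog), slot, "required")
    repeat {
        triple <- c(sample(hs$porin, 1L), sample(hs$anchor, 1L),
                    sample(hs$omc, 1L))
        contains <- any(vapply(req_sets,
                               function(r) all(r %in% triple), NA))
        if (!contains) return(triple)
    }
}

#' Simulate MAG gene inventories from archetypes
#'
#' Every generated inventory satisfies its archetype's defining predicate
#' and violates all stronger ones (verified against the rule engine by the
#' package tests, not assumed).
#'
#' @param params a [genomeSimParams()] list.
#' @param catalog an [EETCatalog-class].
#' @return list with \code{profiles} (list of [MAGProfile-class]) and
#'   \code{truth} (data.frame of planted attributes and the tier each MAG
#'   should receive).
#' @export
simulateGenomes <- function(params = genomeSimParams(),
                            catalog = defaultCatalog()) {
    p <- params
    set.seed(p$seed)
    multi <- Filter(function(cx) length(cx@required) > 1L,
                    catalogComplexes(catalog))
    cond_tr <- conduitLabels(catalog)

    spec_rows <- p$archetype_counts[rep(seq_len(nrow(p$archetype_counts)),
                                        p$archetype_counts$n), ]
    n_mags <- nrow(spec_rows)
    ## designate supported flockers among motile complete transcribers
    idx_ct <- which(spec_rows$archetype == "COMPLETE_PCC_TRANSCRIBER" &
                        spec_rows$motile)
    de_idx <- utils::head(idx_ct, p$n_supported_de)
    corr_idx <- utils::head(setdiff(idx_ct, de_idx), p$n_supported_corr)

    profiles <- vector("list", n_mags)
    truth <- vector("list", n_mags)
    genus_counter <- 0L
    for (i in seq_len(n_mags)) {
        arch <- spec_rows$archetype[i]
        motile <- spec_rows$motile[i]
        mag_id <- sprintf("MAG%02d", i)
        labels <- character(0); low <- logical(0); high <- logical(0)
        add <- function(lab, tl, th) {
            labels <<- c(labels, lab)
            low <<- c(low, rep(tl, length(lab)))
            high <<- c(high, rep(th, length(lab)))
        }
        has_complete <- FALSE; has_hybrid <- FALSE; pcc_tr <- FALSE
        if (arch == "COMPLETE_PCC_TRANSCRIBER") {
            cx <- multi[[sample(length(multi), 1L)]]
            add(cx@required, TRUE, TRUE)
            add(sample(cond_tr, 3L), TRUE, TRUE)
            has_complete <- TRUE; pcc_tr <- TRUE
        } else if (arch == "HYBRID_ONLY") {
            add(.sampleHybridTriple(catalog), FALSE, FALSE)
            has_hybrid <- TRUE
        } else if (arch == "PARTIAL_PCC") {
            cx <- multi[[sample(length(multi), 1L)]]
            add(sample(cx@required, length(cx@required) - 1L), TRUE, TRUE)
        } else if (arch == "SHUTTLE_ONLY") {
            add(c("ribBA", "yeeO", "phzE", "ipdG"), TRUE, TRUE)
        } else if (arch == "CONDUIT_ONLY") {
            add(sample(cond_tr, 3L), TRUE, TRUE)
        }
        n_flag <- if (motile) p$flagellar_motile else p$flagellar_nonmotile
        if (n_flag > 0L)
            add(sample(flagellarSet(catalog), n_flag), FALSE, FALSE)
        n_filler <- max(0L, p$genes_per_genome - length(labels))
        gene_lab <- c(labels, rep(NA_character_, n_filler))
        gene_low <- c(low, rep(TRUE, n_filler))
        gene_high <- c(high, rep(TRUE, n_filler))
        genes <- data.frame(
            gene_id = sprintf("%s_g%03d", mag_id, seq_along(gene_lab)),
            label = gene_lab,
            length_bp = round(stats::runif(length(gene_lab), 300, 3000)),
            transcribed_low = gene_low, transcribed_high = gene_high)

        de_planted <- i %in% de_idx
        corr_flag <- i %in% corr_idx
        if (corr_flag) {
            genus <- p$correlated_genus_pool[[match(i, corr_idx)]]
        } else {
            genus_counter <- genus_counter + 1L
            genus <- sprintf("MagGenus%02d", genus_counter)
        }
        taxonomy <- c("Bacteria", "SimPhylum", "SimClass", "SimOrder",
                      "SimFamily", genus, "")
        profiles[[i]] <- MAGProfile(
            mag_id, genes, taxonomy,
            completeness = stats::runif(1, 90, 100),
            contamination = stats::runif(1, 0, 5))
        tier <- if (motile && (has_complete || has_hybrid)) {
            if (pcc_tr) {
                if (de_planted || corr_flag) "SUPPORTED_CANDIDATE"
                else "ACTIVE_CANDIDATE"
            } else "CANDIDATE"
        } else "NOT_CANDIDATE"
        truth[[i]] <- data.frame(
            mag_id = mag_id, archetype = arch, motile = motile,
            has_complete = has_complete, has_hybrid = has_hybrid,
            pcc_transcribed = pcc_tr, corr_genus = corr_flag,
            de_planted = de_planted, genus = genus, tier = tier)
    }
    list(profiles = profiles, truth = do.call(rbind, truth))
}

#' Simulate negative-binomial transcript counts
#'
#' Counts follow a negative binomial with per-gene log-normal baseline
#' means, per-sample library factors, and a planted fold change in the HIGH
#' condition for the EET genes of designated flocker MAGs. Genes a profile
#' marks untranscribed in a condition receive zero counts there. With
#' \code{dispersion = 0} and unit library factors counts are deterministic
#' (\code{round(mu)}), giving a noise-free matrix.
#'
#' Called without \code{profiles}, generates \code{n_genes} plain unlabelled
#' genes and plants \code{de_fraction} of them with the fold change - the
#' configuration used for null and power calibration of the DE stage.
#'
#' @param profiles list of [MAGProfile-class], or \code{NULL}.
#' @param catalog an [EETCatalog-class] (used to find EET genes).
#' @param de_mags MAG ids whose EET genes are upregulated in HIGH.
#' @param n_low,n_high samples per condition (days 3 and 26/33).
#' @param base_mean,base_sd_log log-normal baseline mean parameters.
#' @param dispersion NB dispersion (0 = deterministic counts).
#' @param fold planted HIGH/LOW fold change (1 = null).
#' @param lib_factor_range per-sample library factor range (log-uniform).
#' @param n_genes,de_fraction used only when \code{profiles} is \code{NULL}.
#' @param seed RNG seed.
#' @return list with \code{counts} (a [TranscriptCounts-class]) and
#'   \code{truth} (planted DE gene ids and MAG ids).
#' @export
simulateTranscripts <- function(profiles = NULL,
                                catalog = defaultCatalog(),
                                de_mags = character(0), n_low = 2L,
                                n_high = 4L, base_mean = 100,
                                base_sd_log = 1, dispersion = 0.2,
                                fold = 8, lib_factor_range = c(0.5, 2),
                                n_genes = 2000L, de_fraction = 0.05,
                                seed = 1L) {
    stopifnot(n_low >= 2L, n_high >= 2L, fold > 0, dispersion >= 0)
    set.seed(seed)
    if (is.null(profiles)) {
        genes <- data.frame(
            gene_id = sprintf("gene%04d", seq_len(n_genes)),
            mag_id = "SIM", label = NA_character_,
            length_bp = round(stats::runif(n_genes, 300, 3000)),
            transcribed_low = TRUE, transcribed_high = TRUE)
        de_genes <- if (fold != 1)
            sample(genes$gene_id, round(de_fraction * n_genes)) else
            character(0)
    } else {
        genes <- do.call(rbind, lapply(profiles, function(p) {
            g <- p@genes; g$mag_id <- p@magId
            g[, c("gene_id", "mag_id", "label", "length_bp",
                  "transcribed_low", "transcribed_high")]
        }))
        eet <- eetLabels(catalog)
        canon <- canonicalLabel(catalog, genes$label)
        de_genes <- genes$gene_id[genes$mag_id %in% de_mags &
                                      !is.na(canon) & canon %in% eet &
                                      genes$transcribed_high]
    }
    n_g <- nrow(genes)
    samples <- data.frame(
        condition = rep(c("LOW", "HIGH"), c(n_low, n_high)),
        day = c(rep(3L, n_low),
                rep(c(26L, 33L), length.out = n_high)),
        row.names = c(sprintf("low_%d", seq_len(n_low)),
                      sprintf("high_%d", seq_len(n_high))))
    n_s <- nrow(samples)
    mu_g <- exp(stats::rnorm(n_g, log(base_mean), base_sd_log))
    libf <- exp(stats::runif(n_s, log(lib_factor_range[1]),
                             log(lib_factor_range[2])))
    is_de <- genes$gene_id %in% de_genes
    on_low <- genes$transcribed_low
    on_high <- genes$transcribed_high
    counts <- matrix(0L, n_g, n_s,
                     dimnames = list(genes$gene_id, rownames(samples)))
    for (j in seq_len(n_s)) {
        hi <- samples$condition[j] == "HIGH"
        mu <- mu_g * libf[j] * (if (hi) on_high else on_low) *
            ifelse(is_de & hi, fold, 1)
        counts[, j] <- if (dispersion > 0)
            stats::rnbinom(n_g, mu = mu, size = 1 / dispersion)
        else as.integer(round(mu))
    }
    tc <- TranscriptCounts(
        counts, genes[, c("mag_id", "label", "length_bp")], samples)
    rownames(tc) <- genes$gene_id
    list(counts = tc,
         truth = list(de_genes = sort(genes$gene_id[is_de]),
                      de_mags = sort(unique(genes$mag_id[is_de]))))
}
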