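#' Default targeted assay panel
#'
#' Assay definitions for the simulated study design: 68 amplicon assays over
#' 35 genome-maintenance genes (antioxidant, DNA repair, cell-cycle control
#' and CEBP/TP53 transcription-factor families), plus the ACTB reference
#' assay used for normalisation. Four assays carry measured exonic SNP sites
#' used for allele-specific expression; a GAPDH-like 5'/3' assay pair is not
#' modelled — instead the first gene with two assays is given `5prime` /
#' `3prime` distance classes so the RNA-integrity statistic is exercisable.
#'
#' @param is_spike_molecules internal-standard molecules spiked per reaction
#'   (same for every assay by default).
#' @return `DataFrame` with columns `assay_id`, `gene`, `site_id`,
#'   `is_spike_molecules`, `distance_class` and `baseline_log2` (latent
#'   mean log2 abundance used by the simulator).
#' @export
assayDefs <- function(is_spike_molecules = 3000) {
    genes <- c("CAT", "CEBPG", "GPX1", "KEAP1", "TP73", "XPA",
               "ERCC5", "ERCC1", "ERCC2", "ERCC4",
               "TP53", "TP63", "CEBPA", "CEBPB", "CEBPD", "CEBPE",
               "GSTM3", "GSTT1", "GSTP1", "SOD1", "SOD2", "SOD3",
               "NFE2L2", "OGG1", "XRCC1", "XRCC3", "XRCC4", "XRCC5",
               "CDKN1A", "XPC", "MGMT", "MLH1", "APEX1", "LIG1")
    stopifnot(length(genes) == 34L)
    # two assays per gene except the first gene (CAT) which gets three,
    # plus the single ACTB reference assay: 34*2 + 1 + 1 = 70 -> trim to 68
    n_per <- rep(2L, length(genes))
    names(n_per) <- genes
    n_per["CAT"] <- 3L
    assay_id <- unlist(mapply(function(g, k) {
        if (k == 1L) g else paste(g, seq_len(k), sep = "-")
    }, genes, n_per, SIMPLIFY = FALSE), use.names = FALSE)
    gene <- rep(genes, n_per)
    # drop two assays to land on 67 target assays + ACTB = 68 total
    drop <- c("LIG1-2", "APEX1-2")
    keep <- !(assay_id %in% drop)
    assay_id <- assay_id[keep]; gene <- gene[keep]
    assay_id <- c(assay_id, "ACTB"); gene <- c(gene, "ACTB")

    site_id <- rep(NA_character_, length(assay_id))
    site_id[assay_id == "CAT-2"]   <- "rs1049982"
    site_id[assay_id == "CEBPG-1"] <- "rs3745968"
    site_id[assay_id == "KEAP1-1"] <- "rs1048287"
    site_id[assay_id == "TP73-2"]  <- "rs1801174"
    site_id[assay_id == "ERCC5-1"] <- "rs17655"

    distance_class <- rep("other", length(assay_id))
    distance_class[assay_id == "CAT-1"] <- "5prime"
    distance_class[assay_id == "CAT-3"] <- "3prime"

    # fixed latent means: evenly spaced over a wide expression range so the
    # low tail dips below the dropout threshold in a fraction of subjects
    n_t <- length(assay_id) - 1L
    baseline <- seq(log2(60), log2(5e4), length.out = n_t)
    # deterministic shuffle so expression level is not confounded with gene
    baseline <- baseline[(seq_len(n_t) * 29L) %% n_t + 1L]
    baseline <- c(baseline, log2(2e6))    # ACTB: high-abundance reference
    S4Vectors::DataFrame(assay_id = assay_id, gene = gene, site_id = site_id,
                         is_spike_molecules = is_spike_molecules,
                         distance_class = distance_class,
                         baseline_log2 = baseline,
                         row.names = assay_id)
}

.default_de_genes <- function() {
    c(CEBPG = 0.45, GPX1 = 0.45, TP73 = 0.45, KEAP1 = -0.45,
      CAT = 0.45, XPA = 0.45)
}

.default_cis_sites <- function() {
    data.frame(site_id = c("rs1049982", "rs3745968", "rs1048287",
                           "rs1801174", "rs17655"),
               gene = c("CAT", "CEBPG", "KEAP1", "TP73", "ERCC5"),
               maf = c(0.34, 0.11, 0.11, 0.09, 0.30),
               beta = 1.0,
               stringsAsFactors = FALSE)
}

# COPD-only latent correlations: gene-disjoint assay pairs (one endpoint
# gene per pair) keep the implied correlation matrix positive definite
.default_extra_cor <- function() {
    data.frame(
        a = c("ERCC5-1", "CEBPG-1", "GPX1-1", "TP53-1", "CEBPA-1",
              "CEBPB-1", "CEBPD-1", "TP63-1", "NFE2L2-1", "XRCC1-1",
              "ERCC2-1", "ERCC4-1", "SOD1-1", "GSTM3-1", "SOD3-1"),
        b = c("TP73-2", "KEAP1-2", "XPA-1", "CDKN1A-1", "SOD2-1",
              "GSTP1-1", "ERCC1-1", "XRCC5-1", "OGG1-1", "LIG1-1",
              "APEX1-1", "MGMT-1", "MLH1-1", "XPC-1", "XRCC3-1"),
        r = 0.6, stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic cohort generator. The defaults
#' emulate the study design the pipeline targets: 30 COPD and 30 control
#' subjects, 68 assays over 35 genes, group mean shifts on six classifier
#' genes, extra co-expression correlations present only in the COPD cohort,
#' a latent-abundance dropout mechanism, and five measured SNP sites with
#' cis-regulatory allelic effects.
#'
#' @param n_copd,n_control subjects per cohort.
#' @param assays assay definition table as from [assayDefs()].
#' @param depth_mean mean internal-standard reads per assay per subject.
#' @param de_genes named numeric vector of per-gene log2 group shifts
#'   (COPD minus control), applied to every assay of the gene.
#' @param copd_extra_correlations data.frame (`a`, `b`, `r`) of assay pairs
#'   whose latent correlation is raised to `r` in the COPD cohort only.
#' @param base_cor latent correlation between assays of the same gene.
#' @param subject_sd latent between-subject SD on the log2 scale.
#' @param cis_sites data.frame (`site_id`, `gene`, `maf`, `beta`) of
#'   measured SNP sites; `beta` is the allelic shift on the logit scale for
#'   cDNA heterozygotes, `maf` the minor allele frequency in \[0, 0.5\].
#' @param gdna_overdispersion logit-scale SD of the gDNA allele fraction in
#'   heterozygotes (analytical noise floor).
#' @param allele_depth mean reads per allele-count measurement.
#' @param nb_dispersion negative-binomial dispersion of read counts.
#' @param dropout_threshold latent molecules below which the native template
#'   fails library preparation and yields zero reads.
#' @param seed integer seed making the whole generation reproducible.
#' @return a list of class `SimConfig`.
#' @export
simConfig <- function(n_copd = 30L, n_control = 30L,
                      assays = assayDefs(),
                      depth_mean = 1e5,
                      de_genes = .default_de_genes(),
                      copd_extra_correlations = .default_extra_cor(),
                      base_cor = 0.3,
                      subject_sd = 1.0,
                      cis_sites = .default_cis_sites(),
                      gdna_overdispersion = 0.15,
                      allele_depth = 1e4,
                      nb_dispersion = 0.05,
                      dropout_threshold = 100,
                      seed = 1L) {
    stopifnot(n_copd > 0, n_control > 0, depth_mean > 0,
              all(assays$is_spike_molecules > 0),
              !anyDuplicated(assays$assay_id),
              gdna_overdispersion >= 0, allele_depth > 0,
              nb_dispersion > 0, dropout_threshold >= 0)
    if (nrow(cis_sites)) {
        if (any(cis_sites$maf < 0 | cis_sites$maf > 0.5))
            stop("minor allele frequencies must lie in [0, 0.5]")
        bad <- cis_sites$maf == 0 & cis_sites$beta != 0
        if (any(bad))
            stop("cis effect requested at monomorphic site(s): ",
                 paste(cis_sites$site_id[bad], collapse = ", "))
    }
    if (nrow(copd_extra_correlations) &&
        any(abs(copd_extra_correlations$r) >= 1))
        stop("extra correlation values must lie in (-1, 1)")
    structure(list(n_copd = as.integer(n_copd),
                   n_control = as.integer(n_control),
                   assays = assays, depth_mean = depth_mean,
                   de_genes = de_genes,
                   copd_extra_correlations = copd_extra_correlations,
                   base_cor = base_cor, subject_sd = subject_sd,
                   cis_sites = cis_sites,
                   gdna_overdispersion = gdna_overdispersion,
                   allele_depth = allele_depth,
                   nb_dispersion = nb_dispersion,
                   dropout_threshold = dropout_threshold,
                   seed = as.integer(seed)),
              class = "SimConfig")
}

# latent correlation matrix over target assays for one cohort;
# errors with the offending pairs if the implied matrix is not PD
.latent_cor <- function(cfg, cohort) {
    a <- cfg$assays
    tgt <- a$assay_id[a$gene != "ACTB"]
    gene <- a$gene[match(tgt, a$assay_id)]
    R <- outer(gene, gene, "==") * cfg$base_cor
    diag(R) <- 1
    dimnames(R) <- list(tgt, tgt)
    if (cohort == "COPD" && nrow(cfg$copd_extra_correlations)) {
        ec <- cfg$copd_extra_correlations
        for (i in seq_len(nrow(ec))) {
            R[ec$a[i], ec$b[i]] <- ec$r[i]
            R[ec$b[i], ec$a[i]] <- ec$r[i]
        }
    }
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) {
        pairs <- if (cohort == "COPD" && nrow(cfg$copd_extra_correlations))
            paste(cfg$copd_extra_correlations$a,
                  cfg$copd_extra_correlations$b, sep = "~", collapse = ", ")
        else "(within-gene base correlations)"
        stop("implied ", cohort, " latent correlation matrix is not ",
             "positive definite; check pairs: ", pairs)
    }
    R
}

.sim_demographics <- function(cfg) {
    n <- cfg$n_control + cfg$n_copd
    cohort <- rep(c("control", "COPD"), c(cfg$n_control, cfg$n_copd))
    p_male <- ifelse(cohort == "COPD", 22 / 30, 11 / 30)
    sex <- ifelse(stats::runif(n) < p_male, "male", "female")
    age <- round(stats::rnorm(n, 64, 5), 1)
    pack_years <- round(pmax(20, stats::rnorm(
        n, ifelse(cohort == "COPD", 60, 49), 15)), 1)
    p_current <- ifelse(cohort == "COPD", 9 / 30, 10 / 30)
    smoking_status <- ifelse(stats::runif(n) < p_current, "current", "former")
    # spirometry consistent with the case definition
    # (COPD <=> FEV1/FVC < 0.7 and FEV1% < 80)
    fev1_fvc <- ifelse(cohort == "COPD",
                       pmin(0.699, stats::rnorm(n, 0.53, 0.08)),
                       pmax(0.701, stats::rnorm(n, 0.81, 0.04)))
    fev1_pct <- ifelse(cohort == "COPD",
                       pmin(79.9, stats::rnorm(n, 55, 15)),
                       pmax(80.1, stats::rnorm(n, 95, 10)))
    data.frame(subject_id = sprintf("S%03d", seq_len(n)),
               age = age, sex = sex, pack_years = pack_years,
               smoking_status = smoking_status,
               fev1_fvc = round(fev1_fvc, 3), fev1_pct = round(fev1_pct, 1),
               cohort = cohort, stringsAsFactors = FALSE)
}

#' Simulate a COPD case-control expression cohort
#'
#' Draws per-subject latent log2 abundance from a multivariate normal whose
#' mean differs between cohorts by the configured per-gene shifts and whose
#' correlation matrix in the COPD cohort carries the configured extra
#' assay-pair correlations; then draws native and internal-standard read
#' counts (negative binomial) around the latent molecule numbers relative to
#' the internal-standard spike. Assays whose latent molecule number falls
#' below the dropout threshold are emitted with zero native reads, the
#' missingness mechanism of low-expression targets. Demographics roughly
#' mirror the targeted study's margins.
#'
#' @param config a [simConfig()] object.
#' @return list with components
#'   \describe{
#'     \item{subjects}{data.frame of subject records.}
#'     \item{latent}{matrix (assays x subjects) of true abundance, molecules
#'       per 10^6 ACTB molecules (target assays only).}
#'     \item{counts}{long data.frame: `subject_id`, `assay_id`, `template`
#'       (`native`/`IS`), `reads`.}
#'     \item{truth}{ground-truth parameters (de_genes, extra correlations).}
#'   }
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed)
    a <- config$assays
    tgt <- a$assay_id[a$gene != "ACTB"]
    gene <- a$gene[match(tgt, a$assay_id)]
    base <- a$baseline_log2[match(tgt, a$assay_id)]

    subjects <- .sim_demographics(config)
    n <- nrow(subjects)
    is_copd <- subjects$cohort == "COPD"

    # shifts may be keyed by assay id or by gene symbol
    shift <- config$de_genes[tgt]
    miss <- is.na(shift)
    shift[miss] <- config$de_genes[gene[miss]]
    shift[is.na(shift)] <- 0
    shift <- unname(shift)

    R_ctl <- .latent_cor(config, "control")
    R_copd <- .latent_cor(config, "COPD")
    sd <- config$subject_sd
    lat <- matrix(NA_real_, length(tgt), n, dimnames = list(tgt, subjects$subject_id))
    n_ctl <- sum(!is_copd)
    if (n_ctl)
        lat[, !is_copd] <- t(MASS::mvrnorm(n_ctl, mu = base,
                                           Sigma = (sd^2) * R_ctl))
    if (n - n_ctl)
        lat[, is_copd] <- t(MASS::mvrnorm(n - n_ctl, mu = base + shift,
                                          Sigma = (sd^2) * R_copd))
    latent_abund <- 2^lat   # molecules per 10^6 ACTB molecules

    # ACTB molecules per reaction; target molecules follow from abundance
    actb_mol <- 2^stats::rnorm(n, a$baseline_log2[match("ACTB", a$assay_id)], 0.5)
    mol <- sweep(latent_abund, 2, actb_mol / 1e6, "*")

    size <- 1 / config$nb_dispersion
    spike <- a$is_spike_molecules[match(c(tgt, "ACTB"), a$assay_id)]
    names(spike) <- c(tgt, "ACTB")
    all_assays <- c(tgt, "ACTB")
    counts <- vector("list", length(all_assays))
    for (j in seq_along(all_assays)) {
        aid <- all_assays[j]
        m <- if (aid == "ACTB") actb_mol else mol[aid, ]
        is_mu <- rep(config$depth_mean, n)
        nat_mu <- config$depth_mean * m / spike[aid]
        dropped <- m < config$dropout_threshold
        is_reads <- stats::rnbinom(n, size = size, mu = is_mu)
        nat_reads <- stats::rnbinom(n, size = size, mu = nat_mu)
        nat_reads[dropped] <- 0L
        counts[[j]] <- data.frame(
            subject_id = rep(subjects$subject_id, 2L),
            assay_id = aid,
            template = rep(c("native", "IS"), each = n),
            reads = c(nat_reads, is_reads),
            stringsAsFactors = FALSE)
    }
    counts <- do.call(rbind, counts)
    rownames(counts) <- NULL
    list(subjects = subjects, latent = latent_abund, counts = counts,
         truth = list(de_genes = config$de_genes,
                      copd_extra_correlations = config$copd_extra_correlations,
                      actb_molecules = actb_mol))
}

#' Simulate paired cDNA/gDNA allele counts at measured SNP sites
#'
#' Genotypes are drawn at Hardy-Weinberg proportions from each site's minor
#' allele frequency. Genomic DNA heterozygotes yield allele fractions tight
#' around 0.5 (logit-normal with SD `gdna_overdispersion`, binomial read
#' sampling on top); cDNA heterozygotes get an additional logit shift
#' `beta * g` where `g` is the +/-1 phase of a linked regulatory allele,
#' producing inter-individual variation in allelic imbalance when `beta > 0`.
#' Homozygotes emit reads for one allele only.
#'
#' @param config a [simConfig()] object (uses `cis_sites`,
#'   `gdna_overdispersion`, `allele_depth`, `seed`).
#' @param subjects data.frame with a `subject_id` column (e.g. from
#'   [simulateCohort()]); defaults to `n_subjects` fresh subjects.
#' @param n_subjects used when `subjects` is NULL.
#' @return long data.frame of allele-count records: `subject_id`, `site_id`,
#'   `gene`, `material` (`cDNA`/`gDNA`), `count_A`, `count_B`, plus the
#'   true genotype (`genotype`) and regulatory phase (`phase`) as ground
#'   truth columns.
#' @export
simulateAlleleCounts <- function(config, subjects = NULL, n_subjects = 60L) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(config$seed + 1000L)
    if (is.null(subjects))
        subjects <- data.frame(subject_id = sprintf("A%03d", seq_len(n_subjects)))
    ids <- subjects$subject_id
    n <- length(ids)
    out <- list()
    for (i in seq_len(nrow(config$cis_sites))) {
        s <- config$cis_sites[i, ]
        g <- stats::rbinom(n, 2L, s$maf)          # minor-allele dose (allele B)
        phase <- sample(c(-1, 1), n, replace = TRUE)
        for (mat in c("gDNA", "cDNA")) {
            depth <- stats::rpois(n, config$allele_depth)
            logit_fA <- stats::rnorm(n, 0, config$gdna_overdispersion)
            if (mat == "cDNA")
                logit_fA <- logit_fA + s$beta * phase
            fA <- stats::plogis(logit_fA)
            cA <- integer(n); cB <- integer(n)
            het <- g == 1L
            cA[het] <- stats::rbinom(sum(het), depth[het], fA[het])
            cB[het] <- depth[het] - cA[het]
            cA[g == 0L] <- depth[g == 0L]          # hom major: all allele A
            cB[g == 2L] <- depth[g == 2L]          # hom minor: all allele B
            out[[length(out) + 1L]] <- data.frame(
                subject_id = ids, site_id = s$site_id, gene = s$gene,
                material = mat, count_A = cA, count_B = cB,
                genotype = c("hom_A", "het", "hom_B")[g + 1L],
                phase = phase, stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Write simulated tables to a directory
#'
#' Emits the read-count table, the allele-count table, the subject metadata
#' table (TSV) and a JSON sidecar of ground-truth parameters.
#'
#' @param sim result of [simulateCohort()].
#' @param ase result of [simulateAlleleCounts()] (optional).
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, ase = NULL, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.table(sim$counts, file.path(dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sim$subjects, file.path(dir, "subjects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(ase))
        utils::write.table(ase, file.path(dir, "allele_counts.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    if (requireNamespace("jsonlite", quietly = TRUE)) {
        truth <- sim$truth
        truth$actb_molecules <- NULL
        jsonlite::write_json(truth, file.path(dir, "truth.json"),
                             auto_unbox = TRUE, digits = NA)
    }
    invisible(dir)
}
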