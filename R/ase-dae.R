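#' Call a genotype from gDNA allele counts
#'
#' Genomic DNA carries one copy of each allele in a heterozygote, so its
#' minor-allele read fraction sits near 0.5; homozygotes show (almost) all
#' reads on one allele. Calls are heterozygous when the minor fraction lies
#' inside `het_band`, homozygous when at most `hom_max`, ambiguous otherwise
#' (ambiguous samples are excluded from DAE analysis).
#'
#' @param count_A,count_B gDNA read counts per allele (vectorised).
#' @param het_band numeric(2), inclusive minor-fraction band for a het call.
#' @param hom_max maximum minor fraction for a homozygote call.
#' @return data.frame: `call` (`het`, `hom_A`, `hom_B`, `ambiguous`) and
#'   `minor_fraction`.
#' @examples
#' callGenotype(500, 500)   # het
#' callGenotype(990, 10)    # hom_A
#' @export
callGenotype <- function(count_A, count_B,
                         het_band = c(0.25, 0.75), hom_max = 0.05) {
    tot <- count_A + count_B
    stopifnot(all(tot > 0))
    minor <- pmin(count_A, count_B) / tot
    call <- ifelse(minor >= het_band[1] & minor <= het_band[2], "het",
            ifelse(minor <= hom_max,
                   ifelse(count_A >= count_B, "hom_A", "hom_B"),
                   "ambiguous"))
    data.frame(call = call, minor_fraction = minor, stringsAsFactors = FALSE)
}

#' Log2 allelic ratio
#'
#' @param count_A,count_B read counts for the two alleles of a called
#'   heterozygote; both must be positive.
#' @return `log2(count_A / count_B)`.
#' @export
log2Ratio <- function(count_A, count_B) {
    stopifnot(all(count_A > 0), all(count_B > 0))
    log2(count_A / count_B)
}

#' F-test for differential allelic expression
#'
#' Compares inter-individual variance of the log2 allelic ratio among cDNA
#' heterozygotes against gDNA heterozygote controls. gDNA ratios reflect
#' analytical noise only (every non-malignant cell carries one copy of each
#' allele), so excess cDNA variance is evidence of cis-regulatory variation
#' segregating in the population. The default alternative is one-sided: cDNA
#' variance exceeding gDNA variance.
#'
#' @param cdna_ratios,gdna_ratios numeric vectors of log2 allelic ratios
#'   (>= 3 values each).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return one-row data.frame: `n_het_cdna`, `n_het_gdna`, `var_cdna`,
#'   `var_gdna`, `F`, `p`, `flag` (`"ok"`, or `"gdna_var_zero"` with p set
#'   to the machine floor).
#' @export
daeFTest <- function(cdna_ratios, gdna_ratios, alternative = c("greater", "two.sided")) {
    alternative <- match.arg(alternative)
    n1 <- length(cdna_ratios); n2 <- length(gdna_ratios)
    stopifnot(n1 >= 3L, n2 >= 3L)
    v1 <- stats::var(cdna_ratios); v2 <- stats::var(gdna_ratios)
    if (v2 == 0) {
        return(data.frame(n_het_cdna = n1, n_het_gdna = n2,
                          var_cdna = v1, var_gdna = 0, F = Inf,
                          p = .Machine$double.xmin, flag = "gdna_var_zero",
                          stringsAsFactors = FALSE))
    }
    F <- v1 / v2
    p_up <- stats::pf(F, n1 - 1L, n2 - 1L, lower.tail = FALSE)
    p <- if (alternative == "greater") p_up
         else min(1, 2 * min(p_up, 1 - p_up))
    data.frame(n_het_cdna = n1, n_het_gdna = n2, var_cdna = v1,
               var_gdna = v2, F = F, p = p, flag = "ok",
               stringsAsFactors = FALSE)
}

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-squared test of observed genotype counts against
#' the p^2 : 2pq : q^2 expectation, with the allele frequency estimated from
#' the counts themselves.
#'
#' @param n_AA,n_AB,n_BB genotype counts (total >= 5).
#' @return data.frame: `chi2`, `p`, `p_A` (estimated frequency of A),
#'   `flag` (`"ok"` or `"monomorphic"`, which forces p = 1).
#' @export
hweTest <- function(n_AA, n_AB, n_BB) {
    N <- n_AA + n_AB + n_BB
    stopifnot(N >= 5L)
    pA <- (2 * n_AA + n_AB) / (2 * N)
    if (pA == 0 || pA == 1)
        return(data.frame(chi2 = 0, p = 1, p_A = pA, flag = "monomorphic",
                          stringsAsFactors = FALSE))
    e <- N * c(pA^2, 2 * pA * (1 - pA), (1 - pA)^2)
    chi2 <- sum((c(n_AA, n_AB, n_BB) - e)^2 / e)
    data.frame(chi2 = chi2, p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
               p_A = pA, flag = "ok", stringsAsFactors = FALSE)
}

#' Bonferroni threshold and decisions
#'
#' @param p_values numeric vector of raw p-values (optionally named).
#' @param m number of tests corrected for; must be at least
#'   `length(p_values)`.
#' @param alpha family-wise error rate.
#' @return list: `threshold` (`alpha / m`), `significant` (logical, strict
#'   `p < threshold`), `m`, `alpha`.
#' @export
adjustBonferroni <- function(p_values, m = length(p_values), alpha = 0.05) {
    stopifnot(m >= length(p_values))
    thr <- alpha / m
    list(threshold = thr, significant = p_values < thr, m = m, alpha = alpha)
}

#' Differential allelic expression analysis over an allele-count table
#'
#' Runs the full DAE chain per site: stochastic read filter, genotype calls
#' from gDNA, heterozygote log2 ratios in cDNA and gDNA, variance F-test and
#' Bonferroni adjustment across sites. cDNA samples from subjects with a
#' matched gDNA call use that call; unmatched cDNA samples are called from
#' the cDNA counts with a wider band and flagged lower-confidence.
#'
#' @param records long data.frame of allele counts: `subject_id`, `site_id`,
#'   `material` (`cDNA`/`gDNA`), `count_A`, `count_B` (the dialect written by
#'   [simulateAlleleCounts()]); a `gene` column is carried through if present.
#' @param min_reads minimum total reads per record.
#' @param het_band,hom_max gDNA genotype-calling parameters, see
#'   [callGenotype()].
#' @param unmatched_band wider het band for cDNA-only subjects.
#' @param alpha family-wise error rate for the Bonferroni step.
#' @param alternative sidedness of the F-test.
#' @param matched_only if `TRUE`, restrict gDNA controls to subjects that
#'   also have a cDNA heterozygote record (default pools all gDNA hets).
#' @return data.frame, one row per testable site: the [daeFTest()] columns
#'   plus `site_id`, `gene`, `p_adjusted` (`pmin(1, p * m)`), `significant`
#'   and `bonferroni_threshold`.
#' @export
daeAnalysis <- function(records, min_reads = 20L,
                        het_band = c(0.25, 0.75), hom_max = 0.05,
                        unmatched_band = c(0.10, 0.90),
                        alpha = 0.05,
                        alternative = c("greater", "two.sided"),
                        matched_only = FALSE) {
    alternative <- match.arg(alternative)
    stopifnot(all(c("subject_id", "site_id", "material",
                    "count_A", "count_B") %in% names(records)))
    records <- records[records$count_A + records$count_B >= min_reads, ]
    out <- list()
    for (site in unique(records$site_id)) {
        d <- records[records$site_id == site, ]
        gd <- d[d$material == "gDNA", ]
        cd <- d[d$material == "cDNA", ]
        if (!nrow(gd) || !nrow(cd)) next
        gcall <- callGenotype(gd$count_A, gd$count_B, het_band, hom_max)
        gd_het <- gd[gcall$call == "het", ]
        # cDNA het set: matched gDNA call where available, else own call
        matched <- cd$subject_id %in% gd$subject_id
        cd_het_ids <- gd$subject_id[gcall$call == "het"]
        cd_m <- cd[matched & cd$subject_id %in% cd_het_ids, ]
        cd_u <- cd[!matched, ]
        if (nrow(cd_u)) {
            ucall <- callGenotype(cd_u$count_A, cd_u$count_B,
                                  unmatched_band, hom_max)
            cd_u <- cd_u[ucall$call == "het", ]
        }
        cd_het <- rbind(cd_m, cd_u)
        cd_het <- cd_het[cd_het$count_A > 0 & cd_het$count_B > 0, ]
        if (matched_only)
            gd_het <- gd_het[gd_het$subject_id %in% cd_het$subject_id, ]
        gd_het <- gd_het[gd_het$count_A > 0 & gd_het$count_B > 0, ]
        if (nrow(cd_het) < 3L || nrow(gd_het) < 3L) next
        res <- daeFTest(log2Ratio(cd_het$count_A, cd_het$count_B),
                        log2Ratio(gd_het$count_A, gd_het$count_B),
                        alternative)
        res$site_id <- site
        res$gene <- if ("gene" %in% names(d)) d$gene[1] else NA_character_
        out[[length(out) + 1L]] <- res
    }
    if (!length(out)) return(data.frame())
    res <- do.call(rbind, out)
    bf <- adjustBonferroni(res$p, m = nrow(res), alpha = alpha)
    res$p_adjusted <- pmin(1, res$p * bf$m)
    res$significant <- bf$significant
    res$bonferroni_threshold <- bf$threshold
    rownames(res) <- NULL
    res[, c("site_id", "gene", "n_het_cdna", "n_het_gdna", "var_cdna",
            "var_gdna", "F", "p", "p_adjusted", "significant",
            "bonferroni_threshold", "flag")]
}
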