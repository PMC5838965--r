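#' Fisher exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule: the sum of hypergeometric
#' probabilities of all tables (with the observed margins) no more probable
#' than the observed one — the convention of [stats::fisher.test].
#'
#' @param a,b,c,d cell counts; rows are groups, columns the outcome.
#' @return two-sided p-value.
#' @examples
#' fisherExact2x2(11, 19, 22, 8)   # ~0.009
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    stopifnot(all(c(a, b, c, d) >= 0), a + b + c + d > 0)
    stats::fisher.test(matrix(c(a, b, c, d), 2L, byrow = TRUE))$p.value
}

#' Two-sample t-test on group values
#'
#' Pooled-variance (Student) form by default; Welch by flag.
#'
#' @param group1,group2 numeric vectors (>= 2 values each).
#' @param welch use the Welch unequal-variance form.
#' @return data.frame: `t`, `df`, `p` (two-sided).
#' @export
groupT <- function(group1, group2, welch = FALSE) {
    stopifnot(length(group1) >= 2L, length(group2) >= 2L)
    if (stats::var(group1) == 0 && stats::var(group2) == 0 &&
        mean(group1) == mean(group2))
        return(data.frame(t = 0, df = length(group1) + length(group2) - 2L,
                          p = 1))
    tt <- stats::t.test(group1, group2, var.equal = !welch)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
}

#' Covariate-adjusted group difference in expression (ANCOVA)
#'
#' Least-squares fit of `y ~ group + covariate`; the adjusted group
#' difference is the group coefficient and the F test is for the group term
#' in the presence of the covariate. With no covariate this reduces exactly
#' to the pooled-variance two-sample comparison. A covariate collinear with
#' the group factor cannot adjust anything: the unadjusted result is
#' returned with a warning and flagged.
#'
#' @param y numeric response (e.g. log10 abundance).
#' @param group two-level factor (difference is level 2 minus level 1, the
#'   usual treatment-contrast coefficient).
#' @param covariate optional numeric or factor covariate.
#' @return data.frame: `difference`, `F`, `p`, `covariate_used` (logical).
#' @export
ancovaGroupDifference <- function(y, group, covariate = NULL) {
    group <- .as_two_class(group)
    stopifnot(length(y) > 3L)
    collinear <- FALSE
    if (!is.null(covariate)) {
        cn <- if (is.factor(covariate) || is.character(covariate))
            as.numeric(as.factor(covariate)) else covariate
        if (stats::var(cn) == 0 ||
            abs(suppressWarnings(stats::cor(cn, as.numeric(group)))) > 1 - 1e-12) {
            warning("covariate collinear with group; unadjusted result returned")
            collinear <- TRUE
            covariate <- NULL
        }
    }
    # covariate enters first so the sequential F for group is adjusted
    fit <- if (is.null(covariate)) stats::lm(y ~ group)
           else stats::lm(y ~ covariate + group)
    an <- suppressWarnings(stats::anova(fit))  # perfect fits handled below
    Fg <- an["group", "F value"]; pg <- an["group", "Pr(>F)"]
    gcoef <- grep("^group", names(stats::coef(fit)), value = TRUE)[1L]
    diff <- unname(stats::coef(fit)[gcoef])
    # response fully explained by the covariate: group adds nothing
    tss <- sum((y - mean(y))^2)
    if (tss > 0 && an["Residuals", "Sum Sq"] < 1e-12 * tss &&
        an["group", "Sum Sq"] < 1e-12 * tss) {
        Fg <- 0; pg <- 1; diff <- 0
    }
    data.frame(difference = diff, F = Fg, p = pg,
               covariate_used = !is.null(covariate) && !collinear)
}

#' N-1 chi-squared comparison of two proportions
#'
#' Pearson's chi-squared on the 2x2 table scaled by `(N - 1) / N`, the
#' recommended small-sample test for comparing two independent proportions.
#' With `a = k1`, `b = n1 - k1`, `c = k2`, `d = n2 - k2`:
#' `chi2 = (ad - bc)^2 (N - 1) / ((a+b)(c+d)(a+c)(b+d))`, referred to the
#' 1-df chi-squared upper tail.
#'
#' @param k1,n1 successes and size of the first group.
#' @param k2,n2 successes and size of the second group.
#' @return data.frame: `chi2`, `p`, `flag` (`"ok"`, or `"degenerate_margin"`
#'   which forces p = 1).
#' @examples
#' n1ChiSquared(4, 4, 2935, 9751)  # p ~ 0.0023
#' @export
n1ChiSquared <- function(k1, n1, k2, n2) {
    stopifnot(n1 > 0, n2 > 0, k1 <= n1, k2 <= n2, k1 >= 0, k2 >= 0)
    a <- k1; b <- n1 - k1; c <- k2; d <- n2 - k2
    N <- n1 + n2
    margins <- c(a + b, c + d, a + c, b + d)
    if (any(margins == 0))
        return(data.frame(chi2 = 0, p = 1, flag = "degenerate_margin",
                          stringsAsFactors = FALSE))
    chi2 <- (a * d - b * c)^2 * (N - 1) / prod(margins)
    data.frame(chi2 = chi2, p = stats::pchisq(chi2, 1L, lower.tail = FALSE),
               flag = "ok", stringsAsFactors = FALSE)
}

#' Demographics comparison table
#'
#' Reproduces the conventional clinical Table-1 comparisons on a subject
#' table: Student t for age and pack-years, Fisher exact for sex and
#' smoking status, and Student t for FEV1/FVC.
#'
#' @param subjects data.frame with columns `cohort` (`COPD` / `control`),
#'   `age`, `pack_years`, `sex`, `smoking_status`, `fev1_fvc`.
#' @return data.frame: `variable`, `test`, `p`.
#' @export
demographicsTable <- function(subjects) {
    g <- subjects$cohort == "COPD"
    num <- function(v) groupT(subjects[[v]][!g], subjects[[v]][g])$p
    cat2 <- function(v) {
        tab <- table(subjects$cohort, subjects[[v]])
        stats::fisher.test(tab)$p.value
    }
    data.frame(
        variable = c("age", "sex", "smoking_status", "pack_years", "fev1_fvc"),
        test = c("t", "fisher", "fisher", "t", "t"),
        p = c(num("age"), cat2("sex"), cat2("smoking_status"),
              num("pack_years"), num("fev1_fvc")),
        stringsAsFactors = FALSE)
}

#' Covariate-adjusted expression differences across assays
#'
#' Loops [ancovaGroupDifference()] over every assay of an
#' [AbundanceExperiment] and over single covariates, on log10 abundance.
#'
#' @param object an imputed [AbundanceExperiment] whose `colData` carries
#'   `cohort` and the covariates.
#' @param covariates covariate column names looped over one at a time.
#' @param log_transform analyse log10 abundance (zeros excluded).
#' @return data.frame: `assay_id`, `covariate`, `difference`, `F`, `p`.
#' @export
ancovaTable <- function(object, covariates = c("age", "sex", "pack_years",
                                               "smoking_status"),
                        log_transform = TRUE) {
    cd <- SummarizedExperiment::colData(object)
    ab <- abundance(object)
    grp <- factor(cd$cohort, levels = c("control", "COPD"))
    out <- list()
    for (aid in rownames(ab)) for (cv in covariates) {
        yv <- ab[aid, ]
        use <- !is.na(yv) & (if (log_transform) yv > 0 else TRUE)
        if (sum(use) <= 3L) next
        yy <- if (log_transform) log10(yv[use]) else yv[use]
        r <- ancovaGroupDifference(yy, grp[use], cd[[cv]][use])
        out[[length(out) + 1L]] <- data.frame(assay_id = aid, covariate = cv,
                                              difference = r$difference,
                                              F = r$F, p = r$p,
                                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}
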