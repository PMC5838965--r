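## Shrinkage linear discriminant analysis with correlation-adjusted t-scores.
## Variances are James-Stein-shrunk toward their median; the feature
## correlation matrix is shrunk toward the identity with the analytic
## variance-minimizing intensity (Schafer-Strimmer form), so the pooled
## covariance is always positive definite even when features rival subjects.

.as_two_class <- function(y) {
    y <- as.factor(y)
    if (nlevels(y) != 2L) stop("exactly two classes required")
    y
}

# class-centered residuals and pooled variances; n - 2 df
.pooled_residuals <- function(X, y) {
    y <- .as_two_class(y)
    X <- as.matrix(X)
    n <- nrow(X)
    stopifnot(min(table(y)) >= 2L)
    mu <- apply(X, 2L, function(col) tapply(col, y, mean))
    E <- X - mu[as.integer(y), , drop = FALSE]
    v <- colSums(E^2) / (n - 2L)
    list(E = E, v = v, mu = t(mu), y = y, n = n)
}

# analytic shrinkage intensity for variances (target: median variance)
.lambda_var <- function(E, v) {
    n <- nrow(E)
    W <- E^2
    wbar <- colMeans(W)
    var_v <- (n / (n - 2L)^3) * colSums(sweep(W, 2L, wbar)^2)
    tgt <- stats::median(v)
    denom <- sum((v - tgt)^2)
    if (denom <= .Machine$double.eps) return(1)
    max(0, min(1, sum(var_v) / denom))
}

# analytic shrinkage intensity for the correlation matrix (target: identity)
.lambda_cor <- function(E, v) {
    n <- nrow(E); p <- ncol(E)
    if (p < 2L) return(1)
    Z <- sweep(E, 2L, sqrt(v), "/")
    R <- crossprod(Z) / (n - 2L)
    diag(R) <- 1
    # empirical variance of each off-diagonal correlation estimate
    num <- 0; denom <- 0
    for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
        w <- Z[, i] * Z[, j]
        num <- num + (n / (n - 2L)^3) * sum((w - mean(w))^2)
        denom <- denom + R[i, j]^2
    }
    lam <- if (denom <= .Machine$double.eps) 1 else num / denom
    list(lambda = max(0, min(1, lam)), R = R)
}

.shrink_moments <- function(X, y, lambda_cor = NULL, lambda_var = NULL) {
    pr <- .pooled_residuals(X, y)
    lv <- if (is.null(lambda_var)) .lambda_var(pr$E, pr$v) else lambda_var
    v_shrunk <- lv * stats::median(pr$v) + (1 - lv) * pr$v
    if (any(v_shrunk <= 0)) stop("zero shrunken variance")
    p <- ncol(pr$E)
    if (p >= 2L) {
        lc <- .lambda_cor(pr$E, pr$v)
        lam <- if (is.null(lambda_cor)) lc$lambda else lambda_cor
        R <- (1 - lam) * lc$R + lam * diag(p)
    } else {
        lam <- 1
        R <- matrix(1, 1L, 1L)
    }
    dimnames(R) <- list(colnames(X), colnames(X))
    list(mu = pr$mu, v = v_shrunk, lambda_var = lv, lambda_cor = lam,
         R = R, y = pr$y, n = pr$n)
}

# symmetric inverse square root by eigendecomposition
.inv_sqrt <- function(R) {
    e <- eigen(R, symmetric = TRUE)
    if (min(e$values) <= 0)
        stop("shrunken correlation matrix is not positive definite")
    e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Shrunken t-scores
#'
#' Per-feature two-class t-statistic using the James-Stein-shrunk pooled
#' variance: `t_k = (m1_k - m2_k) / (sqrt(v_k) * sqrt(1/n1 + 1/n2))`, with
#' `v_k` shrunk toward the median of all feature variances by an analytic
#' intensity. The sign convention is level 1 minus level 2 of `factor(y)`.
#'
#' @param X numeric matrix, subjects x features (no missing values).
#' @param y two-class labels.
#' @param lambda_var optional forced variance-shrinkage intensity in \[0,1\]
#'   (0 recovers the classical pooled-variance t).
#' @return named numeric vector of t-scores.
#' @export
shrunkenTScores <- function(X, y, lambda_var = NULL) {
    sm <- .shrink_moments(X, y, lambda_var = lambda_var)
    tab <- table(sm$y)
    d <- sm$mu[, 1L] - sm$mu[, 2L]
    tt <- d / (sqrt(sm$v) * sqrt(1 / tab[1L] + 1 / tab[2L]))
    stats::setNames(as.numeric(tt), colnames(X))
}

#' Correlation-adjusted t-scores (CAT scores)
#'
#' Decorrelates the shrunken t-score vector by the inverse square root of the
#' shrinkage-estimated feature correlation matrix:
#' `tau = R_shrunk^{-1/2} t`. Features are ranked by `|tau|`; the CAT score
#' measures each feature's contribution to class separation after accounting
#' for its correlation with the other features.
#'
#' @inheritParams shrunkenTScores
#' @param lambda_cor optional forced correlation-shrinkage intensity
#'   (1 gives `tau = t` exactly).
#' @return named numeric vector of CAT scores.
#' @export
catScores <- function(X, y, lambda_cor = NULL, lambda_var = NULL) {
    sm <- .shrink_moments(X, y, lambda_cor = lambda_cor,
                          lambda_var = lambda_var)
    tab <- table(sm$y)
    d <- sm$mu[, 1L] - sm$mu[, 2L]
    tt <- d / (sqrt(sm$v) * sqrt(1 / tab[1L] + 1 / tab[2L]))
    tau <- as.numeric(.inv_sqrt(sm$R) %*% tt)
    stats::setNames(tau, colnames(X))
}

#' Fit a shrinkage linear discriminant model
#'
#' Linear discriminant with pooled covariance
#' `Sigma = D^{1/2} R_shrunk D^{1/2}` where `D = diag(v_shrunk)`; posterior
#' class probabilities follow the two-class linear discriminant rule with
#' empirical class priors.
#'
#' @inheritParams catScores
#' @param features feature subset to fit on (default: all columns).
#' @return an [SLDAModel].
#' @export
fitSlda <- function(X, y, features = colnames(X),
                    lambda_cor = NULL, lambda_var = NULL) {
    X <- as.matrix(X)
    stopifnot(length(features) >= 1L, all(features %in% colnames(X)))
    Xs <- X[, features, drop = FALSE]
    sm <- .shrink_moments(Xs, y, lambda_cor = lambda_cor,
                          lambda_var = lambda_var)
    tab <- table(sm$y)
    d <- sm$mu[, 1L] - sm$mu[, 2L]
    tt <- d / (sqrt(sm$v) * sqrt(1 / tab[1L] + 1 / tab[2L]))
    tau <- as.numeric(.inv_sqrt(sm$R) %*% tt)
    new("SLDAModel", features = features, classes = levels(sm$y),
        means = sm$mu, pooledVar = as.numeric(sm$v),
        lambdaVar = sm$lambda_var, lambdaCor = sm$lambda_cor,
        corShrunk = sm$R, tScores = as.numeric(tt), catScores = tau,
        priors = as.numeric(tab / sum(tab)))
}

#' Posterior probability of the first class under an SLDA model
#'
#' @param model an [SLDAModel].
#' @param newdata numeric matrix (subjects x features) containing at least
#'   the model's features.
#' @return numeric vector of posterior probabilities of `model@classes[1]`.
#' @export
predictPosterior <- function(model, newdata) {
    newdata <- as.matrix(newdata)
    Xs <- newdata[, model@features, drop = FALSE]
    s <- sqrt(model@pooledVar)
    Rinv <- solve(model@corShrunk)
    SigInv <- Rinv / outer(s, s)          # D^{-1/2} R^{-1} D^{-1/2}
    delta <- sapply(1:2, function(c) {
        mu <- model@means[, c]
        as.numeric(Xs %*% (SigInv %*% mu)) -
            0.5 * as.numeric(t(mu) %*% SigInv %*% mu) +
            log(model@priors[c])
    })
    if (is.null(dim(delta))) delta <- matrix(delta, nrow = 1L)
    1 / (1 + exp(delta[, 2L] - delta[, 1L]))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic: the
#' proportion of (positive, negative) score pairs ranked concordantly, ties
#' receiving half credit.
#'
#' @param scores numeric classifier scores.
#' @param labels two-class labels; the first factor level is the positive
#'   class.
#' @return AUC in \[0, 1\].
#' @export
aucRank <- function(scores, labels) {
    labels <- .as_two_class(labels)
    pos <- scores[labels == levels(labels)[1L]]
    neg <- scores[labels == levels(labels)[2L]]
    stopifnot(length(pos) > 0L, length(neg) > 0L)
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

.roc_points <- function(scores, labels) {
    labels <- .as_two_class(labels)
    pos <- labels == levels(labels)[1L]
    thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
    tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
    fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
    data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Stratified bootstrap percentile CI for the AUC
#'
#' @inheritParams aucRank
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return numeric(2), lower and upper percentile bounds.
#' @export
aucCi <- function(scores, labels, n_boot = 2000L, seed = 1L, conf = 0.95) {
    labels <- .as_two_class(labels)
    i_pos <- which(labels == levels(labels)[1L])
    i_neg <- which(labels == levels(labels)[2L])
    set.seed(seed)
    reps <- vapply(seq_len(n_boot), function(b) {
        ip <- sample(i_pos, replace = TRUE)
        ineg <- sample(i_neg, replace = TRUE)
        aucRank(c(scores[ip], scores[ineg]),
                factor(rep(levels(labels), c(length(ip), length(ineg))),
                       levels = levels(labels)))
    }, numeric(1))
    a <- (1 - conf) / 2
    unname(stats::quantile(reps, c(a, 1 - a), names = FALSE))
}

#' Youden-index optimal cut-point
#'
#' Scans the midpoints between adjacent unique scores (plus outer sentinels)
#' and returns the threshold maximizing `J = sensitivity + specificity - 1`,
#' where a subject is called positive when its score is at least the
#' threshold. The smallest maximizing threshold is returned.
#'
#' @inheritParams aucRank
#' @return list: `threshold`, `J`.
#' @export
youdenCutpoint <- function(scores, labels) {
    labels <- .as_two_class(labels)
    pos <- labels == levels(labels)[1L]
    u <- sort(unique(scores))
    cand <- if (length(u) > 1L) (u[-1L] + u[-length(u)]) / 2 else u
    cand <- c(min(u) - 1, cand, max(u) + 1)
    J <- vapply(cand, function(t)
        mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1, numeric(1))
    best <- which.max(J)
    list(threshold = cand[best], J = J[best])
}

#' Diagnostic odds ratio with Wald confidence interval
#'
#' `OR = (TP * TN) / (FP * FN)`; the 95% CI is
#' `exp(log OR +/- z * sqrt(1/TP + 1/FN + 1/FP + 1/TN))`. When any cell is
#' zero the Haldane-Anscombe 0.5 correction is applied to every cell.
#'
#' @param tp,fn,fp,tn confusion-matrix counts.
#' @param conf confidence level.
#' @return list: `or`, `ci` (numeric(2)), `corrected` (logical).
#' @export
diagnosticOddsRatio <- function(tp, fn, fp, tn, conf = 0.95) {
    stopifnot(all(c(tp, fn, fp, tn) >= 0))
    corrected <- any(c(tp, fn, fp, tn) == 0)
    if (corrected) { tp <- tp + 0.5; fn <- fn + 0.5
                     fp <- fp + 0.5; tn <- tn + 0.5 }
    or <- (tp * tn) / (fp * fn)
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- sqrt(1 / tp + 1 / fn + 1 / fp + 1 / tn)
    list(or = or, ci = exp(log(or) + c(-1, 1) * z * se),
         corrected = corrected)
}

.stratified_folds <- function(y, k) {
    y <- .as_two_class(y)
    folds <- integer(length(y))
    for (lev in levels(y)) {
        idx <- sample(which(y == lev))
        folds[idx] <- rep_len(seq_len(k), length(idx))
    }
    folds
}

#' Pooled k-fold cross-validated ROC with CAT-score feature selection
#'
#' For each candidate feature-set size, features are re-ranked by `|tau|`
#' (CAT score) within each training fold, the top-`s` model is fitted, and
#' out-of-fold posterior probabilities are pooled over the k test folds; the
#' size maximizing the pooled AUC wins (ties go to the smaller size; CAT-score
#' ties break by feature name for determinism). The winning size's pooled
#' posteriors drive the ROC curve, bootstrap AUC CI, Youden cut-point,
#' confusion matrix and diagnostic odds ratio; the reported feature set is
#' the top-`s` ranking on the full data.
#'
#' @param X numeric matrix, subjects x features (complete; include
#'   demographic covariates as ordinary columns).
#' @param y two-class labels; the first factor level is the positive class.
#' @param k number of folds.
#' @param candidate_sizes candidate feature-set sizes (capped at `ncol(X)`).
#' @param seed RNG seed controlling fold assignment and the bootstrap.
#' @param n_boot bootstrap replicates for the AUC CI.
#' @param cutpoint_repeats if > 0, the cut-point is the median Youden
#'   threshold over this many repeated stratified k-fold CVs of the winning
#'   model size (the repeated-CV rule); 0 uses the pooled posteriors once.
#' @return a [CVReport].
#' @export
cvPooledRoc <- function(X, y, k = 10L, candidate_sizes = 1:15, seed = 1L,
                        n_boot = 2000L, cutpoint_repeats = 0L) {
    X <- as.matrix(X)
    y <- .as_two_class(y)
    stopifnot(k >= 2L, !anyNA(X))
    if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
    candidate_sizes <- candidate_sizes[candidate_sizes <= ncol(X)]
    stopifnot(length(candidate_sizes) >= 1L)
    if (min(table(y)) < k) stop("stratified ", k, "-fold CV infeasible")
    set.seed(seed)
    folds <- .stratified_folds(y, k)

    rank_features <- function(Xtr, ytr) {
        tau <- catScores(Xtr, ytr)
        ord <- order(-abs(tau), names(tau))   # |tau| desc, name tie-break
        names(tau)[ord]
    }
    post <- matrix(NA_real_, length(y), length(candidate_sizes))
    for (f in seq_len(k)) {
        tr <- folds != f; te <- !tr
        if (length(unique(y[tr])) < 2L || !any(te)) next
        ranked <- rank_features(X[tr, , drop = FALSE], y[tr])
        for (si in seq_along(candidate_sizes)) {
            s <- candidate_sizes[si]
            mod <- fitSlda(X[tr, , drop = FALSE], y[tr],
                           features = ranked[seq_len(s)])
            post[te, si] <- predictPosterior(mod, X[te, , drop = FALSE])
        }
    }
    aucs <- apply(post, 2L, aucRank, labels = y)
    best <- which.max(aucs)                  # first max = smallest size
    scores <- post[, best]
    auc <- aucs[best]
    sel <- rank_features(X, y)[seq_len(candidate_sizes[best])]

    ci <- aucCi(scores, y, n_boot = n_boot, seed = seed + 1L)
    yj <- if (cutpoint_repeats > 0L) {
        thr <- vapply(seq_len(cutpoint_repeats), function(r) {
            fr <- .stratified_folds(y, k)
            sc <- rep(NA_real_, length(y))
            for (f in seq_len(k)) {
                tr <- fr != f
                ranked <- rank_features(X[tr, , drop = FALSE], y[tr])
                mod <- fitSlda(X[tr, , drop = FALSE], y[tr],
                               features = ranked[seq_len(candidate_sizes[best])])
                sc[!tr] <- predictPosterior(mod, X[!tr, , drop = FALSE])
            }
            youdenCutpoint(sc, y)$threshold
        }, numeric(1))
        thr_med <- stats::median(thr)
        pos <- y == levels(y)[1L]
        list(threshold = thr_med,
             J = mean(scores[pos] >= thr_med) + mean(scores[!pos] < thr_med) - 1)
    } else youdenCutpoint(scores, y)

    pred_pos <- scores >= yj$threshold
    truth_pos <- y == levels(y)[1L]
    conf <- matrix(c(sum(pred_pos & truth_pos), sum(pred_pos & !truth_pos),
                     sum(!pred_pos & truth_pos), sum(!pred_pos & !truth_pos)),
                   2L, 2L, byrow = TRUE,
                   dimnames = list(predicted = c("pos", "neg"),
                                   truth = c("pos", "neg")))
    dor <- diagnosticOddsRatio(conf[1, 1], conf[2, 1], conf[1, 2], conf[2, 2])
    new("CVReport", folds = as.integer(folds), posteriors = scores,
        labels = y, roc = .roc_points(scores, y), auc = auc, aucCi = ci,
        youden = yj, confusion = conf, dor = dor, selectedFeatures = sel,
        candidateAuc = data.frame(size = candidate_sizes, auc = aucs))
}
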