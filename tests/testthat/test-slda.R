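test_that("shrunken t-scores reduce to the textbook formula", {
    # single feature, class means 1 and 0, pooled variance exactly 1
    a <- 1 / sqrt(2)
    X <- matrix(c(1 + a, 1 - a, a, -a), ncol = 1,
                dimnames = list(NULL, "f"))
    y <- factor(c("g1", "g1", "g2", "g2"), levels = c("g1", "g2"))
    expect_equal(unname(shrunkenTScores(X, y)), 1)
    # identical class means give t = 0
    X0 <- matrix(c(1, -1, 1, -1), ncol = 1, dimnames = list(NULL, "f"))
    expect_equal(unname(shrunkenTScores(X0, y)), 0)
})

test_that("zero shrinkage recovers the classical pooled-variance t", {
    set.seed(3)
    n1 <- 40; n2 <- 35; p <- 6
    X <- matrix(rnorm((n1 + n2) * p, sd = rep(c(1, 3), length.out = p)),
                n1 + n2, p, byrow = TRUE,
                dimnames = list(NULL, paste0("f", 1:p)))
    X[1:n1, 1] <- X[1:n1, 1] + 1
    y <- factor(rep(c("a", "b"), c(n1, n2)))
    got <- shrunkenTScores(X, y, lambda_var = 0)
    classic <- apply(X, 2, function(col) {
        x1 <- col[1:n1]; x2 <- col[-(1:n1)]
        sp <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
        (mean(x1) - mean(x2)) / (sqrt(sp) * sqrt(1 / n1 + 1 / n2))
    })
    expect_equal(unname(got), unname(classic), tolerance = 1e-6)
})

test_that("CAT scores decorrelate by the inverse root of the correlation", {
    # residuals built to have empirical correlation exactly 0.8
    z1 <- c(1, -1, 1, -1); z2 <- c(1, 1, -1, -1)
    e1 <- z1; e2 <- 0.8 * z1 + 0.6 * z2
    X <- rbind(cbind(e1, e2) + 2, cbind(e1, e2))    # class means differ by 2
    colnames(X) <- c("f1", "f2")
    y <- factor(rep(c("a", "b"), each = 4))
    tt <- shrunkenTScores(X, y, lambda_var = 0)
    tau <- catScores(X, y, lambda_cor = 0, lambda_var = 0)
    # closed form for [[1, r], [r, 1]]^(-1/2): eigenvalues 1 +/- r on the
    # (1,1)/(1,-1) axes
    r <- 0.8
    s <- (tt[1] + tt[2]) / 2; d <- (tt[1] - tt[2]) / 2
    want <- c(s / sqrt(1 + r) + d / sqrt(1 - r),
              s / sqrt(1 + r) - d / sqrt(1 - r))
    expect_equal(unname(tau), unname(want), tolerance = 1e-10)
    # identity shrinkage: tau equals t exactly
    expect_equal(catScores(X, y, lambda_cor = 1, lambda_var = 0),
                 shrunkenTScores(X, y, lambda_var = 0))
    # feature permutation equivariance
    tau2 <- catScores(X[, c(2, 1)], y, lambda_cor = 0, lambda_var = 0)
    expect_equal(unname(tau2), unname(tau[c(2, 1)]), tolerance = 1e-10)
})

test_that("SLDA posteriors respect symmetry and separation limits", {
    set.seed(4)
    n <- 20
    X <- rbind(matrix(rnorm(n * 2, 5), n, 2), matrix(rnorm(n * 2, -5), n, 2))
    colnames(X) <- c("f1", "f2")
    y <- factor(rep(c("hi", "lo"), each = n), levels = c("hi", "lo"))
    fit <- fitSlda(X, y)
    mid <- matrix((fit@means[, 1] + fit@means[, 2]) / 2, 1,
                  dimnames = list(NULL, c("f1", "f2")))
    expect_equal(predictPosterior(fit, mid), 0.5, tolerance = 1e-9)
    at_mean <- matrix(fit@means[, 1], 1, dimnames = list(NULL, c("f1", "f2")))
    expect_gt(predictPosterior(fit, at_mean), 0.99)
})

test_that("unshrunk SLDA matches a textbook LDA oracle", {
    set.seed(5)
    n1 <- 25; n2 <- 30
    X <- rbind(matrix(rnorm(n1 * 3, 1), n1, 3), matrix(rnorm(n2 * 3), n2, 3))
    colnames(X) <- paste0("f", 1:3)
    y <- factor(rep(c("a", "b"), c(n1, n2)))
    fit <- fitSlda(X, y, lambda_cor = 0, lambda_var = 0)
    new <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, colnames(X)))
    expect_equal(predictPosterior(fit, new), bf_lda_posterior(X, y, new),
                 tolerance = 1e-10)
})

test_that("rank AUC equals explicit pair counting, with ties", {
    set.seed(6)
    for (i in 1:10) {
        sc <- sample(seq(0, 1, 0.1), 20, replace = TRUE)   # forces ties
        y <- factor(sample(c("p", "n"), 20, replace = TRUE,
                           prob = c(0.5, 0.5)), levels = c("p", "n"))
        if (length(unique(y)) < 2) next
        expect_equal(aucRank(sc, y), bf_auc(sc, y), tolerance = 1e-12)
    }
})

test_that("cross-validated classifier is perfect on separable data", {
    d <- make_gaussian_classes(20, 20, 4, shifts = c(10, 10, 0, 0), seed = 9)
    cv <- cvPooledRoc(d$X, d$y, k = 5, candidate_sizes = 1:4, seed = 2,
                      n_boot = 50)
    expect_equal(cv@auc, 1.0)
    expect_equal(cv@aucCi[2], 1.0)
    expect_equal(cv@youden$J, 1.0)
})

test_that("fold seed determinism yields identical reports", {
    d <- make_gaussian_classes(15, 15, 6, shifts = c(1, 1, 0, 0, 0, 0),
                               seed = 10)
    cv1 <- cvPooledRoc(d$X, d$y, k = 5, candidate_sizes = 1:4, seed = 3,
                       n_boot = 50)
    cv2 <- cvPooledRoc(d$X, d$y, k = 5, candidate_sizes = 1:4, seed = 3,
                       n_boot = 50)
    expect_identical(cv1@posteriors, cv2@posteriors)
    expect_identical(cv1@auc, cv2@auc)
    expect_identical(cv1@aucCi, cv2@aucCi)
    expect_identical(cv1@selectedFeatures, cv2@selectedFeatures)
})

test_that("pooled AUC increases with the simulated effect size", {
    mean_auc <- vapply(c(0, 0.6, 1.5), function(d) {
        aucs <- vapply(1:50, function(i) {
            dd <- make_gaussian_classes(15, 15, 6,
                                        shifts = c(rep(d, 3), 0, 0, 0),
                                        seed = 1000L + round(997 * d) + i)
            cvPooledRoc(dd$X, dd$y, k = 5, candidate_sizes = 1:4,
                        seed = i, n_boot = 10)@auc
        }, numeric(1))
        mean(aucs)
    }, numeric(1))
    expect_true(all(diff(mean_auc) > 0))
})

test_that("bootstrap CI behaves: covers the point estimate, narrows with n", {
    set.seed(11)
    for (i in 1:20) {
        sc <- c(rnorm(15, 1), rnorm(15))
        y <- factor(rep(c("p", "n"), each = 15), levels = c("p", "n"))
        ci <- aucCi(sc, y, n_boot = 300, seed = i)
        a <- aucRank(sc, y)
        expect_true(ci[1] <= a && a <= ci[2])
    }
    w <- vapply(c(60, 200), function(n) {
        sc <- c(rnorm(n / 2, 1), rnorm(n / 2))
        y <- factor(rep(c("p", "n"), each = n / 2), levels = c("p", "n"))
        diff(aucCi(sc, y, n_boot = 500, seed = 1))
    }, numeric(1))
    expect_lt(w[2], w[1])
})

test_that("Youden cut-point matches an exhaustive scan", {
    sep <- youdenCutpoint(c(0.8, 0.9, 0.1, 0.2),
                          factor(c("p", "p", "n", "n"), levels = c("p", "n")))
    expect_equal(sep$J, 1)
    expect_gt(sep$threshold, 0.2)
    expect_lte(sep$threshold, 0.8)
    ident <- youdenCutpoint(rep(c(0.3, 0.6), 4),
                            factor(rep(c("p", "n"), each = 4),
                                   levels = c("p", "n")))
    expect_equal(ident$J, 0)
    set.seed(13)
    for (i in 1:10) {
        sc <- round(runif(14), 2)
        y <- factor(sample(rep(c("p", "n"), 7)), levels = c("p", "n"))
        expect_equal(youdenCutpoint(sc, y)$J, bf_youden_J(sc, y),
                     tolerance = 1e-12)
    }
})

test_that("diagnostic odds ratio and its CI follow the 2x2 formulas", {
    r <- diagnosticOddsRatio(20, 10, 8, 22)
    expect_equal(r$or, 5.5)
    expect_equal(r$ci,
                 exp(log(5.5) + c(-1, 1) * qnorm(0.975) *
                     sqrt(1 / 20 + 1 / 10 + 1 / 8 + 1 / 22)))
    r1 <- diagnosticOddsRatio(10, 10, 10, 10)
    expect_equal(r1$or, 1)
    expect_true(r1$ci[1] < 1 && 1 < r1$ci[2])
    r0 <- diagnosticOddsRatio(10, 0, 5, 15)
    expect_true(is.finite(r0$or) && r0$corrected)
})

test_that("repeated-CV cut-point is reproducible and in range", {
    d <- make_gaussian_classes(15, 15, 5, shifts = c(1, 1, 1, 0, 0),
                               seed = 14)
    cv <- cvPooledRoc(d$X, d$y, k = 5, candidate_sizes = 1:4, seed = 4,
                      n_boot = 50, cutpoint_repeats = 5)
    expect_true(cv@youden$threshold >= 0 && cv@youden$threshold <= 1)
    expect_true(cv@youden$J >= -1 && cv@youden$J <= 1)
})
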