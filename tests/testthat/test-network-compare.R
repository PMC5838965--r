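test_that("edge inclusion follows the correlation t-test threshold", {
    x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
    m <- rbind(a = x, b = 2 * x)
    net <- pearsonEdges(m, log_transform = FALSE)
    e <- networkEdges(net)
    expect_equal(nrow(e), 1L)
    expect_equal(e$r, 1)
    # exactly orthogonal pair: no edge
    m2 <- rbind(a = rep(c(1, -1), 4), b = rep(c(1, 1, -1, -1), 2))
    expect_equal(nrow(networkEdges(pearsonEdges(m2, log_transform = FALSE))), 0L)
})

test_that("boundary p-values follow the strict p < alpha rule", {
    # construct r = 0.632 exactly from orthonormal components (n = 10)
    x <- scale(1:10)[, 1]; x <- x / sqrt(sum(x^2))
    z <- rep(c(1, -1), 5); z <- z - mean(z)
    z <- z - x * sum(x * z); z <- z / sqrt(sum(z^2))
    r <- 0.632
    y <- r * x + sqrt(1 - r^2) * z
    expect_equal(cor(x, y), r, tolerance = 1e-12)
    tt <- r * sqrt(8 / (1 - r^2))
    p_oracle <- 2 * pt(-tt, 8)           # 0.04995: just under 0.05
    net <- pearsonEdges(rbind(a = x, b = y), log_transform = FALSE)
    e <- networkEdges(net)
    expect_equal(nrow(e), 1L)
    expect_equal(e$p, p_oracle, tolerance = 1e-10)
    # and strictly excluded at a tighter alpha equal to that p
    net2 <- pearsonEdges(rbind(a = x, b = y), alpha = p_oracle,
                         log_transform = FALSE)
    expect_equal(nrow(networkEdges(net2)), 0L)
})

test_that("edge set is invariant to positive affine rescaling", {
    set.seed(12)
    m <- matrix(rexp(6 * 20), 6, 20,
                dimnames = list(paste0("A", 1:6), NULL))
    m2 <- m; m2[3, ] <- m2[3, ] * 7.5      # scale on the raw scale
    key <- function(net) {
        e <- networkEdges(net)
        sort(paste(e$from, e$to))
    }
    expect_identical(key(pearsonEdges(m)), key(pearsonEdges(m2)))
})

test_that("centrality matches the definitions on canonical graphs", {
    path <- new("CorrelationNetwork", nodes = c("A", "B", "C"),
                edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                                   r = 0.9, p = 0.001, n = 10),
                alpha = 0.05, cohort = "toy")
    ct <- centrality(path)
    expect_equal(ct$degree, c(1L, 2L, 1L))
    expect_equal(ct$betweenness, c(0, 1, 0))
    k4e <- t(combn(paste0("N", 1:4), 2))
    k4 <- new("CorrelationNetwork", nodes = paste0("N", 1:4),
              edges = data.frame(from = k4e[, 1], to = k4e[, 2],
                                 r = 0.9, p = 0.001, n = 10),
              alpha = 0.05, cohort = "toy")
    ck <- centrality(k4)
    expect_equal(ck$betweenness, rep(0, 4))
    expect_equal(ck$closeness, rep(1, 4))
})

test_that("centrality equals a BFS brute-force oracle on random graphs", {
    set.seed(77)
    for (rep in 1:20) {
        n <- 8L
        adj <- matrix(0L, n, n)
        for (i in 1:(n - 1)) for (j in (i + 1):n)
            if (runif(1) < 0.35) adj[i, j] <- adj[j, i] <- 1L
        nodes <- paste0("V", 1:n)
        idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
        edges <- if (nrow(idx))
            data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                       r = 0.9, p = 0.001, n = 10)
        else data.frame(from = character(), to = character(),
                        r = numeric(), p = numeric(), n = integer())
        net <- new("CorrelationNetwork", nodes = nodes, edges = edges,
                   alpha = 0.05, cohort = "toy")
        got <- centrality(net)
        want <- bf_centrality(adj)
        expect_equal(got$degree, as.integer(want$degree))
        expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
        expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
    }
})

test_that("network comparison reproduces exact Wilcoxon references", {
    mk <- function(vals) data.frame(node = paste0("n", seq_along(vals)),
                                    degree = vals, betweenness = vals,
                                    closeness = vals)
    same <- compareNetworks(mk(c(1, 2, 3)), mk(c(1, 2, 3)))
    expect_true(all(same$p == 1))
    r1 <- compareNetworks(mk(c(1, 2, 3)), mk(c(4, 5, 6)))
    expect_equal(unique(r1$p), 0.1)           # 2/20 rank assignments
    r2 <- compareNetworks(mk(c(1, 2, 3, 4)), mk(c(10, 11, 12, 13)))
    expect_equal(unique(r2$p), 2 / 70)
})

test_that("Wilcoxon p agrees with a label-permutation oracle", {
    set.seed(5)
    x <- c(0.3, 1.2, 2.4, 0.9); y <- c(1.8, 3.1, 2.9, 4.0)
    obs <- compareNetworks(
        data.frame(node = paste0("n", 1:4), degree = x, betweenness = x,
                   closeness = x),
        data.frame(node = paste0("n", 1:4), degree = y, betweenness = y,
                   closeness = y))$p[1]
    pool <- c(x, y)
    ranks <- rank(pool)
    w_obs <- sum(ranks[1:4])
    combs <- combn(8, 4)
    w_all <- apply(combs, 2, function(ix) sum(ranks[ix]))
    # two-sided exact p by tail symmetry around the mean rank sum
    dev <- abs(w_all - mean(w_all))
    p_exact <- mean(dev >= abs(w_obs - mean(w_all)) - 1e-9)
    expect_equal(obs, p_exact, tolerance = 1e-12)
})

test_that("Fisher r-to-z matches hand computation and is antisymmetric", {
    expect_equal(fisherRtoZ(0.5, 20, 0.5, 35)$z, 0)
    expect_equal(fisherRtoZ(0.5, 20, 0.5, 35)$p, 1)
    r <- fisherRtoZ(0.8, 30, 0.0, 30)
    expect_equal(r$z, 4.036559, tolerance = 1e-6)
    expect_equal(r$p, 5.424082e-5, tolerance = 1e-6)
    r2 <- fisherRtoZ(0.0, 30, 0.8, 30)
    expect_equal(r2$z, -r$z)
    expect_equal(r2$p, r$p)
    expect_error(fisherRtoZ(1, 10, 0.5, 10), "infinite")
})

test_that("COPD-specific correlations inflate the COPD edge count", {
    # dedicated strong configuration: 8 disjoint correlated pairs on a
    # 16-assay panel; property holds in nearly every replicate
    panel <- assayDefs()[c(sprintf("CAT-%d", 1:3), "CEBPG-1", "CEBPG-2",
                           "GPX1-1", "GPX1-2", "KEAP1-1", "KEAP1-2",
                           "TP73-1", "TP73-2", "XPA-1", "XPA-2",
                           "ERCC5-1", "ERCC5-2", "TP53-1", "ACTB"), ]
    extra <- data.frame(
        a = c("CAT-1", "CAT-2", "CEBPG-1", "GPX1-1", "KEAP1-1", "TP73-1",
              "XPA-1", "ERCC5-1"),
        b = c("CEBPG-2", "GPX1-2", "KEAP1-2", "TP73-2", "XPA-2", "ERCC5-2",
              "TP53-1", "CAT-3"),
        r = 0.8)
    wins <- vapply(1:100, function(i) {
        cfg <- simConfig(seed = 400L + i, assays = panel, base_cor = 0,
                         de_genes = numeric(0),
                         copd_extra_correlations = extra)
        sim <- simulateCohort(cfg)
        g <- sim$subjects$cohort
        nd <- nrow(networkEdges(pearsonEdges(sim$latent[, g == "COPD"])))
        nc <- nrow(networkEdges(pearsonEdges(sim$latent[, g == "control"])))
        nd > nc
    }, logical(1))
    expect_gte(mean(wins), 0.95)
})
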