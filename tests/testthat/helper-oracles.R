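# Independent brute-force oracles used across the suite. Each is written as
# plainly as possible (explicit loops, textbook formulas) and never shares
# code with the implementation it checks.

# variance via explicit sums
bf_var <- function(x) {
    n <- length(x); m <- sum(x) / n
    s <- 0
    for (v in x) s <- s + (v - m)^2
    s / (n - 1)
}

bf_f_test <- function(x, y) {
    F <- bf_var(x) / bf_var(y)
    list(F = F, p = 1 - pf(F, length(x) - 1, length(y) - 1))
}

# BFS over an adjacency matrix: distances and shortest-path counts from s
bf_bfs <- function(adj, s) {
    n <- nrow(adj)
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
        nxt <- integer(0)
        for (v in frontier) for (w in which(adj[v, ] == 1)) {
            if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1
                                        nxt <- c(nxt, w) }
            if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
        frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
}

# normalized betweenness and harmonic closeness by full path enumeration
bf_centrality <- function(adj) {
    n <- nrow(adj)
    bfs <- lapply(seq_len(n), function(s) bf_bfs(adj, s))
    btw <- rep(0, n)
    for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
        if (s >= t || s == v || t == v) next
        d <- bfs[[s]]$dist[t]
        if (is.infinite(d)) next
        through <- if (bfs[[s]]$dist[v] + bfs[[v]]$dist[t] == d)
            bfs[[s]]$sigma[v] * bfs[[v]]$sigma[t] else 0
        btw[v] <- btw[v] + through / bfs[[s]]$sigma[t]
    }
    if (n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
    cls <- vapply(seq_len(n), function(v) {
        d <- bfs[[v]]$dist[-v]
        sum(1 / d[is.finite(d) & d > 0]) / (n - 1)
    }, numeric(1))
    list(degree = rowSums(adj), betweenness = btw, closeness = cls)
}

# textbook two-class LDA posterior with unshrunk pooled covariance
bf_lda_posterior <- function(X, y, newdata) {
    y <- factor(y)
    X1 <- X[y == levels(y)[1], , drop = FALSE]
    X2 <- X[y == levels(y)[2], , drop = FALSE]
    mu1 <- colMeans(X1); mu2 <- colMeans(X2)
    n <- nrow(X)
    S <- (crossprod(sweep(X1, 2, mu1)) + crossprod(sweep(X2, 2, mu2))) / (n - 2)
    Si <- solve(S)
    pri <- c(nrow(X1), nrow(X2)) / n
    d1 <- newdata %*% Si %*% mu1 - 0.5 * c(t(mu1) %*% Si %*% mu1) + log(pri[1])
    d2 <- newdata %*% Si %*% mu2 - 0.5 * c(t(mu2) %*% Si %*% mu2) + log(pri[2])
    as.numeric(1 / (1 + exp(d2 - d1)))
}

# AUC by explicit concordant-pair counting
bf_auc <- function(scores, labels) {
    labels <- factor(labels)
    pos <- scores[labels == levels(labels)[1]]
    neg <- scores[labels == levels(labels)[2]]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
    tot / (length(pos) * length(neg))
}

# best Youden J by exhaustive scan over all observed scores as thresholds
bf_youden_J <- function(scores, labels) {
    labels <- factor(labels)
    pos <- labels == levels(labels)[1]
    best <- -Inf
    for (t in sort(unique(c(scores, min(scores) - 1)))) {
        J <- mean(scores[pos] >= t) + mean(scores[!pos] < t) - 1
        best <- max(best, J)
    }
    best
}

# least squares by normal equations with direct matrix inversion
bf_ols <- function(X, y) as.numeric(solve(t(X) %*% X) %*% t(X) %*% y)

# all-pairs containment scan: SNP (1-based) in 0-based half-open region
bf_restrict <- function(snps, regions) {
    keep <- logical(nrow(snps))
    for (i in seq_len(nrow(snps))) for (j in seq_len(nrow(regions))) {
        if (snps$chrom[i] == regions$chrom[j] &&
            snps$pos[i] - 1 >= regions$start[j] &&
            snps$pos[i] - 1 < regions$end[j]) keep[i] <- TRUE
    }
    snps[keep, , drop = FALSE]
}

bf_dprime <- function(nAB, nAb, naB, nab) {
    N <- nAB + nAb + naB + nab
    pAB <- nAB / N; pA <- (nAB + nAb) / N; pB <- (nAB + naB) / N
    D <- pAB - pA * pB
    if (D == 0) return(0)
    dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    abs(D) / dmax
}

# small helper: a quick feature matrix + labels with optional mean shifts
make_gaussian_classes <- function(n1, n2, p, shifts = numeric(p), seed = 1) {
    set.seed(seed)
    X <- matrix(rnorm((n1 + n2) * p), n1 + n2, p,
                dimnames = list(NULL, sprintf("F%02d", seq_len(p))))
    X[seq_len(n1), ] <- sweep(X[seq_len(n1), , drop = FALSE], 2, shifts, "+")
    list(X = X,
         y = factor(rep(c("case", "control"), c(n1, n2)),
                    levels = c("case", "control")))
}
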