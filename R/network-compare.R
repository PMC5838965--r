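#' Significance-thresholded Pearson correlation network for one cohort
#'
#' Correlates every pair of assays over the cohort's subjects using
#' pairwise-complete observations of (by default) log10 abundance, keeping an
#' edge when the two-sided p-value of `t = r * sqrt((n - 2) / (1 - r^2))`
#' falls strictly below `alpha`. Constant columns produce undefined
#' correlations; their node is left isolated with a warning.
#'
#' @param object an [AbundanceExperiment], or a plain numeric matrix
#'   (assays x subjects).
#' @param cohort optional value matched against `colData(object)$cohort` to
#'   select the subjects; `NULL` uses every subject.
#' @param alpha edge-inclusion threshold on the two-sided p-value.
#' @param log_transform apply `log10` to abundance first (requires positive
#'   values; zeros become missing).
#' @param use_imputed if `FALSE` (default) imputed cells are treated as
#'   missing for correlation (networks are built on measured data);
#'   `TRUE` uses the matrix as-is.
#' @return a [CorrelationNetwork].
#' @export
pearsonEdges <- function(object, cohort = NULL, alpha = 0.05,
                         log_transform = TRUE, use_imputed = FALSE) {
    if (is(object, "AbundanceExperiment")) {
        m <- abundance(object)
        if (!use_imputed)
            m[abundanceStatus(object) == "imputed"] <- NA_real_
        if (!is.null(cohort)) {
            cd <- SummarizedExperiment::colData(object)
            m <- m[, cd$cohort == cohort, drop = FALSE]
        }
    } else m <- as.matrix(object)
    if (ncol(m) < 4L) stop("at least 4 subjects required")
    if (log_transform) {
        m[!is.na(m) & m <= 0] <- NA_real_
        m <- log10(m)
    }
    nodes <- rownames(m)
    if (is.null(nodes)) nodes <- paste0("V", seq_len(nrow(m)))
    ok <- !is.na(m)
    const <- apply(m, 1L, function(x) {
        x <- x[!is.na(x)]; length(x) >= 2L && stats::var(x) == 0
    })
    if (any(const))
        warning("constant assay(s) left isolated: ",
                paste(nodes[const], collapse = ", "))
    edges <- list()
    nr <- nrow(m)
    for (i in seq_len(nr - 1L)) for (j in seq(i + 1L, nr)) {
        if (const[i] || const[j]) next
        use <- ok[i, ] & ok[j, ]
        n <- sum(use)
        if (n < 4L) next
        r <- suppressWarnings(stats::cor(m[i, use], m[j, use]))
        if (is.na(r)) next
        if (abs(r) >= 1) { p <- 0 } else {
            tt <- r * sqrt((n - 2) / (1 - r^2))
            p <- 2 * stats::pt(-abs(tt), n - 2L)
        }
        if (p < alpha)
            edges[[length(edges) + 1L]] <-
                data.frame(from = nodes[i], to = nodes[j], r = r, p = p,
                           n = n, stringsAsFactors = FALSE)
    }
    edges <- if (length(edges)) do.call(rbind, edges)
             else data.frame(from = character(), to = character(),
                             r = numeric(), p = numeric(), n = integer(),
                             stringsAsFactors = FALSE)
    new("CorrelationNetwork", nodes = nodes, edges = edges, alpha = alpha,
        cohort = if (is.null(cohort)) "all" else as.character(cohort))
}

#' Node centrality metrics of a correlation network
#'
#' Degree (incident edges), shortest-path betweenness normalised by
#' `(n - 1)(n - 2) / 2`, and harmonic closeness (mean of inverse geodesic
#' distances to all other nodes, unreachable contributing 0) normalised by
#' `n - 1`. Paths are unweighted. Harmonic closeness is used because
#' significance-thresholded correlation graphs are routinely disconnected,
#' where classic closeness is undefined.
#'
#' @param network a [CorrelationNetwork].
#' @return data.frame: `node`, `degree`, `betweenness`, `closeness`.
#' @export
centrality <- function(network) {
    g <- asIgraph(network)
    n <- igraph::vcount(g)
    deg <- igraph::degree(g)
    btw <- igraph::betweenness(g, directed = FALSE)
    if (n > 2L) btw <- btw / ((n - 1) * (n - 2) / 2)
    cls <- igraph::harmonic_centrality(g, normalized = FALSE)
    if (n > 1L) cls <- cls / (n - 1)
    data.frame(node = igraph::V(g)$name, degree = as.integer(deg),
               betweenness = unname(btw), closeness = unname(cls),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare node centrality between two cohort networks
#'
#' Two-sided Wilcoxon rank-sum test on each metric's per-node values between
#' the two cohorts (exact distribution when sample sizes permit and there are
#' no ties; otherwise normal approximation with tie and continuity
#' correction, as in [stats::wilcox.test]).
#'
#' @param metrics_A,metrics_B node metric tables from [centrality()] over
#'   the same node universe.
#' @return data.frame: `metric`, `W`, `p`.
#' @export
compareNetworks <- function(metrics_A, metrics_B) {
    stopifnot(setequal(metrics_A$node, metrics_B$node))
    mets <- c("degree", "betweenness", "closeness")
    res <- lapply(mets, function(m) {
        x <- metrics_A[[m]]; y <- metrics_B[[m]]
        if (all(x == y) || (stats::var(c(x, y)) == 0))
            return(data.frame(metric = m, W = NA_real_, p = 1))
        wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                                  correct = TRUE))
        data.frame(metric = m, W = unname(wt$statistic), p = wt$p.value,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
}

#' Fisher r-to-z test for the difference of two correlations
#'
#' @param r1,r2 Pearson correlations from two independent groups (|r| < 1).
#' @param n1,n2 group sizes (> 3).
#' @return data.frame: `z`, `p` (two-sided normal).
#' @examples
#' fisherRtoZ(0.8, 30, 0.0, 30)  # z ~ 4.04, p ~ 5.4e-5
#' @export
fisherRtoZ <- function(r1, n1, r2, n2) {
    stopifnot(n1 > 3, n2 > 3)
    if (any(abs(c(r1, r2)) >= 1))
        stop("|r| = 1 has an infinite transform")
    z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
    data.frame(z = z, p = 2 * stats::pnorm(-abs(z)))
}
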