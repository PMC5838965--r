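#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assays assay rowData colData
NULL

.STATUS_LEVELS <- c("measured", "native_low", "IS_low", "sample_fail",
                    "not_detected", "imputed")

#' AbundanceExperiment: absolute transcript abundance with provenance
#'
#' An extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' subjects-by-assays grid of absolute transcript abundance, expressed as
#' target molecules per 10^6 ACTB molecules. Rows are targeted assays
#' (amplicons), columns are subjects. Two assay matrices are carried:
#' \describe{
#'   \item{abundance}{numeric; `NA` marks a missing measurement.}
#'   \item{status}{character provenance flag per cell, one of
#'     `"measured"`, `"native_low"`, `"IS_low"`, `"sample_fail"`,
#'     `"not_detected"` or `"imputed"`. Typed reason codes distinguish a
#'     cell dropped for low native reads from one dropped because the
#'     internal-standard reads were unreliable or the whole sample failed
#'     reference-gene QC.}
#' }
#' `rowData` carries the assay definitions (gene symbol, measured SNP site,
#' internal-standard spike quantity in molecules, 5'/3' distance class);
#' `colData` carries subject demographics and cohort labels.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("AbundanceExperiment", contains = "SummarizedExperiment")

setValidity("AbundanceExperiment", function(object) {
    msg <- NULL
    an <- SummarizedExperiment::assayNames(object)
    if (!all(c("abundance", "status") %in% an))
        msg <- c(msg, "assays must include 'abundance' and 'status'")
    else {
        ab <- SummarizedExperiment::assay(object, "abundance")
        st <- SummarizedExperiment::assay(object, "status")
        if (any(ab < 0, na.rm = TRUE))
            msg <- c(msg, "abundance values must be >= 0 where present")
        if (!all(st %in% .STATUS_LEVELS))
            msg <- c(msg, sprintf("status values must be in {%s}",
                                  paste(.STATUS_LEVELS, collapse = ", ")))
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct an AbundanceExperiment
#'
#' @param abundance numeric matrix, assays (rows) by subjects (columns);
#'   `NA` marks missing cells. Units: molecules per 10^6 ACTB molecules.
#' @param status character matrix of per-cell provenance flags; defaults to
#'   `"measured"` where `abundance` is finite and `"not_detected"` elsewhere.
#' @param rowData `DataFrame` of assay definitions (see [assayDefs()]).
#' @param colData `DataFrame` of subject metadata.
#' @return an `AbundanceExperiment`.
#' @examples
#' m <- matrix(c(100, 200, NA, 400), 2, 2,
#'             dimnames = list(c("A1", "A2"), c("s1", "s2")))
#' ae <- AbundanceExperiment(m)
#' abundance(ae)
#' @export
AbundanceExperiment <- function(abundance,
                                status = NULL,
                                rowData = NULL,
                                colData = NULL) {
    abundance <- as.matrix(abundance)
    if (is.null(status)) {
        status <- ifelse(is.na(abundance), "not_detected", "measured")
        dimnames(status) <- dimnames(abundance)
    }
    args <- list(assays = list(abundance = abundance, status = status))
    if (!is.null(rowData)) args$rowData <- rowData
    if (!is.null(colData)) args$colData <- colData
    se <- do.call(SummarizedExperiment::SummarizedExperiment, args)
    new("AbundanceExperiment", se)
}

#' @describeIn AbundanceExperiment the abundance matrix (assays x subjects).
#' @param object an `AbundanceExperiment`.
#' @export
abundance <- function(object) SummarizedExperiment::assay(object, "abundance")

#' @describeIn AbundanceExperiment the per-cell provenance flag matrix.
#' @export
abundanceStatus <- function(object) SummarizedExperiment::assay(object, "status")

#' @describeIn AbundanceExperiment fraction of subjects with a measured
#'   (non-missing) value, per assay.
#' @export
measuredFraction <- function(object) {
    ab <- abundance(object)
    rowMeans(!is.na(ab))
}

#' CorrelationNetwork: significance-thresholded Pearson co-expression graph
#'
#' Undirected graph over assays for one cohort. Each edge records the Pearson
#' correlation of log-transformed abundance between two assays, the two-sided
#' p-value of the t-statistic `r * sqrt((n - 2) / (1 - r^2))`, and the number
#' of pairwise-complete subjects used. Only edges with `p < alpha` are kept.
#'
#' @slot nodes character vector of assay identifiers (all assays considered,
#'   including isolated ones).
#' @slot edges data.frame with columns `from`, `to`, `r`, `p`, `n`.
#' @slot alpha numeric edge-inclusion threshold.
#' @slot cohort character label of the cohort the network was built from.
#' @export
setClass("CorrelationNetwork",
         representation(nodes = "character",
                        edges = "data.frame",
                        alpha = "numeric",
                        cohort = "character"))

setValidity("CorrelationNetwork", function(object) {
    e <- object@edges
    msg <- NULL
    need <- c("from", "to", "r", "p", "n")
    if (!all(need %in% names(e)))
        msg <- c(msg, "edges need columns from, to, r, p, n")
    else if (nrow(e)) {
        if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
        if (any(abs(e$r) > 1)) msg <- c(msg, "|r| must be <= 1")
        if (any(e$p >= object@alpha))
            msg <- c(msg, "every edge must satisfy p < alpha")
        if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
            msg <- c(msg, "edge endpoints must be listed in nodes")
    }
    if (is.null(msg)) TRUE else msg
})

#' @describeIn CorrelationNetwork the edge table.
#' @param object a `CorrelationNetwork`.
#' @export
networkEdges <- function(object) object@edges

#' @describeIn CorrelationNetwork the node (assay) identifiers.
#' @export
networkNodes <- function(object) object@nodes

#' @describeIn CorrelationNetwork convert to an [igraph::graph] object
#'   (undirected, unweighted vertices carrying all nodes incl. isolated).
#' @export
asIgraph <- function(object) {
    igraph::graph_from_data_frame(object@edges[, c("from", "to")],
                                  directed = FALSE,
                                  vertices = object@nodes)
}

setMethod("show", "CorrelationNetwork", function(object) {
    cat("CorrelationNetwork (", object@cohort, ")\n", sep = "")
    cat("  nodes:", length(object@nodes),
        " edges:", nrow(object@edges),
        " alpha:", object@alpha, "\n")
})

#' SLDAModel: shrinkage linear discriminant COPD classifier
#'
#' Two-class linear discriminant with James-Stein-type shrinkage of the
#' pooled feature variances (toward their median) and of the feature
#' correlation matrix (toward the identity), plus correlation-adjusted
#' t-scores (CAT scores) used for feature ranking.
#'
#' @slot features character, features the model was fitted on.
#' @slot classes character(2); the first entry is the positive class whose
#'   posterior probability `predictPosterior` returns.
#' @slot means matrix features x 2 of class means.
#' @slot pooledVar numeric, shrunken pooled variance per feature.
#' @slot lambdaVar,lambdaCor numeric in \[0,1\], shrinkage intensities.
#' @slot corShrunk shrunken feature correlation matrix.
#' @slot tScores,catScores numeric, shrunken t and CAT score per feature.
#' @slot priors numeric(2), empirical class priors.
#' @export
setClass("SLDAModel",
         representation(features = "character",
                        classes = "character",
                        means = "matrix",
                        pooledVar = "numeric",
                        lambdaVar = "numeric",
                        lambdaCor = "numeric",
                        corShrunk = "matrix",
                        tScores = "numeric",
                        catScores = "numeric",
                        priors = "numeric"))

setValidity("SLDAModel", function(object) {
    msg <- NULL
    if (length(object@classes) != 2L) msg <- c(msg, "exactly two classes")
    if (object@lambdaVar < 0 || object@lambdaVar > 1 ||
        object@lambdaCor < 0 || object@lambdaCor > 1)
        msg <- c(msg, "shrinkage intensities must lie in [0, 1]")
    if (any(object@pooledVar <= 0))
        msg <- c(msg, "shrunken pooled variances must be positive")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "SLDAModel", function(object) {
    cat("SLDAModel:", length(object@features), "features;",
        "classes", paste(object@classes, collapse = " vs "), "\n")
    cat("  lambda (correlation):", signif(object@lambdaCor, 4),
        " lambda (variance):", signif(object@lambdaVar, 4), "\n")
})

#' CVReport: pooled cross-validated classifier evaluation
#'
#' @slot folds integer fold assignment per subject.
#' @slot posteriors numeric pooled out-of-fold posterior probability of the
#'   positive class, one per subject.
#' @slot labels factor true class labels (level 1 = positive class).
#' @slot roc data.frame of ROC curve points (`fpr`, `tpr`, `threshold`).
#' @slot auc numeric pooled AUC in \[0,1\].
#' @slot aucCi numeric(2) bootstrap percentile confidence interval.
#' @slot youden list with `threshold` and `J`.
#' @slot confusion 2x2 integer matrix (predicted x truth) at the cut-point.
#' @slot dor list with `or`, `ci` (diagnostic odds ratio).
#' @slot selectedFeatures character, features of the winning candidate size.
#' @slot candidateAuc data.frame of candidate feature-set sizes and pooled AUC.
#' @export
setClass("CVReport",
         representation(folds = "integer",
                        posteriors = "numeric",
                        labels = "factor",
                        roc = "data.frame",
                        auc = "numeric",
                        aucCi = "numeric",
                        youden = "list",
                        confusion = "matrix",
                        dor = "list",
                        selectedFeatures = "character",
                        candidateAuc = "data.frame"))

setValidity("CVReport", function(object) {
    msg <- NULL
    if (length(object@folds) != length(object@posteriors))
        msg <- c(msg, "one fold assignment per subject")
    if (object@auc < 0 || object@auc > 1) msg <- c(msg, "auc must be in [0,1]")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "CVReport", function(object) {
    cat("CVReport: pooled ", max(object@folds), "-fold CV\n", sep = "")
    cat("  AUC:", signif(object@auc, 4))
    if (length(object@aucCi) == 2L)
        cat("  (95% CI ", signif(object@aucCi[1], 4), "-",
            signif(object@aucCi[2], 4), ")", sep = "")
    cat("\n  features:", paste(object@selectedFeatures, collapse = ", "), "\n")
    cat("  Youden cut-point:", signif(object@youden$threshold, 4),
        " J:", signif(object@youden$J, 4), "\n")
})
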