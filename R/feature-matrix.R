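#' Build the classifier feature matrix from an imputed abundance experiment
#'
#' Assembles the subjects-by-features matrix for the COPD classifier:
#' log10 abundance of every retained assay plus the demographic covariates
#' sex (male = 1), age (years) and smoking history (pack-years) as ordinary
#' feature columns, and the cohort labels with COPD as the positive class.
#'
#' @param object an imputed [AbundanceExperiment] (no missing cells) whose
#'   `colData` carries `cohort`, `sex`, `age` and `pack_years`.
#' @param log_transform use log10 abundance (default).
#' @return list: `X` (numeric matrix, subjects x features), `y` (factor with
#'   levels `COPD`, `control`).
#' @export
classifierMatrix <- function(object, log_transform = TRUE) {
    ab <- abundance(object)
    if (anyNA(ab)) stop("missing cells remain; run meanImpute() first")
    cd <- SummarizedExperiment::colData(object)
    X <- t(if (log_transform) log10(pmax(ab, .Machine$double.xmin)) else ab)
    X <- cbind(X,
               sex = as.integer(cd$sex == "male"),
               age = as.numeric(cd$age),
               pack_years = as.numeric(cd$pack_years))
    list(X = X, y = factor(cd$cohort, levels = c("COPD", "control")))
}
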