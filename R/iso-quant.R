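#' Absolute molecule count from competitive amplicon reads
#'
#' In a competitive multiplex PCR library a known number of internal-standard
#' (IS) molecules is co-amplified with the native target, so the native/IS
#' read ratio times the spike quantity gives the absolute number of native
#' molecules loaded into the reaction.
#'
#' @param native_reads,is_reads read counts for the native and the
#'   internal-standard template (vectorised).
#' @param spike internal-standard molecules spiked into the reaction.
#' @return molecules, `spike * native_reads / is_reads`; `NA` (not an error)
#'   where `is_reads == 0`, since an absent internal standard makes the
#'   measurement undefined rather than zero.
#' @examples
#' computeMolecules(1000, 1000, 1e4)  # 1e4
#' computeMolecules(500, 1000, 1e4)   # 5e3
#' @export
computeMolecules <- function(native_reads, is_reads, spike) {
    ifelse(is_reads > 0, spike * native_reads / is_reads, NA_real_)
}

#' Normalise molecule counts to the ACTB reference
#'
#' @param target_molecules molecules of the target measured in a reaction.
#' @param actb_molecules molecules of ACTB measured in the same reaction.
#' @return abundance as target molecules per 10^6 ACTB molecules; `NA` where
#'   `actb_molecules` is 0 or missing (whole-sample failure).
#' @export
normalizeToActb <- function(target_molecules, actb_molecules) {
    ifelse(!is.na(actb_molecules) & actb_molecules > 0,
           1e6 * target_molecules / actb_molecules, NA_real_)
}

#' Stochastic-sampling-error filter
#'
#' A measurement is only trusted when both templates were sequenced deeply
#' enough that Poisson counting error is small; at the default 20 reads the
#' counting CV is about 22%.
#'
#' @param native_reads,is_reads read counts (vectorised).
#' @param min_reads minimum acceptable reads for either template.
#' @return data.frame with logical `pass` and character `reason`
#'   (`"pass"`, `"native_low"` or `"IS_low"`; a cell failing both is
#'   reported `"native_low"`).
#' @export
stochasticFilter <- function(native_reads, is_reads, min_reads = 20L) {
    stopifnot(min_reads >= 1)
    pass <- native_reads >= min_reads & is_reads >= min_reads
    reason <- ifelse(pass, "pass",
                     ifelse(native_reads < min_reads, "native_low", "IS_low"))
    data.frame(pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Assemble an AbundanceExperiment from a long read-count table
#'
#' Applies the full quantification chain per subject: the ACTB reference
#' assay is quantified from its own internal standard first; a sample whose
#' ACTB measurement fails the stochastic filter fails QC entirely
#' (`sample_fail`). Every other assay is filtered, converted to molecules
#' and normalised to molecules per 10^6 ACTB molecules.
#'
#' @param counts long data.frame with columns `subject_id`, `assay_id`,
#'   `template` (`native` / `IS`), `reads` (the dialect written by
#'   [writeSimulation()]).
#' @param assays assay definition table (needs `assay_id`, `gene`,
#'   `is_spike_molecules`); see [assayDefs()].
#' @param min_reads stochastic-filter threshold applied to both templates.
#' @param subjects optional subject metadata data.frame (keyed by
#'   `subject_id`) stored in `colData`.
#' @param actb_assay identifier of the reference assay.
#' @return an [AbundanceExperiment] (target assays x subjects).
#' @export
quantifyCounts <- function(counts, assays, min_reads = 20L,
                           subjects = NULL, actb_assay = "ACTB") {
    stopifnot(all(c("subject_id", "assay_id", "template", "reads") %in%
                  names(counts)))
    if (!actb_assay %in% counts$assay_id)
        stop("reference assay '", actb_assay, "' absent from the count table")
    subj <- unique(counts$subject_id)
    aid <- setdiff(intersect(assays$assay_id, unique(counts$assay_id)),
                   actb_assay)
    wide <- function(tmpl) {
        d <- counts[counts$template == tmpl, ]
        m <- matrix(NA_real_, length(aid) + 1L, length(subj),
                    dimnames = list(c(aid, actb_assay), subj))
        m[cbind(match(d$assay_id, rownames(m)),
                match(d$subject_id, subj))] <- d$reads
        m
    }
    nat <- wide("native"); isr <- wide("IS")
    spike <- assays$is_spike_molecules[match(rownames(nat), assays$assay_id)]

    # reference gene first: whole-sample QC
    f_actb <- stochasticFilter(nat[actb_assay, ], isr[actb_assay, ], min_reads)
    actb_mol <- computeMolecules(nat[actb_assay, ], isr[actb_assay, ],
                                 spike[match(actb_assay, rownames(nat))])
    sample_ok <- f_actb$pass & !is.na(actb_mol) & actb_mol > 0

    ab <- matrix(NA_real_, length(aid), length(subj),
                 dimnames = list(aid, subj))
    st <- matrix("not_detected", length(aid), length(subj),
                 dimnames = list(aid, subj))
    for (i in seq_along(aid)) {
        f <- stochasticFilter(nat[i, ], isr[i, ], min_reads)
        mol <- computeMolecules(nat[i, ], isr[i, ], spike[i])
        val <- normalizeToActb(mol, actb_mol)
        ok <- sample_ok & f$pass & !is.na(val)
        ab[i, ok] <- val[ok]
        st[i, ok] <- "measured"
        st[i, !sample_ok] <- "sample_fail"
        miss <- sample_ok & !f$pass
        st[i, miss] <- f$reason[miss]
    }
    rd <- assays[match(aid, assays$assay_id), , drop = FALSE]
    cd <- if (!is.null(subjects))
        S4Vectors::DataFrame(subjects[match(subj, subjects$subject_id), ,
                                      drop = FALSE], row.names = subj)
    else S4Vectors::DataFrame(subject_id = subj, row.names = subj)
    AbundanceExperiment(ab, st, rowData = rd, colData = cd)
}

#' Retain assays measured in a minimum fraction of subjects
#'
#' @param object an [AbundanceExperiment].
#' @param min_fraction minimum fraction of subjects with a measured value
#'   (inclusive boundary; the conventional cut is 0.70).
#' @return the subsetted `AbundanceExperiment`; `metadata()` gains
#'   `retainedAssays`, `nAssaysRetained` and `nGenesRetained`.
#' @export
representationFilter <- function(object, min_fraction = 0.70) {
    stopifnot(min_fraction > 0, min_fraction <= 1)
    if (nrow(object) == 0L || ncol(object) == 0L)
        stop("empty abundance matrix")
    frac <- measuredFraction(object)
    keep <- frac >= min_fraction
    res <- object[keep, ]
    genes <- unique(SummarizedExperiment::rowData(res)$gene)
    S4Vectors::metadata(res)$retainedAssays <- rownames(res)
    S4Vectors::metadata(res)$nAssaysRetained <- sum(keep)
    S4Vectors::metadata(res)$nGenesRetained <- length(genes)
    res
}

#' Impute missing cells with the per-assay mean
#'
#' Replaces each missing cell with the mean of the assay's measured values
#' across the whole cohort and flags it `imputed`. (This replicates the
#' conventional pre-CV imputation; for a leakage-free variant impute within
#' training folds via `cvPooledRoc(impute_within_fold = TRUE)`.)
#'
#' @param object an [AbundanceExperiment] with every assay measured at least
#'   once (apply [representationFilter()] first).
#' @return the imputed `AbundanceExperiment` (no `NA` cells remain).
#' @export
meanImpute <- function(object) {
    ab <- abundance(object)
    st <- abundanceStatus(object)
    all_missing <- rowSums(!is.na(ab)) == 0L
    if (any(all_missing))
        stop("assay(s) with no measured values: ",
             paste(rownames(ab)[all_missing], collapse = ", "),
             " (should have been filtered)")
    mu <- rowMeans(ab, na.rm = TRUE)
    idx <- which(is.na(ab), arr.ind = TRUE)
    if (nrow(idx)) {
        ab[idx] <- mu[idx[, 1L]]
        st[idx] <- "imputed"
    }
    AbundanceExperiment(ab, st,
                        rowData = SummarizedExperiment::rowData(object),
                        colData = SummarizedExperiment::colData(object))
}

#' 5'/3' mRNA integrity ratio
#'
#' With oligo-dT-primed reverse transcription, degraded RNA depresses signal
#' at assays far from the 3' end, so the ratio of a 5' assay to a 3' assay of
#' the same gene falls below 1 in fragmented samples.
#'
#' @param object an [AbundanceExperiment].
#' @param gene gene symbol carrying the assay pair.
#' @param five_assay,three_assay assay identifiers; default to the assays of
#'   `gene` with `distance_class` `5prime` / `3prime`.
#' @param threshold subjects with a ratio strictly below this are flagged.
#' @return data.frame per subject: `subject_id`, `ratio`, `flagged`
#'   (`NA` ratio, e.g. zero or missing 3' abundance, is flagged).
#' @export
integrityRatio <- function(object, gene, five_assay = NULL, three_assay = NULL,
                           threshold = 0.2) {
    rd <- SummarizedExperiment::rowData(object)
    if (is.null(five_assay))
        five_assay <- rownames(object)[rd$gene == gene &
                                       rd$distance_class == "5prime"][1]
    if (is.null(three_assay))
        three_assay <- rownames(object)[rd$gene == gene &
                                        rd$distance_class == "3prime"][1]
    if (is.na(five_assay) || is.na(three_assay) ||
        !all(c(five_assay, three_assay) %in% rownames(object)))
        stop("5' and 3' assays for gene '", gene, "' not both present")
    ab <- abundance(object)
    denom <- ab[three_assay, ]
    ratio <- ifelse(!is.na(denom) & denom > 0,
                    ab[five_assay, ] / denom, NA_real_)
    data.frame(subject_id = colnames(object), ratio = ratio,
               flagged = is.na(ratio) | ratio < threshold,
               row.names = NULL, stringsAsFactors = FALSE)
}
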