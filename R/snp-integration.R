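## GWAS-integration utilities. Coordinate conventions: interval tables
## (regulatory regions, gene spans) are BED-style 0-based half-open;
## SNP positions are 1-based (VCF convention) and converted on ingestion.

.regions_gr <- function(regions) {
    stopifnot(all(c("chrom", "start", "end") %in% names(regions)),
              all(regions$start < regions$end))
    GenomicRanges::GRanges(
        seqnames = regions$chrom,
        ranges = IRanges::IRanges(start = regions$start + 1L,
                                  end = regions$end),
        label = if ("label" %in% names(regions)) regions$label
                else NA_character_)
}

.snps_gr <- function(snps) {
    stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
              all(snps$pos > 0))
    GenomicRanges::GRanges(seqnames = snps$chrom,
                           ranges = IRanges::IRanges(start = snps$pos,
                                                     width = 1L))
}

.check_chroms <- function(snps, regions) {
    bad <- setdiff(unique(snps$chrom), unique(regions$chrom))
    if (length(bad))
        stop("chromosome name mismatch between SNP table and interval set; ",
             "offending chromosome(s): ", paste(bad, collapse = ", "))
}

#' Restrict SNPs to putative regulatory regions
#'
#' Keeps SNPs whose 0-based position falls inside any interval of a BED-style
#' region set. The overlap is computed with an interval-tree lookup
#' ([IRanges::findOverlaps]), sub-quadratic in the input sizes.
#'
#' @param snps data.frame of SNP associations: `snp_id`, `chrom`, `pos`
#'   (1-based), typically also `p` and `phenotype`.
#' @param regions data.frame of intervals: `chrom`, `start`, `end`
#'   (0-based half-open), optional `label`.
#' @return the subset of `snps` rows overlapping any region.
#' @export
restrictToRegions <- function(snps, regions) {
    .check_chroms(snps, regions)
    if (!nrow(snps)) return(snps)
    hits <- GenomicRanges::findOverlaps(.snps_gr(snps), .regions_gr(regions))
    snps[sort(unique(S4Vectors::queryHits(hits))), , drop = FALSE]
}

#' Intersect SNPs with gene intervals
#'
#' Keeps SNPs within a gene span extended by `flank` bases on both sides and
#' annotates each kept SNP with the overlapping gene label(s)
#' (comma-separated when genes overlap).
#'
#' @inheritParams restrictToRegions
#' @param gene_intervals data.frame of gene spans (`chrom`, `start`, `end`
#'   0-based half-open, `label` = gene symbol).
#' @param flank bases added on both sides of every gene span.
#' @return the annotated subset with an added `gene` column; the result also
#'   carries a per-gene SNP count in `attr(, "gene_counts")`.
#' @export
intersectGenes <- function(snps, gene_intervals, flank = 10000L) {
    stopifnot("label" %in% names(gene_intervals))
    .check_chroms(snps, gene_intervals)
    if (!nrow(snps)) { snps$gene <- character(0); return(snps) }
    gr <- .regions_gr(gene_intervals)
    gr <- GenomicRanges::resize(gr, GenomicRanges::width(gr) + 2L * flank,
                                fix = "center")
    GenomicRanges::start(gr) <- pmax(1L, GenomicRanges::start(gr))
    hits <- GenomicRanges::findOverlaps(.snps_gr(snps), gr)
    if (!length(hits)) {
        out <- snps[0, , drop = FALSE]; out$gene <- character(0)
        attr(out, "gene_counts") <- table(character(0))
        return(out)
    }
    qh <- S4Vectors::queryHits(hits)
    lab <- gr$label[S4Vectors::subjectHits(hits)]
    ann <- vapply(split(lab, qh), function(g)
        paste(sort(unique(g)), collapse = ","), character(1))
    keep <- as.integer(names(ann))
    out <- snps[keep, , drop = FALSE]
    out$gene <- unname(ann)
    attr(out, "gene_counts") <- table(lab)
    out
}

#' Keep SNPs with association p strictly below alpha
#'
#' @param snps data.frame with a `p` column.
#' @param alpha threshold in (0, 1); strict inequality `p < alpha`.
#' @return the subset.
#' @export
filterSignificant <- function(snps, alpha = 0.05) {
    stopifnot(alpha > 0, alpha < 1)
    snps[snps$p < alpha, , drop = FALSE]
}

#' Bonferroni validation of queried associations
#'
#' @param p_values named numeric vector, one entry per validation query.
#' @param alpha family-wise error rate.
#' @param m number of queries corrected for (defaults to the number of
#'   p-values supplied).
#' @return list: `threshold` (`alpha / m`), `validated` (logical per query),
#'   `m`, `alpha`.
#' @examples
#' validateBonferroni(c(CB = 0.0046, EM = 0.32), alpha = 0.05)
#' @export
validateBonferroni <- function(p_values, alpha = 0.05, m = length(p_values)) {
    stopifnot(m >= 1L)
    list(threshold = alpha / m, validated = p_values < alpha / m,
         m = m, alpha = alpha)
}

#' Normalised linkage disequilibrium D' from haplotype counts
#'
#' With haplotype frequencies `p_AB` etc. and allele frequencies
#' `p_A`, `p_B`: `D = p_AB - p_A p_B`; `D' = |D| / D_max` where `D_max` is
#' `min(p_A p_b, p_a p_B)` when `D > 0` and `min(p_A p_B, p_a p_b)` when
#' `D < 0`. `D' = 1` denotes complete linkage (at most three haplotypes
#' observed).
#'
#' @param n_AB,n_Ab,n_aB,n_ab haplotype counts for two biallelic sites.
#' @return D' in \[0, 1\] (0 when D = 0).
#' @examples
#' dPrime(10, 0, 0, 90)  # 1: only two haplotypes
#' @export
dPrime <- function(n_AB, n_Ab, n_aB, n_ab) {
    n <- c(n_AB, n_Ab, n_aB, n_ab)
    stopifnot(all(n >= 0), sum(n) > 0)
    f <- n / sum(n)
    pA <- f[1] + f[2]; pB <- f[1] + f[3]
    if (pA %in% c(0, 1) || pB %in% c(0, 1))
        stop("monomorphic site: D' undefined")
    D <- f[1] - pA * pB
    if (D == 0) return(0)
    dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
            else min(pA * pB, (1 - pA) * (1 - pB))
    abs(D) / dmax
}

#' Read a BED-style interval file
#'
#' Plain-text BED (chrom, start, end, optional name): 0-based half-open,
#' the convention every interval function in this package expects.
#'
#' @param path file path.
#' @return data.frame: `chrom`, `start`, `end`, `label`.
#' @export
readBedRegions <- function(path) {
    d <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    names(d) <- c("chrom", "start", "end", "label", "score",
                  "strand")[seq_len(ncol(d))]
    if (!"label" %in% names(d)) d$label <- NA_character_
    d[, c("chrom", "start", "end", "label")]
}
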