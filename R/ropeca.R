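# Paired peptide-level differential tests aggregated to protein level via
# the beta law of the median order statistic, with BH FDR control.

.P_FLOOR <- 1e-15

#' Paired peptide-level differential test
#'
#' For each peptide, forms per-replicate paired differences d_r = log2(a_r)
#' - log2(b_r) between two condition groups sharing replicate indices, and
#' tests mean(d) = 0 with an ordinary paired t statistic, t =
#' mean(d) / (sd(d)/sqrt(n)), two-sided p from the t distribution with n-1
#' degrees of freedom. Quantities must be imputed (complete); inputs on raw
#' or bait-normalized scale are log2-transformed internally. Zero-variance
#' difference vectors (which imputation can create) get p = 1 when the mean
#' difference is zero and p = 1e-15 otherwise.
#'
#' @param qm a peptide- or protein-level \linkS4class{QuantMatrix} (raw or
#'   bait_normalized scale, no missing values).
#' @param groupA,groupB condition-group labels as produced by
#'   \code{\link{groupLabel}} (numerator group first).
#' @return data.table with columns \code{protein_id}, \code{peptide_id},
#'   \code{log2_fc}, \code{t_stat}, \code{p_value}, \code{n_pairs}.
#' @export
pairedPeptideTest <- function(qm, groupA, groupB) {
    stopifnot(is(qm, "QuantMatrix"))
    d <- sampleDesign(qm)
    gl <- groupLabel(d)
    for (g in c(groupA, groupB))
        if (!g %in% gl) .stopf("group '%s' not found in design (have: %s)",
                               g, paste(unique(gl), collapse = ", "))
    da <- d[gl == groupA, ]
    db <- d[gl == groupB, ]
    reps <- intersect(da$replicate, db$replicate)
    if (!setequal(da$replicate, db$replicate) ||
        anyDuplicated(da$replicate) || anyDuplicated(db$replicate))
        .stopf("replicate indices of '%s' and '%s' do not pair one-to-one",
               groupA, groupB)
    if (length(reps) < 2L)
        .stopf("paired test needs >= 2 complete replicate pairs")
    reps <- sort(reps)
    q <- quantData(qm)
    if (anyNA(q)) .stopf("quantities contain missing values; impute first")
    xa <- log2(q[, da$sample_id[match(reps, da$replicate)], drop = FALSE])
    xb <- log2(q[, db$sample_id[match(reps, db$replicate)], drop = FALSE])
    dd <- xa - xb
    n <- length(reps)
    m <- rowMeans(dd)
    s <- apply(dd, 1L, sd)
    t <- ifelse(s > 0, m / (s / sqrt(n)), NA_real_)
    p <- ifelse(s > 0, 2 * pt(-abs(t), df = n - 1L),
                ifelse(m == 0, 1, .P_FLOOR))
    rd <- as.data.frame(rowData(qm))
    data.table(protein_id = rd$protein_id,
               peptide_id = if ("peptide_id" %in% names(rd)) rd$peptide_id
                            else rd$protein_id,
               log2_fc = m, t_stat = t, p_value = p, n_pairs = n)
}

#' Protein-level p-value from the median peptide p-value
#'
#' The reproducibility-optimized aggregation: with n peptide p-values, let
#' k = floor(n/2) + 1 (upper median) and m the k-th smallest p-value. Under
#' the null the k-th order statistic of n uniforms follows Beta(k, n-k+1),
#' so the protein-level p-value is the Beta(k, n-k+1) CDF evaluated at m.
#' Requiring the \emph{median} peptide to be significant rewards effects
#' reproduced across a protein's peptides rather than driven by one.
#'
#' @param pvalues non-empty numeric vector of peptide-level p-values in
#'   [0, 1].
#' @return the protein-level p-value.
#' @examples
#' betaMedianPValue(0.3)                 # n = 1: uniform, returns 0.3
#' betaMedianPValue(c(0.2, 0.5, 0.9))    # Beta(2,2) CDF at 0.5 = 0.5
#' @export
betaMedianPValue <- function(pvalues) {
    if (!length(pvalues)) .stopf("empty p-value list")
    if (anyNA(pvalues) || any(pvalues < 0) || any(pvalues > 1))
        .stopf("p-values must lie in [0, 1]")
    n <- length(pvalues)
    k <- n %/% 2L + 1L
    m <- sort(pvalues)[k]
    pbeta(m, k, n - k + 1L)
}

#' Aggregate peptide statistics to protein level
#'
#' Per protein: \code{median_log2_fc} is the median of the peptide log2 fold
#' changes (mean of the two central values for even counts), the p-value is
#' \code{\link{betaMedianPValue}} of the peptide p-values, and q-values are
#' Benjamini-Hochberg adjusted across all proteins in the contrast.
#'
#' @param peptideStats output of \code{\link{pairedPeptideTest}} (phospho
#'   routing, if any, already applied to \code{protein_id}).
#' @return data.table with columns \code{protein_id}, \code{median_log2_fc},
#'   \code{n_peptides}, \code{p_value}, \code{q_value}, sorted by protein.
#' @export
aggregateToProtein <- function(peptideStats) {
    ps <- as.data.table(peptideStats)
    out <- ps[, .(median_log2_fc = median(log2_fc),
                  n_peptides = .N,
                  p_value = betaMedianPValue(p_value)),
              by = protein_id]
    setorder(out, protein_id)
    out[, q_value := adjustBH(p_value)]
    out[]
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over \code{stats::p.adjust(method = "BH")}, applied per
#' contrast across all proteins tested in that contrast.
#'
#' @param pvalues numeric vector in [0, 1].
#' @return step-up adjusted q-values, capped at 1, order-invariant.
#' @export
adjustBH <- function(pvalues) {
    p.adjust(pvalues, method = "BH")
}

#' Run a full protein-level contrast
#'
#' Convenience wrapper: paired peptide test between two condition groups
#' followed by protein aggregation and BH adjustment.
#'
#' @inheritParams pairedPeptideTest
#' @return as \code{\link{aggregateToProtein}}.
#' @export
testContrast <- function(qm, groupA, groupB) {
    aggregateToProtein(pairedPeptideTest(qm, groupA, groupB))
}

#' Route phosphopeptides to their own protein identifier
#'
#' Peptides whose id matches \code{pattern} (a modification token) are
#' reassigned the synthetic protein id \code{"<protein>@<peptide_id>"}, so
#' regulated phosphopeptides are tested and reported as independent
#' entities instead of being masked (and filtered) within their parent
#' protein's peptide population.
#'
#' @param fe a \linkS4class{FragmentExperiment}.
#' @param pattern regular expression identifying modified peptide ids
#'   (default matches a \code{"[ph]"} token).
#' @return a \linkS4class{FragmentExperiment} with routed protein ids.
#' @export
routePhosphopeptides <- function(fe, pattern = "\\[ph\\]") {
    stopifnot(is(fe, "FragmentExperiment"))
    fr <- fragmentData(fe)
    hit <- grepl(pattern, fr$peptide_id)
    fr[hit, protein_id := paste0(protein_id, "@", peptide_id)]
    FragmentExperiment(fr, sampleDesign(fe))
}
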