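# iBAQ-based interaction stoichiometry from in-silico tryptic digestion.

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the following residue is P, producing
#' fully tryptic peptides; with \code{missedCleavages > 0}, concatenations
#' of up to that many adjacent peptides are appended.
#'
#' @param sequence amino-acid sequence (one-letter codes).
#' @param params a \linkS4class{DigestParams}.
#' @return character vector of peptides (all lengths; filtering to the
#'   countable range is done by \code{\link{theoreticalPeptideCount}}).
#' @export
digestSequence <- function(sequence, params = digestParams()) {
    stopifnot(is(params, "DigestParams"))
    sequence <- toupper(sequence)
    if (!nzchar(sequence)) .stopf("empty sequence")
    aa <- strsplit(sequence, "")[[1L]]
    n <- length(aa)
    cut <- which(aa %in% c("K", "R"))
    cut <- cut[cut < n & aa[pmin(cut + 1L, n)] != "P" | cut == n]
    bounds <- c(0L, cut[cut < n], n)
    starts <- head(bounds, -1L) + 1L
    ends <- bounds[-1L]
    peps <- substring(sequence, starts, ends)
    if (params@missedCleavages > 0 && length(peps) > 1L) {
        extra <- list()
        for (mc in seq_len(params@missedCleavages)) {
            if (length(peps) <= mc) break
            idx <- seq_len(length(peps) - mc)
            extra[[mc]] <- vapply(idx, function(i)
                paste(peps[i:(i + mc)], collapse = ""), character(1))
        }
        peps <- c(peps, unlist(extra))
    }
    peps
}

#' Theoretically observable tryptic peptide count
#'
#' The iBAQ denominator: the number of digestion products whose length lies
#' in \code{[minLen, maxLen]} (defaults 6-30, the original iBAQ
#' convention).
#'
#' @inheritParams digestSequence
#' @return integer count (0 means iBAQ is undefined for this protein).
#' @examples
#' theoreticalPeptideCount("MKAAAAAAKRCCCCCCK")  # 2 (AAAAAAK, CCCCCCK)
#' theoreticalPeptideCount("AAKPAA")             # 1 (KP suppresses cleavage)
#' @export
theoreticalPeptideCount <- function(sequence, params = digestParams()) {
    peps <- digestSequence(sequence, params)
    len <- nchar(peps)
    sum(len >= params@minLen & len <= params@maxLen)
}

#' iBAQ values from an imputed protein matrix
#'
#' iBAQ = mean raw quantity over the selected samples divided by the
#' protein's theoretical peptide count; proportional to molar abundance, so
#' ratios of iBAQ values are molar ratios.
#'
#' @param qm imputed raw-scale protein-level \linkS4class{QuantMatrix}.
#' @param sequences named character vector of protein sequences (must cover
#'   every protein scored).
#' @param params a \linkS4class{DigestParams}.
#' @param samples sample ids to average over (e.g. the tagged replicates of
#'   one condition). Default: all samples.
#' @param proteins protein ids to score. Default: all rows with a sequence.
#' @return data.table with \code{protein_id}, \code{mean_quantity},
#'   \code{peptide_count}, \code{ibaq} (\code{NA} with a flag when the
#'   count is zero).
#' @export
computeIbaq <- function(qm, sequences, params = digestParams(),
                        samples = NULL, proteins = NULL) {
    stopifnot(is(qm, "QuantMatrix"), quantLevel(qm) == "protein")
    if (scaleType(qm) != "raw")
        .stopf("iBAQ requires the raw-scale matrix, got '%s'", scaleType(qm))
    q <- quantData(qm)
    if (is.null(samples)) samples <- colnames(q)
    bad <- setdiff(samples, colnames(q))
    if (length(bad))
        .stopf("unknown sample(s): %s", paste(bad, collapse = ", "))
    if (is.null(proteins)) proteins <- rownames(q)
    noSeq <- setdiff(proteins, names(sequences))
    if (length(noSeq))
        .stopf("no sequence for protein(s): %s",
               paste(head(noSeq, 5L), collapse = ", "))
    cnt <- vapply(sequences[proteins], theoreticalPeptideCount, numeric(1),
                  params = params)
    mq <- rowMeans(q[proteins, samples, drop = FALSE])
    out <- data.table(protein_id = proteins, mean_quantity = mq,
                      peptide_count = as.integer(cnt),
                      ibaq = ifelse(cnt > 0, mq / cnt, NA_real_))
    if (any(cnt == 0))
        warning("iBAQ undefined (zero countable peptides) for: ",
                paste(out$protein_id[cnt == 0], collapse = ", "))
    out[]
}

#' Interaction stoichiometry relative to the bait
#'
#' stoichiometry = prey iBAQ / bait iBAQ, interpreted as the fraction of
#' bait molecules occupied by the prey in the averaged condition; reported
#' both as a fraction and as a percentage. The bait's own value is exactly 1.
#'
#' @param ibaq output of \code{\link{computeIbaq}}.
#' @param baitId bait protein id (must have positive iBAQ).
#' @return data.table with \code{protein_id}, \code{ibaq},
#'   \code{stoichiometry_fraction}, \code{stoichiometry_pct}, sorted by
#'   descending stoichiometry.
#' @export
stoichiometry <- function(ibaq, baitId) {
    ib <- as.data.table(ibaq)
    if (!baitId %in% ib$protein_id)
        .stopf("bait '%s' absent from iBAQ table", baitId)
    bi <- ib$ibaq[ib$protein_id == baitId]
    if (is.na(bi) || bi <= 0) .stopf("bait iBAQ must be positive")
    out <- ib[, .(protein_id, ibaq,
                  stoichiometry_fraction = ibaq / bi,
                  stoichiometry_pct = 100 * ibaq / bi)]
    setorder(out, -stoichiometry_fraction, protein_id, na.last = TRUE)
    out[]
}

#' Stoichiometry of a condition group in one call
#'
#' Convenience wrapper: averages the imputed raw quantities over the
#' replicates of one condition group, computes iBAQ for the requested
#' proteins and normalizes to the bait.
#'
#' @inheritParams computeIbaq
#' @param group condition-group label (see \code{\link{groupLabel}}) whose
#'   replicate samples are averaged.
#' @param baitId bait protein id.
#' @return as \code{\link{stoichiometry}}.
#' @export
stoichiometryAt <- function(qm, sequences, group, baitId,
                            params = digestParams(), proteins = NULL) {
    d <- sampleDesign(qm)
    gl <- groupLabel(d)
    if (!group %in% gl)
        .stopf("group '%s' not in design (have: %s)", group,
               paste(unique(gl), collapse = ", "))
    samples <- d$sample_id[gl == group]
    if (is.null(proteins)) proteins <- rownames(quantData(qm))
    proteins <- union(proteins, baitId)
    stoichiometry(computeIbaq(qm, sequences, params, samples, proteins),
                  baitId)
}
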