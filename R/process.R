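# Fragment reliability filtering, roll-up, imputation, bait normalization.

#' Per-condition detection filter
#'
#' A fragment ion's rows are retained for a condition group (background x
#' condition x time) only if the fragment has at least \code{minDetect}
#' non-missing intensities within that group's replicates; the same fragment
#' is judged independently in every group. Filters only remove rows, never
#' alter intensities.
#'
#' @param fe a \linkS4class{FragmentExperiment}.
#' @param minDetect minimum detections per condition group (default 2).
#' @return a filtered \linkS4class{FragmentExperiment}.
#' @export
detectionFilter <- function(fe, minDetect = 2) {
    stopifnot(is(fe, "FragmentExperiment"))
    if (minDetect < 1) .stopf("minDetect must be >= 1")
    fr <- fragmentData(fe)
    d <- sampleDesign(fe)
    fr[, .grp := groupLabel(d)[match(sample_id, d$sample_id)]]
    fr[, .ndet := sum(!is.na(intensity)),
       by = .(protein_id, peptide_id, fragment_id, .grp)]
    out <- fr[.ndet >= minDetect]
    out[, c(".grp", ".ndet") := NULL]
    FragmentExperiment(out, d)
}

#' Fragment reliability filter
#'
#' Within each peptide, fragments are compared against a reference profile
#' (the across-fragment median of log2 intensities, per sample). Two rules
#' are applied in sequence, each independently switchable by setting its
#' parameter to a permissive value:
#' \enumerate{
#'   \item \emph{correlation rule}: drop fragments whose Pearson correlation
#'     with the reference over their shared observed samples is below
#'     \code{minCorrelation} (fragments sharing fewer than 3 samples with
#'     the reference, or with zero variance, are kept);
#'   \item \emph{deviation rule}: recompute the reference on survivors, then
#'     drop fragments whose mean absolute log2 deviation from it --- after
#'     removing the fragment's constant offset (fragment ions of one peptide
#'     differ by fixed response factors, which carry no information about
#'     reliability) --- exceeds \code{sdFactor} times the across-fragment
#'     mean of those deviations.
#' }
#' Peptides with fewer than two fragments pass unchanged. A single pass is
#' made; rules do not cascade.
#'
#' @param fe a \linkS4class{FragmentExperiment} (detection-filtered).
#' @param sdFactor deviation multiplier (default 2).
#' @param minCorrelation correlation threshold (default 0.25).
#' @return a filtered \linkS4class{FragmentExperiment}.
#' @export
reliabilityFilter <- function(fe, sdFactor = 2, minCorrelation = 0.25) {
    stopifnot(is(fe, "FragmentExperiment"))
    fr <- fragmentData(fe)
    d <- sampleDesign(fe)
    samples <- d$sample_id
    keepKey <- fr[, {
        frs <- unique(fragment_id)
        if (length(frs) < 2L) {
            list(fragment_id = frs)
        } else {
            m <- matrix(NA_real_, length(frs), length(samples),
                        dimnames = list(frs, samples))
            m[cbind(match(fragment_id, frs), match(sample_id, samples))] <-
                log2(ifelse(intensity > 0, intensity, NA_real_))
            ref <- apply(m, 2L, median, na.rm = TRUE)
            keep <- vapply(seq_along(frs), function(i) {
                sh <- which(!is.na(m[i, ]) & !is.na(ref))
                if (length(sh) < 3L) return(TRUE)
                # flat profiles carry no information to correlate
                if (sd(m[i, sh]) < 1e-8 || sd(ref[sh]) < 1e-8) return(TRUE)
                cor(m[i, sh], ref[sh]) >= minCorrelation
            }, logical(1))
            if (sum(keep) >= 2L) {
                m2 <- m[keep, , drop = FALSE]
                ref2 <- apply(m2, 2L, median, na.rm = TRUE)
                dev <- vapply(seq_len(nrow(m2)), function(i) {
                    sh <- which(!is.na(m2[i, ]) & !is.na(ref2))
                    if (!length(sh)) return(0)
                    r <- m2[i, sh] - ref2[sh]
                    mean(abs(r - mean(r)))
                }, numeric(1))
                spread <- mean(dev)
                # a spread at numerical-noise scale means the fragments are
                # effectively proportional; the relative rule must not fire
                keep[keep] <- spread < 1e-6 | dev <= sdFactor * spread
            }
            list(fragment_id = frs[keep])
        }
    }, by = .(protein_id, peptide_id)]
    out <- fr[keepKey, on = c("protein_id", "peptide_id", "fragment_id")]
    FragmentExperiment(out, d)
}

#' Roll fragments up to peptide and protein quantities
#'
#' Peptide quantity = sum of retained fragment intensities per sample;
#' protein quantity = sum of its peptide quantities. A quantity is missing
#' only when every constituent is missing, so roll-up conserves the total
#' retained intensity per sample.
#'
#' @param fe a filtered \linkS4class{FragmentExperiment}.
#' @return list with \code{peptide} and \code{protein}
#'   \linkS4class{QuantMatrix} objects (raw scale).
#' @export
rollUp <- function(fe) {
    stopifnot(is(fe, "FragmentExperiment"))
    fr <- fragmentData(fe)
    d <- sampleDesign(fe)
    sumNA <- function(x) if (all(is.na(x))) NA_real_ else sum(x, na.rm = TRUE)
    pep <- fr[, .(quant = sumNA(intensity)),
              by = .(protein_id, peptide_id, sample_id)]
    pepKey <- unique(pep[, .(protein_id, peptide_id)])
    setorder(pepKey, protein_id, peptide_id)
    pmatPep <- matrix(NA_real_, nrow(pepKey), nrow(d),
                      dimnames = list(paste(pepKey$protein_id,
                                            pepKey$peptide_id, sep = "|"),
                                      d$sample_id))
    pmatPep[cbind(match(paste(pep$protein_id, pep$peptide_id, sep = "|"),
                        rownames(pmatPep)),
                  match(pep$sample_id, d$sample_id))] <- pep$quant

    prot <- pep[, .(quant = sumNA(quant)), by = .(protein_id, sample_id)]
    prots <- sort(unique(prot$protein_id))
    pmatProt <- matrix(NA_real_, length(prots), nrow(d),
                       dimnames = list(prots, d$sample_id))
    pmatProt[cbind(match(prot$protein_id, prots),
                   match(prot$sample_id, d$sample_id))] <- prot$quant

    list(peptide = QuantMatrix(pmatPep, d, level = "peptide",
                               rowData = data.frame(
                                   protein_id = pepKey$protein_id,
                                   peptide_id = pepKey$peptide_id)),
         protein = QuantMatrix(pmatProt, d, level = "protein"))
}

#' Impute missing quantities from each analyte's own distribution
#'
#' Every missing entry of an analyte (row) is replaced by the
#' \code{imputeQuantile} quantile (linear-interpolation convention) of that
#' analyte's observed values across all samples, mirroring the idea that a
#' non-detection reflects signal near the low end of the analyte's observed
#' range. Rows with no observed value at all cannot be imputed; they are
#' dropped and listed in \code{metadata(x)$dropped_analytes}. Imputed
#' positions are recorded in a logical assay \code{"imputed"}. The operation
#' is idempotent.
#'
#' @param qm a raw-scale \linkS4class{QuantMatrix}.
#' @param imputeQuantile quantile in (0,1), default 0.01.
#' @return an imputed \linkS4class{QuantMatrix} with no missing entries.
#' @export
imputeMissing <- function(qm, imputeQuantile = 0.01) {
    stopifnot(is(qm, "QuantMatrix"))
    if (imputeQuantile <= 0 || imputeQuantile >= 1)
        .stopf("imputeQuantile must be in (0, 1)")
    q <- quantData(qm)
    nObs <- rowSums(!is.na(q))
    dropped <- rownames(q)[nObs == 0L]
    keep <- nObs > 0L
    qk <- q[keep, , drop = FALSE]
    imp <- if ("imputed" %in% names(assays(qm)))
        assay(qm, "imputed")[keep, , drop = FALSE]
    else matrix(FALSE, nrow(qk), ncol(qk), dimnames = dimnames(qk))
    for (i in which(rowSums(is.na(qk)) > 0L)) {
        obs <- qk[i, !is.na(qk[i, ])]
        fill <- type7Quantile(obs, imputeQuantile)
        imp[i, is.na(qk[i, ])] <- TRUE
        qk[i, is.na(qk[i, ])] <- fill
    }
    se <- SummarizedExperiment(
        assays = list(quant = qk, imputed = imp),
        rowData = rowData(qm)[keep, , drop = FALSE],
        colData = colData(qm))
    out <- new("QuantMatrix", se, scaleType = qm@scaleType, level = qm@level)
    metadata(out)$dropped_analytes <- dropped
    metadata(out)$impute_quantile <- imputeQuantile
    out
}

#' Normalize protein quantities to the bait signal
#'
#' Divides every entry by the bait protein's quantity in the same sample
#' (per-sample, not per-condition-mean, so replicate pairing is preserved
#' for the paired test). The bait row becomes 1 everywhere. The bait must be
#' present with a positive quantity in every tagged-bait sample.
#'
#' @param qm an imputed protein-level \linkS4class{QuantMatrix}.
#' @param baitId protein id of the bait.
#' @return a \linkS4class{QuantMatrix} with \code{scaleType
#'   "bait_normalized"}.
#' @export
normalizeToBait <- function(qm, baitId) {
    stopifnot(is(qm, "QuantMatrix"), quantLevel(qm) == "protein")
    q <- quantData(qm)
    if (!baitId %in% rownames(q))
        .stopf("bait '%s' absent from the protein matrix", baitId)
    b <- q[baitId, ]
    d <- sampleDesign(qm)
    badTagged <- d$sample_id[d$background == "tagged_bait" &
                             (is.na(b) | b <= 0)]
    if (length(badTagged))
        .stopf("bait '%s' missing or zero in tagged sample(s): %s", baitId,
               paste(badTagged, collapse = ", "))
    if (any(is.na(b) | b <= 0))
        .stopf("bait '%s' missing or zero in sample(s): %s (impute first)",
               baitId,
               paste(colnames(q)[is.na(b) | b <= 0], collapse = ", "))
    qn <- sweep(q, 2L, b, `/`)
    se <- SummarizedExperiment(
        assays = c(list(quant = qn),
                   as.list(assays(qm))[setdiff(names(assays(qm)), "quant")]),
        rowData = rowData(qm), colData = colData(qm))
    new("QuantMatrix", se, scaleType = "bait_normalized", level = "protein")
}
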