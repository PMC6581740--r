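# Two-step interactor calling: specific (bait vs control enrichment across
# conditions, contaminant removal) then dynamic (bait-normalized change on
# stimulation), plus the report tables derived from the calls.

#' Call specific interactors
#'
#' Step 1 of the two orthogonal filters. A protein counts as enriched in a
#' condition when its bait-vs-control \code{median_log2_fc} exceeds
#' \code{log2(enrichmentFcThreshold)} (one-sided: bait over control) at
#' \code{q_value < enrichmentFdr}. A protein is a \emph{specific} interactor
#' when it is enriched in at least \code{minConditions} independent
#' conditions and does not match the contaminant list. Contaminant-matched
#' and excluded (bait/tag) proteins are reported with flags, never silently
#' dropped.
#'
#' @param statsPerCondition named list, condition label ->
#'   \code{\link{aggregateToProtein}} table computed on \emph{un-normalized}
#'   bait-vs-control contrasts.
#' @param params a \linkS4class{CallingParams}.
#' @param contaminants a \code{"ContaminantList"} (default
#'   \code{\link{defaultContaminants}()}).
#' @param exclude protein ids excluded from calling but retained in the
#'   report (typically the bait and the tag pseudo-entry).
#' @return data.table with one row per tested protein: \code{protein_id},
#'   \code{n_enriched}, \code{enriched_conditions} (comma-separated),
#'   \code{removed_as_contaminant}, \code{excluded}, \code{is_specific},
#'   \code{best_q}.
#' @export
callSpecific <- function(statsPerCondition, params = callingParams("mouse"),
                         contaminants = defaultContaminants(),
                         exclude = character()) {
    stopifnot(is(params, "CallingParams"))
    if (!length(statsPerCondition))
        .stopf("empty contrast map: need at least one bait-vs-control contrast")
    if (is.null(names(statsPerCondition)))
        .stopf("statsPerCondition must be a named list (condition labels)")
    fcGate <- log2(params@enrichmentFcThreshold)
    long <- rbindlist(lapply(names(statsPerCondition), function(cond) {
        st <- as.data.table(statsPerCondition[[cond]])
        st[, condition := cond]
        st
    }))
    calls <- long[, .(
        n_enriched = sum(median_log2_fc > fcGate &
                         q_value < params@enrichmentFdr),
        enriched_conditions = paste(
            sort(condition[median_log2_fc > fcGate &
                           q_value < params@enrichmentFdr]),
            collapse = ","),
        best_q = min(q_value)), by = protein_id]
    calls[, removed_as_contaminant := isContaminant(protein_id, contaminants)]
    calls[, excluded := protein_id %in% exclude]
    calls[, is_specific := n_enriched >= params@minConditions &
              !removed_as_contaminant & !excluded]
    setorder(calls, protein_id)
    calls[]
}

#' Call dynamic interactors
#'
#' Step 2: among the specific interactors, a protein is \emph{dynamic} when
#' its bait-normalized quantity changes at least
#' \code{dynamicFcThreshold}-fold in either direction
#' (\code{|median_log2_fc| >= log2(threshold)}) at \code{q_value <
#' dynamicFdr} in at least one stimulated-vs-unstimulated contrast.
#'
#' @param statsPerContrast named list, contrast label ->
#'   \code{\link{aggregateToProtein}} table computed on
#'   \emph{bait-normalized} quantities (stimulated vs unstimulated).
#' @param specificCalls output of \code{\link{callSpecific}}.
#' @param params a \linkS4class{CallingParams}.
#' @return \code{specificCalls} with added columns \code{is_dynamic},
#'   \code{dynamic_contrasts}, \code{best_dynamic_q}. \code{is_dynamic} is
#'   always a subset of \code{is_specific}.
#' @export
callDynamic <- function(statsPerContrast, specificCalls,
                        params = callingParams("mouse")) {
    stopifnot(is(params, "CallingParams"))
    if (missing(specificCalls) || is.null(specificCalls) ||
        !nrow(specificCalls))
        .stopf("dynamic filter requires specific calls from callSpecific()")
    if (!length(statsPerContrast))
        .stopf("empty contrast map for the dynamic filter")
    fcGate <- log2(params@dynamicFcThreshold)
    long <- rbindlist(lapply(names(statsPerContrast), function(cn) {
        st <- as.data.table(statsPerContrast[[cn]])
        st[, contrast := cn]
        st
    }))
    dyn <- long[, .(
        n_dynamic = sum(abs(median_log2_fc) >= fcGate &
                        q_value < params@dynamicFdr),
        dynamic_contrasts = paste(
            sort(contrast[abs(median_log2_fc) >= fcGate &
                          q_value < params@dynamicFdr]),
            collapse = ","),
        best_dynamic_q = min(q_value)), by = protein_id]
    out <- merge(as.data.table(specificCalls), dyn, by = "protein_id",
                 all.x = TRUE)
    out[is.na(n_dynamic), `:=`(n_dynamic = 0L, dynamic_contrasts = "")]
    out[, is_dynamic := is_specific & n_dynamic >= 1L]
    setorder(out, protein_id)
    out[]
}

#' Volcano-plot table
#'
#' Pure projection of a protein statistics table onto the coordinates of the
#' enrichment volcano: median log2 fold change vs -log10 q-value. Rows are
#' ordered by (q ascending, protein id) for deterministic output.
#'
#' @param stats an \code{\link{aggregateToProtein}} table.
#' @return data.table with \code{protein_id}, \code{median_log2_fc},
#'   \code{neg_log10_q}.
#' @export
volcanoTable <- function(stats) {
    st <- as.data.table(stats)
    out <- st[, .(protein_id, median_log2_fc, q_value,
                  neg_log10_q = -log10(q_value))]
    setorderv(out, c("q_value", "protein_id"))
    out[, q_value := NULL]
    out[]
}

#' Time-course heatmap table, row-normalized to the maximum
#'
#' For each interactor, the mean imputed quantity over replicates is
#' computed per time point within the tagged-bait purifications, and each
#' row is divided by its maximum, giving values in [0, 1] with the maximum
#' exactly 1 (the representation used for signalosome recruitment
#' heatmaps).
#'
#' @param qm an imputed protein-level \linkS4class{QuantMatrix}.
#' @param interactors protein ids to include (typically the specific calls).
#' @return matrix, interactors x time points (columns named
#'   \code{t<minutes>}).
#' @export
heatmapTable <- function(qm, interactors) {
    stopifnot(is(qm, "QuantMatrix"), quantLevel(qm) == "protein")
    if (!length(interactors)) .stopf("interactor set is empty")
    q <- quantData(qm)
    missing <- setdiff(interactors, rownames(q))
    if (length(missing))
        .stopf("interactor(s) absent from matrix: %s",
               paste(missing, collapse = ", "))
    d <- sampleDesign(qm)
    tagged <- d$background == "tagged_bait"
    times <- sort(unique(d$time_min[tagged]))
    m <- sapply(times, function(tp) {
        cols <- d$sample_id[tagged & d$time_min == tp]
        rowMeans(q[interactors, cols, drop = FALSE], na.rm = TRUE)
    })
    m <- matrix(m, nrow = length(interactors),
                dimnames = list(interactors,
                                paste0("t", format(times, trim = TRUE))))
    mx <- apply(m, 1L, max)
    if (any(mx <= 0))
        .stopf("all-zero time-course row for protein: %s",
               interactors[which(mx <= 0)[1L]])
    sweep(m, 1L, mx, `/`)
}

#' Bait-normalized profile of a phosphopeptide / unmodified peptide pair
#'
#' Reports the per-sample intensities of the phosphorylated and unmodified
#' forms of a site-bearing peptide, each divided by the bait protein
#' quantity in the same sample (so profiles are comparable across
#' injections), together with imputation flags.
#'
#' @param peptideQm imputed peptide-level \linkS4class{QuantMatrix}.
#' @param proteinQm imputed raw-scale protein-level \linkS4class{QuantMatrix}
#'   providing the bait quantities.
#' @param phosphoPeptideId,unmodifiedPeptideId peptide ids of the two forms.
#' @param baitId bait protein id.
#' @return data.table with \code{sample_id}, \code{time_min},
#'   \code{replicate}, \code{form} ("phospho"/"unmodified"),
#'   \code{normalized_intensity}, \code{imputed}.
#' @export
phosphoSiteProfile <- function(peptideQm, proteinQm, phosphoPeptideId,
                               unmodifiedPeptideId, baitId) {
    stopifnot(is(peptideQm, "QuantMatrix"), is(proteinQm, "QuantMatrix"))
    rd <- as.data.frame(rowData(peptideQm))
    q <- quantData(peptideQm)
    pq <- quantData(proteinQm)
    if (!baitId %in% rownames(pq))
        .stopf("bait '%s' absent from protein matrix", baitId)
    b <- pq[baitId, colnames(q)]
    if (any(is.na(b) | b <= 0))
        .stopf("bait quantity missing or non-positive; impute first")
    imp <- if ("imputed" %in% names(assays(peptideQm)))
        assay(peptideQm, "imputed") else
        matrix(FALSE, nrow(q), ncol(q), dimnames = dimnames(q))
    d <- sampleDesign(peptideQm)
    oneForm <- function(pid, label) {
        i <- which(rd$peptide_id == pid)
        if (!length(i)) .stopf("unknown peptide id: %s", pid)
        if (length(i) > 1L)
            .stopf("peptide id '%s' matches several rows; qualify by protein",
                   pid)
        data.table(sample_id = colnames(q),
                   time_min = d$time_min[match(colnames(q), d$sample_id)],
                   replicate = d$replicate[match(colnames(q), d$sample_id)],
                   form = label,
                   normalized_intensity = as.numeric(q[i, ] / b),
                   imputed = as.logical(imp[i, ]))
    }
    rbind(oneForm(phosphoPeptideId, "phospho"),
          oneForm(unmodifiedPeptideId, "unmodified"))
}
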