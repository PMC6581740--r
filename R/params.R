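#' Fragment filtering and imputation parameters
#'
#' @slot minDetectPerCondition minimum number of non-missing observations a
#'   fragment needs within a condition group to be retained there (default 2).
#' @slot sdFactor multiplier on the peptide's across-fragment deviation
#'   spread above which a fragment is considered unreliable (default 2).
#' @slot minCorrelation minimum Pearson correlation of a fragment with its
#'   peptide's reference profile (default 0.25).
#' @slot imputeQuantile quantile of an analyte's observed values used to fill
#'   its missing entries (default 0.01).
#' @export
setClass("FilterParams",
         slots = c(minDetectPerCondition = "numeric", sdFactor = "numeric",
                   minCorrelation = "numeric", imputeQuantile = "numeric"))

setValidity("FilterParams", function(object) {
    if (object@minDetectPerCondition < 1) return("minDetectPerCondition >= 1")
    if (object@sdFactor <= 0) return("sdFactor must be > 0")
    if (object@minCorrelation < -1 || object@minCorrelation > 1)
        return("minCorrelation must be in [-1, 1]")
    if (object@imputeQuantile <= 0 || object@imputeQuantile >= 1)
        return("imputeQuantile must be in (0, 1)")
    TRUE
})

#' @rdname FilterParams-class
#' @param minDetectPerCondition,sdFactor,minCorrelation,imputeQuantile see slots
#' @export
filterParams <- function(minDetectPerCondition = 2, sdFactor = 2,
                         minCorrelation = 0.25, imputeQuantile = 0.01) {
    new("FilterParams", minDetectPerCondition = minDetectPerCondition,
        sdFactor = sdFactor, minCorrelation = minCorrelation,
        imputeQuantile = imputeQuantile)
}

#' Interactor-calling thresholds
#'
#' The two orthogonal filters: step 1 calls a protein a specific interactor
#' when it is enriched over the untagged control beyond
#' \code{enrichmentFcThreshold}-fold at BH FDR < \code{enrichmentFdr} in at
#' least \code{minConditions} condition groups and is not on the contaminant
#' list; step 2 calls a specific interactor dynamic when its bait-normalized
#' quantity changes at least \code{dynamicFcThreshold}-fold (either
#' direction) at FDR < \code{dynamicFdr} in at least one
#' stimulated-vs-unstimulated contrast.
#'
#' @export
setClass("CallingParams",
         slots = c(enrichmentFcThreshold = "numeric", enrichmentFdr = "numeric",
                   minConditions = "numeric", dynamicFcThreshold = "numeric",
                   dynamicFdr = "numeric"))

setValidity("CallingParams", function(object) {
    if (object@enrichmentFcThreshold <= 1)
        return("enrichmentFcThreshold must be > 1")
    if (object@dynamicFcThreshold <= 0)
        return("dynamicFcThreshold must be > 0")
    for (f in c(object@enrichmentFdr, object@dynamicFdr))
        if (f <= 0 || f >= 1) return("FDR thresholds must be in (0, 1)")
    if (object@minConditions < 1) return("minConditions >= 1")
    TRUE
})

#' @rdname CallingParams-class
#' @param preset "mouse" (3-fold enrichment gate, primary T cells) or
#'   "jurkat" (6-fold, cell lines with higher background binding).
#' @param enrichmentFcThreshold,enrichmentFdr,minConditions,dynamicFcThreshold,dynamicFdr
#'   explicit overrides of the preset.
#' @export
callingParams <- function(preset = c("mouse", "jurkat"),
                          enrichmentFcThreshold = NULL,
                          enrichmentFdr = 0.01, minConditions = 2,
                          dynamicFcThreshold = 2, dynamicFdr = 0.05) {
    preset <- match.arg(preset)
    if (is.null(enrichmentFcThreshold))
        enrichmentFcThreshold <- switch(preset, mouse = 3, jurkat = 6)
    new("CallingParams", enrichmentFcThreshold = enrichmentFcThreshold,
        enrichmentFdr = enrichmentFdr, minConditions = minConditions,
        dynamicFcThreshold = dynamicFcThreshold, dynamicFdr = dynamicFdr)
}

#' In-silico digestion parameters for iBAQ
#'
#' Fully tryptic digestion: cleave C-terminal to K or R except when the next
#' residue is P. Peptides whose length falls in \code{[minLen, maxLen]} count
#' as theoretically observable.
#'
#' @export
setClass("DigestParams",
         slots = c(protease = "character", minLen = "numeric",
                   maxLen = "numeric", missedCleavages = "numeric"))

setValidity("DigestParams", function(object) {
    if (object@protease != "trypsin") return("only trypsin is supported")
    if (object@minLen < 1 || object@minLen > object@maxLen)
        return("need 1 <= minLen <= maxLen")
    if (object@missedCleavages < 0) return("missedCleavages >= 0")
    TRUE
})

#' @rdname DigestParams-class
#' @param protease only \code{"trypsin"}.
#' @param minLen,maxLen countable peptide length range (defaults 6-30).
#' @param missedCleavages number of missed cleavage sites allowed (default 0).
#' @export
digestParams <- function(protease = "trypsin", minLen = 6, maxLen = 30,
                         missedCleavages = 0) {
    new("DigestParams", protease = protease, minLen = minLen, maxLen = maxLen,
        missedCleavages = missedCleavages)
}

# ---------------------------------------------------------------------------
# Contaminant list: explicit ids plus identifier-prefix family rules.

#' Build a contaminant list
#'
#' @param ids character vector of explicit protein/gene identifiers.
#' @param prefixes identifier prefixes (protein families such as keratins,
#'   myosins, tubulins) matched case-insensitively at the start of an id.
#' @return an object of class \code{"ContaminantList"}.
#' @export
contaminantList <- function(ids = character(), prefixes = character()) {
    structure(list(ids = toupper(ids), prefixes = toupper(prefixes)),
              class = "ContaminantList")
}

#' Default AP-MS contaminant list
#'
#' The eleven recurrent affinity-purification background proteins removed in
#' the reference analysis plus prefix rules covering the keratin, myosin and
#' tubulin families. Fully user-replaceable; the full community contaminant
#' repository (CRAPome) is not bundled.
#'
#' @return a \code{"ContaminantList"}.
#' @export
defaultContaminants <- function() {
    contaminantList(
        ids = c("EEF1A1", "GAPDH", "HSP90AB1", "HSPA5", "HSPA8", "KRT33B",
                "TUBA1A", "TUBA1B", "TUBB", "TUBA4A", "TUBB4B"),
        prefixes = c("KRT", "MYH", "MYL", "TUB"))
}

#' Match identifiers against a contaminant list
#'
#' Matching is case-insensitive; explicit ids match exactly, prefix rules
#' match the start of the identifier.
#'
#' @param ids character vector of protein identifiers.
#' @param contaminants a \code{"ContaminantList"}.
#' @return logical vector.
#' @export
isContaminant <- function(ids, contaminants) {
    if (!inherits(contaminants, "ContaminantList"))
        .stopf("contaminants must be a ContaminantList")
    up <- toupper(ids)
    hit <- up %in% contaminants$ids
    for (p in contaminants$prefixes)
        hit <- hit | startsWith(up, p)
    hit
}

#' @export
print.ContaminantList <- function(x, ...) {
    cat(sprintf("ContaminantList: %d explicit ids, %d prefix rules (%s)\n",
                length(x$ids), length(x$prefixes),
                paste(x$prefixes, collapse = ", ")))
    invisible(x)
}
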