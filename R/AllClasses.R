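#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @import data.table
NULL

setOldClass("data.table")

.BACKGROUNDS <- c("tagged_bait", "untagged_control")
.SILAC_CHANNELS <- c("none", "light", "heavy")
.FRAGMENT_COLS <- c("protein_id", "peptide_id", "fragment_id", "sample_id",
                    "intensity")
.DESIGN_COLS <- c("sample_id", "background", "condition", "time_min",
                  "replicate", "silac_channel")

#' Fragment-level AP-MS experiment
#'
#' Container pairing a long-format table of fragment ion intensities with the
#' sample design of the purification experiment. Rows of the fragment table
#' are keyed by (protein, peptide, fragment, sample); a missing intensity
#' (\code{NA}) means the fragment ion was not detected in that injection and
#' is distinct from an observed low value.
#'
#' @slot fragments \code{data.table} with columns \code{protein_id},
#'   \code{peptide_id} (modified-sequence token; phospho-forms are distinct
#'   peptides), \code{fragment_id}, \code{sample_id}, \code{intensity}
#'   (non-negative or \code{NA}).
#' @slot design \code{data.frame} with one row per sample: \code{sample_id},
#'   \code{background} (\code{"tagged_bait"} or \code{"untagged_control"}),
#'   \code{condition}, \code{time_min}, \code{replicate} (pairing key across
#'   compared groups), \code{silac_channel} (\code{"none"}, \code{"light"},
#'   \code{"heavy"}).
#'
#' @export
setClass("FragmentExperiment",
         slots = c(fragments = "data.table", design = "data.frame"))

.validFragmentTable <- function(fr) {
    if (!all(.FRAGMENT_COLS %in% names(fr)))
        return(sprintf("fragment table lacks column(s): %s",
                       paste(setdiff(.FRAGMENT_COLS, names(fr)),
                             collapse = ", ")))
    bad <- which(!is.na(fr$intensity) & fr$intensity < 0)
    if (length(bad))
        return(sprintf("negative intensity at row %d", bad[1L]))
    if (anyDuplicated(fr, by = c("protein_id", "peptide_id", "fragment_id",
                                 "sample_id")))
        return("duplicate (protein, peptide, fragment, sample) key")
    TRUE
}

.validDesign <- function(d) {
    if (!all(.DESIGN_COLS %in% names(d)))
        return(sprintf("design lacks column(s): %s",
                       paste(setdiff(.DESIGN_COLS, names(d)), collapse = ", ")))
    if (anyDuplicated(d$sample_id))
        return("duplicate sample_id in design")
    if (!all(d$background %in% .BACKGROUNDS))
        return(sprintf("unknown background value(s): %s",
                       paste(unique(setdiff(d$background, .BACKGROUNDS)),
                             collapse = ", ")))
    if (!all(d$silac_channel %in% .SILAC_CHANNELS))
        return("unknown silac_channel value")
    if (any(is.na(d$time_min)) || any(d$time_min < 0))
        return("time_min must be non-negative")
    if (any(d$replicate < 1) || any(d$replicate != round(d$replicate)))
        return("replicate must be a positive integer")
    TRUE
}

setValidity("FragmentExperiment", function(object) {
    ok <- .validFragmentTable(object@fragments)
    if (!isTRUE(ok)) return(ok)
    ok <- .validDesign(object@design)
    if (!isTRUE(ok)) return(ok)
    orphan <- setdiff(unique(object@fragments$sample_id),
                      object@design$sample_id)
    if (length(orphan))
        return(sprintf("sample(s) absent from design: %s",
                       paste(head(orphan, 3L), collapse = ", ")))
    TRUE
})

#' Construct a FragmentExperiment
#'
#' @param fragments data.frame/data.table of fragment intensities (long
#'   format, see \linkS4class{FragmentExperiment}).
#' @param design data.frame of per-sample metadata.
#' @return A validated \linkS4class{FragmentExperiment}.
#' @examples
#' fr <- data.frame(protein_id = "P1", peptide_id = "PEPTIDEK",
#'                  fragment_id = "f1", sample_id = "s1", intensity = 1000)
#' de <- data.frame(sample_id = "s1", background = "tagged_bait",
#'                  condition = "stim", time_min = 0, replicate = 1,
#'                  silac_channel = "none")
#' FragmentExperiment(fr, de)
#' @export
FragmentExperiment <- function(fragments, design) {
    fragments <- as.data.table(fragments)
    design <- as.data.frame(design, stringsAsFactors = FALSE)
    new("FragmentExperiment", fragments = fragments, design = design)
}

#' @describeIn FragmentExperiment-class the fragment intensity table
#' @param object a \code{FragmentExperiment}
#' @export
setMethod("fragmentData", "FragmentExperiment",
          function(object, ...) copy(object@fragments))

#' @describeIn FragmentExperiment-class the sample design table
#' @export
setMethod("sampleDesign", "FragmentExperiment",
          function(object, ...) object@design)

setMethod("show", "FragmentExperiment", function(object) {
    fr <- object@fragments
    cat("FragmentExperiment\n")
    cat(sprintf("  %d fragment rows | %d proteins | %d peptides | %d samples\n",
                nrow(fr), length(unique(fr$protein_id)),
                length(unique(paste(fr$protein_id, fr$peptide_id))),
                nrow(object@design)))
    cat(sprintf("  missing intensities: %d (%.1f%%)\n",
                sum(is.na(fr$intensity)),
                100 * mean(is.na(fr$intensity))))
    gr <- groupLabel(object@design)
    cat(sprintf("  groups: %s\n", paste(unique(gr), collapse = ", ")))
})

# ---------------------------------------------------------------------------

#' Quantity matrix for peptides or proteins
#'
#' A \code{SummarizedExperiment} holding one analyte x sample quantity matrix
#' (assay \code{"quant"}) plus, after imputation, a logical assay
#' \code{"imputed"} marking filled-in entries. \code{rowData} carries
#' \code{protein_id} (and \code{peptide_id} at peptide level); \code{colData}
#' is the sample design.
#'
#' @slot scaleType one of \code{"raw"}, \code{"log2"},
#'   \code{"bait_normalized"}.
#' @slot level \code{"peptide"} or \code{"protein"}.
#' @export
setClass("QuantMatrix",
         contains = "SummarizedExperiment",
         slots = c(scaleType = "character", level = "character"))

setValidity("QuantMatrix", function(object) {
    if (!object@scaleType %in% c("raw", "log2", "bait_normalized"))
        return("scaleType must be raw, log2 or bait_normalized")
    if (!object@level %in% c("peptide", "protein"))
        return("level must be peptide or protein")
    if (!"quant" %in% names(assays(object)))
        return("assay 'quant' is required")
    if (!"protein_id" %in% names(rowData(object)))
        return("rowData must carry protein_id")
    if (object@level == "peptide" &&
        !"peptide_id" %in% names(rowData(object)))
        return("peptide-level rowData must carry peptide_id")
    q <- assay(object, "quant")
    if (object@scaleType != "log2" && any(q[!is.na(q)] < 0))
        return("raw-scale quantities must be non-negative")
    TRUE
})

#' Construct a QuantMatrix
#'
#' @param quant numeric matrix, analytes x samples; colnames are sample ids.
#' @param design sample design data.frame (subset/reordered to colnames).
#' @param level "peptide" or "protein".
#' @param scaleType "raw", "log2" or "bait_normalized".
#' @param rowData optional data.frame of row annotations; must contain
#'   \code{protein_id} (defaults to rownames for protein level).
#' @return A \linkS4class{QuantMatrix}.
#' @export
QuantMatrix <- function(quant, design, level = c("protein", "peptide"),
                        scaleType = "raw", rowData = NULL) {
    level <- match.arg(level)
    if (is.null(colnames(quant)))
        stop("quant must have sample ids as colnames")
    design <- as.data.frame(design)
    idx <- match(colnames(quant), design$sample_id)
    if (anyNA(idx))
        stop("samples in matrix absent from design: ",
             paste(colnames(quant)[is.na(idx)], collapse = ", "))
    if (is.null(rowData)) {
        if (level == "protein")
            rowData <- data.frame(protein_id = rownames(quant))
        else stop("peptide-level matrices need explicit rowData")
    }
    se <- SummarizedExperiment(assays = list(quant = quant),
                               rowData = DataFrame(rowData),
                               colData = DataFrame(design[idx, , drop = FALSE],
                                                   row.names = colnames(quant)))
    new("QuantMatrix", se, scaleType = scaleType, level = level)
}

#' @describeIn QuantMatrix-class the quantity matrix
#' @param object a \code{QuantMatrix}
#' @export
setMethod("quantData", "QuantMatrix",
          function(object, ...) assay(object, "quant"))

#' @describeIn QuantMatrix-class the scale flag
#' @export
setMethod("scaleType", "QuantMatrix", function(object) object@scaleType)

#' @describeIn QuantMatrix-class "peptide" or "protein"
#' @export
setMethod("quantLevel", "QuantMatrix", function(object) object@level)

#' @describeIn QuantMatrix-class the sample design stored in \code{colData}
#' @export
setMethod("sampleDesign", "QuantMatrix",
          function(object, ...) as.data.frame(colData(object)))

setMethod("show", "QuantMatrix", function(object) {
    q <- assay(object, "quant")
    cat(sprintf("QuantMatrix (%s level, %s scale)\n", object@level,
                object@scaleType))
    cat(sprintf("  %d analytes x %d samples, %d missing\n",
                nrow(q), ncol(q), sum(is.na(q))))
})
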