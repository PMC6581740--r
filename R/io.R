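#' @importFrom Biostrings readAAStringSet writeXStringSet AAStringSet width
NULL

.readTsv <- function(path, required, what) {
    if (!file.exists(path)) .stopf("%s file not found: %s", what, path)
    dt <- fread(path, sep = "\t", header = TRUE, na.strings = "",
                colClasses = NULL, showProgress = FALSE)
    miss <- setdiff(required, names(dt))
    if (length(miss))
        .stopf("%s file %s lacks required column(s): %s", what, path,
               paste(miss, collapse = ", "))
    dt
}

#' Read a long-format fragment intensity table
#'
#' Expects a TSV with header columns \code{protein_id}, \code{peptide_id},
#' \code{fragment_id}, \code{sample_id}, \code{intensity}. An empty intensity
#' cell encodes a missing (not detected) value; zeros are observed values.
#' Row order is preserved; duplicate (protein, peptide, fragment, sample)
#' keys and negative intensities are rejected.
#'
#' @param path path to the TSV file.
#' @return a validated \code{data.table} of fragment records.
#' @export
readFragmentTable <- function(path) {
    dt <- .readTsv(path, .FRAGMENT_COLS, "fragment table")
    dt[, `:=`(protein_id = as.character(protein_id),
              peptide_id = as.character(peptide_id),
              fragment_id = as.character(fragment_id),
              sample_id = as.character(sample_id),
              intensity = as.numeric(intensity))]
    ok <- .validFragmentTable(dt)
    if (!isTRUE(ok)) .stopf("invalid fragment table %s: %s", path, ok)
    dt[, .SD, .SDcols = .FRAGMENT_COLS]
}

#' Read a sample design table
#'
#' TSV with columns \code{sample_id}, \code{background}, \code{condition},
#' \code{time_min}, \code{replicate}, \code{silac_channel}. Enum fields are
#' checked (\code{background} in tagged_bait/untagged_control;
#' \code{silac_channel} in none/light/heavy) and duplicate sample ids are
#' rejected.
#'
#' @param path path to the TSV file.
#' @return a validated design \code{data.frame}.
#' @export
readSampleDesign <- function(path) {
    dt <- .readTsv(path, .DESIGN_COLS, "design")
    d <- as.data.frame(dt)
    d$sample_id <- as.character(d$sample_id)
    d$background <- as.character(d$background)
    d$condition <- as.character(d$condition)
    d$silac_channel <- as.character(d$silac_channel)
    d$time_min <- as.numeric(d$time_min)
    d$replicate <- as.integer(d$replicate)
    ok <- .validDesign(d)
    if (!isTRUE(ok)) .stopf("invalid design %s: %s", path, ok)
    d[, .DESIGN_COLS]
}

#' Read protein sequences from FASTA
#'
#' The first whitespace-delimited token of each header is the protein id.
#' Duplicate ids and empty sequences are rejected; sequences are uppercased.
#'
#' @param path path to a FASTA file.
#' @return named character vector, protein id to amino-acid sequence.
#' @export
readProteinFasta <- function(path) {
    aa <- readAAStringSet(path)
    ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L)
    if (anyDuplicated(ids))
        .stopf("duplicate protein id in FASTA: %s",
               ids[duplicated(ids)][1L])
    if (any(width(aa) == 0L))
        .stopf("empty sequence in FASTA for id: %s", ids[width(aa) == 0L][1L])
    setNames(toupper(as.character(aa)), ids)
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @export
writeProteinFasta <- function(sequences, path) {
    aa <- AAStringSet(sequences)
    writeXStringSet(aa, path, width = 60L)
    invisible(path)
}

#' Read a contaminant list file
#'
#' One identifier per line; lines ending in \code{*} are prefix rules
#' (e.g. \code{KRT*} matches every keratin). Blank lines and lines starting
#' with \code{#} are ignored.
#'
#' @param path path to the text file.
#' @return a \code{"ContaminantList"}.
#' @export
readContaminantList <- function(path) {
    ln <- trimws(readLines(path, warn = FALSE))
    ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
    if (!length(ln)) .stopf("contaminant list %s is empty", path)
    pref <- endsWith(ln, "*")
    contaminantList(ids = ln[!pref], prefixes = sub("\\*$", "", ln[pref]))
}

#' Write a fragment table (round-trip safe)
#'
#' Missing intensities are written as empty cells; doubles are written with
#' full round-trip precision so that read-after-write reproduces the table
#' exactly.
#'
#' @param fragments fragment \code{data.table}.
#' @param path output TSV path.
#' @export
writeFragmentTable <- function(fragments, path) {
    out <- as.data.table(fragments)
    # 17 significant digits: lossless text representation of doubles
    out[, intensity := ifelse(is.na(intensity), NA_character_,
                              sprintf("%.17g", intensity))]
    fwrite(out, path, sep = "\t", na = "", quote = FALSE, eol = "\n",
           scipen = 999)
    invisible(path)
}

#' @rdname writeFragmentTable
#' @param design sample design data.frame.
#' @export
writeSampleDesign <- function(design, path) {
    fwrite(as.data.table(design), path, sep = "\t", na = "", quote = FALSE,
           eol = "\n", scipen = 999)
    invisible(path)
}

#' Write pipeline result tables deterministically
#'
#' Each table is written as UTF-8 TSV with LF line endings and a fixed column
#' order. Tables carrying a \code{q_value} column are sorted by (q_value
#' ascending, protein_id lexicographic); other tables with a
#' \code{protein_id} column are sorted by protein_id, so repeated runs on the
#' same inputs produce byte-identical files.
#'
#' @param tables named list of data.frames/data.tables.
#' @param outDir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
writeResultTables <- function(tables, outDir) {
    if (!dir.exists(outDir)) {
        ok <- dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
        if (!ok && !dir.exists(outDir))
            .stopf("cannot create output directory %s", outDir)
    }
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
        .stopf("tables must be a named list")
    paths <- character(0)
    for (nm in names(tables)) {
        dt <- as.data.table(tables[[nm]])
        if ("q_value" %in% names(dt) && "protein_id" %in% names(dt)) {
            setorderv(dt, c("q_value", "protein_id"))
        } else if ("protein_id" %in% names(dt)) {
            setorderv(dt, intersect(c("protein_id", "peptide_id", "sample_id"),
                                    names(dt)))
        }
        p <- file.path(outDir, paste0(nm, ".tsv"))
        fwrite(dt, p, sep = "\t", na = "", quote = FALSE, eol = "\n",
               scipen = 999)
        paths <- c(paths, p)
    }
    invisible(paths)
}
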